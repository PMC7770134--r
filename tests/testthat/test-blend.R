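test_that("charge blending applies the stated proportions and preserves caps and net charge", {
  qa <- charge_set(c(0.6, -0.6), 0L, c("SIDECHAIN", "SIDECHAIN"))
  qb <- charge_set(c(0.0, 0.0), 0L, c("SIDECHAIN", "SIDECHAIN"))
  # beta/6 + alpha*5/6 proportion on toy charges
  out <- blend_charges(qa, qb, blend_spec(w_beta = 1 / 6))
  expect_equal(out$charges, c(0.5, -0.5), tolerance = 1e-12)
  # identity weight
  expect_equal(blend_charges(qa, qb, blend_spec(w_alpha = 1))$charges,
               qa$charges)
  # frozen cap atoms keep reference values; net charge exact
  fx <- make_toy_dipeptide(5)
  bl <- blend_charges(fx$q_alpha, fx$q_beta, blend_spec(w_beta = 0.5))
  caps <- fx$q_alpha$groups %in% c("ACE", "NME")
  expect_identical(bl$charges[caps], fx$q_alpha$charges[caps])
  expect_equal(sum(bl$charges), 0, tolerance = 1e-12)
  expect_error(blend_charges(qa, charge_set(c(1, 0), 1L), blend_spec(0.5)),
               "net charges")
})

test_that("rms deviation follows its definition under both divisor conventions", {
  x <- c(1, 2, 3, 4); y <- c(1.5, 1.5, 3.5, 3.5)
  expect_equal(rms_deviation(x, x), 0)
  expect_equal(rms_deviation(x, y, "n"), sqrt(sum((x - y)^2) / 4))
  expect_equal(rms_deviation(x, y, "n_minus_1"), sqrt(sum((x - y)^2) / 3))
  expect_equal(rms_deviation(x, y), rms_deviation(y, x))
  # differences scale linearly
  expect_equal(rms_deviation(2 * x, 2 * y, "n"),
               2 * rms_deviation(x, y, "n"))
  expect_error(rms_deviation(x, y[1:3]), "mismatch")
})

test_that("squared Pearson correlation is affine-invariant and exact for linear data", {
  x <- c(1, 2, 4, 7, 11)
  expect_equal(pearson_r2(x, 2 * x + 1), 1.0)
  set.seed(41)
  y <- x + rnorm(5)
  expect_equal(pearson_r2(x, y), pearson_r2(3 * x - 2, -0.5 * y + 4),
               tolerance = 1e-12)
  expect_error(pearson_r2(x, rep(1, 5)), "variance")
})

test_that("per-system weight search matches an exhaustive scan and beats any fixed weight", {
  # synthetic systems whose model RE is exactly linear in w_beta
  slopes <- c(2, -3, 1.5); intercepts <- c(5, 7, 6)
  mk_sys <- function(s) {
    fx <- make_toy_dipeptide(s, system_id = s)
    list(pair = fx$pair, q_alpha = fx$q_alpha, q_beta = fx$q_beta,
         params = fx$params, slope = slopes[s], icept = intercepts[s])
  }
  systems <- lapply(1:3, mk_sys)
  evaluator <- function(pair, params, charges) {
    s <- pair$system_id
    # recover w_beta from the blended side-chain charge (linear in w)
    qa <- systems[[s]]$q_alpha$charges[6]; qb <- systems[[s]]$q_beta$charges[6]
    w <- (charges$charges[6] - qa) / (qb - qa)
    intercepts[s] + slopes[s] * w
  }
  bench <- c(5.6, 5.2, 7.1)
  grid <- seq(0, 1, by = 0.1)
  opt <- optimize_blend(systems, bench, weights_beta = grid,
                        evaluator = evaluator)
  brute <- vapply(1:3, function(s) {
    errs <- abs(intercepts[s] + slopes[s] * grid - bench[s])
    max(grid[errs <= min(errs) + 1e-12])  # ties toward beta
  }, numeric(1))
  expect_equal(opt$selection$w_beta, brute)
  # optimized per-system RMS never exceeds any fixed single weight
  for (w in grid) {
    fixed_re <- intercepts + slopes * w
    expect_lte(opt$global_rms,
               rms_deviation(fixed_re, bench) + 1e-12)
  }
  # constructed optimum at pure beta
  bench_beta <- intercepts + slopes  # RE at w_beta = 1
  opt2 <- optimize_blend(systems, bench_beta, weights_beta = grid,
                         evaluator = evaluator)
  expect_true(all(opt2$selection$w_beta == 1))
  expect_equal(opt2$global_rms, 0, tolerance = 1e-12)
})

test_that("the default candidate grid contains the published blend fractions", {
  w <- default_blend_weights()
  expect_true(all(c(1, 1 / 2, 1 / 3, 1 / 5, 1 / 6, 7 / 8, 0) %in% w))
  expect_error(optimize_blend(list(), numeric(0), weights_beta = numeric(0)),
               "empty candidate")
})
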