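test_that("point-charge ESP obeys the Coulomb law, superposition and the singularity guard", {
  expect_equal(esp_from_point_charges(c(0, 0), rbind(c(0, 0, 0), c(2, 0, 0)),
                                      rbind(c(1, 1, 1))), 0)
  expect_equal(esp_from_point_charges(1, matrix(0, 1, 3), rbind(c(1, 0, 0))),
               1.0)
  set.seed(21)
  pts <- matrix(rnorm(30, sd = 4), 10, 3)
  ac <- rbind(c(0.3, 0, 0), c(-0.4, 0.2, 0))
  v12 <- esp_from_point_charges(c(0.7, -0.2), ac, pts)
  v1 <- esp_from_point_charges(c(0.7, 0), ac, pts)
  v2 <- esp_from_point_charges(c(0, -0.2), ac, pts)
  expect_equal(v12, v1 + v2, tolerance = 1e-12)
  expect_error(esp_from_point_charges(1, matrix(0, 1, 3), matrix(1e-8, 1, 3)),
               "singular")
})

test_that("shell grids sit on scaled vdW spheres, cull interior points and are seed-deterministic", {
  bohr <- uaaff_constants()$bohr_to_angstrom
  g <- build_mk_grid(matrix(0, 1, 3), "C", shells = 1.4, density = 1,
                     seed = 3)
  d <- sqrt(rowSums(g$points^2)) * bohr
  expect_equal(d, rep(1.4 * 1.7, g$n_points), tolerance = 1e-9)
  # two overlapping atoms: no retained point inside either scaled sphere
  coords <- rbind(c(0, 0, 0), c(1.2, 0, 0))
  g2 <- build_mk_grid(coords, c("C", "O"), shells = c(1.4, 1.6), seed = 5)
  pa <- g2$points * bohr
  d1 <- sqrt(rowSums(sweep(pa, 2, coords[1, ])^2))
  d2 <- sqrt(rowSums(sweep(pa, 2, coords[2, ])^2))
  expect_true(all(d1 >= 1.4 * 1.7 - 1e-9 | d2 >= 1.4 * 1.52 - 1e-9))
  expect_true(all(pmin(d1 / 1.7, d2 / 1.52) >= 1.4 - 1e-9))
  # determinism across runs
  g3 <- build_mk_grid(coords, c("C", "O"), shells = c(1.4, 1.6), seed = 5)
  expect_identical(g2$points, g3$points)
  expect_error(build_mk_grid(matrix(0, 0, 3), character(0)), "empty")
})

test_that("unrestrained fitting recovers generating charges and matches the constrained OLS oracle", {
  for (seed in c(5, 17)) {
    pr <- make_esp_recovery_problem(seed, 4)
    fit <- resp_fit(pr$grid, pr$coords_bohr,
                    resp_options(restraint_a = 0, net_charge = 0),
                    elements = pr$elements)
    expect_lt(max(abs(coef(fit) - pr$hidden$charges)), 1e-8)
    expect_lt(fit$rrms, 1e-6)
    expect_lt(abs(sum(coef(fit)) - 0), 1e-10)
    q_oracle <- oracle_ols_charges(pr$grid$points, pr$grid$values,
                                   pr$coords_bohr, 0)
    expect_equal(unname(coef(fit)), unname(q_oracle), tolerance = 1e-8)
  }
  # zero hidden charges come back as zeros
  pr0 <- make_esp_recovery_problem(8, 3)
  pr0$grid$values <- pr0$grid$values * 0
  f0 <- resp_fit(pr0$grid, pr0$coords_bohr,
                 resp_options(restraint_a = 0, net_charge = 0),
                 elements = pr0$elements)
  expect_lt(max(abs(coef(f0))), 1e-10)
})

test_that("net-charge, equivalence and frozen-atom constraints hold exactly", {
  pr <- make_esp_recovery_problem(9, 5)
  f <- resp_fit(pr$grid, pr$coords_bohr,
                resp_options(restraint_a = 5e-4, net_charge = 0,
                             equivalence_classes = list(c(2L, 4L))),
                elements = pr$elements)
  expect_lt(abs(sum(coef(f))), 1e-10)
  expect_identical(coef(f)[2], coef(f)[4])
  fz <- resp_fit(pr$grid, pr$coords_bohr,
                 resp_options(restraint_a = 0, net_charge = 0,
                              frozen = c("1" = 0.25)),
                 elements = pr$elements)
  expect_identical(coef(fz)[1], 0.25)
  expect_lt(abs(sum(coef(fz))), 1e-10)
  expect_error(resp_options(equivalence_classes = list(c(1L, 2L), c(2L, 3L))),
               "disjoint")
})

test_that("the hyperbolic restraint shrinks restrained charges monotonically and spares hydrogens", {
  pr <- make_esp_recovery_problem(9, 5)
  prev <- Inf
  for (a in c(0, 1e-4, 1e-3, 1e-2, 1e-1)) {
    f <- resp_fit(pr$grid, pr$coords_bohr,
                  resp_options(restraint_a = a, net_charge = 0),
                  elements = pr$elements)
    s <- sum(abs(coef(f)[pr$elements != "H"]))
    expect_lte(s, prev + 1e-12)
    prev <- s
  }
})

test_that("fitting is invariant under a joint rigid transform of atoms and grid", {
  pr <- make_esp_recovery_problem(9, 5)
  opts <- resp_options(restraint_a = 5e-4, net_charge = 0)
  f0 <- resp_fit(pr$grid, pr$coords_bohr, opts, pr$elements)
  R <- rotation_about("z", 37)
  g2 <- esp_grid(rigid_transform(pr$grid$points, R, c(1, 2, 3)),
                 pr$grid$values)
  f1 <- resp_fit(g2, rigid_transform(pr$coords_bohr, R, c(1, 2, 3)),
                 opts, pr$elements)
  expect_equal(coef(f0), coef(f1), tolerance = 1e-10)
})

test_that("the two-stage protocol freezes stage-1 charges outside the refit set", {
  pr <- make_esp_recovery_problem(9, 5)
  ts <- resp_two_stage(pr$grid, pr$coords_bohr, pr$elements,
                       refit_atoms = c(2L, 4L),
                       equivalence_classes_stage2 = list(c(2L, 4L)),
                       net_charge = 0)
  expect_identical(coef(ts)[2], coef(ts)[4])
  keep <- c(1, 3, 5)
  expect_identical(coef(ts)[keep], coef(ts$stage1)[keep])
  expect_lt(abs(sum(coef(ts))), 1e-10)
})

test_that("resp_fit model methods are consistent", {
  pr <- make_esp_recovery_problem(5, 4)
  fit <- resp_fit(pr$grid, pr$coords_bohr,
                  resp_options(restraint_a = 0, net_charge = 0),
                  elements = pr$elements)
  expect_equal(fitted(fit) + residuals(fit), pr$grid$values)
  expect_equal(predict(fit), fitted(fit))
  newp <- pr$grid$points[1:5, ] * 1.1
  expect_equal(predict(fit, newp),
               esp_from_point_charges(coef(fit), pr$coords_bohr, newp))
})
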