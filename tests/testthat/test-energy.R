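lj0 <- function(n) data.frame(rmin2 = rep(0, n), eps = rep(0, n))
all_excl <- function(n) t(combn(n, 2))

test_that("each term matches its closed form", {
  # bond: K (r - r_eq)^2 with K = 100, displacement 0.1
  p <- ff_params(bonds = data.frame(i = 1, j = 2, k_r = 100, r_eq = 1.5),
                 lj = lj0(2), exclusions = rbind(c(1, 2)))
  e <- energy(rbind(c(0, 0, 0), c(1.6, 0, 0)), p, c(0, 0))
  expect_equal(e$e_bond, 1.0, tolerance = 1e-12)
  expect_equal(e$e_total, 1.0, tolerance = 1e-12)
  # dihedral: (V/2)(1 + cos 0) with V = 2 at phi = 0
  x <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
  pd <- ff_params(dihedrals = data.frame(i = 1, j = 2, k = 3, l = 4,
                                         v_n = 2, n = 1, gamma = 0),
                  lj = lj0(4), exclusions = all_excl(4))
  expect_equal(energy(x, pd, rep(0, 4))$e_dihedral, 2.0, tolerance = 1e-12)
  # Coulomb pair: 332.0637 * 0.25 / 3
  pc <- ff_params(lj = lj0(2))
  ec <- energy(rbind(c(0, 0, 0), c(3, 0, 0)), pc, c(0.5, 0.5))
  expect_equal(ec$e_es, 332.0637 * 0.25 / 3.0, tolerance = 1e-12)
  expect_equal(ec$e_vdw, 0)
  # breakdown sums to total
  fx <- make_toy_dipeptide(4)
  br <- energy(fx$pair$alpha, fx$params, fx$q_alpha)
  expect_equal(br$e_total,
               br$e_bond + br$e_angle + br$e_dihedral + br$e_es + br$e_vdw,
               tolerance = 1e-9)
})

test_that("1-4 pairs are scaled by the ff14SB factors", {
  x <- rbind(c(0, 0, 0), c(4, 0, 0))
  base <- ff_params(lj = data.frame(rmin2 = c(1.9, 1.9), eps = c(0.1, 0.1)))
  p14 <- ff_params(lj = data.frame(rmin2 = c(1.9, 1.9), eps = c(0.1, 0.1)),
                   pairs14 = rbind(c(1, 2)))
  q <- c(0.3, -0.2)
  e0 <- energy(x, base, q); e1 <- energy(x, p14, q)
  expect_equal(e1$e_es, e0$e_es / 1.2, tolerance = 1e-12)
  expect_equal(e1$e_vdw, e0$e_vdw / 2.0, tolerance = 1e-12)
})

test_that("energy is invariant under rigid transforms and consistent atom re-indexing", {
  fx <- make_toy_dipeptide(4)
  e0 <- energy(fx$pair$alpha, fx$params, fx$q_alpha)$e_total
  cf <- fx$pair$alpha
  cf$xyz <- rigid_transform(cf$xyz, rotation_about("x", 71), c(5, -2, 9))
  expect_equal(energy(cf, fx$params, fx$q_alpha)$e_total, e0,
               tolerance = 1e-9)
  # permute atoms and remap every index consistently
  set.seed(31)
  perm <- sample(14)           # perm[old] = new position
  inv <- order(perm)
  cp <- fx$pair$alpha
  cp$atoms <- cp$atoms[inv, ]
  cp$xyz <- cp$xyz[inv, ]
  remap <- function(ii) perm[ii]
  p <- fx$params
  p$bonds[, c("i", "j")] <- lapply(p$bonds[, c("i", "j")], remap)
  p$angles[, c("i", "j", "k")] <- lapply(p$angles[, c("i", "j", "k")], remap)
  p$dihedrals[, c("i", "j", "k", "l")] <-
    lapply(p$dihedrals[, c("i", "j", "k", "l")], remap)
  p$lj <- p$lj[inv, ]
  p$exclusions <- matrix(remap(p$exclusions), ncol = 2)
  p$pairs14 <- matrix(remap(p$pairs14), ncol = 2)
  expect_equal(energy(cp, p, fx$q_alpha$charges[inv])$e_total, e0,
               tolerance = 1e-9)
})

test_that("electrostatics is quadratic in charges and vdW vanishes with zero epsilon", {
  fx <- make_toy_dipeptide(4)
  e1 <- energy(fx$pair$alpha, fx$params, fx$q_alpha$charges)
  e2 <- energy(fx$pair$alpha, fx$params, 2 * fx$q_alpha$charges)
  expect_equal(e2$e_es, 4 * e1$e_es, tolerance = 1e-9)
  p0 <- fx$params
  p0$lj$eps[] <- 0
  expect_equal(energy(fx$pair$alpha, p0, fx$q_alpha)$e_vdw, 0)
})

test_that("analytic gradients match central finite differences on random toy systems", {
  set.seed(32)
  fx <- make_toy_dipeptide(6)
  restr <- list(list(atoms = fx$torsions$phi, target = -60, k = 100))
  xyz <- fx$pair$alpha$xyz + matrix(rnorm(42, sd = 0.05), 14, 3)
  ana <- energy_gradient(conformer(fx$pair$alpha$atoms, xyz), fx$params,
                         fx$q_alpha, restraints = restr)$gradient
  h <- 1e-6
  num <- matrix(0, 14, 3)
  for (i in 1:14) for (d in 1:3) {
    xp <- xyz; xp[i, d] <- xp[i, d] + h
    xm <- xyz; xm[i, d] <- xm[i, d] - h
    ep <- energy_gradient(conformer(fx$pair$alpha$atoms, xp), fx$params,
                          fx$q_alpha, restraints = restr)$objective
    em <- energy_gradient(conformer(fx$pair$alpha$atoms, xm), fx$params,
                          fx$q_alpha, restraints = restr)$objective
    num[i, d] <- (ep - em) / (2 * h)
  }
  expect_lt(max(abs(ana - num)) / max(abs(num)), 1e-6)
})

test_that("minimization honors fixed points, 1-D closed forms and torsion restraints", {
  # diatomic: converges to r_eq from a stretched start
  atoms2 <- data.frame(name = c("C1", "C2"), element = c("C", "C"),
                       resname = "LIG", resindex = 1)
  p2 <- ff_params(bonds = data.frame(i = 1, j = 2, k_r = 100, r_eq = 1.5),
                  lj = lj0(2), exclusions = rbind(c(1, 2)))
  m <- minimize(conformer(atoms2, rbind(c(0, 0, 0), c(1.8, 0, 0))), p2,
                c(0, 0), gtol = 1e-8)
  expect_true(m$converged)
  expect_equal(sqrt(sum((m$conformer$xyz[1, ] - m$conformer$xyz[2, ])^2)),
               1.5, tolerance = 1e-5)
  # exact minimum is a fixed point
  m2 <- minimize(m$conformer, p2, c(0, 0), gtol = 1e-6)
  expect_identical(m2$conformer$xyz, m$conformer$xyz)
  expect_true(m2$converged)
  # a k = 100 kcal/(mol rad^2) torsion restraint dominates a Fourier term
  # whose unrestrained minimum lies at 180 degrees
  atoms4 <- data.frame(name = paste0("C", 1:4), element = "C",
                       resname = "LIG", resindex = 1)
  x4 <- rbind(c(0, 1.4, 0), c(0, 0, 0), c(1.5, 0, 0), c(1.5, 1.0, 1.0))
  p4 <- ff_params(dihedrals = data.frame(i = 1, j = 2, k = 3, l = 4,
                                         v_n = 2, n = 1, gamma = 0),
                  lj = lj0(4), exclusions = all_excl(4))
  mt <- minimize(conformer(atoms4, x4), p4, rep(0, 4),
                 restraints = list(list(atoms = 1:4, target = -60, k = 100)),
                 gtol = 1e-7)
  expect_true(mt$converged)
  expect_lt(abs(measure_dihedral(mt$conformer, 1, 2, 3, 4) - (-60)), 1)
  # on the full dipeptide the restrained backbone settles near its targets
  fx <- make_toy_dipeptide(4)
  mr <- minimize(fx$pair$alpha, fx$params, fx$q_alpha,
                 restraints = list(
                   list(atoms = fx$torsions$phi, target = -60, k = 100),
                   list(atoms = fx$torsions$psi, target = -40, k = 100)),
                 gtol = 1e-5)
  expect_lt(abs(mr$conformer$phi - (-60)), 3)
  expect_lt(abs(mr$conformer$psi - (-40)), 3)
  expect_lte(utils::tail(mr$trace, 1), mr$trace[1] + 1e-12)
})

test_that("relative energy is zero for identical or rigidly shifted conformers and matches a term-wise sum", {
  fx <- make_toy_dipeptide(4)
  same <- conformer_pair(1, fx$pair$alpha, fx$pair$alpha)
  expect_equal(relative_energy(same, fx$params, fx$q_alpha,
                               mode = "single_point"), 0)
  shifted <- fx$pair$alpha
  shifted$xyz <- rigid_transform(shifted$xyz, rotation_about("y", 33),
                                 c(1, 1, 1))
  pr <- conformer_pair(1, fx$pair$alpha, shifted)
  expect_equal(relative_energy(pr, fx$params, fx$q_alpha,
                               mode = "single_point"), 0, tolerance = 1e-9)
  # term-wise oracle on the real pair
  ea <- energy(fx$pair$alpha, fx$params, fx$q_alpha)
  eb <- energy(fx$pair$beta, fx$params, fx$q_alpha)
  byhand <- (ea$e_bond - eb$e_bond) + (ea$e_angle - eb$e_angle) +
    (ea$e_dihedral - eb$e_dihedral) + (ea$e_es - eb$e_es) +
    (ea$e_vdw - eb$e_vdw)
  expect_equal(relative_energy(fx$pair, fx$params, fx$q_alpha,
                               mode = "single_point"), byhand,
               tolerance = 1e-9)
})
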