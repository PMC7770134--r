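born_exact <- function(q, R, ei, eo) {
  kc <- uaaff_constants()$coulomb_kcal
  -(kc / 2) * (1 / ei - 1 / eo) * q^2 / R
}

test_that("the PB solver reproduces the Born ion and the null cases", {
  opt <- pbsa_options(ionic_strength = 0, grid_spacing = 0.5)
  r <- solve_pb(matrix(0, 1, 3), 1, 2.0, opt)
  expect_lt(abs(r$energy / born_exact(1, 2, 1, 80) - 1), 0.05)
  # no dielectric contrast and no charge both give zero
  flat <- pbsa_options(eps_solute = 80, eps_solvent = 80,
                       ionic_strength = 0, grid_spacing = 0.5)
  expect_equal(solve_pb(matrix(0, 1, 3), 1, 2.0, flat)$energy, 0,
               tolerance = 1e-6)
  expect_equal(solve_pb(matrix(0, 1, 3), 0, 2.0, opt)$energy, 0)
})

test_that("Born-ion error decreases under grid refinement", {
  errs <- vapply(c(0.8, 0.5, 0.35), function(h) {
    o <- pbsa_options(ionic_strength = 0, grid_spacing = h)
    abs(solve_pb(matrix(0, 1, 3), 1, 2.0, o)$energy /
          born_exact(1, 2, 1, 80) - 1)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("PB solvation is rigid-invariant up to grid-placement noise", {
  opt <- pbsa_options(ionic_strength = 0, grid_spacing = 0.5,
                      grid_padding = 8)
  xyz <- rbind(c(0, 0, 0), c(2.5, 0.4, -0.3))
  q <- c(0.5, -0.5); rad <- c(1.8, 1.6)
  e0 <- solve_pb(xyz, q, rad, opt)$energy
  x2 <- rigid_transform(xyz, rotation_about("z", 53), c(0.17, -0.29, 0.11))
  e1 <- solve_pb(x2, q, rad, opt)$energy
  expect_lt(abs(e1 / e0 - 1), 0.02)
})

test_that("SASA matches analytic spheres, burial and additivity, and is stable in point count", {
  s <- sasa(matrix(0, 1, 3), 1.9, 1.4, 960)
  expect_lt(abs(s$total / (4 * pi * 3.3^2) - 1), 0.01)
  far <- sasa(rbind(c(0, 0, 0), c(0, 0, 50)), c(1.9, 1.9), 1.4, 960)
  expect_equal(far$total, 4 * pi * 3.3^2 * 2, tolerance = 1e-9)
  buried <- sasa(rbind(c(0, 0, 0), c(0, 0, 0.1)), c(1.0, 3.0), 1.4, 960)
  expect_equal(buried$per_atom[1], 0)
  set.seed(51)
  xyz <- matrix(rnorm(15, sd = 2), 5, 3)
  rad <- runif(5, 1.4, 2.0)
  a1 <- sasa(xyz, rad, 1.4, 480)$total
  a2 <- sasa(xyz, rad, 1.4, 960)$total
  expect_lt(abs(a2 / a1 - 1), 0.005)
})

test_that("the nonpolar model is the stated linear form in the surface area", {
  expect_equal(nonpolar_solvation(0), 0.92)
  expect_equal(nonpolar_solvation(100), 0.00542 * 100 + 0.92)
  o2 <- pbsa_options(gamma = 2 * 0.00542)
  expect_equal(nonpolar_solvation(100, o2) - 0.92,
               2 * (nonpolar_solvation(100) - 0.92))
})

test_that("binding energies satisfy their accounting identities and the single-trajectory limits", {
  fx <- make_binding_complex(11, n_res = 3, n_snapshots = 3)
  be <- binding_energy(fx$snapshots, fx$ligand_atoms, coarse_pbsa(),
                       fx$params, fx$charges, fx$radii)
  s <- be$summary; rownames(s) <- s$component
  expect_equal(s["de_mm", "mean"], s["de_vdw", "mean"] + s["de_ele", "mean"],
               tolerance = 1e-9)
  expect_equal(s["dg_solv", "mean"],
               s["dg_pb_solv", "mean"] + s["dg_np_solv", "mean"],
               tolerance = 1e-9)
  expect_equal(s["dg_bind", "mean"], s["de_mm", "mean"] + s["dg_solv", "mean"],
               tolerance = 1e-9)
  expect_equal(unname(colMeans(be$per_snapshot)), s$mean, tolerance = 1e-12)
  # the population-SD convention, checked on {1,2,3}
  expect_equal(uaaff:::.sd_pop(c(1, 2, 3)), sqrt(2 / 3))
  # non-interacting ligand: MM term vanishes; one snapshot: all SDs zero
  fi <- make_binding_complex(11, n_res = 3, n_snapshots = 1,
                             inert_ligand = TRUE)
  bi <- binding_energy(fi$snapshots, fi$ligand_atoms, coarse_pbsa(),
                       fi$params, fi$charges, fi$radii)
  si <- bi$summary; rownames(si) <- si$component
  expect_equal(si["de_mm", "mean"], 0)
  expect_true(all(si$sd == 0))
})

test_that("a two-point-charge snapshot gives the closed-form Coulomb cross term", {
  atoms <- data.frame(name = c("A", "B"), element = c("C", "C"),
                      resname = c("REC", "LIG"), resindex = c(1, 2))
  cf <- conformer(atoms, rbind(c(0, 0, 0), c(4, 0, 0)))
  p <- ff_params(lj = data.frame(rmin2 = c(0, 0), eps = c(0, 0)))
  opt <- pbsa_options(eps_solute = 1, eps_solvent = 1, ionic_strength = 0,
                      grid_spacing = 0.8, grid_padding = 6,
                      sasa_points = 120)
  be <- binding_energy(cf, 2L, opt, p, c(1, -1), radii = c(1.7, 1.7))
  s <- be$summary; rownames(s) <- s$component
  expect_equal(s["de_ele", "mean"], -332.0637 / 4, tolerance = 1e-9)
  expect_equal(s["dg_pb_solv", "mean"], 0, tolerance = 1e-6)
})

test_that("an infinitely separated ligand contributes no interaction energy or buried area", {
  fx <- make_binding_complex(12, n_res = 2, n_snapshots = 1)
  cf <- fx$snapshots[[1]]
  cf$xyz[fx$ligand_atoms, ] <- cf$xyz[fx$ligand_atoms, ] +
    matrix(rep(c(0, 0, 1e5), each = 2), 2, 3)
  mm <- uaaff:::.cross_mm(cf$xyz, fx$charges$charges, fx$params$lj,
                          setdiff(1:6, fx$ligand_atoms), fx$ligand_atoms)
  expect_lt(abs(mm$e_es) + abs(mm$e_vdw), 1e-3)
  rec <- setdiff(1:6, fx$ligand_atoms)
  sc <- sasa(cf$xyz, fx$radii, 1.4, 240)$total
  sr <- sasa(cf$xyz[rec, ], fx$radii[rec], 1.4, 240)$total
  sl <- sasa(cf$xyz[fx$ligand_atoms, ], fx$radii[fx$ligand_atoms], 1.4,
             240)$total
  expect_equal(sc, sr + sl, tolerance = 1e-9)
})

test_that("per-residue decomposition conserves every global component", {
  fx <- make_binding_complex(11, n_res = 3, n_snapshots = 1)
  dec <- per_residue_decomposition(fx$snapshots[[1]], fx$ligand_atoms,
                                   coarse_pbsa(), fx$params, fx$charges,
                                   fx$radii)
  tt <- attr(dec, "totals")
  expect_equal(sum(dec$de_mm_res), unname(tt["de_mm"]), tolerance = 1e-6)
  expect_equal(sum(dec$dg_pb_res), unname(tt["dg_pb"]), tolerance = 1e-6)
  expect_equal(sum(dec$dg_np_res), unname(tt["dg_np"]), tolerance = 1e-6)
  expect_equal(sum(dec$total_res), unname(sum(tt)), tolerance = 1e-6)
  # a one-residue receptor puts the whole receptor share in one bucket
  expect_setequal(dec$role, c("receptor", "ligand"))
})
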