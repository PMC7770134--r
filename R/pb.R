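#' MM/PBSA options
#'
#' Constants of the implicit-solvent model: solute/solvent dielectrics 1 and
#' 80, 300 K, 0.5 Angstrom finite-difference grid, 0.1 M monovalent salt
#' with Na+/Cl- radii 0.95/1.81 Angstrom, a 1.4 Angstrom SASA probe, and the
#' nonpolar model gamma*SASA + b with gamma = 0.00542 kcal/(mol*A^2) and
#' b = 0.92 kcal/mol.
#'
#' @param eps_solute,eps_solvent relative dielectric constants.
#' @param temperature K.
#' @param grid_spacing finite-difference spacing, Angstrom.
#' @param ionic_strength molar concentration of 1:1 salt.
#' @param ion_radii named vector of ion radii (Angstrom) defining per-species
#'   Stern exclusion layers.
#' @param probe_radius SASA probe, Angstrom.
#' @param gamma,b_const nonpolar model constants, kcal/(mol*A^2) and
#'   kcal/mol.
#' @param grid_padding clearance between solute surface and box faces,
#'   Angstrom.
#' @param sasa_points Shrake-Rupley points per atom.
#' @param pb_tol relative-residual convergence target of the SOR iteration.
#' @param pb_maxit iteration cap.
#' @return object of class `"pbsa_options"`.
#' @export
pbsa_options <- function(eps_solute = 1, eps_solvent = 80, temperature = 300,
                         grid_spacing = 0.5, ionic_strength = 0.1,
                         ion_radii = c(Na = 0.95, Cl = 1.81),
                         probe_radius = 1.4, gamma = 0.00542, b_const = 0.92,
                         grid_padding = 10, sasa_points = 960L,
                         pb_tol = 1e-6, pb_maxit = 10000L) {
  stopifnot(eps_solvent >= eps_solute, eps_solute >= 1, grid_spacing > 0,
            grid_padding >= grid_spacing, sasa_points >= 8)
  structure(list(eps_solute = eps_solute, eps_solvent = eps_solvent,
                 temperature = temperature, grid_spacing = grid_spacing,
                 ionic_strength = ionic_strength, ion_radii = ion_radii,
                 probe_radius = probe_radius, gamma = gamma,
                 b_const = b_const, grid_padding = grid_padding,
                 sasa_points = as.integer(sasa_points),
                 pb_tol = pb_tol, pb_maxit = as.integer(pb_maxit)),
            class = "pbsa_options")
}

# inverse Debye screening parameter kappa (1/Angstrom) in the solvent
.kappa_inv_ang <- function(options) {
  if (options$ionic_strength <= 0) return(0)
  kc <- uaaff_constants()$coulomb_kcal
  rt <- 0.0019872041 * options$temperature
  conc <- options$ionic_strength * 6.0221408e-4  # mol/L -> ions/A^3
  # 1:1 electrolyte: sum over species of z^2 c = 2 * conc
  sqrt(8 * pi * kc * conc / (options$eps_solvent * rt))
}

# Debye-Hueckel (kappa = 0: Coulomb) potential of the charges at arbitrary
# points, used as Dirichlet boundary condition and initial guess.
.dh_potential <- function(points, xyz, charges, eps, kappa) {
  kc <- uaaff_constants()$coulomb_kcal
  v <- numeric(nrow(points))
  for (a in seq_len(nrow(xyz))) {
    if (charges[a] == 0) next
    d <- sqrt(rowSums(sweep(points, 2, xyz[a, ])^2))
    d <- pmax(d, 1e-6)
    v <- v + kc * charges[a] * exp(-kappa * d) / (eps * d)
  }
  v
}

#' Finite-difference linearized Poisson-Boltzmann solvation energy
#'
#' Solves the linearized PB equation on a cubic grid by red-black successive
#' over-relaxation. The dielectric map is built from the van der Waals
#' surface of the solute (nodes inside any atomic sphere take the solute
#' dielectric) with harmonic-mean smoothing on grid edges. Debye screening
#' acts outside a per-species Stern layer (atom radius + ion radius) and the
#' box faces carry a Debye-Hueckel analytic boundary condition. The
#' electrostatic solvation energy is
#' \deqn{\Delta G = \tfrac12 \sum_i q_i \phi_\mathrm{reac}(r_i)}
#' where the reaction potential is the solvated-grid potential minus a
#' uniform-solute-dielectric reference solved on the identical grid, so the
#' discrete Coulomb self-energy cancels by subtraction.
#'
#' @param xyz n x 3 coordinates, Angstrom (or a `conformer`).
#' @param charges numeric vector or `charge_set`, e.
#' @param radii per-atom radii, Angstrom (e.g. from [vdw_radii()]).
#' @param options a `pbsa_options`.
#' @return list: `energy` (kcal/mol), `phi_reaction` (per-atom reaction
#'   potential, kcal/(mol*e)), `dims`, `iterations`, `residual` for both
#'   solves.
#' @export
solve_pb <- function(xyz, charges, radii, options = pbsa_options()) {
  if (inherits(xyz, "conformer")) xyz <- xyz$xyz
  xyz <- as.matrix(xyz)
  if (inherits(charges, "charge_set")) charges <- charges$charges
  n <- nrow(xyz)
  stopifnot(length(charges) == n, length(radii) == n, all(radii > 0))
  h <- options$grid_spacing
  kc <- uaaff_constants()$coulomb_kcal

  center <- (apply(xyz, 2, max) + apply(xyz, 2, min)) / 2
  half <- max(sweep(abs(sweep(xyz, 2, center)), 1, radii, "+")) +
    options$grid_padding
  m <- as.integer(ceiling(half / h))
  if (m < 2) stop("grid too small: increase padding")
  nn <- 2L * m + 1L
  ax <- center[1] + (-m:m) * h
  ay <- center[2] + (-m:m) * h
  az <- center[3] + (-m:m) * h

  # node-inside masks per exclusion radius set (logical arrays as vectors,
  # index = i + nn*(j-1 + nn*(k-1)) matching the C++ kernel layout)
  inside_mask <- function(rad) {
    ins <- logical(nn^3)
    for (a in seq_len(n)) {
      ri <- rad[a]
      ii <- which(abs(ax - xyz[a, 1]) <= ri)
      jj <- which(abs(ay - xyz[a, 2]) <= ri)
      kk <- which(abs(az - xyz[a, 3]) <= ri)
      if (!length(ii) || !length(jj) || !length(kk)) next
      dx2 <- (ax[ii] - xyz[a, 1])^2
      dy2 <- (ay[jj] - xyz[a, 2])^2
      dz2 <- (az[kk] - xyz[a, 3])^2
      sub <- outer(dx2, dy2, "+")
      for (t in seq_along(kk)) {
        hit <- sub + dz2[t] <= ri^2
        if (any(hit)) {
          lin <- outer(ii, (jj - 1) * nn, "+")[hit] + (kk[t] - 1) * nn * nn
          ins[lin] <- TRUE
        }
      }
    }
    ins
  }

  # Edge dielectrics by harmonic smoothing over the solute-interior fraction
  # of each grid edge (fractions from exact sphere-segment intersections,
  # merged across overlapping atoms).
  edge_fractions <- function(axc, p1c, p2c, axA, p1A, p2A) {
    nA <- length(axc); n1 <- length(p1c)
    store <- new.env(hash = TRUE)
    for (a in seq_len(n)) {
      R <- radii[a]
      d1 <- p1c - p1A[a]; d2 <- p2c - p2A[a]
      jj <- which(abs(d1) < R); kk <- which(abs(d2) < R)
      if (!length(jj) || !length(kk)) next
      for (k in kk) {
        rem <- R^2 - d1[jj]^2 - d2[k]^2
        for (s in which(rem > 0)) {
          j <- jj[s]; cc <- sqrt(rem[s])
          lo <- (axA[a] - cc - axc[1]) / h
          hi <- lo + 2 * cc / h
          e0 <- max(0, floor(lo)); e1 <- min(nA - 1, floor(hi))
          if (e1 < e0) next
          for (e in e0:e1) {
            f0 <- max(lo, e); f1 <- min(hi, e + 1)
            if (f1 <= f0) next
            keyi <- as.character(e + 1 + (j - 1) * nA + (k - 1) * nA * n1)
            store[[keyi]] <- rbind(store[[keyi]], c(f0 - e, f1 - e))
          }
        }
      }
    }
    f <- numeric(nA * n1 * length(p2c))
    for (keyi in ls(store)) {
      iv <- store[[keyi]]
      o <- order(iv[, 1])
      tot <- 0; cur0 <- iv[o[1], 1]; cur1 <- iv[o[1], 2]
      for (r in o[-1]) {
        if (iv[r, 1] > cur1) {
          tot <- tot + cur1 - cur0
          cur0 <- iv[r, 1]; cur1 <- iv[r, 2]
        } else cur1 <- max(cur1, iv[r, 2])
      }
      f[as.integer(keyi)] <- tot + cur1 - cur0
    }
    f
  }
  frac_to_eps <- function(f)
    1 / (f / options$eps_solute + (1 - f) / options$eps_solvent)
  xe <- ax[-nn]; ye <- ay[-nn]; ze <- az[-nn]
  epsx <- array(frac_to_eps(edge_fractions(xe, ay, az, xyz[, 1], xyz[, 2],
                                           xyz[, 3])),
                dim = c(nn - 1, nn, nn))
  epsy <- aperm(array(frac_to_eps(edge_fractions(ye, ax, az, xyz[, 2],
                                                 xyz[, 1], xyz[, 3])),
                      dim = c(nn - 1, nn, nn)), c(2, 1, 3))
  epsz <- aperm(array(frac_to_eps(edge_fractions(ze, ax, ay, xyz[, 3],
                                                 xyz[, 1], xyz[, 2])),
                      dim = c(nn - 1, nn, nn)), c(2, 3, 1))

  # screening term eps_s * kappa^2 * h^2, active outside the Stern layer
  kap2h2 <- numeric(nn^3)
  kappa <- .kappa_inv_ang(options)
  if (kappa > 0) {
    rt <- 0.0019872041 * options$temperature
    conc <- options$ionic_strength * 6.0221408e-4
    for (s in seq_along(options$ion_radii)) {
      excl <- inside_mask(radii + options$ion_radii[s])
      kap2h2[!excl] <- kap2h2[!excl] + 4 * pi * kc * conc / rt * h^2
    }
  }

  # trilinear charge assignment; remember stencils for energy interpolation
  src <- numeric(nn^3)
  stencils <- vector("list", n)
  for (a in seq_len(n)) {
    fx <- (xyz[a, 1] - ax[1]) / h; i0 <- floor(fx); tx <- fx - i0
    fy <- (xyz[a, 2] - ay[1]) / h; j0 <- floor(fy); ty <- fy - j0
    fz <- (xyz[a, 3] - az[1]) / h; k0 <- floor(fz); tz <- fz - k0
    if (i0 < 1 || j0 < 1 || k0 < 1 || i0 > nn - 3 || j0 > nn - 3 || k0 > nn - 3)
      stop("atom too close to the grid boundary; increase padding")
    wx <- c(1 - tx, tx); wy <- c(1 - ty, ty); wz <- c(1 - tz, tz)
    idx8 <- integer(8); w8 <- numeric(8); t <- 0L
    for (dk in 0:1) for (dj in 0:1) for (di in 0:1) {
      t <- t + 1L
      idx8[t] <- (i0 + di + 1) + nn * (j0 + dj + nn * (k0 + dk))
      w8[t] <- wx[di + 1] * wy[dj + 1] * wz[dk + 1]
    }
    stencils[[a]] <- list(idx = idx8, w = w8)
    src[idx8] <- src[idx8] + 4 * pi * kc * charges[a] * w8 / h
  }

  grid_pts <- as.matrix(expand.grid(x = ax, y = ay, z = az))
  run <- function(eps_x, eps_y, eps_z, k2h2, eps_bc, kappa_bc) {
    phi <- .dh_potential(grid_pts, xyz, charges, eps_bc, kappa_bc)
    sol <- pb_sor(phi, as.numeric(eps_x), as.numeric(eps_y),
                  as.numeric(eps_z), k2h2, src, nn, nn, nn,
                  omega = 2 / (1 + sin(pi / nn)),
                  tol = options$pb_tol, maxit = options$pb_maxit)
    if (is.na(sol$residual) || sol$residual > options$pb_tol)
      warning(sprintf("PB iteration stopped at relative residual %.3g",
                      sol$residual))
    list(phi = sol$phi, iterations = sol$iterations, residual = sol$residual)
  }

  solv <- run(epsx, epsy, epsz, kap2h2, options$eps_solvent, kappa)
  eu <- array(options$eps_solute, dim = c(nn, nn, nn))
  ref <- run(eu[-nn, , ], eu[, -nn, ], eu[, , -nn], numeric(nn^3),
             options$eps_solute, 0)

  phi_reac <- vapply(seq_len(n), function(a) {
    st <- stencils[[a]]
    sum(st$w * (solv$phi[st$idx] - ref$phi[st$idx]))
  }, numeric(1))
  energy <- 0.5 * sum(charges * phi_reac)
  list(energy = energy, phi_reaction = phi_reac, dims = c(nn, nn, nn),
       iterations = c(solvated = solv$iterations, reference = ref$iterations),
       residual = c(solvated = solv$residual, reference = ref$residual))
}
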