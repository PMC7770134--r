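#' Gas-phase Amber-functional-form potential energy
#'
#' Evaluates
#' E_total = E_bond + E_angle + E_dihedral + E_es + E_vdW
#' with the Amber conventions: harmonic bonds and angles without the 1/2
#' factor, Fourier dihedrals (V_n/2)(1 + cos(n phi - gamma)), Coulomb sum
#' with k_e = 332.0637 kcal*A/(mol*e^2) over non-excluded pairs (1-4 pairs
#' scaled by 1/1.2), and 12-6 Lennard-Jones in r_min/epsilon form with
#' Lorentz-Berthelot combination (1-4 pairs scaled by 1/2). No cutoff:
#' the model is the gas-phase dipeptide energy used for conformer
#' relative-energy benchmarking.
#'
#' @param conf a `conformer` (or n x 3 coordinate matrix).
#' @param params a `ff_params` object.
#' @param charges a `charge_set` (or numeric vector, e).
#' @return An object of class `"energy_breakdown"`: list with `e_bond`,
#'   `e_angle`, `e_dihedral`, `e_es`, `e_vdw`, `e_total` (kcal/mol).
#' @export
energy <- function(conf, params, charges) {
  .energy_impl(conf, params, charges, gradient = FALSE)$breakdown
}

#' Energy and analytic Cartesian gradient
#'
#' @inheritParams energy
#' @param restraints optional list of torsion restraints, each
#'   `list(atoms = c(i,j,k,l), target = degrees, k = kcal/(mol*rad^2))`,
#'   added as flat-bottom-free harmonic terms `k * wrap(phi - target)^2`.
#' @return list with `breakdown` (unrestrained terms), `e_restraint`,
#'   `objective` (= e_total + e_restraint) and `gradient` (n x 3 matrix of
#'   d(objective)/dx, kcal/(mol*A)).
#' @export
energy_gradient <- function(conf, params, charges, restraints = list()) {
  .energy_impl(conf, params, charges, gradient = TRUE, restraints = restraints)
}

.wrap_deg <- function(a) {
  a <- a %% 360
  ifelse(a > 180, a - 360, a)
}

.energy_impl <- function(conf, params, charges, gradient = FALSE,
                         restraints = list()) {
  xyz <- if (inherits(conf, "conformer")) conf$xyz else as.matrix(conf)
  if (inherits(charges, "charge_set")) charges <- charges$charges
  n <- nrow(xyz)
  kc <- uaaff_constants()$coulomb_kcal
  g <- if (gradient) matrix(0, n, 3) else NULL

  e_bond <- 0
  bd <- params$bonds
  for (r in seq_len(nrow(bd))) {
    i <- bd$i[r]; j <- bd$j[r]
    dv <- xyz[i, ] - xyz[j, ]
    rij <- sqrt(sum(dv^2))
    e_bond <- e_bond + bd$k_r[r] * (rij - bd$r_eq[r])^2
    if (gradient) {
      f <- 2 * bd$k_r[r] * (rij - bd$r_eq[r]) * dv / rij
      g[i, ] <- g[i, ] + f
      g[j, ] <- g[j, ] - f
    }
  }

  e_angle <- 0
  an <- params$angles
  for (r in seq_len(nrow(an))) {
    i <- an$i[r]; j <- an$j[r]; k <- an$k[r]
    u <- xyz[i, ] - xyz[j, ]
    v <- xyz[k, ] - xyz[j, ]
    lu <- sqrt(sum(u^2)); lv <- sqrt(sum(v^2))
    ct <- sum(u * v) / (lu * lv)
    ct <- max(-1, min(1, ct))
    th <- acos(ct)
    th0 <- an$theta_eq[r] * pi / 180
    e_angle <- e_angle + an$k_theta[r] * (th - th0)^2
    if (gradient) {
      st <- sqrt(max(1 - ct^2, 1e-14))
      uh <- u / lu; vh <- v / lv
      dthi <- -(vh - ct * uh) / (lu * st)
      dthk <- -(uh - ct * vh) / (lv * st)
      dthj <- -(dthi + dthk)
      pref <- 2 * an$k_theta[r] * (th - th0)
      g[i, ] <- g[i, ] + pref * dthi
      g[j, ] <- g[j, ] + pref * dthj
      g[k, ] <- g[k, ] + pref * dthk
    }
  }

  # shared dihedral machinery: value phi (radians) and dphi/dx for 4 atoms
  dihedral_geom <- function(i, j, k, l) {
    b1 <- xyz[j, ] - xyz[i, ]
    b2 <- xyz[k, ] - xyz[j, ]
    b3 <- xyz[l, ] - xyz[k, ]
    n1 <- .cross3(b1, b2)
    n2 <- .cross3(b2, b3)
    lb2 <- sqrt(sum(b2^2))
    m1 <- .cross3(b2 / lb2, n1)
    phi <- atan2(sum(m1 * n2), sum(n1 * n2))
    dphi <- NULL
    if (gradient) {
      ln1 <- sum(n1^2); ln2 <- sum(n2^2)
      Fi <- -(lb2 / ln1) * n1
      Gl <- (lb2 / ln2) * n2
      s12 <- sum(b1 * b2) / lb2^2
      s32 <- sum(b3 * b2) / lb2^2
      Fj <- -(1 + s12) * Fi + s32 * Gl
      Fk <- s12 * Fi - (1 + s32) * Gl
      dphi <- rbind(Fi, Fj, Fk, Gl)
    }
    list(phi = phi, dphi = dphi)
  }

  e_dihedral <- 0
  dh <- params$dihedrals
  for (r in seq_len(nrow(dh))) {
    at <- c(dh$i[r], dh$j[r], dh$k[r], dh$l[r])
    geo <- dihedral_geom(at[1], at[2], at[3], at[4])
    gam <- dh$gamma[r] * pi / 180
    arg <- dh$n[r] * geo$phi - gam
    e_dihedral <- e_dihedral + dh$v_n[r] / 2 * (1 + cos(arg))
    if (gradient) {
      pref <- -dh$v_n[r] / 2 * dh$n[r] * sin(arg)
      for (m in 1:4) g[at[m], ] <- g[at[m], ] + pref * geo$dphi[m, ]
    }
  }

  # nonbonded: all i<j pairs, minus exclusions, 1-4 scaled
  e_es <- 0; e_vdw <- 0
  if (n >= 2) {
    pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    key <- function(i, j) paste(pmin(i, j), pmax(i, j))
    pk <- key(pr[, 1], pr[, 2])
    scale_ee <- rep(1, nrow(pr)); scale_vdw <- rep(1, nrow(pr))
    if (nrow(params$exclusions)) {
      drop <- pk %in% key(params$exclusions[, 1], params$exclusions[, 2])
      scale_ee[drop] <- 0; scale_vdw[drop] <- 0
    }
    if (nrow(params$pairs14)) {
      p14 <- pk %in% key(params$pairs14[, 1], params$pairs14[, 2])
      scale_ee[p14] <- params$scale_ee_14
      scale_vdw[p14] <- params$scale_vdw_14
    }
    act <- scale_ee > 0 | scale_vdw > 0
    pr <- pr[act, , drop = FALSE]
    scale_ee <- scale_ee[act]; scale_vdw <- scale_vdw[act]
    if (nrow(pr)) {
      dvec <- xyz[pr[, 1], , drop = FALSE] - xyz[pr[, 2], , drop = FALSE]
      r2 <- rowSums(dvec^2)
      if (any(r2 < 1e-12)) stop("overlapping atoms in nonbonded sum")
      rij <- sqrt(r2)
      qq <- charges[pr[, 1]] * charges[pr[, 2]]
      ees_pair <- scale_ee * kc * qq / rij
      e_es <- sum(ees_pair)
      rmin <- params$lj$rmin2[pr[, 1]] + params$lj$rmin2[pr[, 2]]
      eps <- sqrt(params$lj$eps[pr[, 1]] * params$lj$eps[pr[, 2]])
      sr6 <- (rmin / rij)^6
      evdw_pair <- scale_vdw * eps * (sr6^2 - 2 * sr6)
      e_vdw <- sum(evdw_pair)
      if (gradient) {
        # dE/dr for each pair, force along the pair vector
        dEdr <- -ees_pair / rij +
          scale_vdw * eps * (-12 * sr6^2 + 12 * sr6) / rij
        fpair <- dvec * (dEdr / rij)
        for (m in seq_len(nrow(pr))) {
          g[pr[m, 1], ] <- g[pr[m, 1], ] + fpair[m, ]
          g[pr[m, 2], ] <- g[pr[m, 2], ] - fpair[m, ]
        }
      }
    }
  }

  e_restraint <- 0
  for (rs in restraints) {
    at <- rs$atoms
    geo <- dihedral_geom(at[1], at[2], at[3], at[4])
    dphi_w <- .wrap_deg(geo$phi * 180 / pi - rs$target) * pi / 180
    e_restraint <- e_restraint + rs$k * dphi_w^2
    if (gradient) {
      pref <- 2 * rs$k * dphi_w
      for (m in 1:4) g[at[m], ] <- g[at[m], ] + pref * geo$dphi[m, ]
    }
  }

  breakdown <- energy_breakdown(e_bond, e_angle, e_dihedral, e_es, e_vdw)
  list(breakdown = breakdown, e_restraint = e_restraint,
       objective = breakdown$e_total + e_restraint, gradient = g)
}

#' Energy breakdown container
#' @param e_bond,e_angle,e_dihedral,e_es,e_vdw term values, kcal/mol.
#' @return object of class `"energy_breakdown"`; `e_total` is their sum.
#' @export
energy_breakdown <- function(e_bond, e_angle, e_dihedral, e_es, e_vdw) {
  structure(list(e_bond = e_bond, e_angle = e_angle, e_dihedral = e_dihedral,
                 e_es = e_es, e_vdw = e_vdw,
                 e_total = e_bond + e_angle + e_dihedral + e_es + e_vdw),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf(paste0(
    "E_total  %12.4f kcal/mol\n",
    "  bond     %12.4f\n  angle    %12.4f\n  dihedral %12.4f\n",
    "  elec     %12.4f\n  vdW      %12.4f\n"),
    x$e_total, x$e_bond, x$e_angle, x$e_dihedral, x$e_es, x$e_vdw))
  invisible(x)
}

#' @export
as.data.frame.energy_breakdown <- function(x, ...) {
  data.frame(term = c("bond", "angle", "dihedral", "elec", "vdw", "total"),
             energy = c(x$e_bond, x$e_angle, x$e_dihedral, x$e_es, x$e_vdw,
                        x$e_total))
}

#' Restrained gradient-based energy minimization
#'
#' Quasi-Newton (BFGS) local minimization of the gas-phase energy, with
#' optional harmonic torsion restraints `k * wrap(phi - target)^2` added to
#' the objective (used to hold alpha/beta backbone states during conformer
#' optimization). The reported breakdown is the unrestrained energy at the
#' final geometry.
#'
#' @inheritParams energy_gradient
#' @param max_steps iteration cap (default 5000).
#' @param gtol gradient-norm (max component) convergence target,
#'   kcal/(mol*A).
#' @return list with `conformer` (final geometry), `breakdown` (unrestrained
#'   terms), `objective`, `grad_norm` (max abs component of the restrained
#'   gradient), `converged`, `trace` (objective per outer iteration).
#' @export
minimize <- function(conf, params, charges, restraints = list(),
                     max_steps = 5000L, gtol = 1e-6) {
  stopifnot(inherits(conf, "conformer"))
  x0 <- as.numeric(conf$xyz)
  nr <- nrow(conf$xyz)
  trace <- numeric(0)
  fn <- function(x) {
    xm <- matrix(x, nr, 3)
    v <- .energy_impl(xm, params, charges, gradient = FALSE,
                      restraints = restraints)$objective
    if (!is.finite(v)) return(1e30)
    v
  }
  gr <- function(x) {
    xm <- matrix(x, nr, 3)
    as.numeric(.energy_impl(xm, params, charges, gradient = TRUE,
                            restraints = restraints)$gradient)
  }
  g0 <- gr(x0)
  if (!all(is.finite(g0))) stop("non-finite gradient at starting geometry")
  if (max(abs(g0)) <= gtol) {
    ev <- .energy_impl(matrix(x0, nr, 3), params, charges, gradient = FALSE,
                       restraints = restraints)
    out_conf <- conf
    return(list(conformer = out_conf, breakdown = ev$breakdown,
                objective = ev$objective, grad_norm = max(abs(g0)),
                converged = TRUE, trace = ev$objective))
  }
  x <- x0
  for (chunk in seq_len(ceiling(max_steps / 100))) {
    res <- stats::optim(x, fn, gr, method = "BFGS",
                        control = list(maxit = 100, reltol = 1e-16))
    x <- res$par
    trace <- c(trace, res$value)
    if (max(abs(gr(x))) <= gtol) break
    if (length(trace) >= 2 &&
        abs(trace[length(trace)] - trace[length(trace) - 1]) < 1e-13) break
  }
  gfin <- max(abs(gr(x)))
  xm <- matrix(x, nr, 3)
  ev <- .energy_impl(xm, params, charges, gradient = FALSE,
                     restraints = restraints)
  out <- conf
  out$xyz <- xm
  if (!is.null(out$torsions)) {
    if (!is.null(out$torsions$phi))
      out$phi <- measure_dihedral(xm, out$torsions$phi[1], out$torsions$phi[2],
                                  out$torsions$phi[3], out$torsions$phi[4])
    if (!is.null(out$torsions$psi))
      out$psi <- measure_dihedral(xm, out$torsions$psi[1], out$torsions$psi[2],
                                  out$torsions$psi[3], out$torsions$psi[4])
  }
  list(conformer = out, breakdown = ev$breakdown, objective = ev$objective,
       grad_norm = gfin, converged = gfin <= gtol, trace = trace)
}

#' Relative energy of an alpha/beta conformer pair
#'
#' RE = E(alpha) - E(beta) under one shared charge set (the blended charges
#' of the residue), the sign convention under which the more stable
#' beta-strand backbone gives positive values. `mode = "minimized"` first
#' relaxes each conformer under harmonic phi/psi restraints toward the
#' canonical alpha (-60, -40) and beta (180, 180) targets; `"single_point"`
#' evaluates the input geometries as given.
#'
#' @param pair a `conformer_pair` (see [conformer_pair()]).
#' @param params a `ff_params`.
#' @param charges a single `charge_set` used for both conformers.
#' @param mode `"minimized"` or `"single_point"`.
#' @param restraint_k torsion restraint force constant, kcal/(mol*rad^2).
#' @param gtol,max_steps passed to [minimize()].
#' @return relative energy, kcal/mol.
#' @export
relative_energy <- function(pair, params, charges,
                            mode = c("minimized", "single_point"),
                            restraint_k = 100, gtol = 1e-4,
                            max_steps = 5000L) {
  mode <- match.arg(mode)
  eval_one <- function(conf, targets) {
    if (mode == "single_point") return(energy(conf, params, charges)$e_total)
    rs <- list()
    if (!is.null(conf$torsions$phi))
      rs <- c(rs, list(list(atoms = conf$torsions$phi, target = targets[1],
                            k = restraint_k)))
    if (!is.null(conf$torsions$psi))
      rs <- c(rs, list(list(atoms = conf$torsions$psi, target = targets[2],
                            k = restraint_k)))
    minimize(conf, params, charges, restraints = rs, gtol = gtol,
             max_steps = max_steps)$breakdown$e_total
  }
  ea <- eval_one(pair$alpha, c(-60, -40))
  eb <- eval_one(pair$beta, c(180, 180))
  ea - eb
}

#' Alpha/beta conformer pair for one residue system
#'
#' @param system_id integer system label (1-18 in the shipped benchmark).
#' @param alpha,beta `conformer` objects sharing atom ordering.
#' @param re_qm optional benchmark relative energy, kcal/mol.
#' @return object of class `"conformer_pair"`.
#' @export
conformer_pair <- function(system_id, alpha, beta, re_qm = NA_real_) {
  stopifnot(inherits(alpha, "conformer"), inherits(beta, "conformer"),
            nrow(alpha$atoms) == nrow(beta$atoms))
  structure(list(system_id = system_id, alpha = alpha, beta = beta,
                 re_qm = re_qm),
            class = "conformer_pair")
}
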