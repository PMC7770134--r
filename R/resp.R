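#' ESP grid container
#'
#' Off-surface sample points (Bohr) with optional target electrostatic
#' potential values (hartree/e). All ESP work is in atomic units; conversion
#' to and from Angstrom happens only at I/O boundaries.
#'
#' @param points n x 3 matrix, Bohr.
#' @param values optional numeric vector of potentials, hartree/e.
#' @return An object of class `"esp_grid"` with elements `points`, `values`,
#'   `n_points`.
#' @export
esp_grid <- function(points, values = NULL) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3, all(is.finite(points)))
  if (!is.null(values)) {
    values <- as.numeric(values)
    if (length(values) != nrow(points))
      stop("values length must equal number of points")
  }
  structure(list(points = points, values = values, n_points = nrow(points)),
            class = "esp_grid")
}

#' @export
print.esp_grid <- function(x, ...) {
  cat(sprintf("<esp_grid> %d points%s\n", x$n_points,
              if (is.null(x$values)) " (no values)" else ""))
  invisible(x)
}

#' Electrostatic potential of point charges (atomic units)
#'
#' Exact Coulomb superposition V(r) = sum_j q_j / |r - r_j| in atomic units
#' (charges in e, coordinates in Bohr, potential in hartree/e). Linear in the
#' charges; used both to synthesize fitting targets and as the model the RESP
#' fit inverts.
#'
#' @param charges numeric vector or `charge_set`, e.
#' @param atom_coords n_atoms x 3 matrix, Bohr.
#' @param points n_points x 3 matrix, Bohr.
#' @return numeric vector of potentials, hartree/e.
#' @export
esp_from_point_charges <- function(charges, atom_coords, points) {
  if (inherits(charges, "charge_set")) charges <- charges$charges
  A <- .esp_design(as.matrix(atom_coords), as.matrix(points))
  as.numeric(A %*% charges)
}

# inverse-distance design matrix (n_points x n_atoms), atomic units
.esp_design <- function(atom_coords, points) {
  d2 <- outer(rowSums(points^2), rowSums(atom_coords^2), "+") -
    2 * points %*% t(atom_coords)
  d <- sqrt(pmax(d2, 0))
  if (any(d < 1e-6))
    stop("grid point within 1e-6 Bohr of an atom position (singular Coulomb term)")
  1 / d
}

#' Build a Merz-Kollman style ESP sampling grid
#'
#' Points are placed pseudo-randomly (seeded, hence reproducible) on
#' union-of-spheres shells at each van der Waals scale factor and culled if
#' they fall inside any atom's scaled sphere. This mirrors the conventional
#' ESP sampling layout used with HF/6-31G* potentials; here it samples
#' synthetic point-charge potentials for testing and charge recovery.
#'
#' @param x a `conformer`, or an n x 3 coordinate matrix in Angstrom.
#' @param elements element symbols (required when `x` is a matrix).
#' @param shells numeric vector of vdW scale factors (default 1.4-2.0).
#' @param density target surface density, points per Angstrom^2.
#' @param seed integer seed; identical seeds give identical grids.
#' @param radii optional named vdW radius override (see [vdw_radii()]).
#' @return An `esp_grid` (points only, Bohr).
#' @export
build_mk_grid <- function(x, elements = NULL, shells = c(1.4, 1.6, 1.8, 2.0),
                          density = 1.0, seed = 1L, radii = NULL) {
  if (inherits(x, "conformer")) {
    elements <- x$atoms$element
    coords <- x$xyz
  } else {
    coords <- as.matrix(x)
    if (is.null(elements)) stop("elements required for matrix input")
  }
  if (nrow(coords) < 1) stop("empty molecule")
  rv <- vdw_radii(elements, override = radii)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  pts <- list()
  for (s in shells) {
    for (a in seq_len(nrow(coords))) {
      r <- s * rv[a]
      n <- max(1L, as.integer(ceiling(density * 4 * pi * r^2)))
      # uniform points on the sphere via normalized Gaussians
      g <- matrix(stats::rnorm(3 * n), n, 3)
      g <- g / sqrt(rowSums(g^2))
      p <- sweep(g * r, 2, coords[a, ], "+")
      # cull points strictly inside any atom's scaled sphere
      keep <- rep(TRUE, n)
      for (bdx in seq_len(nrow(coords))) {
        if (bdx == a) next
        d2 <- rowSums(sweep(p, 2, coords[bdx, ])^2)
        keep <- keep & d2 >= (s * rv[bdx])^2 * (1 - 1e-12)
      }
      pts[[length(pts) + 1]] <- p[keep, , drop = FALSE]
    }
  }
  all_pts <- do.call(rbind, pts)
  esp_grid(all_pts / uaaff_constants()$bohr_to_angstrom)
}

#' RESP fitting options
#'
#' @param restraint_a hyperbolic restraint strength, hartree (canonical
#'   two-stage values: 0.0005 for stage 1, 0.001 for stage 2; 0 gives an
#'   unrestrained ESP fit).
#' @param restraint_b restraint tightness, e (default 0.1).
#' @param restrain_hydrogens should hydrogens feel the restraint (default
#'   `FALSE`, the conventional choice)?
#' @param equivalence_classes list of integer vectors; charges within a class
#'   are constrained equal.
#' @param frozen named numeric vector: `frozen["idx"]` fixes atom `idx` at the
#'   given charge (used to pin Ace/NMe capping groups at their reference
#'   force-field values, and to freeze stage-1 charges in stage 2).
#' @param net_charge integer total molecular charge.
#' @param max_iter,tolerance iteration control for the reweighted solve;
#'   convergence is `max |delta q| < tolerance`.
#' @return An object of class `"resp_options"`.
#' @export
resp_options <- function(restraint_a = 0.0005, restraint_b = 0.1,
                         restrain_hydrogens = FALSE,
                         equivalence_classes = list(),
                         frozen = NULL, net_charge = 0L,
                         max_iter = 200L, tolerance = 1e-10) {
  stopifnot(restraint_a >= 0, restraint_b > 0, max_iter >= 1, tolerance > 0)
  if (length(equivalence_classes)) {
    all_idx <- unlist(equivalence_classes)
    if (anyDuplicated(all_idx)) stop("equivalence classes must be disjoint")
    if (!is.null(frozen) && any(as.integer(names(frozen)) %in% all_idx))
      stop("frozen atoms may not appear in an equivalence class")
  }
  structure(list(restraint_a = restraint_a, restraint_b = restraint_b,
                 restrain_hydrogens = restrain_hydrogens,
                 equivalence_classes = equivalence_classes,
                 frozen = frozen, net_charge = as.integer(net_charge),
                 max_iter = as.integer(max_iter), tolerance = tolerance),
            class = "resp_options")
}

#' Restrained (RESP) / unrestrained (ESP) charge fitting
#'
#' Fits atomic point charges to a sampled electrostatic potential by
#' minimizing
#' \deqn{\sum_k (V_k - \sum_j q_j/|r_k - r_j|)^2 +
#'       a \sum_{j\,\mathrm{restrained}} (\sqrt{q_j^2 + b^2} - b)}
#' subject to the exact net-charge constraint, equality within each
#' equivalence class, and any frozen charges. The hyperbolic restraint is
#' handled by iterated reweighted linear solves with a Lagrange row for the
#' charge constraint; with `restraint_a = 0` the fit reduces to constrained
#' ordinary least squares.
#'
#' @param grid an `esp_grid` with values (atomic units).
#' @param atom_coords n_atoms x 3 matrix, Bohr.
#' @param options a `resp_options` object.
#' @param elements element symbols (needed to exempt hydrogens from the
#'   restraint; may be omitted when `restraint_a = 0` or
#'   `restrain_hydrogens = TRUE`).
#' @return An object of class `"resp_fit"` with components `charges`
#'   (full-length numeric), `charge_set`, `rrms` (relative RMS of the ESP
#'   residual), `rmse`, `n_iter`, `converged`, plus the inputs needed by
#'   `fitted`/`residuals`/`predict` methods.
#' @seealso [resp_two_stage()] for the standard two-stage protocol.
#' @export
resp_fit <- function(grid, atom_coords, options = resp_options(),
                     elements = NULL) {
  stopifnot(inherits(grid, "esp_grid"), !is.null(grid$values))
  atom_coords <- as.matrix(atom_coords)
  n <- nrow(atom_coords)
  V <- grid$values
  A <- .esp_design(atom_coords, grid$points)

  frozen_idx <- integer(0); frozen_q <- numeric(0)
  if (!is.null(options$frozen)) {
    frozen_idx <- as.integer(names(options$frozen))
    frozen_q <- as.numeric(options$frozen)
    if (any(frozen_idx < 1 | frozen_idx > n)) stop("frozen index out of range")
  }
  free_idx <- setdiff(seq_len(n), frozen_idx)

  # variable map: one column per free equivalence class / singleton
  classes <- options$equivalence_classes
  classed <- if (length(classes)) unlist(classes) else integer(0)
  singles <- setdiff(free_idx, classed)
  vars <- c(lapply(singles, identity), classes)
  vars <- lapply(vars, as.integer)
  p <- length(vars)
  if (p == 0) stop("no free charges to fit")
  if (grid$n_points < p)
    stop("fewer grid points than free charge degrees of freedom")
  M <- matrix(0, n, p)
  for (v in seq_len(p)) M[vars[[v]], v] <- 1

  Af <- A %*% M
  y <- V
  if (length(frozen_idx))
    y <- y - A[, frozen_idx, drop = FALSE] %*% frozen_q
  Q_free <- options$net_charge - sum(frozen_q)
  cvec <- colSums(M)

  # which atoms feel the restraint
  restrained_atom <- rep(options$restraint_a > 0, n)
  if (!options$restrain_hydrogens && options$restraint_a > 0) {
    if (is.null(elements))
      stop("elements needed to exempt hydrogens from the restraint")
    restrained_atom <- restrained_atom & elements != "H"
  }
  n_restr <- as.numeric(crossprod(M, as.numeric(restrained_atom)))

  AtA <- crossprod(Af)
  Aty <- crossprod(Af, y)
  a <- options$restraint_a; b <- options$restraint_b

  q <- rep(0, p)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    w <- if (a > 0) a * n_restr / sqrt(q^2 + b^2) else rep(0, p)
    K <- rbind(cbind(AtA + diag(w, p), cvec),
               c(cvec, 0))
    rhs <- c(Aty, Q_free)
    sol <- solve(K, rhs)
    qn <- sol[seq_len(p)]
    if (max(abs(qn - q)) < options$tolerance) {
      q <- qn; converged <- TRUE; break
    }
    q <- qn
    if (iter >= options$max_iter) break
    if (a == 0) { converged <- TRUE; break }  # linear problem: one solve
  }

  charges <- numeric(n)
  charges[frozen_idx] <- frozen_q
  for (v in seq_len(p)) charges[vars[[v]]] <- q[v]

  fitted_v <- as.numeric(A %*% charges)
  resid <- V - fitted_v
  rmse <- sqrt(mean(resid^2))
  denom <- sqrt(sum(V^2))
  rrms <- if (denom > 0) sqrt(sum(resid^2)) / denom else rmse

  structure(list(charges = charges,
                 charge_set = charge_set(charges,
                                         net_charge = options$net_charge,
                                         tol = 1e-6),
                 rrms = rrms, rmse = rmse,
                 n_iter = iter, converged = converged,
                 options = options, atom_coords = atom_coords,
                 fitted_values = fitted_v, target = V),
            class = "resp_fit")
}

#' @export
print.resp_fit <- function(x, ...) {
  cat(sprintf("<resp_fit> %d charges, net %+d e, RRMS %.3g (%s after %d iteration%s)\n",
              length(x$charges), x$options$net_charge, x$rrms,
              if (x$converged) "converged" else "NOT converged",
              x$n_iter, if (x$n_iter == 1) "" else "s"))
  invisible(x)
}

#' @export
coef.resp_fit <- function(object, ...) object$charges

#' @export
fitted.resp_fit <- function(object, ...) object$fitted_values

#' @export
residuals.resp_fit <- function(object, ...) object$target - object$fitted_values

#' @export
#' @rdname resp_fit
#' @param object a fitted `resp_fit`.
#' @param newpoints m x 3 matrix of grid points (Bohr) at which to evaluate
#'   the fitted-charge ESP; defaults to the fitting grid.
#' @param ... unused.
predict.resp_fit <- function(object, newpoints = NULL, ...) {
  if (is.null(newpoints)) return(object$fitted_values)
  esp_from_point_charges(object$charges, object$atom_coords, newpoints)
}

#' @export
summary.resp_fit <- function(object, ...) {
  cat(sprintf("RESP fit: %d atoms, net charge %+d e\n",
              length(object$charges), object$options$net_charge))
  cat(sprintf("  restraint a = %g hartree, b = %g e\n",
              object$options$restraint_a, object$options$restraint_b))
  cat(sprintf("  RRMS = %.4g, RMSE = %.4g hartree/e, %d iterations (%s)\n",
              object$rrms, object$rmse, object$n_iter,
              if (object$converged) "converged" else "not converged"))
  cat(sprintf("  sum of charges = %+.10f e\n", sum(object$charges)))
  invisible(object)
}

#' Two-stage RESP protocol
#'
#' Stage 1 fits all non-frozen charges under the weak restraint
#' (`a_stage1`) with no equivalence constraints. Stage 2 freezes every atom
#' at its stage-1 value except the declared refit set (typically methyl and
#' methylene groups whose hydrogens must come out equivalent), then refits
#' that set under the stronger restraint (`a_stage2`) with the supplied
#' equivalence classes.
#'
#' @inheritParams resp_fit
#' @param refit_atoms integer indices refit in stage 2.
#' @param equivalence_classes_stage2 list of integer vectors applied in
#'   stage 2 (subsets of `refit_atoms`).
#' @param net_charge integer total charge.
#' @param a_stage1,a_stage2,b restraint constants (hartree, hartree, e).
#' @param frozen optional named numeric vector of permanently frozen charges
#'   (applied in both stages).
#' @return The stage-2 `resp_fit`, with the stage-1 fit attached as
#'   `$stage1`.
#' @export
resp_two_stage <- function(grid, atom_coords, elements, refit_atoms,
                           equivalence_classes_stage2 = list(),
                           net_charge = 0L,
                           a_stage1 = 0.0005, a_stage2 = 0.001, b = 0.1,
                           frozen = NULL) {
  s1 <- resp_fit(grid, atom_coords,
                 resp_options(restraint_a = a_stage1, restraint_b = b,
                              frozen = frozen, net_charge = net_charge),
                 elements = elements)
  n <- nrow(as.matrix(atom_coords))
  refit_atoms <- as.integer(refit_atoms)
  keep_frozen <- setdiff(seq_len(n), refit_atoms)
  frz <- stats::setNames(s1$charges[keep_frozen], keep_frozen)
  s2 <- resp_fit(grid, atom_coords,
                 resp_options(restraint_a = a_stage2, restraint_b = b,
                              equivalence_classes = equivalence_classes_stage2,
                              frozen = frz, net_charge = net_charge),
                 elements = elements)
  s2$stage1 <- s1
  s2
}
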