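#' Blend specification for alpha/beta charge averaging
#'
#' A convex combination of the alpha-helical and beta-strand RESP charge
#' sets applied to backbone and side-chain atoms, with the capping groups
#' (Ace, NMe) frozen at their reference force-field values.
#'
#' @param w_alpha,w_beta nonnegative weights summing to 1 (either may be
#'   omitted and is filled as the complement).
#' @param frozen_groups group tags never blended (default `c("ACE","NME")`).
#' @return object of class `"blend_spec"`.
#' @export
blend_spec <- function(w_alpha = NULL, w_beta = NULL,
                       frozen_groups = c("ACE", "NME")) {
  if (is.null(w_alpha) && is.null(w_beta)) stop("supply a weight")
  if (is.null(w_alpha)) w_alpha <- 1 - w_beta
  if (is.null(w_beta)) w_beta <- 1 - w_alpha
  stopifnot(w_alpha >= 0, w_beta >= 0)
  if (abs(w_alpha + w_beta - 1) > 1e-12) stop("weights must sum to 1")
  structure(list(w_alpha = w_alpha, w_beta = w_beta,
                 frozen_groups = frozen_groups),
            class = "blend_spec")
}

#' @export
print.blend_spec <- function(x, ...) {
  cat(sprintf("<blend_spec> alpha %.4f / beta %.4f (frozen: %s)\n",
              x$w_alpha, x$w_beta, paste(x$frozen_groups, collapse = ", ")))
  invisible(x)
}

#' Default candidate blend weights
#'
#' The beta-fraction grid over which [optimize_blend()] searches: pure beta,
#' the simple alpha/beta average, and the intermediate fractions used when
#' individual residues need finer adjustment (beta/6 + alpha*5/6,
#' beta/5 + alpha*4/5, beta/3 + alpha*2/3, beta*7/8 + alpha/8), plus pure
#' alpha.
#'
#' @return numeric vector of w_beta values.
#' @export
default_blend_weights <- function() {
  sort(unique(c(1, 7 / 8, 1 / 2, 1 / 3, 1 / 5, 1 / 6, 0)))
}

#' Blend two conformer charge sets
#'
#' Non-frozen atoms receive `w_alpha * q_alpha + w_beta * q_beta`; atoms in
#' frozen groups keep their values from `reference` (by default `q_alpha`,
#' whose cap charges equal the reference force field's). Net charge is
#' preserved exactly because blending is convex and both inputs carry the
#' same group-wise sums on frozen atoms.
#'
#' @param q_alpha,q_beta `charge_set` objects on the same atom ordering with
#'   equal net charges.
#' @param spec a `blend_spec`.
#' @param reference optional `charge_set` supplying the frozen-group values.
#' @return a blended `charge_set`.
#' @export
blend_charges <- function(q_alpha, q_beta, spec, reference = q_alpha) {
  stopifnot(inherits(q_alpha, "charge_set"), inherits(q_beta, "charge_set"))
  if (length(q_alpha$charges) != length(q_beta$charges))
    stop("charge sets have mismatched lengths")
  if (q_alpha$net_charge != q_beta$net_charge)
    stop("charge sets have mismatched net charges")
  frozen <- q_alpha$groups %in% spec$frozen_groups
  q <- spec$w_alpha * q_alpha$charges + spec$w_beta * q_beta$charges
  q[frozen] <- reference$charges[frozen]
  charge_set(q, net_charge = q_alpha$net_charge, groups = q_alpha$groups,
             tol = 1e-6)
}

#' Root-mean-square deviation between two series
#'
#' RMS = sqrt(sum((x_i - y_i)^2) / D). The divisor is selectable because the
#' two printed summary statistics this package reproduces use different
#' conventions: the 18-system benchmark RMS rows require D = N - 1, while
#' the four-system comparison in the accompanying text requires D = N. See
#' the methods vignette for the full discussion.
#'
#' @param x,y numeric series of equal length.
#' @param denominator `"n_minus_1"` or `"n"`.
#' @return RMS deviation in the units of the inputs.
#' @export
rms_deviation <- function(x, y, denominator = c("n_minus_1", "n")) {
  denominator <- match.arg(denominator)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("series length mismatch")
  n <- length(x)
  if (denominator == "n_minus_1" && n < 2)
    stop("need at least 2 observations for denominator n-1")
  if (n < 1) stop("empty series")
  D <- if (denominator == "n") n else n - 1
  sqrt(sum((x - y)^2) / D)
}

#' Squared Pearson correlation
#'
#' @param x,y numeric series, equal length >= 3, each with nonzero variance.
#' @return R^2 in `[0, 1]`.
#' @export
pearson_r2 <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("series length mismatch")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance series")
  stats::cor(x, y)^2
}

#' Per-system blend-weight optimization against a QM benchmark
#'
#' Formalizes the cycle-style manual charge adjustment as a deterministic
#' per-system grid search: for each alpha/beta conformer pair, every
#' candidate beta-weight is evaluated through `evaluator` (by default
#' [relative_energy()] on the blended charges) and the weight minimizing
#' `|RE_model - RE_QM|` is selected, ties broken toward larger w_beta. The
#' global RMS of the selected model energies against the benchmark is
#' reported.
#'
#' @param systems list of per-system inputs, each a list with elements
#'   `pair` (a `conformer_pair`), `q_alpha`, `q_beta` (`charge_set`s) and
#'   `params` (`ff_params`).
#' @param benchmark numeric vector of QM relative energies, kcal/mol, one
#'   per system.
#' @param weights_beta candidate w_beta grid (default
#'   [default_blend_weights()]).
#' @param evaluator function(pair, params, charges) -> RE_model; defaults to
#'   single-point [relative_energy()].
#' @param denominator RMS divisor convention for the reported global RMS.
#' @return object of class `"blend_opt"`: data.frame `selection` (system,
#'   w_beta, re_model, re_qm, abs_err), `global_rms`, `specs` (list of
#'   `blend_spec`), `charges` (list of blended `charge_set`s).
#' @export
optimize_blend <- function(systems, benchmark,
                           weights_beta = default_blend_weights(),
                           evaluator = NULL,
                           denominator = c("n_minus_1", "n")) {
  denominator <- match.arg(denominator)
  if (!length(weights_beta)) stop("empty candidate weight grid")
  if (length(systems) != length(benchmark))
    stop("benchmark length must match number of systems")
  if (is.null(evaluator)) {
    evaluator <- function(pair, params, charges)
      relative_energy(pair, params, charges, mode = "single_point")
  }
  weights_beta <- sort(weights_beta)  # ties resolved toward larger w_beta
  sel <- data.frame(system = integer(0), w_beta = numeric(0),
                    re_model = numeric(0), re_qm = numeric(0),
                    abs_err = numeric(0))
  specs <- list(); blended <- list()
  for (s in seq_along(systems)) {
    sys <- systems[[s]]
    best <- NULL
    for (wb in weights_beta) {
      sp <- blend_spec(w_beta = wb)
      qb <- blend_charges(sys$q_alpha, sys$q_beta, sp)
      re <- evaluator(sys$pair, sys$params, qb)
      err <- abs(re - benchmark[s])
      if (is.null(best) || err < best$err - 1e-12 ||
          (abs(err - best$err) <= 1e-12 && wb > best$wb)) {
        best <- list(wb = wb, re = re, err = err, spec = sp, charges = qb)
      }
    }
    sel <- rbind(sel, data.frame(system = s, w_beta = best$wb,
                                 re_model = best$re, re_qm = benchmark[s],
                                 abs_err = best$err))
    specs[[s]] <- best$spec
    blended[[s]] <- best$charges
  }
  structure(list(selection = sel,
                 global_rms = rms_deviation(sel$re_model, sel$re_qm,
                                            denominator = denominator),
                 denominator = denominator,
                 specs = specs, charges = blended),
            class = "blend_opt")
}

#' @export
print.blend_opt <- function(x, ...) {
  cat(sprintf("<blend_opt> %d systems, global RMS %.4f kcal/mol (denominator %s)\n",
              nrow(x$selection), x$global_rms, x$denominator))
  invisible(x)
}

#' @export
summary.blend_opt <- function(object, ...) {
  print(object)
  print(object$selection, row.names = FALSE)
  invisible(object)
}
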