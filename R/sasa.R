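# deterministic, near-uniform unit-sphere point set (Fibonacci lattice)
.fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(1 - z^2, 0))
  golden <- pi * (3 - sqrt(5))
  th <- golden * (seq_len(n) - 1)
  cbind(r * cos(th), r * sin(th), z)
}

#' Solvent accessible surface area (Shrake-Rupley)
#'
#' Each atom is covered with a deterministic near-uniform point set at radius
#' r_i + probe; the accessible area is the fraction of points not buried
#' inside any neighbour's probe-expanded sphere, times the sphere area.
#'
#' @param xyz n x 3 coordinates (Angstrom) or a `conformer`.
#' @param radii per-atom radii, Angstrom.
#' @param probe_radius probe radius, Angstrom (1.4 for water).
#' @param n_points test points per atom (default 960).
#' @return list: `total` (Angstrom^2) and `per_atom`.
#' @export
sasa <- function(xyz, radii, probe_radius = 1.4, n_points = 960L) {
  if (inherits(xyz, "conformer")) xyz <- xyz$xyz
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  stopifnot(length(radii) == n, all(radii > 0), probe_radius >= 0)
  sphere <- .fibonacci_sphere(as.integer(n_points))
  rr <- radii + probe_radius
  per_atom <- numeric(n)
  for (a in seq_len(n)) {
    pts <- sweep(sphere * rr[a], 2, xyz[a, ], "+")
    exposed <- rep(TRUE, nrow(pts))
    for (b in seq_len(n)) {
      if (b == a) next
      # only neighbours whose expanded spheres can overlap this one
      if (sum((xyz[a, ] - xyz[b, ])^2) >= (rr[a] + rr[b])^2) next
      d2 <- rowSums(sweep(pts, 2, xyz[b, ])^2)
      exposed <- exposed & d2 > rr[b]^2
      if (!any(exposed)) break
    }
    per_atom[a] <- 4 * pi * rr[a]^2 * mean(exposed)
  }
  list(total = sum(per_atom), per_atom = per_atom)
}

#' Nonpolar solvation free energy
#'
#' The linear surface-area model gamma * SASA + b with the constants carried
#' in `options` (defaults gamma = 0.00542 kcal/(mol*A^2), b = 0.92
#' kcal/mol).
#'
#' @param sasa_total total solvent accessible surface area, Angstrom^2.
#' @param options a `pbsa_options`.
#' @return kcal/mol.
#' @export
nonpolar_solvation <- function(sasa_total, options = pbsa_options()) {
  stopifnot(sasa_total >= 0)
  options$gamma * sasa_total + options$b_const
}
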