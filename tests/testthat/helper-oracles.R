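# Independent oracles used across test files. These deliberately avoid the
# package's own code paths.

# dihedral from the two plane normals and atan2, IUPAC sign
oracle_dihedral <- function(x, i, j, k, l) {
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  b1 <- x[j, ] - x[i, ]; b2 <- x[k, ] - x[j, ]; b3 <- x[l, ] - x[k, ]
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  s <- sum(cr(n1, n2) * b2) / sqrt(sum(b2^2))
  ang <- atan2(s, sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang + 360 else ang
}

# best-rmsd rigid superposition by direct search over rotations
# (axis-angle parameterization, multi-start Nelder-Mead; no Kabsch)
oracle_superpose_rmsd <- function(A, B) {
  rotvec_to_mat <- function(v) {
    th <- sqrt(sum(v^2))
    if (th < 1e-12) return(diag(3))
    k <- v / th
    K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3,
                byrow = TRUE)
    diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  }
  A0 <- sweep(A, 2, colMeans(A)); B0 <- sweep(B, 2, colMeans(B))
  obj <- function(v) {
    R <- rotvec_to_mat(v)
    sqrt(sum((A0 %*% t(R) - B0)^2) / nrow(A))
  }
  best <- Inf
  set.seed(99)
  starts <- rbind(matrix(0, 1, 3),
                  matrix(stats::runif(3 * 40, -pi, pi), 40, 3))
  for (s in seq_len(nrow(starts))) {
    r <- stats::optim(starts[s, ], obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
    if (r$value < best) best <- r$value
  }
  best
}

# constrained ordinary-least-squares charge fit (KKT system, no restraint)
oracle_ols_charges <- function(points, values, atom_coords, net_charge) {
  d2 <- outer(rowSums(points^2), rowSums(atom_coords^2), "+") -
    2 * points %*% t(atom_coords)
  A <- 1 / sqrt(d2)
  p <- ncol(A)
  K <- rbind(cbind(crossprod(A), rep(1, p)), c(rep(1, p), 0))
  sol <- solve(K, c(crossprod(A, values), net_charge))
  sol[seq_len(p)]
}

coarse_pbsa <- function(...) {
  pbsa_options(grid_spacing = 0.8, grid_padding = 6, sasa_points = 240L, ...)
}
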