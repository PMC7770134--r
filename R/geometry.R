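#' Measure a proper dihedral angle
#'
#' Standard IUPAC sign convention: looking down the j->k bond, a clockwise
#' rotation of the far bond relative to the near bond is positive. Used to
#' verify constructed (phi, psi) backbone states and to restrain them during
#' minimization.
#'
#' @param x a `conformer` or an n x 3 coordinate matrix (Angstrom).
#' @param i,j,k,l distinct atom indices (1-based).
#' @return angle in degrees, in (-180, 180].
#' @export
measure_dihedral <- function(x, i, j, k, l) {
  xyz <- if (inherits(x, "conformer")) x$xyz else as.matrix(x)
  idx <- c(i, j, k, l)
  if (anyDuplicated(idx) || any(idx < 1) || any(idx > nrow(xyz)))
    stop("dihedral indices must be four distinct in-range atoms")
  b1 <- xyz[j, ] - xyz[i, ]
  b2 <- xyz[k, ] - xyz[j, ]
  b3 <- xyz[l, ] - xyz[k, ]
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-10 || sqrt(sum(n2^2)) < 1e-10)
    stop("degenerate geometry: three collinear atoms in dihedral")
  m1 <- .cross3(b2 / sqrt(sum(b2^2)), n1)
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  # atan2 returns (-180, 180]; map -180 to +180 for the stated range
  if (ang <= -180) ang <- ang + 360
  ang
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Optimal rigid-body superposition (Kabsch) and RMSD
#'
#' Least-squares superposition of `mobile` onto `reference` over the chosen
#' atom selection, pairing atoms by index. The returned rotation is proper
#' (det = +1). The RMSD is measured on the same selection used for fitting,
#' matching the heavy-atom / all-atom displacement protocol used to compare
#' minimized and quantum-mechanical dipeptide structures.
#'
#' @param mobile,reference `conformer` objects (or n x 3 matrices) with equal
#'   atom counts.
#' @param selection `"heavy"` (non-hydrogen atoms) or `"all"`. Matrices only
#'   support `"all"`.
#' @return A list with `rotation` (3 x 3), `translation` (length 3; the
#'   transform is `x %*% t(R) + t`), `rmsd` (Angstrom) and `xyz` (the
#'   transformed full mobile coordinate set).
#' @export
superpose <- function(mobile, reference, selection = c("heavy", "all")) {
  selection <- match.arg(selection)
  get_xyz <- function(z) if (inherits(z, "conformer")) z$xyz else as.matrix(z)
  xm <- get_xyz(mobile); xr <- get_xyz(reference)
  if (selection == "heavy") {
    if (!inherits(mobile, "conformer") || !inherits(reference, "conformer"))
      stop("heavy-atom selection requires conformer inputs")
    sm <- is_heavy(mobile); sr <- is_heavy(reference)
  } else {
    sm <- rep(TRUE, nrow(xm)); sr <- rep(TRUE, nrow(xr))
  }
  if (sum(sm) != sum(sr)) stop("selections have mismatched atom counts")
  if (sum(sm) < 3) stop("superposition needs at least 3 selected atoms")
  A <- xm[sm, , drop = FALSE]
  B <- xr[sr, , drop = FALSE]
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  H <- crossprod(A0, B0)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- cb - as.numeric(R %*% ca)
  fitA <- A %*% t(R) + matrix(tr, nrow(A), 3, byrow = TRUE)
  rmsd <- sqrt(sum((fitA - B)^2) / nrow(B))
  list(rotation = R, translation = tr, rmsd = rmsd,
       xyz = xm %*% t(R) + matrix(tr, nrow(xm), 3, byrow = TRUE))
}

#' RMSD after optimal superposition
#'
#' @inheritParams superpose
#' @return RMSD in Angstrom.
#' @export
rmsd_fit <- function(mobile, reference, selection = c("heavy", "all")) {
  superpose(mobile, reference, selection)$rmsd
}

#' Apply a rigid transform to coordinates
#' @param xyz n x 3 matrix.
#' @param rotation 3 x 3 proper rotation matrix.
#' @param translation length-3 vector.
#' @return transformed n x 3 matrix.
#' @export
rigid_transform <- function(xyz, rotation = diag(3), translation = c(0, 0, 0)) {
  as.matrix(xyz) %*% t(rotation) + matrix(translation, nrow(xyz), 3, byrow = TRUE)
}

#' Rotation matrix about a coordinate axis
#' @param axis "x", "y" or "z".
#' @param angle degrees.
#' @return 3 x 3 rotation matrix.
#' @export
rotation_about <- function(axis = c("x", "y", "z"), angle) {
  axis <- match.arg(axis)
  a <- angle * pi / 180
  ca <- cos(a); sa <- sin(a)
  switch(axis,
    x = matrix(c(1, 0, 0, 0, ca, -sa, 0, sa, ca), 3, 3, byrow = TRUE),
    y = matrix(c(ca, 0, sa, 0, 1, 0, -sa, 0, ca), 3, 3, byrow = TRUE),
    z = matrix(c(ca, -sa, 0, sa, ca, 0, 0, 0, 1), 3, 3, byrow = TRUE))
}
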