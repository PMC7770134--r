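#' Construct a conformer
#'
#' A conformer is an ordered atom list with Cartesian coordinates and optional
#' backbone torsion annotations. It is the basic structural unit of the
#' package: capped dipeptides (Ace-XXX-NMe) in their alpha-helical
#' (phi, psi) ~ (-60, -40) and beta-strand (phi, psi) ~ (180, 180) backbone
#' states are represented this way, as are receptor/ligand selections of an
#' MM/PBSA complex.
#'
#' @param atoms data.frame with columns `name` (atom label), `element`
#'   (symbol), `resname` (3-4 character residue code, noncanonical codes such
#'   as "NIY" allowed), `resindex` (integer residue number).
#' @param xyz numeric matrix, n x 3, coordinates in Angstrom.
#' @param label one of "alpha", "beta", "other".
#' @param phi,psi backbone torsions in degrees, in (-180, 180], or `NA`.
#' @return An object of class `"conformer"`: a list with elements `atoms`,
#'   `xyz`, `label`, `phi`, `psi`.
#' @export
conformer <- function(atoms, xyz, label = "other", phi = NA_real_, psi = NA_real_) {
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  stopifnot(is.data.frame(atoms), ncol(xyz) == 3, nrow(xyz) == nrow(atoms),
            nrow(atoms) >= 1)
  if (!all(c("name", "element", "resname", "resindex") %in% names(atoms)))
    stop("atoms must have columns name, element, resname, resindex")
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  label <- match.arg(label, c("alpha", "beta", "other"))
  for (ang in c(phi, psi)) {
    if (!is.na(ang) && (ang <= -180 || ang > 180))
      stop("torsion annotations must lie in (-180, 180]")
  }
  structure(list(atoms = atoms, xyz = xyz, label = label,
                 phi = as.numeric(phi), psi = as.numeric(psi)),
            class = "conformer")
}

#' @export
print.conformer <- function(x, ...) {
  cat(sprintf("<conformer> %d atoms, label=%s", nrow(x$atoms), x$label))
  if (!is.na(x$phi)) cat(sprintf(", phi=%.1f", x$phi))
  if (!is.na(x$psi)) cat(sprintf(", psi=%.1f", x$psi))
  cat("\n")
  invisible(x)
}

#' Number of atoms in a conformer
#' @param x a `conformer`.
#' @return integer atom count.
#' @export
n_atoms <- function(x) nrow(x$atoms)

#' Logical mask of heavy (non-hydrogen) atoms
#' @param x a `conformer`.
#' @return logical vector, `TRUE` where the element is not hydrogen.
#' @export
is_heavy <- function(x) x$atoms$element != "H"

#' Construct a per-atom partial charge set
#'
#' Charges are in elementary charge units and must sum to the declared
#' integer net charge. Each atom carries a group tag used by the blending
#' step: capping groups (`ACE`, `NME`) keep their reference force-field
#' charges, while `BACKBONE` and `SIDECHAIN` atoms are refit/blended.
#'
#' @param charges numeric vector, e.
#' @param net_charge integer total charge.
#' @param groups character vector of tags in
#'   `c("ACE", "NME", "BACKBONE", "SIDECHAIN")`, recycled if length 1.
#' @param tol tolerance on `|sum(charges) - net_charge|`.
#' @return An object of class `"charge_set"`.
#' @export
charge_set <- function(charges, net_charge = 0L, groups = "SIDECHAIN",
                       tol = 1e-6) {
  charges <- as.numeric(charges)
  if (length(groups) == 1) groups <- rep(groups, length(charges))
  stopifnot(length(groups) == length(charges))
  if (!all(groups %in% c("ACE", "NME", "BACKBONE", "SIDECHAIN")))
    stop("unknown group tag")
  if (abs(sum(charges) - net_charge) > tol)
    stop(sprintf("charges sum to %.8f, declared net charge is %d",
                 sum(charges), net_charge))
  structure(list(charges = charges, net_charge = as.integer(net_charge),
                 groups = groups),
            class = "charge_set")
}

#' @export
print.charge_set <- function(x, ...) {
  cat(sprintf("<charge_set> %d atoms, net %+d e, range [%.3f, %.3f]\n",
              length(x$charges), x$net_charge,
              min(x$charges), max(x$charges)))
  invisible(x)
}

#' Construct a force-field parameter set (Amber functional form)
#'
#' Holds the bonded and Lennard-Jones parameters of the potential
#' E = E_bond + E_angle + E_dihedral + E_es + E_vdW. Bonded and LJ parameters
#' are inputs to this package (they originate from GAFF/ff14SB-style
#' assignments upstream); only the charges are derived here.
#'
#' @param bonds data.frame `i, j, k_r, r_eq`: harmonic K_r in
#'   kcal/(mol*A^2) (E = K_r (r - r_eq)^2, Amber convention without the 1/2),
#'   r_eq in Angstrom.
#' @param angles data.frame `i, j, k, k_theta, theta_eq`: K_theta in
#'   kcal/(mol*rad^2), theta_eq in degrees.
#' @param dihedrals data.frame `i, j, k, l, v_n, n, gamma`: barrier V_n in
#'   kcal/mol, integer periodicity n >= 1, phase gamma in degrees. Several
#'   rows may share the same four atoms (Fourier series).
#' @param lj data.frame `rmin2, eps`: per-atom r_min/2 in Angstrom and epsilon
#'   in kcal/mol; combined by Lorentz-Berthelot rules
#'   (r_min,ij = r_min,i/2 + r_min,j/2, eps_ij = sqrt(eps_i eps_j)).
#' @param exclusions two-column matrix of 1-2 and 1-3 atom pairs excluded from
#'   nonbonded sums.
#' @param pairs14 two-column matrix of 1-4 pairs, scaled by `scale_ee_14` and
#'   `scale_vdw_14`.
#' @param scale_ee_14,scale_vdw_14 1-4 scale factors; Amber ff14SB convention
#'   1/1.2 and 1/2.0.
#' @return An object of class `"ff_params"`.
#' @export
ff_params <- function(bonds = NULL, angles = NULL, dihedrals = NULL,
                      lj, exclusions = NULL, pairs14 = NULL,
                      scale_ee_14 = 1 / 1.2, scale_vdw_14 = 0.5) {
  empty <- function(cols) {
    as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)), cols))
  }
  if (is.null(bonds)) bonds <- empty(c("i", "j", "k_r", "r_eq"))
  if (is.null(angles)) angles <- empty(c("i", "j", "k", "k_theta", "theta_eq"))
  if (is.null(dihedrals)) dihedrals <- empty(c("i", "j", "k", "l", "v_n", "n", "gamma"))
  norm_pairs <- function(p) {
    if (is.null(p) || NROW(p) == 0) return(matrix(integer(0), 0, 2))
    p <- as.matrix(p)[, 1:2, drop = FALSE]
    storage.mode(p) <- "integer"
    t(apply(p, 1, sort))
  }
  exclusions <- norm_pairs(exclusions)
  pairs14 <- norm_pairs(pairs14)
  if (nrow(exclusions) && nrow(pairs14)) {
    key <- function(m) paste(m[, 1], m[, 2])
    if (length(intersect(key(exclusions), key(pairs14))))
      stop("exclusion and 1-4 lists must be disjoint")
  }
  stopifnot(all(bonds$k_r >= 0), all(angles$k_theta >= 0),
            all(lj$eps >= 0), all(dihedrals$n >= 1))
  structure(list(bonds = bonds, angles = angles, dihedrals = dihedrals,
                 lj = lj, exclusions = exclusions, pairs14 = pairs14,
                 scale_ee_14 = scale_ee_14, scale_vdw_14 = scale_vdw_14),
            class = "ff_params")
}

#' @export
print.ff_params <- function(x, ...) {
  cat(sprintf(
    "<ff_params> %d bonds, %d angles, %d dihedral terms, %d LJ atoms\n",
    nrow(x$bonds), nrow(x$angles), nrow(x$dihedrals), nrow(x$lj)))
  invisible(x)
}
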