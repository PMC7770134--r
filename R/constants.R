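#' Physical constants and radii used throughout the package
#'
#' @description
#' `uaaff_constants()` returns the fixed unit-conversion and energy constants
#' the package computes with. All Cartesian work is in Angstrom and kcal/mol;
#' ESP fitting is carried out in atomic units (Bohr, hartree) and converted
#' only at I/O boundaries.
#'
#' @return A named list:
#' \describe{
#'   \item{bohr_to_angstrom}{0.52917721 Angstrom per Bohr.}
#'   \item{coulomb_kcal}{Electrostatic prefactor, 332.0637 kcal*Angstrom/(mol*e^2)
#'     (Amber code convention).}
#'   \item{kT_300}{k_B T at 300 K, kcal/mol.}
#' }
#' @export
uaaff_constants <- function() {
  list(
    bohr_to_angstrom = 0.52917721,
    coulomb_kcal     = 332.0637,
    kT_300           = 0.0019872041 * 300
  )
}

# Bondi van der Waals radii (Angstrom), with iodine replaced by the Pauling
# value 2.15 used for the halogenated side chains handled here.
.default_vdw <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47, S = 1.80, P = 1.80,
  Cl = 1.75, Br = 1.85, I = 2.15, Na = 2.27, K = 2.75, Mg = 1.73, Zn = 1.39
)

#' Van der Waals radii lookup
#'
#' Bondi radii for all supported elements except iodine, which uses the
#' Pauling radius (2.15 Angstrom). The table is configurable via `override`.
#'
#' @param elements character vector of element symbols.
#' @param override optional named numeric vector of radii (Angstrom) that
#'   replaces or extends the built-in table.
#' @return numeric vector of radii, Angstrom.
#' @export
#' @examples
#' vdw_radii(c("C", "I"))
vdw_radii <- function(elements, override = NULL) {
  tab <- .default_vdw
  if (!is.null(override)) tab[names(override)] <- override
  r <- tab[elements]
  if (anyNA(r)) {
    stop("no van der Waals radius for element(s): ",
         paste(unique(elements[is.na(r)]), collapse = ", "))
  }
  unname(r)
}
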