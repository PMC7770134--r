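.element_from_name <- function(name) {
  core <- sub("^[0-9 ]+", "", toupper(name))
  two <- substr(core, 1, 2)
  if (two %in% c("CL", "BR", "NA", "MG", "ZN"))
    return(paste0(substr(two, 1, 1), tolower(substr(two, 2, 2))))
  substr(core, 1, 1)
}

#' Read structures from a PDB file
#'
#' Fixed-column PDB reader (via bio3d) returning package `conformer`
#' objects. Multi-model files (MODEL/ENDMDL snapshot series) yield one
#' conformer per model with identical atom ordering. The element column is
#' honored when present, falling back to name-derived elements, and
#' nonstandard residue codes (noncanonical amino acids such as "NIY") are
#' preserved verbatim.
#'
#' @param path PDB file.
#' @return a single `conformer`, or a list of conformers for multi-model
#'   files.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  at <- grep("^(ATOM  |HETATM)", lines)
  for (ln in at) {
    rec <- lines[ln]
    coords <- suppressWarnings(as.numeric(c(
      substr(rec, 31, 38), substr(rec, 39, 46), substr(rec, 47, 54))))
    if (nchar(rec) < 54 || anyNA(coords))
      stop(sprintf("malformed ATOM record at line %d of %s", ln, path))
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atom <- pdb$atom
  elem <- trimws(atom$elesy)
  bad <- is.na(elem) | elem == ""
  if (any(bad))
    elem[bad] <- vapply(atom$elety[bad], .element_from_name, character(1))
  elem <- paste0(toupper(substr(elem, 1, 1)),
                 tolower(substring(elem, 2)))
  atoms <- data.frame(name = trimws(atom$elety), element = elem,
                      resname = trimws(atom$resid), resindex = atom$resno)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_models <- nrow(xyz)
  confs <- lapply(seq_len(n_models), function(m) {
    conformer(atoms, matrix(xyz[m, ], ncol = 3, byrow = TRUE))
  })
  if (n_models == 1) confs[[1]] else confs
}

#' Write conformers to a PDB file
#'
#' @param confs a `conformer` or list of conformers (written as
#'   MODEL/ENDMDL series; atom counts must match).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(confs, path) {
  if (inherits(confs, "conformer")) confs <- list(confs)
  n <- vapply(confs, n_atoms, integer(1))
  if (length(unique(n)) != 1) stop("mixed atom counts across models")
  a <- confs[[1]]$atoms
  multi <- length(confs) > 1
  out <- character(0)
  fmt_atom <- function(i, xyz) {
    sprintf("ATOM  %5d %-4s %-4s%5d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            i, substr(a$name[i], 1, 4), substr(a$resname[i], 1, 4),
            a$resindex[i], xyz[i, 1], xyz[i, 2], xyz[i, 3], 1, 0,
            toupper(a$element[i]))
  }
  for (m in seq_along(confs)) {
    if (multi) out <- c(out, sprintf("MODEL     %4d", m))
    out <- c(out, vapply(seq_len(n[1]), fmt_atom, character(1),
                         xyz = confs[[m]]$xyz))
    out <- c(out, if (multi) "ENDMDL" else "TER")
  }
  out <- c(out, "END")
  writeLines(out, path)
  invisible(path)
}

#' Write an ESP grid file
#'
#' Plain-text dialect mirroring the classic RESP/Gaussian ESP layout:
#' a header line `n_atoms n_points net_charge`, then one `x y z` line per
#' atom (Bohr), then one `V x y z` line per grid point (hartree/e, Bohr).
#'
#' @param atom_coords n x 3 matrix, Bohr.
#' @param grid an `esp_grid` with values.
#' @param path output file.
#' @param net_charge integer, stored in the header.
#' @return `path`, invisibly.
#' @export
write_esp_grid <- function(atom_coords, grid, path, net_charge = 0L) {
  stopifnot(inherits(grid, "esp_grid"), !is.null(grid$values))
  atom_coords <- as.matrix(atom_coords)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d%6d%4d", nrow(atom_coords), grid$n_points,
                     as.integer(net_charge)), con)
  writeLines(sprintf("%16.7E%16.7E%16.7E", atom_coords[, 1], atom_coords[, 2],
                     atom_coords[, 3]), con)
  writeLines(sprintf("%16.7E%16.7E%16.7E%16.7E", grid$values,
                     grid$points[, 1], grid$points[, 2], grid$points[, 3]),
             con)
  invisible(path)
}

#' Read an ESP grid file
#'
#' Reads the dialect written by [write_esp_grid()]. Fortran D-exponents
#' (`1.0D-03`) are tolerated.
#'
#' @param path input file.
#' @return list: `atom_coords` (Bohr), `grid` (an `esp_grid` with values),
#'   `net_charge`.
#' @export
read_esp_grid <- function(path) {
  lines <- gsub("[dD]([+-][0-9])", "E\\1", readLines(path, warn = FALSE))
  head <- scan(text = lines[1], quiet = TRUE)
  if (length(head) < 2) stop("malformed ESP header")
  na <- head[1]; np <- head[2]
  nq <- if (length(head) >= 3) as.integer(head[3]) else 0L
  nums <- scan(text = lines[-1], quiet = TRUE)
  if (length(nums) != 3 * na + 4 * np)
    stop("ESP file length inconsistent with header")
  ac <- matrix(nums[seq_len(3 * na)], ncol = 3, byrow = TRUE)
  rest <- matrix(nums[-seq_len(3 * na)], ncol = 4, byrow = TRUE)
  list(atom_coords = ac,
       grid = esp_grid(rest[, 2:4], values = rest[, 1]),
       net_charge = nq)
}

#' Write a force-field parameter file
#'
#' Versioned YAML schema with a units declaration, per-atom metadata
#' (name, element, LJ r_min/2 and epsilon, charge, group tag), bonded
#' parameter sections, exclusion and 1-4 pair lists. Round-trips exactly
#' through [read_ff_params()].
#'
#' @param atoms data.frame with `name`, `element` (e.g. `conformer$atoms`).
#' @param params a `ff_params`.
#' @param charges a `charge_set`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ff_params <- function(atoms, params, charges, path) {
  doc <- list(
    format = "uaaff-params-1",
    units = list(energy = "kcal/mol", length = "angstrom", charge = "e",
                 angle = "degrees"),
    net_charge = charges$net_charge,
    scale_ee_14 = params$scale_ee_14,
    scale_vdw_14 = params$scale_vdw_14,
    atoms = lapply(seq_len(nrow(atoms)), function(i) {
      list(name = atoms$name[i], element = atoms$element[i],
           rmin2 = params$lj$rmin2[i], eps = params$lj$eps[i],
           charge = charges$charges[i], group = charges$groups[i])
    }),
    bonds = unname(apply(params$bonds, 1, as.list)),
    angles = unname(apply(params$angles, 1, as.list)),
    dihedrals = unname(apply(params$dihedrals, 1, as.list)),
    exclusions = unname(apply(params$exclusions, 1, as.integer,
                              simplify = FALSE)),
    pairs14 = unname(apply(params$pairs14, 1, as.integer, simplify = FALSE)))
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

#' Read a force-field parameter file
#'
#' @param path a file written by [write_ff_params()] (YAML; JSON also
#'   accepted since JSON is a YAML subset).
#' @return list: `atoms` (data.frame name/element), `params` (`ff_params`),
#'   `charges` (`charge_set`).
#' @export
read_ff_params <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$format) || !startsWith(doc$format, "uaaff-params"))
    stop("not a uaaff parameter file (missing format tag)")
  if (is.null(doc$units)) stop("parameter file must declare units")
  df_from <- function(lst, cols) {
    if (!length(lst))
      return(as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)),
                                           cols)))
    out <- do.call(rbind, lapply(lst, function(r) as.data.frame(r[cols])))
    out
  }
  atoms <- df_from(doc$atoms, c("name", "element"))
  lj <- df_from(doc$atoms, c("rmin2", "eps"))
  qs <- vapply(doc$atoms, function(a) as.numeric(a$charge), numeric(1))
  grp <- vapply(doc$atoms, function(a) as.character(a$group), character(1))
  pairs_mat <- function(lst) {
    if (!length(lst)) return(NULL)
    do.call(rbind, lapply(lst, as.integer))
  }
  params <- ff_params(
    bonds = df_from(doc$bonds, c("i", "j", "k_r", "r_eq")),
    angles = df_from(doc$angles, c("i", "j", "k", "k_theta", "theta_eq")),
    dihedrals = df_from(doc$dihedrals, c("i", "j", "k", "l", "v_n", "n", "gamma")),
    lj = lj,
    exclusions = pairs_mat(doc$exclusions),
    pairs14 = pairs_mat(doc$pairs14),
    scale_ee_14 = doc$scale_ee_14, scale_vdw_14 = doc$scale_vdw_14)
  list(atoms = atoms, params = params,
       charges = charge_set(qs, net_charge = doc$net_charge, groups = grp))
}

#' Read a relative-energy benchmark table
#'
#' Tab-separated with a header row (`system`, then one column per
#' method/cycle series); empty fields are missing values.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_benchmark <- function(path) {
  utils::read.delim(path, check.names = FALSE)
}

#' Write a relative-energy benchmark table
#' @param tab data.frame as returned by [read_benchmark()] or [table2()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_benchmark <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Import partial charges from a mol2 file
#'
#' Minimal importer for the charge column of the `@<TRIPOS>ATOM` block.
#'
#' @param path mol2 file.
#' @return data.frame with `name` and `charge`.
#' @export
read_mol2_charges <- function(path) {
  lines <- readLines(path, warn = FALSE)
  start <- grep("^@<TRIPOS>ATOM", lines)
  if (!length(start)) stop("no @<TRIPOS>ATOM section")
  end <- grep("^@<TRIPOS>", lines)
  end <- c(end[end > start[1]], length(lines) + 1)[1]
  block <- lines[(start[1] + 1):(end - 1)]
  block <- block[nzchar(trimws(block))]
  fields <- strsplit(trimws(block), "[[:space:]]+")
  data.frame(name = vapply(fields, `[`, character(1), 2),
             charge = vapply(fields, function(f)
               as.numeric(f[min(9, length(f))]), numeric(1)))
}
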