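#' Atom indices of a set of residues
#' @param conf a `conformer`.
#' @param resindices integer residue indices.
#' @return integer atom indices.
#' @export
select_residues <- function(conf, resindices) {
  which(conf$atoms$resindex %in% resindices)
}

# receptor-ligand cross nonbonded terms (no exclusions across molecules)
.cross_mm <- function(xyz, charges, lj, rec_idx, lig_idx) {
  kc <- uaaff_constants()$coulomb_kcal
  A <- xyz[rec_idx, , drop = FALSE]
  B <- xyz[lig_idx, , drop = FALSE]
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  d <- sqrt(pmax(d2, 0))
  if (any(d < 1e-6)) stop("overlapping receptor/ligand atoms")
  ees <- kc * outer(charges[rec_idx], charges[lig_idx]) / d
  rmin <- outer(lj$rmin2[rec_idx], lj$rmin2[lig_idx], "+")
  eps <- sqrt(outer(lj$eps[rec_idx], lj$eps[lig_idx]))
  sr6 <- (rmin / d)^6
  evdw <- eps * (sr6^2 - 2 * sr6)
  list(e_es = sum(ees), e_vdw = sum(evdw), ees = ees, evdw = evdw)
}

# population standard deviation, sqrt(sum((x - mean)^2) / N)
.sd_pop <- function(x) sqrt(sum((x - mean(x))^2) / length(x))

#' Single-trajectory MM/PBSA binding free energy
#'
#' For each snapshot the receptor and ligand coordinates are extracted from
#' the complex frame (so all bonded terms cancel identically) and
#' \deqn{\Delta G_\mathrm{bind} = \Delta E_\mathrm{vdW} + \Delta E_\mathrm{ele}
#'       + \Delta G_\mathrm{pb/solv} + \Delta G_\mathrm{np/solv}}
#' is accumulated: the molecular-mechanics terms from receptor-ligand cross
#' interactions, the polar solvation from three [solve_pb()] calls
#' (complex, receptor, ligand) and the nonpolar solvation from the three
#' SASAs (so the area term is gamma * Delta SASA - b). The entropy term
#' -T Delta S is deliberately not computed. Averages are reported with the
#' population standard deviation sqrt(sum((x_i - mean)^2) / N) over
#' snapshots.
#'
#' @param snapshots a `conformer` or list of `conformer`s (identical atom
#'   ordering), e.g. from [read_pdb()] on a multi-model file.
#' @param ligand_atoms integer atom indices of the ligand; the receptor is
#'   the complement.
#' @param options a `pbsa_options`.
#' @param params a `ff_params` (LJ block is used for cross terms).
#' @param charges a `charge_set` for the whole complex.
#' @param radii per-atom radii for the dielectric boundary and SASA;
#'   defaults to [vdw_radii()] of the elements.
#' @return object of class `"binding_energy"`: `summary` data.frame
#'   (component, mean, sd), `per_snapshot` data.frame, `n_snapshots`.
#' @export
binding_energy <- function(snapshots, ligand_atoms, options = pbsa_options(),
                           params, charges, radii = NULL) {
  if (inherits(snapshots, "conformer")) snapshots <- list(snapshots)
  stopifnot(length(snapshots) >= 1)
  conf1 <- snapshots[[1]]
  n <- n_atoms(conf1)
  lig <- sort(unique(as.integer(ligand_atoms)))
  if (!length(lig) || any(lig < 1 | lig > n)) stop("bad ligand selection")
  rec <- setdiff(seq_len(n), lig)
  if (!length(rec)) stop("empty receptor selection")
  if (inherits(charges, "charge_set")) qv <- charges$charges else qv <- charges
  if (is.null(radii)) radii <- vdw_radii(conf1$atoms$element)

  comp <- c("de_vdw", "de_ele", "dg_pb_solv", "dg_np_solv",
            "de_mm", "dg_solv", "dg_bind")
  per <- matrix(NA_real_, length(snapshots), length(comp),
                dimnames = list(NULL, comp))
  for (s in seq_along(snapshots)) {
    xyz <- snapshots[[s]]$xyz
    mm <- .cross_mm(xyz, qv, params$lj, rec, lig)
    pb_c <- solve_pb(xyz, qv, radii, options)$energy
    pb_r <- solve_pb(xyz[rec, , drop = FALSE], qv[rec], radii[rec], options)$energy
    pb_l <- solve_pb(xyz[lig, , drop = FALSE], qv[lig], radii[lig], options)$energy
    sa_c <- sasa(xyz, radii, options$probe_radius, options$sasa_points)$total
    sa_r <- sasa(xyz[rec, , drop = FALSE], radii[rec], options$probe_radius,
                 options$sasa_points)$total
    sa_l <- sasa(xyz[lig, , drop = FALSE], radii[lig], options$probe_radius,
                 options$sasa_points)$total
    dg_np <- nonpolar_solvation(sa_c, options) -
      nonpolar_solvation(sa_r, options) - nonpolar_solvation(sa_l, options)
    dg_pb <- pb_c - pb_r - pb_l
    per[s, ] <- c(mm$e_vdw, mm$e_es, dg_pb, dg_np,
                  mm$e_vdw + mm$e_es, dg_pb + dg_np,
                  mm$e_vdw + mm$e_es + dg_pb + dg_np)
  }
  summ <- data.frame(component = comp,
                     mean = colMeans(per),
                     sd = apply(per, 2, .sd_pop))
  structure(list(summary = summ, per_snapshot = as.data.frame(per),
                 n_snapshots = length(snapshots),
                 ligand_atoms = lig),
            class = "binding_energy")
}

#' @export
print.binding_energy <- function(x, ...) {
  lab <- c(de_vdw = "dE_vdW", de_ele = "dE_ele", dg_pb_solv = "dG_pb/solv",
           dg_np_solv = "dG_np/solv", de_mm = "dE_MM", dg_solv = "dG_solv",
           dg_bind = "dG_bind")
  cat(sprintf("MM/PBSA binding energy over %d snapshot%s (kcal/mol)\n",
              x$n_snapshots, if (x$n_snapshots == 1) "" else "s"))
  for (r in seq_len(nrow(x$summary)))
    cat(sprintf("  %-11s %8.2f (%.2f)\n", lab[x$summary$component[r]],
                x$summary$mean[r], x$summary$sd[r]))
  invisible(x)
}

#' @export
summary.binding_energy <- function(object, ...) {
  print(object)
  invisible(object$summary)
}

#' Per-residue decomposition of the binding free energy
#'
#' Splits \eqn{\Delta G_\mathrm{bind}} of one snapshot into per-residue
#' contributions \eqn{\Delta G^\mathrm{res} = \Delta E^\mathrm{res}_{MM} +
#' \Delta G^\mathrm{res}_\mathrm{pb} + \Delta G^\mathrm{res}_\mathrm{np}}:
#' receptor-ligand cross interaction terms are assigned half to each
#' partner's residue; the polar term by the 1/2 q_i delta-phi reaction-field
#' attribution of the three PB solves; the nonpolar term from per-atom SASA
#' differences, with the constant b spread uniformly over atoms so that
#' residue totals sum exactly to the global components.
#'
#' @param snapshot a `conformer` (one frame of the complex).
#' @inheritParams binding_energy
#' @return object of class `"residue_decomposition"`: a data.frame with
#'   columns `resindex`, `resname`, `role`, `de_mm_res`, `dg_pb_res`,
#'   `dg_np_res`, `total_res`; the matching global components are attached
#'   as attribute `"totals"`.
#' @export
per_residue_decomposition <- function(snapshot, ligand_atoms,
                                      options = pbsa_options(),
                                      params, charges, radii = NULL) {
  stopifnot(inherits(snapshot, "conformer"))
  n <- n_atoms(snapshot)
  lig <- sort(unique(as.integer(ligand_atoms)))
  rec <- setdiff(seq_len(n), lig)
  if (inherits(charges, "charge_set")) qv <- charges$charges else qv <- charges
  if (is.null(radii)) radii <- vdw_radii(snapshot$atoms$element)
  xyz <- snapshot$xyz
  res_of <- snapshot$atoms$resindex

  # MM cross terms, half to each partner atom's residue
  mm <- .cross_mm(xyz, qv, params$lj, rec, lig)
  pair_e <- mm$ees + mm$evdw
  atom_mm <- numeric(n)
  atom_mm[rec] <- rowSums(pair_e) / 2
  atom_mm[lig] <- colSums(pair_e) / 2

  # polar: 1/2 q_i (phi_complex - phi_state) charge attribution
  pb_c <- solve_pb(xyz, qv, radii, options)
  pb_r <- solve_pb(xyz[rec, , drop = FALSE], qv[rec], radii[rec], options)
  pb_l <- solve_pb(xyz[lig, , drop = FALSE], qv[lig], radii[lig], options)
  atom_pb <- numeric(n)
  atom_pb[rec] <- 0.5 * qv[rec] * (pb_c$phi_reaction[rec] - pb_r$phi_reaction)
  atom_pb[lig] <- 0.5 * qv[lig] * (pb_c$phi_reaction[lig] - pb_l$phi_reaction)

  # nonpolar: per-atom SASA differences, b spread uniformly over atoms
  sa_c <- sasa(xyz, radii, options$probe_radius, options$sasa_points)$per_atom
  sa_r <- sasa(xyz[rec, , drop = FALSE], radii[rec], options$probe_radius,
               options$sasa_points)$per_atom
  sa_l <- sasa(xyz[lig, , drop = FALSE], radii[lig], options$probe_radius,
               options$sasa_points)$per_atom
  b <- options$b_const
  atom_np <- numeric(n)
  atom_np[rec] <- options$gamma * (sa_c[rec] - sa_r) + b / n - b / length(rec)
  atom_np[lig] <- options$gamma * (sa_c[lig] - sa_l) + b / n - b / length(lig)

  agg <- function(v) tapply(v, res_of, sum)
  resindex <- sort(unique(res_of))
  out <- data.frame(
    resindex = resindex,
    resname = snapshot$atoms$resname[match(resindex, res_of)],
    role = ifelse(resindex %in% res_of[lig], "ligand", "receptor"),
    de_mm_res = as.numeric(agg(atom_mm)[as.character(resindex)]),
    dg_pb_res = as.numeric(agg(atom_pb)[as.character(resindex)]),
    dg_np_res = as.numeric(agg(atom_np)[as.character(resindex)]))
  out$total_res <- out$de_mm_res + out$dg_pb_res + out$dg_np_res
  attr(out, "totals") <- c(
    de_mm = mm$e_es + mm$e_vdw,
    dg_pb = pb_c$energy - pb_r$energy - pb_l$energy,
    dg_np = options$gamma * (sum(sa_c) - sum(sa_r) - sum(sa_l)) - b)
  class(out) <- c("residue_decomposition", "data.frame")
  out
}

#' @export
print.residue_decomposition <- function(x, ...) {
  cat("Per-residue binding energy decomposition (kcal/mol)\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  tt <- attr(x, "totals")
  cat(sprintf("totals: dE_MM %.4f, dG_pb %.4f, dG_np %.4f\n",
              tt["de_mm"], tt["dg_pb"], tt["dg_np"]))
  invisible(x)
}
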