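# NeRF-style internal-coordinate placement: position atom d bonded to c at
# distance r, with angle(b,c,d) = theta and dihedral(a,b,c,d) = phi.
.place_atom <- function(a, b, c, r, theta_deg, phi_deg) {
  th <- theta_deg * pi / 180
  ph <- phi_deg * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- .cross3(ab, bc)
  n <- n / sqrt(sum(n^2))
  m <- .cross3(n, bc)
  c + r * (-cos(th) * bc + sin(th) * cos(ph) * m + sin(th) * sin(ph) * n)
}

# run fn with a temporarily seeded RNG, restoring the caller's stream
.with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  fn()
}

#' Exclusion and 1-4 pair lists from a bond graph
#'
#' @param bonds data.frame with columns `i`, `j`.
#' @param n atom count.
#' @return list with `exclusions` (1-2 and 1-3 pairs) and `pairs14`
#'   matrices.
#' @export
pairs_from_bonds <- function(bonds, n) {
  adj <- vector("list", n)
  for (r in seq_len(nrow(bonds))) {
    i <- bonds$i[r]; j <- bonds$j[r]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  p12 <- key(bonds$i, bonds$j)
  p13 <- character(0); p14 <- character(0)
  for (i in seq_len(n)) {
    for (j in adj[[i]]) {
      for (k in setdiff(adj[[j]], i)) {
        p13 <- c(p13, key(i, k))
        for (l in setdiff(adj[[k]], c(i, j))) p14 <- c(p14, key(i, l))
      }
    }
  }
  p13 <- setdiff(unique(p13), p12)
  p14 <- setdiff(unique(p14), c(p12, p13))
  unkey <- function(k) {
    if (!length(k)) return(NULL)
    do.call(rbind, lapply(strsplit(k, " "), as.integer))
  }
  list(exclusions = unkey(c(p12, p13)), pairs14 = unkey(p14))
}

#' Synthetic capped-dipeptide conformer pair
#'
#' Builds a 14-atom Ace-X-NMe-like chain from internal coordinates: acetyl
#' and N-methyl caps, a backbone with defined phi (C-N-CA-C) and psi
#' (N-CA-C-N) torsions, a two-atom side chain whose geometry varies with the
#' seed, and hydrogens off the torsion path (so heavy-atom and all-atom
#' selections differ). The alpha copy is built at (phi, psi) = (-60, -40)
#' and the beta copy at (180, 180). Bond and angle equilibria equal the
#' construction values, so both conformers are finite-energy and near a
#' local minimum; Fourier terms sit on phi, psi and the side-chain torsion.
#' Alpha- and beta-state charge sets share the cap charges and differ
#' (seed-dependently) on backbone and side chain.
#'
#' @param seed integer; identical seeds give identical fixtures.
#' @param system_id label stored in the returned pair.
#' @return list: `pair` (`conformer_pair`), `params` (`ff_params`),
#'   `q_alpha`, `q_beta` (`charge_set`s), `torsions` (phi/psi atom index
#'   vectors).
#' @export
make_toy_dipeptide <- function(seed = 1L, system_id = 1L) {
  .with_seed(seed, function() {
    # 1 CH3(Ace) 2 C(Ace) 3 O(Ace) 4 N 5 CA 6 CB 7 CG 8 C 9 O
    # 10 N(NMe) 11 CH3(NMe) 12 H(N4) 13 H(CG) 14 H(N10)
    atoms <- data.frame(
      name = c("CH3", "C", "O", "N", "CA", "CB", "CG", "C", "O",
               "N", "CN", "H", "HG", "HN"),
      element = c("C", "C", "O", "N", "C", "C", "C", "C", "O",
                  "N", "C", "H", "H", "H"),
      resname = c(rep("ACE", 3), rep("UAX", 6), rep("NME", 2),
                  "UAX", "UAX", "NME"),
      resindex = c(1, 1, 1, 2, 2, 2, 2, 2, 2, 3, 3, 2, 2, 3))
    groups <- c("ACE", "ACE", "ACE", "BACKBONE", "BACKBONE", "SIDECHAIN",
                "SIDECHAIN", "BACKBONE", "BACKBONE", "NME", "NME",
                "BACKBONE", "SIDECHAIN", "NME")
    chi <- stats::runif(1, -150, 150)
    hg_tor <- stats::runif(1, -180, 180)

    build <- function(phi, psi) {
      x <- matrix(NA_real_, 14, 3)
      dummy <- c(0, 1, 0)
      x[1, ] <- c(0, 0, 0)
      x[2, ] <- c(1.52, 0, 0)
      x[4, ] <- .place_atom(dummy, x[1, ], x[2, ], 1.35, 116, 180)
      x[5, ] <- .place_atom(x[1, ], x[2, ], x[4, ], 1.45, 122, 180)
      x[8, ] <- .place_atom(x[2, ], x[4, ], x[5, ], 1.52, 111, phi)
      x[10, ] <- .place_atom(x[4, ], x[5, ], x[8, ], 1.35, 116, psi)
      x[11, ] <- .place_atom(x[5, ], x[8, ], x[10, ], 1.45, 122, 180)
      x[3, ] <- .place_atom(x[5, ], x[4, ], x[2, ], 1.23, 121, 180)
      x[9, ] <- .place_atom(x[11, ], x[10, ], x[8, ], 1.23, 121, 0)
      x[6, ] <- .place_atom(x[2, ], x[4, ], x[5, ], 1.53, 110, phi + 122)
      x[7, ] <- .place_atom(x[4, ], x[5, ], x[6, ], 1.52, 112, chi)
      x[12, ] <- .place_atom(x[1, ], x[2, ], x[4, ], 1.01, 118, 0)
      x[13, ] <- .place_atom(x[5, ], x[6, ], x[7, ], 1.09, 110, hg_tor)
      x[14, ] <- .place_atom(x[5, ], x[8, ], x[10, ], 1.01, 118, 0)
      x
    }
    xa <- build(-60, -40)
    xb <- build(180, 180)

    bonds_ij <- rbind(c(1, 2), c(2, 3), c(2, 4), c(4, 5), c(5, 6), c(6, 7),
                      c(5, 8), c(8, 9), c(8, 10), c(10, 11), c(4, 12),
                      c(7, 13), c(10, 14))
    blen <- sqrt(rowSums((xa[bonds_ij[, 1], ] - xa[bonds_ij[, 2], ])^2))
    bonds <- data.frame(i = bonds_ij[, 1], j = bonds_ij[, 2],
                        k_r = 300, r_eq = blen)
    # all bonded angle triples, equilibria at the constructed geometry
    adj <- vector("list", 14)
    for (r in seq_len(nrow(bonds_ij))) {
      adj[[bonds_ij[r, 1]]] <- c(adj[[bonds_ij[r, 1]]], bonds_ij[r, 2])
      adj[[bonds_ij[r, 2]]] <- c(adj[[bonds_ij[r, 2]]], bonds_ij[r, 1])
    }
    ang <- NULL
    for (j in 1:14) {
      nb <- adj[[j]]
      if (length(nb) < 2) next
      cmb <- utils::combn(sort(nb), 2)
      for (cidx in seq_len(ncol(cmb))) {
        i <- cmb[1, cidx]; k <- cmb[2, cidx]
        u <- xa[i, ] - xa[j, ]; v <- xa[k, ] - xa[j, ]
        th <- acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
        ang <- rbind(ang, data.frame(i = i, j = j, k = k, k_theta = 50,
                                     theta_eq = th))
      }
    }
    dihedrals <- data.frame(
      i = c(2, 2, 4, 4), j = c(4, 4, 5, 5), k = c(5, 5, 8, 6),
      l = c(8, 8, 10, 7),
      v_n = c(1.5, 0.8, 1.2, 0.9), n = c(1, 3, 2, 3),
      gamma = c(0, 0, 180, 0))
    lj_tab <- list(C = c(1.908, 0.086), N = c(1.824, 0.17),
                   O = c(1.661, 0.21), H = c(0.6, 0.0157))
    lj <- do.call(rbind, lapply(atoms$element, function(e)
      data.frame(rmin2 = lj_tab[[e]][1], eps = lj_tab[[e]][2])))
    pp <- pairs_from_bonds(bonds, 14)
    params <- ff_params(bonds = bonds, angles = ang, dihedrals = dihedrals,
                        lj = lj, exclusions = pp$exclusions,
                        pairs14 = pp$pairs14)

    cap <- c(0.05, 0.55, -0.60, rep(NA, 6), -0.45, 0.30, NA, NA, 0.15)
    free <- which(is.na(cap))
    qa <- cap; qb <- cap
    raw <- stats::runif(length(free), -0.4, 0.4)
    qa[free] <- raw - mean(raw)
    dq <- stats::runif(length(free), -0.15, 0.15)
    qb[free] <- qa[free] + (dq - mean(dq))
    q_alpha <- charge_set(qa, net_charge = 0L, groups = groups)
    q_beta <- charge_set(qb, net_charge = 0L, groups = groups)

    torsions <- list(phi = c(2, 4, 5, 8), psi = c(4, 5, 8, 10))
    mk <- function(x, label, phi, psi) {
      cf <- conformer(atoms, x, label = label,
                      phi = measure_dihedral(x, 2, 4, 5, 8),
                      psi = measure_dihedral(x, 4, 5, 8, 10))
      cf$torsions <- torsions
      cf
    }
    list(pair = conformer_pair(system_id,
                               mk(xa, "alpha", -60, -40),
                               mk(xb, "beta", 180, 180)),
         params = params, q_alpha = q_alpha, q_beta = q_beta,
         torsions = torsions)
  })
}

#' Ground-truth ESP charge-recovery problem
#'
#' Places a few atoms with known ("hidden") charges summing to an integer
#' net charge, builds a Merz-Kollman shell grid around them and evaluates
#' the exact point-charge ESP on it. Fitting this grid with no restraint
#' must recover the hidden charges.
#'
#' @param seed integer.
#' @param n_atoms number of atoms (>= 1).
#' @return list: `coords_ang` (Angstrom), `coords_bohr`, `elements`,
#'   `hidden` (`charge_set`), `grid` (`esp_grid` with values),
#'   `net_charge`.
#' @export
make_esp_recovery_problem <- function(seed = 1L, n_atoms = 4L) {
  stopifnot(n_atoms >= 1)
  .with_seed(seed, function() {
    elements <- rep(c("C", "H", "O", "N"), length.out = n_atoms)
    coords <- matrix(NA_real_, n_atoms, 3)
    coords[1, ] <- c(0, 0, 0)
    i <- 2L
    while (i <= n_atoms) {
      cand <- stats::runif(3, -2.5, 2.5)
      d <- sqrt(rowSums(sweep(coords[seq_len(i - 1), , drop = FALSE], 2,
                              cand)^2))
      if (all(d > 1.4)) {
        coords[i, ] <- cand
        i <- i + 1L
      }
    }
    q <- stats::runif(n_atoms, -0.5, 0.5)
    q <- q - mean(q)  # integer (zero) net charge
    hidden <- charge_set(q, net_charge = 0L,
                         groups = rep("SIDECHAIN", n_atoms))
    bohr <- uaaff_constants()$bohr_to_angstrom
    grid <- build_mk_grid(coords, elements, seed = seed + 1L)
    grid$values <- esp_from_point_charges(hidden, coords / bohr, grid$points)
    list(coords_ang = coords, coords_bohr = coords / bohr,
         elements = elements, hidden = hidden, grid = grid, net_charge = 0L)
  })
}

#' Synthetic receptor-ligand complex with snapshots
#'
#' A desk-scale stand-in for a protein-ligand complex: `n_res` two-atom
#' pseudo-residues on a ring form the receptor, a two-atom ligand residue
#' sits above the ring center, and snapshots are seeded coordinate jitters
#' of the base frame. All interactions are analytic-friendly (bare charges
#' and Lennard-Jones spheres, no bonded terms across the interface).
#'
#' @param seed integer.
#' @param n_res receptor residue count (>= 2).
#' @param n_snapshots number of frames (>= 1).
#' @param inert_ligand zero the ligand charges and epsilons (the
#'   non-interacting control).
#' @return list: `snapshots` (list of `conformer`s), `ligand_atoms`,
#'   `params` (`ff_params`, LJ only), `charges` (`charge_set`), `radii`.
#' @export
make_binding_complex <- function(seed = 1L, n_res = 3L, n_snapshots = 3L,
                                 inert_ligand = FALSE) {
  stopifnot(n_res >= 2, n_snapshots >= 1)
  .with_seed(seed, function() {
    n <- 2L * (n_res + 1L)
    atoms <- data.frame(
      name = rep(c("C1", "O1"), n_res + 1L),
      element = c(rep(c("C", "O"), n_res), "N", "C"),
      resname = c(rep("REC", 2 * n_res), "LIG", "LIG"),
      resindex = rep(seq_len(n_res + 1L), each = 2))
    atoms$name[n - 1L] <- "N1"; atoms$name[n] <- "C2"
    xyz <- matrix(NA_real_, n, 3)
    for (r in seq_len(n_res)) {
      th <- 2 * pi * (r - 1) / n_res
      base <- c(4.5 * cos(th), 4.5 * sin(th), 0)
      xyz[2 * r - 1, ] <- base
      xyz[2 * r, ] <- base + c(0.8 * cos(th), 0.8 * sin(th), 1.0)
    }
    xyz[n - 1L, ] <- c(0, 0, 2.2)
    xyz[n, ] <- c(0, 0, 3.6)
    q <- stats::runif(n, -0.3, 0.3)
    q <- q - mean(q)
    eps <- stats::runif(n, 0.05, 0.15)
    if (inert_ligand) {
      q[c(n - 1L, n)] <- 0
      rec <- seq_len(n - 2L)
      q[rec] <- q[rec] - mean(q[rec])  # keep the total at the declared zero
      eps[c(n - 1L, n)] <- 0
    }
    charges <- charge_set(q, net_charge = 0L,
                          groups = rep("SIDECHAIN", n))
    params <- ff_params(lj = data.frame(rmin2 = stats::runif(n, 1.7, 1.9),
                                        eps = eps))
    snaps <- lapply(seq_len(n_snapshots), function(s) {
      jit <- if (s == 1) 0 else matrix(stats::rnorm(3 * n, sd = 0.08), n, 3)
      conformer(atoms, xyz + jit)
    })
    list(snapshots = snaps, ligand_atoms = c(n - 1L, n), params = params,
         charges = charges, radii = vdw_radii(atoms$element))
  })
}

#' The embedded 18-system relative-energy benchmark
#'
#' Relative energies E(alpha) - E(beta) (kcal/mol) of 18 capped
#' phenylalanine/tyrosine-derivative dipeptides: the MP2/cc-pVTZ benchmark
#' column, an M06-2X comparison column, the four charge-optimization cycles,
#' and literature-parameter reference values available for systems 7, 9, 11
#' and 13 only.
#'
#' @return data.frame with columns `system`, `MP2`, `M06-2X`, `cycle1` ..
#'   `cycle4`, `reference`.
#' @export
table2 <- function() {
  path <- system.file("extdata", "benchmark_relative_energies.tsv",
                      package = "uaaff", mustWork = TRUE)
  read_benchmark(path)
}

#' Final-cycle blend weights of the embedded benchmark
#'
#' The beta fractions selected in the final optimization cycle: pure beta
#' charges for systems 4 and 18, beta/6 + alpha*5/6 for systems 9 and 12,
#' beta/5 + alpha*4/5 for 10, beta/3 + alpha*2/3 for 11,
#' beta*7/8 + alpha/8 for 17, and the alpha/beta average for the rest.
#'
#' @return numeric vector of length 18 (w_beta per system).
#' @export
table2_blend_weights <- function() {
  w <- rep(1 / 2, 18)
  w[c(4, 18)] <- 1
  w[c(9, 12)] <- 1 / 6
  w[10] <- 1 / 5
  w[11] <- 1 / 3
  w[17] <- 7 / 8
  w
}
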