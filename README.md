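# uaaff

Force-field charge parametrization and end-point binding free energy
analysis for noncanonical (unnatural) amino acids, in R.

Noncanonical amino acids — here, phenylalanine and tyrosine derivatives
such as halogenated, nitro- or azido-substituted side chains — are routinely
incorporated into proteins, but standard biomolecular force fields carry no
parameters for them. The established remedy is to derive partial charges for
each residue as a capped dipeptide (Ace-XXX-NMe) by restrained
electrostatic-potential (RESP) fitting, validate and adjust them against a
quantum-mechanical benchmark of the relative energy of the two canonical
backbone states,

    RE = E(alpha) - E(beta),    alpha: (phi, psi) = (-60, -40),
                                beta:  (phi, psi) = (180, 180),

and then use the finished parameters in molecular-dynamics and
MM/PBSA binding studies. `uaaff` implements that pipeline as a tested
library plus a small command-line tool:

* **RESP charge fitting** — Merz–Kollman-style shell grids, the Coulomb ESP
  model, and constrained least squares with the hyperbolic restraint
  `a * (sqrt(q^2 + b^2) - b)`, exact net-charge and equivalence constraints,
  frozen capping-group charges, and the two-stage protocol
  (`build_mk_grid()`, `resp_fit()`, `resp_two_stage()`).
* **Conformer charge blending** — convex combinations
  `w_alpha * q_alpha + w_beta * q_beta` of the alpha- and beta-state RESP
  charges with frozen Ace/NMe caps, selected per residue by a deterministic
  grid search against the benchmark
  (`blend_charges()`, `optimize_blend()`), with the benchmark statistics
  RMS = sqrt(sum (RE_QM - RE_model)^2 / D) and squared Pearson correlation
  (`rms_deviation()`, `pearson_r2()`). The 18-system benchmark table ships
  with the package (`table2()`).
* **Gas-phase energy model** — the Amber functional form
  E = E_bond + E_angle + E_dihedral + E_es + E_vdW with ff14SB 1-4 scaling,
  analytic gradients, restrained BFGS minimization and conformer relative
  energies (`energy()`, `minimize()`, `relative_energy()`).
* **MM/PBSA** — single-trajectory binding free energies
  dG_bind = dE_vdW + dE_ele + dG_pb + dG_np (entropy omitted) with a
  finite-difference linearized Poisson–Boltzmann solver (0.5 A grid,
  eps 1/80, 0.1 M salt, Debye–Hückel boundaries), Shrake–Rupley solvent
  accessible surface areas and the nonpolar model gamma*SASA + b
  (gamma = 0.00542 kcal/(mol A^2), b = 0.92 kcal/mol), plus per-residue
  decomposition (`binding_energy()`, `solve_pb()`, `sasa()`,
  `per_residue_decomposition()`).
* **I/O** — fixed-column (multi-model) PDB via bio3d, a plain-text ESP grid
  dialect, a versioned YAML parameter schema, TSV benchmark tables, and a
  mol2 charge importer.

## Worked example

```r
library(uaaff)

## the shipped relative-energy benchmark: final-cycle charges vs MP2
tb <- table2()
sprintf("cycle 4 vs MP2: RMS %.2f kcal/mol, R^2 %.4f",
        rms_deviation(tb$MP2, tb$cycle4, "n_minus_1"),
        pearson_r2(tb$MP2, tb$cycle4))
#> "cycle 4 vs MP2: RMS 0.33 kcal/mol, R^2 0.9407"

## blend alpha/beta conformer charges at the beta/6 + alpha*5/6 proportion
qa <- charge_set(c(0.6, -0.6), 0L, c("SIDECHAIN", "SIDECHAIN"))
qb <- charge_set(c(0.0,  0.0), 0L, c("SIDECHAIN", "SIDECHAIN"))
blend_charges(qa, qb, blend_spec(w_beta = 1/6))$charges
#> [1]  0.5 -0.5

## the Born-ion check of the PB solver (analytic value -81.98 kcal/mol)
born <- solve_pb(matrix(0, 1, 3), charges = 1, radii = 2,
                 pbsa_options(ionic_strength = 0))
round(born$energy, 2)
#> [1] -82.44

## MM/PBSA on the synthetic receptor-ligand complex
fx <- make_binding_complex(seed = 1, n_res = 3, n_snapshots = 3)
opt <- pbsa_options(grid_spacing = 0.8, grid_padding = 6, sasa_points = 240)
binding_energy(fx$snapshots, fx$ligand_atoms, opt,
               fx$params, fx$charges, fx$radii)
#> MM/PBSA binding energy over 3 snapshots (kcal/mol)
#>   dE_vdW         -0.21 (0.01)
#>   dE_ele         -4.04 (0.08)
#>   dG_pb/solv      3.95 (0.07)
#>   dG_np/solv     -1.26 (0.02)
#>   dE_MM          -4.26 (0.09)
#>   dG_solv         2.69 (0.05)
#>   dG_bind        -1.56 (0.05)
```

The RMS row of the benchmark (4.86, 5.68, 2.33, 0.33 kcal/mol across the
four optimization cycles, 1.08 for M06-2X) uses the N−1 divisor; the
four-system literature comparison (2.25 vs 0.38 kcal/mol) uses N. Both
conventions are explicit flags of `rms_deviation()` — see the methods
vignette (`vignettes/uaaff-methods.Rmd`) for why both exist.

## Command line

A thin wrapper script is installed at `exec/uaaff` (or call
`uaaff::uaaff_cli()` directly):

```sh
uaaff stats --columns MP2,cycle4 --denominator n-1
# statistic  value
# rms        0.33
# r2         0.9407
# n          18
uaaff fixtures --kind esp --seed 7 --out /tmp/demo
uaaff respfit --esp /tmp/demo.esp --restraint-a 0
```

Subcommands: `respfit`, `energy`, `blend`, `stats`, `pbsa`, `fixtures`;
all outputs are tab-separated, all randomness is controlled by `--seed`,
exit status is 0/1/2 for success/computation failure/usage error.

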