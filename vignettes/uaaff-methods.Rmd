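---
title: "Methods: charge parametrization and MM/PBSA in uaaff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: charge parametrization and MM/PBSA in uaaff}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uaaff)
```

# The problem

Noncanonical amino acids (NCAAs) — phenylalanine and tyrosine derivatives
carrying halogen, nitro, azido, hydroxy or methyl substituents — have no
charges in standard protein force fields. The accepted derivation unit is
the capped dipeptide Ace-XXX-NMe, parametrized so that a fixed-charge
molecular-mechanics model reproduces quantum-mechanical (QM) target data in
the two canonical backbone states: the alpha-helical
(phi, psi) = (-60, -40) and the beta-strand (180, 180) conformer. The
quantity the charges are tuned against is the conformer relative energy

$$\mathrm{RE} = E(\alpha) - E(\beta),$$

positive when the beta backbone is the more stable, as it is for every
system in the shipped benchmark. `uaaff` implements the full desk-side
pipeline: ESP/RESP charge fitting, per-residue blending of the alpha- and
beta-state charge sets against the benchmark, the gas-phase energy model
used to evaluate RE, and the MM/PBSA machinery used downstream when the
finished residue binds a protein.

# The energy model

The potential is the Amber functional form

$$E_\mathrm{total} = \sum_\mathrm{bonds} K_r (r - r_{eq})^2
 + \sum_\mathrm{angles} K_\theta (\theta - \theta_{eq})^2
 + \sum_\mathrm{dihedrals} \tfrac{V_n}{2}\left[1 + \cos(n\phi - \gamma)\right]
 + E_\mathrm{es} + E_\mathrm{vdW}$$

with electrostatics $k_e q_i q_j / r_{ij}$,
$k_e = 332.0637\ \mathrm{kcal\,\mathring{A}/(mol\,e^2)}$ (the constant used
by the Amber codes, fixed so that energies are bit-comparable), and 12-6
Lennard-Jones in $r_\mathrm{min}/\varepsilon$ form under Lorentz–Berthelot
combination. 1-2 and 1-3 pairs are excluded; 1-4 pairs are scaled by 1/1.2
(electrostatics) and 1/2.0 (Lennard-Jones), the ff14SB convention that the
charge sets are meant to be compatible with. There is no cutoff: the model
is the gas-phase dipeptide. Bonded and Lennard-Jones parameters are
*inputs* (they come from GAFF/ff14SB-style assignment upstream); only the
charges are derived here.

Analytic Cartesian gradients are implemented for every term (including the
torsion restraints below) and are verified against central finite
differences at 1e-6 relative tolerance in the test suite. Dihedral angles
follow the standard sign convention (checked against both `bio3d` and
`biotite` as independent references).

# RESP fitting

The electrostatic potential of the candidate charges at grid point $k$ is
the Coulomb superposition $V_k(q) = \sum_j q_j / |r_k - r_j|$ in atomic
units (Bohr, hartree/e; fitting is atomic-units end-to-end, with the
conversion constant 0.52917721 A/Bohr applied only at I/O boundaries).
`resp_fit()` minimizes

$$\chi^2 = \sum_k \left(V_k^\mathrm{target} - V_k(q)\right)^2
 + a \sum_{j\,\mathrm{restrained}} \left(\sqrt{q_j^2 + b^2} - b\right)$$

subject to (i) $\sum_j q_j$ equal to the integer net charge, enforced
exactly by a Lagrange row, (ii) equality within declared equivalence
classes, enforced by variable reduction, and (iii) frozen charges (the
Ace/NMe capping groups keep their reference force-field values; stage 2 of
the two-stage protocol freezes stage-1 values outside the refit set). The
hyperbolic restraint is handled by iterated reweighted linear solves —
the diagonal term $a/\sqrt{q_j^2+b^2}$ is lagged — iterating until
$\max_j |\Delta q_j| < 10^{-10}$ e. With $a = 0$ the problem is linear and
one solve suffices; the result then equals a constrained ordinary
least-squares oracle to 1e-8 e (tested).

Defaults follow the canonical two-stage choices: $a = 0.0005$ hartree in
stage 1, $0.001$ in stage 2, $b = 0.1$ e, hydrogens unrestrained. All are
arguments, not constants. Equivalence classes are supplied explicitly
rather than detected from graph symmetry: the systems this package targets
need only a handful of classes (methyl hydrogens, symmetric ring atoms) and
automatic symmetry perception is out of scope. Each backbone conformer is
fitted independently and reconciled afterwards by blending; a joint
multi-conformer fit is a possible variant but would pre-empt the blending
step that the optimization cycles operate on.

Sampling grids (`build_mk_grid()`) follow the Merz–Kollman layout: points
seeded pseudo-randomly on union-of-spheres shells at 1.4, 1.6, 1.8 and 2.0
times the van der Waals radii, about 1 point/A^2 per shell, culled inside
any scaled sphere. Radii are Bondi values except iodine, which uses the
Pauling radius 2.15 A (the Bondi table has no iodine entry suitable for
the halogenated side chains targeted here); the table is configurable.
Grids are bit-reproducible given the seed.

# Blending alpha- and beta-state charges

The optimization cycles that reconcile the per-conformer RESP fits are
formalized as a deterministic per-system grid search (`optimize_blend()`).
For each system the candidate charge set is

$$q = w_\alpha q_\alpha + w_\beta q_\beta,\qquad w_\alpha + w_\beta = 1,$$

applied to backbone and side-chain atoms only (caps stay at their reference
values; net charge is preserved exactly by convexity). The default
candidate grid contains exactly the fractions used in the final published
cycle — pure beta, 7/8, 1/2, 1/3, 1/5, 1/6 beta, and pure alpha — and is
extensible. The weight minimizing $|\mathrm{RE}_\mathrm{model} -
\mathrm{RE}_\mathrm{QM}|$ is selected per system, ties broken toward larger
$w_\beta$ so the search is deterministic. Because selection is per-system,
the resulting global RMS is never worse than any single fixed weight
applied to all systems (a tested invariant).

## The two RMS divisor conventions

The benchmark summary statistic is
$\mathrm{RMS} = \sqrt{\sum_i (\mathrm{RE}_{QM,i} - \mathrm{RE}_{model,i})^2 / D}$.
The printed 18-system RMS row of the shipped table (4.86, 5.68, 2.33, 0.33
kcal/mol for cycles 1-4; 1.08 for M06-2X) is reproduced from the printed
columns only with $D = N - 1$, while the in-text four-system comparison
against literature parameters (2.25 vs 0.38 kcal/mol) requires $D = N$.
This inconsistency is a property of the source data, not something this
package can resolve; `rms_deviation()` therefore exposes the divisor as an
explicit flag, the default being `n_minus_1` (the convention of the main
table). The test suite asserts both reproductions *and* that swapping the
flag breaks them — a guard against silent convention drift. One caveat is
recorded there: for the cycle-4 column the two divisors differ by only
0.009 kcal/mol, below the 0.01 print-rounding tolerance, so the negative
guard is asserted over the full set of printed statistics rather than
column-by-column. $R^2$ is the squared Pearson correlation, which
reproduces the printed 0.9407/0.8072/0.8212 values to four decimals.

# Conformer relative energies and minimization

`relative_energy()` evaluates both conformers under one shared (blended)
charge set. Two modes exist because the provenance of published RE values
is ambiguous between fixed-geometry and relaxed-geometry evaluation:

* `single_point` — energies at the input geometries;
* `minimized` (default) — each conformer is relaxed by BFGS with harmonic
  torsion restraints $k\,\mathrm{wrap}(\phi - \phi_0)^2$,
  $k = 100$ kcal/(mol rad^2), pulling (phi, psi) toward (-60, -40) and
  (180, 180) respectively. The restraints are the package's answer to an
  underdetermined question — *something* must keep the backbone from
  relaxing away from its nominal state during MM minimization — and are
  documented as an assumption. The reported energy is the unrestrained
  breakdown at the final geometry.

The minimizer runs BFGS in chunks of 100 iterations (up to 5000 steps)
with analytic gradients, declaring convergence when the largest gradient
component falls below `gtol` (default 1e-6 kcal/(mol A)). A harmonic
restraint has a finite equilibrium offset against an opposing torque: at
$k = 100$ the offset is a fraction of a degree when the restraint dominates
(the tested construction) but can reach a few degrees on a strained toy
system; raise $k$ when tighter pinning is needed.

Structure comparisons (`superpose()`, `rmsd_fit()`) use the Kabsch
algorithm with proper-rotation correction; RMSDs are fitted and measured on
the same atom selection (heavy or all), pairing atoms by index. Fitting on
one selection and measuring on another is deliberately not offered — the
reported heavy-atom and all-atom displacement protocols imply fit-then-
measure on the same set.

# MM/PBSA

`binding_energy()` implements the single-trajectory scheme: receptor and
ligand coordinates are extracted from each complex frame, so every bonded
term cancels identically and

$$\Delta G_\mathrm{bind} = \Delta E_\mathrm{vdW} + \Delta E_\mathrm{ele}
 + \Delta G_\mathrm{pb} + \Delta G_\mathrm{np},$$

with the entropy term $-T\Delta S$ declared in the result type but never
computed (the options carry the temperature, 300 K, used only for Debye
screening). The molecular-mechanics terms are receptor-ligand cross sums;
the solvation terms come from three PB solves and three SASA evaluations
per frame, so the nonpolar part is effectively
$\gamma\,\Delta\mathrm{SASA} - b$. Snapshot averages are reported with the
population standard deviation $\sqrt{\sum_i (x_i - \bar x)^2 / N}$ (the
spread convention; a single snapshot gives SD 0).

## The PB solver

The linearized Poisson–Boltzmann equation is discretized by finite
differences on a cubic grid (default spacing 0.5 A, padding 10 A, box
centered on the solute, odd node counts so a centered atom sits on a
node) and solved by red-black successive over-relaxation in compiled code,
with $\omega = 2/(1 + \sin(\pi/n))$ and a relative-residual tolerance of
1e-6. Numerical choices that matter:

* **Dielectric boundary.** Edge dielectrics use harmonic smoothing over the
  solute-interior fraction of each grid edge, with fractions computed from
  exact sphere-segment intersections merged across overlapping atoms (the
  DelPhi-style scheme). This was chosen over the simpler node-wise
  harmonic mean after measuring both on the Born ion: the node scheme gave
  4% error at 0.5 A and non-monotone refinement; edge fractions give 0.6%
  at 0.5 A, decreasing monotonically (1.7% → 0.6% → 0.3% at
  0.8/0.5/0.35 A).
* **Salt.** 0.1 M monovalent salt by default. Each ion species is excluded
  from a Stern layer of its own radius (Na+ 0.95 A, Cl- 1.81 A) around
  every atom; outside it the species contributes its share of
  $\bar\kappa^2$. The box faces carry the Debye–Hückel analytic boundary
  condition, which also serves as the initial guess.
* **Self-energy.** The grid self-energy of a spread point charge is huge
  but identical between the solvated solve and a uniform-solute-dielectric
  reference solve on the *same* grid with the same trilinear charge
  assignment; the solvation energy
  $\tfrac12 \sum_i q_i \phi_\mathrm{reac}(r_i)$ uses the difference of the
  two potentials interpolated with the same trilinear stencil, so the
  artifact cancels by construction without analytic corrections.

## SASA and the nonpolar term

Shrake–Rupley with a deterministic Fibonacci-lattice point set (default
960 points/atom; doubling the count moves toy-system totals by <0.5%),
probe radius 1.4 A, and the linear model $\gamma\,\mathrm{SASA} + b$ with
$\gamma = 0.00542$ kcal/(mol A^2), $b = 0.92$ kcal/mol.

## Per-residue decomposition

$\Delta G^\mathrm{res} = \Delta E^\mathrm{res}_{MM} +
\Delta G^\mathrm{res}_\mathrm{pb} + \Delta G^\mathrm{res}_\mathrm{np}$,
with three attribution conventions, each chosen so residue sums reproduce
the global components exactly (tested to 1e-6 kcal/mol):

* cross MM terms: half to each partner atom's residue;
* polar: $\tfrac12 q_i\,[\phi^\mathrm{complex}_\mathrm{reac}(r_i) -
  \phi^\mathrm{state}_\mathrm{reac}(r_i)]$ charge attribution;
* nonpolar: per-atom SASA differences times $\gamma$, with the intercept
  $b$ spread uniformly over the atoms of each state — $b$ has no per-area
  meaning, and the uniform split is the only convention that conserves the
  global $\gamma\,\Delta\mathrm{SASA} - b$ regardless of geometry. This
  split is this package's convention; other implementations do not
  document theirs.

# The synthetic generators

Every test input is generated in code (`make_toy_dipeptide()`,
`make_esp_recovery_problem()`, `make_binding_complex()`), bit-reproducible
from the seed. The toy dipeptide is a 14-atom Ace-X-NMe-like chain built
from internal coordinates with exact (-60, -40) / (180, 180) backbone
construction, bond/angle equilibria at the built geometry (so both
conformers are near-minimum and clash-free), Fourier terms on phi, psi and
the side-chain torsion, and hydrogens off the torsion path so heavy-atom
and all-atom selections genuinely differ. The binding complex is a ring of
two-atom pseudo-residues around a two-atom ligand with jittered snapshots.

These generators emulate the *structure* of the real problem — conformer
pairs sharing parameters, exact ESP ground truth, receptor/ligand
partitions with analytic-friendly interactions — not its chemistry: there
are no aromatic rings, no nitro/halogen electronic effects, no conformer
ensembles, and the QM benchmark is an embedded table rather than a
computable quantity. Passing tests therefore demonstrate the correctness
of the numerics (fitting, energies, solvers, accounting identities), not
force-field quality on real NCAAs; the embedded 18-system table is the
only contact with real QM data, and reproducing its printed statistics is
an arithmetic check on the statistics layer, not a re-derivation of the
charges.

Problem sizes used by the tests and the acceptance script were chosen to
keep each check comfortably interactive: 4-5-atom ESP recovery problems
(~700-800 grid points), the 14-atom dipeptide, 8-atom complexes with 1-3
snapshots at 0.8 A PB spacing and 240 SASA points, and the Born ion at
0.35-0.8 A spacing. All scale up by argument.

# Known limitations

* The PB solver is linear only, Dirichlet-bounded, and has no
  multigrid/focusing; very large solutes would want a coarser pre-solve.
* No automatic equivalence detection, bond perception, protonation or atom
  typing; bonded/LJ parameters and exclusion lists are caller-supplied
  (the parameter file schema carries them).
* Per-conformer RESP fits are independent; a joint multi-conformer fit
  with shared constraints is not implemented.
* The entropy term of the binding free energy is intentionally absent.
* `relative_energy(mode = "minimized")` assumes harmonic backbone
  restraints; results a degree or two from the nominal (phi, psi) targets
  are expected on strained systems.
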