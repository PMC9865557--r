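---
title: "Tuning fixed-charge ionic-liquid force fields by charge and sigma scaling"
author: "ilscale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tuning fixed-charge ionic-liquid force fields by charge and sigma scaling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ilscale)
```

## The problem

Room-temperature ionic liquids (ILs) are simulated almost exclusively with
fixed-charge additive force fields: the cell sizes (~10,000 atoms) and time
scales needed to converge bulk densities and solvation free energies rule out
polarizable models for routine work. Atomic charges fitted to the gas-phase
electrostatic potential (RESP) ignore condensed-phase polarization and charge
transfer, so the ions pack too tightly and simulated densities, solvation and
partition free energies drift away from experiment.

Two one-parameter remedies exist, and this package implements both ends of
the workflow around them:

* **charge scaling** — multiply every ionic partial charge by a common factor
  $s_q$ (typically 0.6–0.9; 0.8 is a widely usable near-optimum);
* **vdW (sigma) scaling** — multiply the Lennard-Jones collision diameter
  $\sigma$ of the ions' atom types by a common factor $s_\sigma$ (a few
  percent, e.g. 1.03 or 1.05) to loosen or tighten the packing when charge
  scaling barely moves the density.

Both transforms act on the solvent ions only; solutes keep their full RESP
charges and vdW radii. This is the package default (`targets =
"solvent-ion"`), and it is configurable because sigma scaling of solutes in
solvation runs is a genuinely open choice — we default to solvent-only and
expose the flag.

## Topology transforms

`readTopology()` parses a documented subset of the GROMACS topology dialect
(`[ defaults ]`, `[ atomtypes ]`, `[ moleculetype ]`/`[ atoms ]`,
`[ molecules ]`); every other section — bonded terms, `[ system ]` — passes
through verbatim, so a scaled topology differs from its parent only in the
intended numbers. Output formatting is canonical (charges at 8 decimals so
net charges survive the round trip to better than $10^{-6}$ e, with a
post-write check); byte-exact preservation of input whitespace is not
guaranteed, semantic round-trip identity is, and is tested.

Scaling is multiplicative and composes: `scaleCharges(top, a)` then `b`
equals scaling by `ab`, and charge and sigma scaling commute. Because sigma
lives on atom *types*, a type shared between a solvent ion and a solute
cannot be scaled for one and not the other; `scaleSigma()` refuses, and
`duplicateAtomTypes()` clones the shared type under a suffixed name first.
Cross interactions between scaled and unscaled species follow from
re-applying the combination rule to the scaled per-type sigma; no pair-type
overrides are generated.

```{r topo}
top <- readTopology(toyTopologyText())
scaled <- scaleSigma(scaleCharges(top, 0.8), 1.03)
netCharge(scaled, "CAT")
```

## Charge quality from the ESP

The quality of a point-charge set is scored by how well it reproduces a
reference (ab initio) electrostatic potential on a molecular grid,

$$\mathrm{RRMSE} \;=\; \sqrt{\frac{\sum_k \left(V_{\mathrm{model},k} -
V_{\mathrm{ref},k}\right)^2}{\sum_k V_{\mathrm{ref},k}^2}},$$

the conventional normalisation in the RESP literature (the source analyses
never print the formula; this ratio-of-sums definition is our documented
choice). Internally everything is in atomic units; Angstrom input converts
at 1 Å = 1.889726 bohr. `mkShellGrid()` builds Merz–Kollman-style shells
(default scales 1.4–2.0 of the vdW radii) from Fibonacci lattices with
seeded random rotations, pruning points that fall inside any scaled atomic
sphere, so a grid can be built deterministically from geometry alone.
Charges are scored as given: whether to score full or scaled charges is the
caller's decision, not applied silently.

## Free energies from fast-growth works

Nonequilibrium (fast-growth) solvation calculations create the solute in the
equilibrated solvent along a switching path; each realization yields a
dimensionless microscopic work $W$ (units of kT). The free energy comes from
exponential averaging (EXP, the Jarzynski identity):

$$\Delta A_{\mathrm{solvation}} = -\ln \left\langle e^{-W} \right\rangle,$$

evaluated with log-sum-exp stabilisation (works anywhere in roughly
$\pm 10^3$ kT cannot overflow) and exact for a single realization. The works
are for solute *creation*, so the estimate is the solvation free energy
directly; no sign flips exist anywhere downstream. EXP is asymptotically
unbiased but overestimates $\Delta A$ at finite $n$; the test suite checks
that bias direction against the Gaussian generator below.

Numerical choices, stated once:

* **Uncertainty** is the sample SD of the EXP estimate over bootstrap
  resamples (default $B = 1000$, seeded, works canonically ordered by
  realization id first so the result is permutation invariant). The
  analytical EXP variance formula underestimates uncertainty, which is why
  bootstrap is the default; $B$ and the SD convention are this package's
  documented defaults, not inherited values.
* **Stage composition**: the protocol runs a vdW-coupling and then a
  charging sub-step sequentially within each realization, so the default
  `combineStages()` mode sums the two works per realization before
  estimation; a per-stage mode (EXP per stage, SDs in quadrature) is
  available for independently seeded stages.
* **Quadrature**: when the input is a $(\lambda, dH/d\lambda)$ series,
  work is the trapezoid-rule integral over the recorded grid; engines'
  own accumulated-work columns can be read directly instead.
* **Units**: works are stored in kT; kcal/mol conversion uses
  $k_B = 0.0019872041$ kcal/mol/K with the work set's own temperature.

Transfer (water → IL) free energies are plain differences
$\Delta\Delta G = \Delta G_{\mathrm{solv,IL}} - \Delta G_{\mathrm{solv,water}}$
with quadrature-combined SDs.

## Agreement metrics

`qualityMetrics()` reports MAE, signed MSE, RMSE (always
$\mathrm{RMSE} \ge \mathrm{MAE} \ge |\mathrm{MSE}|$), Kendall's rank
correlation, Pearlman's predictive index, Pearson r, and outlier counts
outside ±1 and ±2 kcal/mol bands. Two conventions the sources leave open are
fixed here and tested against brute-force pairwise oracles:

* Kendall's τ is the tie-corrected **tau-b** (via `stats::cor`);
* PI uses Pearlman's original experimental-difference weights
  $w_{ij} = |\Delta_{ij}^{\mathrm{expt}}|$ with $c_{ij} = 0$ when the
  calculated values tie.

## Density response and factor selection

Over the narrow scan ranges used in practice the bulk density responds
linearly to sigma scaling. `linearFit()` is unweighted OLS (the scan SDs are
carried for display only); the relative slope divides by the experimental
density to give a dimensionless response coefficient comparable across ILs.
Reported two-decimal values use truncation toward zero — the only convention
consistent with both reference slope/density pairs
(−1.82/1.358 → −1.34 and −1.73/1.295 → −1.33); full precision is always kept
internally.

`densityMatchedFactor()` solves the fitted line for the experimental
density (warning on extrapolation or an anomalous positive slope). Because
density-matching alone overfits solvent–solvent interactions at the expense
of solute–solvent ones, `balancedFactor()` recommends the interval between
the density-derived and solvation-derived factors, suggesting the point one
step (default 0.01) from the density end — slightly-too-dense parameter sets
are preferred — e.g. 1.03 and 1.00 yield 1.02. Per-temperature scans are
independent records; no thermal-expansion model is fitted.

## What the toy fluid is, and is not

`runNptMC()` samples a periodic cubic cell of soft-sphere cations and anions
in the NPT ensemble by Metropolis Monte Carlo: one trial displacement per
particle per sweep plus a ln-V volume move accepted with probability
$\min\{1, \exp[-\beta(\Delta U + P\Delta V) + (N{+}1)\Delta \ln V]\}$.
The potential is Lennard-Jones with Lorentz–Berthelot mixing plus
damped-shifted-force (Wolf-type) Coulomb — adequate for a qualitative toy;
it is explicitly *not* a substitute for Ewald electrostatics, and the cell
(tens of pairs) makes no claim of reproducing any real IL's absolute
density. What it does supply, deterministically per seed, is the *shape* of
the physics the analysis stack consumes: a density that responds smoothly
and monotonically to sigma scaling, an exact NPT ideal-gas limit
$\langle V\rangle = (N{+}1)k_BT/P$ when interactions vanish, and
incremental-vs-recomputed energy bookkeeping that must agree to $10^{-6}$
relative.

Default study conditions, chosen once: 32 ion pairs, $\sigma$ = 0.34/0.30 nm,
$\varepsilon$ = 1.0 kJ/mol, charges ±0.5 e with $s_q = 0.8$, 298 K,
**1000 bar**, cutoff 0.55 nm, $\alpha$ = 3.6 nm⁻¹, displacement 0.05 nm and
ln-V step 0.03 (fixed sizes, ~30–50% acceptance; no auto-tuning, for
determinism). The elevated pressure deserves a sentence: at 1 bar a
64-particle cell sits near gas–liquid coexistence, where NPT densities are
bistable and seed-dependent; at 1000 bar the cell is deep in the dense-fluid
region and the density–sigma response is smooth and monotone. Since the
response to packing, not the absolute state point, is what the pipeline
needs, the compressed fluid is the right study condition at this scale.
Block averaging uses 10 blocks; the box must always exceed twice the cutoff
(the run aborts with a diagnostic otherwise, which also bounds valid cell
sizes from below — small cells need proportionally smaller cutoffs).

Problem sizes used in the shipped tests and acceptance script — 8–32 pairs,
a few hundred to 2000 sweeps, $10^3$–$10^5$ synthetic works — were chosen as
the smallest sizes at which the statistical assertions (3-SD separations,
0.05 kT estimator recovery) are comfortably resolved.

The companion generators carry exact truths: `generateGaussianWorks()` draws
works from $N(\Delta G + \sigma_w^2/2, \sigma_w^2)$, the unique Gaussian
consistent with the Crooks fluctuation theorem, so the infinite-sample EXP
limit is exactly $\Delta G$; `generatePairedDataset()` adds Gaussian noise
to a fixed experimental grid so that at zero noise every agreement metric is
exactly perfect.

## What passing tests do and do not show

The toy fluid has no molecular geometry, no bonded terms, no Ewald sums and
no real time scale; agreement of the pipeline on it demonstrates the
correctness of the estimators, transforms and fitting logic, not the
accuracy of any force field for a real ionic liquid. Conversely, everything
the package computes from *real* engine output (work lists, dH/dλ series,
density scans, paired datasets) goes through exactly the code paths the toy
exercises.

## Known limitations

* Topology support is the documented GROMACS-dialect subset; CHARMM/AMBER
  formats, bonded-parameter editing and RESP fitting itself are out of scope.
* Only the unidirectional EXP estimator is provided; bidirectional
  (Crooks/BAR) estimation is deliberately absent in this version.
* Gaussian cube files are not read; ESP references come from plain
  four-column tables.
* The density-response machinery fits whatever scan it is given; it does not
  judge whether the scanned range is narrow enough for linearity beyond
  reporting R².
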