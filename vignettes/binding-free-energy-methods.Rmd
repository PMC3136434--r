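---
title: "Post-processing binding free-energy analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Post-processing binding free-energy analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bindfe)
```

`bindfe` post-processes conformer ensembles of a receptor–peptide complex
into binding free energies and per-residue energetics. It does not run
molecular dynamics or quantum chemistry: it consumes structures, ensembles,
and (optionally) externally computed high-level energies and forces, and
assembles the thermodynamic quantities downstream of sampling. This
vignette explains the models, the tunable parameters and their defaults,
what the synthetic-data generator does and does not emulate, and the
numerical choices made where the design was genuinely open.

## The end-state model (MM-PBSA)

In the single-trajectory convention, the binding free energy of a
receptor–ligand complex is estimated per snapshot and ensemble averaged:

$$
\Delta G_\mathrm{bind} =
  \left\langle \Delta E_\mathrm{EL} + \Delta E_\mathrm{vdW} \right\rangle
+ \left\langle \Delta G_\mathrm{PB} + \Delta G_\mathrm{SA} \right\rangle
- T\,\Delta S .
$$

Receptor and ligand coordinates are extracted from the complex frame, so
all intramolecular terms cancel and the gas-phase term reduces to the
receptor–ligand cross interaction (`gas_phase_binding()`); the package
verifies this identity against a full intramolecular sum in its tests.
Units are fixed package wide: Å, kcal/mol, elementary charge, amu, ps;
the default temperature is 300 K.

* **Electrostatics** — vacuum Coulomb with infinite cutoff and the
  conversion constant 332.0637 kcal Å mol⁻¹ e⁻².
* **van der Waals** — 12-6 potential in the $r_\mathrm{min}/\varepsilon$
  parameterisation with Lorentz–Berthelot combination (arithmetic
  $r_\mathrm{min}/2$ radii, geometric well depths).
* **Polar solvation** — finite-difference linearized Poisson–Boltzmann
  (below), solute/solvent dielectrics 1/80, 0.5 Å grid.
* **Nonpolar solvation** — $\gamma \cdot \mathrm{SASA} + c$ with defaults
  $\gamma = 0.00542$ kcal mol⁻¹ Å⁻² and $c = 0.92$ kcal/mol. These two
  numbers are the conventional companions of this PB setup, chosen here as
  configurable defaults; they are deliberately not presented as reference
  values from any particular force field release.
* **Entropy** — translational (Sackur–Tetrode, 1 atm standard state),
  rigid-rotor rotational, and quantum harmonic-oscillator vibrational
  entropies of minimized snapshots, via `binding_entropy()`.

Standard errors of all ensemble averages use block averaging
(default ≈ √N contiguous blocks), because snapshots from a trajectory are
autocorrelated; the tests confirm the expected inflation over the naive
standard error on an AR(1) series. Convergence of a run is monitored with
`running_average_convergence()`: the running mean of the per-frame total
must vary by no more than a tolerance (default 1 kcal/mol) over a trailing
window (default 12 ns).

## The Poisson–Boltzmann solver

`solve_pb()` discretizes $\nabla\!\cdot\!(\varepsilon\nabla\phi)
- \bar\kappa^2\phi = -4\pi\rho$ on a uniform grid with a 7-point stencil:

* **Dielectric boundary** — the union of atom spheres at their configured
  cavity radii (the atomic `lj_radius`). No re-entrant molecular surface
  is built; the sphere-union choice is simple, reproducible, and isolated
  behind `pb_settings()`.
* **Boundary smoothing** — grid edges crossing the cavity surface receive
  a harmonic-mean dielectric weighted by the inside fraction of the edge
  (found by bisection). This is on by default; it markedly improves grid
  convergence of the Born-ion test.
* **Charges** — trilinear spreading to grid nodes. The grid self-energy is
  removed by a second solve of the same grid and charges with a uniform
  solute dielectric; the reported polar energy is the difference
  (the reaction-field energy).
* **Boundary condition** — analytic Coulomb potential of all charges
  screened by the solvent dielectric (Debye-screened when the ionic
  strength is nonzero) imposed on the grid faces.
* **Linear solver** — red–black successive over-relaxation to a relative
  residual of 1e-6 (configurable), with the standard optimal relaxation
  estimate from the grid dimension.

Accuracy against the closed-form Born ion (q = 1 e, cavity 2 Å,
$\varepsilon$ 1→80): about 3% at 1.0 Å spacing, 0.6% at 0.5 Å, and 0.1% at
0.25 Å — monotone in the spacing, as the acceptance test asserts. Grid
placement contributes a documented uncertainty: shifting the grid origin by
half a spacing moves a two-charge reaction-field energy by well under
0.5 kcal/mol, the tolerance the self-consistency test uses. A solute whose
cavity spheres approach the two outermost grid layers is rejected with an
instruction to enlarge `grid_padding` (default 8 Å).

SASA uses deterministic Shrake–Rupley sampling on a Fibonacci sphere
lattice (960 points per atom by default; the three-atom refinement test
compares against a 10× denser lattice). Exactly coincident atoms of equal
radius are deduplicated so that a doubly-stored sphere contributes its
surface once.

## Normal-mode entropy

Each sampled snapshot is minimized under a differentiable energy model —
nonbonded Coulomb + LJ with 1-2/1-3 exclusions (1-4 unscaled), harmonic
bond terms whose reference lengths come from the topology's stored
coordinates (default k = 300 kcal mol⁻¹ Å⁻²), and optionally a smooth
generalized-Born-style solvent term with fixed per-atom Born radii equal to
the cavity radii. The minimization schedule is conjugate gradients to a
gradient RMS of 1e-2, then quasi-Newton (BFGS) refinement to the final
tolerance (default 1e-4 kcal mol⁻¹ Å⁻¹); failure to reach tolerance is an
error carrying the final RMS, and `binding_entropy()` skips such snapshots
(erroring if more than half fail).

The Hessian is built by central finite differences of the analytic gradient
(step 1e-4 Å), mass-weighted and diagonalized. Modes below 1 cm⁻¹ are
treated as rigid-body modes: six for a nonlinear solute, five for a linear
one, three for a single atom — more than that triggers a warning of
incomplete minimization. The diatomic closed form
$\tilde\nu = \frac{1}{2\pi c}\sqrt{k/\mu}$ is reproduced to ~1e-10
relative error.

The fixed-Born-radius solvent term is intentionally minimal: it is a
smooth, documented implicit model sufficient to keep minimized geometries
compact, not a calibrated solvation model, and it is flagged in the
entropy result's provenance (the `gb` argument).

## Alanine and glycine scanning

`residue_scan()` probes each hairpin position by geometric truncation on
existing snapshots — no re-minimization, no resampling, so all non-mutated
coordinates are bit-identical between wild type and mutant (a property the
tests assert). Alanine mutants truncate at Cβ and replace the Cγ atom with
a hydrogen at 1.09 Å (configurable) along the Cβ→Cγ bond; glycine mutants
(applied at positions whose wild type is alanine, the hotspot convention)
truncate at Cα the same way. The ΔΔG is enthalpic by default — gas +
PB/SA differences, entropy excluded — matching the usual post-processing
scan convention; an entropy-inclusive variant can be assembled from
`binding_entropy()` results if wanted.

Truncating an ionized side chain changes the net charge; the PB term is
simply recomputed with the mutant charge set, with no neutralization
correction. This is a known limitation for charged positions, and it has a
visible analogue in the synthetic fixture: positions *flanking* a charged
site show a polar ΔΔG of a few tenths of kcal/mol purely from the change
in the dielectric cavity around the charge, so "negligible ΔΔG" is only
expected of residues that are uncharged, non-contacting, *and* not
adjacent to a charged site. Alanine and glycine scans are reported as
distinct mutation types and are never numerically compared.

## The hybrid (high-level) assembly

`hybrid_binding_free_energy()` replaces the per-snapshot MM gas term with
externally supplied high-level gas-phase binding energies (e.g. from
large-scale quantum chemistry) and multiplies the MM polar binding term by
a weight derived from a power-law fit $|G_\mathrm{PB}| = A\,\varepsilon^b$
of the polar solvation against the solute dielectric
(`fit_polar_scaling()`, least squares in log–log space). The weight is the
fitted ratio $(\varepsilon_\mathrm{target}/\varepsilon_\mathrm{ref})^b$;
both dielectrics default to 1, making the identity weight, because the
precise weighting rule is a configuration point rather than something this
package can fix on first principles. Entropy and SA terms are unchanged.
With identity records and weight 1 the hybrid result reduces exactly to
the classical one (asserted to 1e-9), and constant offsets in the records
shift ΔG by exactly the offset.

Representative snapshots for expensive high-level calculations are chosen
by `select_representative_snapshots()`: mandatory coarse-stride frames plus
k extra frames minimizing the sum of squared z-scored deviations of the
subset's statistics (mean and standard deviation of the per-frame enthalpic
total, plus each hydrogen bond's occupancy) from the full-trajectory
values, with equal weights. The search is exhaustive up to 5000 candidate
subsets and greedy-with-swap beyond; the greedy path matches the
exhaustive optimum on the package's fixtures. Note that the *optimal*
objective value is not guaranteed to decrease as k grows — the subset
standard deviation is not a nested statistic — so the package asserts
optimality against enumeration rather than monotonicity in k. A half-vs-full
subset ΔG difference is reported as the convergence diagnostic.

Force-error diagnostics (`force_error_profile()`) compare supplied
high-level forces against the analytic gradient of the configured MM model,
reporting the per-atom mean magnitude of the force difference.

## Thermodynamic integration

`ti_stage()` / `stage_delta_g()` implement
$\Delta G = \int_0^1 \langle \partial V/\partial\lambda \rangle\, d\lambda$
by 9-node Gauss–Legendre quadrature mapped to (0,1) (exact for polynomials
of degree ≤ 17, asserted to 1e-10). The alchemical path is three stages —
decharge, soft-core van der Waals transformation, recharge — combined by
`three_stage_total()` with standard errors in quadrature. The soft-core
12-6 potential is the separation-shifted form with shift
$\alpha(1-\lambda_\mathrm{cpl})^p \sigma^6$, defaults $\alpha = 0.5$,
$p = 1$ (values from the common soft-core formulation; exposed in
`softcore_params()` because nothing in the end-state model pins them), with
the analytic $\partial V/\partial\lambda$ cross-checked against finite
differences. It reduces to the plain 12-6 potential at full coupling and is
finite at zero separation for interior λ.

Desk-scale sampling uses seeded Metropolis Monte Carlo on toy potentials
with closed-form free energies (`emit_ti_samples()`): a harmonic
spring-constant change ($\Delta G = \tfrac{kT}{2}\ln(k_1/k_0)$), linear
field coupling (decharge/recharge, $\pm c^2/2k$), and an appearing
soft-core site whose reference value comes from deterministic radial
quadrature of the two partition functions. Node standard errors are block
averaged; per-node first-half vs second-half means are reported as the
staged convergence diagnostic. A per-node equilibration-discard fraction is
configurable, standing in for the equilibration periods a real alchemical
simulation would discard.

## Trajectory analytics

* **Hydrogen bonds** — a frame satisfies a bond if the donor–acceptor
  distance is ≤ 3.5 Å and, when a hydrogen is specified, the
  donor–H–acceptor angle is ≥ 120°. These defaults are the conventional
  geometric criterion of trajectory-analysis tooling and are config-exposed,
  since occupancies are only comparable under a stated criterion.
* **Block averaging** — contiguous equal blocks, remainder folded into the
  last block, SE = sd(block means)/√n_blocks.
* **Distance distributions** — 0.1 Å bins by default; log₁₀ counts mask
  empty bins as explicit missing values, never as zeros.
* **Backbone RMSD** — least-squares rigid-body superposition (Kabsch, via
  bio3d) then coordinate RMSD; the monitor flags ensembles whose trace
  exceeds a bound (default 2.0 Å against the reference structure, with
  2.5 Å the suggested bound when the reference is a remodelled homologue
  rather than the system's own starting structure).

## The synthetic-data generator

`build_complex()` makes a coarse-grained receptor–hairpin complex: a
15-residue two-strand hairpin ligand (backbone N/CA/C plus CB/CG side
chains, PDB naming so every I/O and truncation path is exercised) lying in
a groove of receptor sites. It emulates exactly the statistical structure
the analysis assumes:

* a 4-residue hotspot module (default positions 6–9, phenylalanine-like /
  threonine-like ×2 / alanine) whose side chains sit in deep
  Lennard-Jones pockets at their pair-minimum distances, so binding energy
  is concentrated there with analytically known per-residue contributions
  (stored in the ground-truth record and checked against the MM path to
  1e-9);
* a cationic series (+1/+2/+3 e on lysine-like Cβ sites at positions 12,
  2, 14) against a fixed anionic receptor patch, giving a strictly
  monotone electrostatic ranking;
* intermittent donor–acceptor bonds realized as two-state telegraph
  processes (default correlation time 10 frames so block-averaging sees
  real autocorrelation). After sampling the Markov path, the realized
  state count is corrected to the rounded target by flipping randomly
  chosen frames — a variance-controlled telegraph whose realized occupancy
  equals the target to within 1/(2n) for every seed, while preserving the
  dwell structure that matters for the autocorrelation tests;
* harmonic positional fluctuation: isotropic Gaussian displacement of
  every atom about the reference pose (default σ = 0.1 Å).

Charge sites live on Cβ so that alanine truncation preserves the net
charge; the charged-residue cavity effect described above is then the only
polar signature of those positions. Side-chain well depths of several
kcal/mol are deliberately deeper than chemically realistic so that a
4-residue module carries most of a ~25 kcal/mol interface at desk scale.

What passing tests on this generator do **not** show about real data:
there is no conformational change on binding, no solvent granularity, no
correlated collective motion (frames are independent apart from the
telegraph bonds), no protonation chemistry, and the entropy of binding of
the toy complexes is dominated by rigid-body terms. The generator
validates the *machinery* — estimators, integrators, solvers, bookkeeping —
not force-field accuracy.

## Numerical choices and degenerate inputs

* Zero interatomic distance in any pair sum is an explicit singularity
  error naming the pair (except coincident-sphere SASA, which dedupes).
* An empty atom group contributes zero interaction energy; an empty
  species is an error in entropy and solvation contexts.
* The power-law fit refuses sign-mixed or zero-crossing polar energies and
  degenerate dielectric sets; an all-zero polar input returns the identity
  fit.
* Frame-selection strides must be multiples of the stored frame stride;
  mismatches are errors rather than silent rounding.
* All randomness is seeded: the fixture spec requires a seed, Metropolis
  node seeds are derived deterministically from the stage seed, and
  identical configuration + seed reproduces byte-identical reports (a
  determinism the acceptance checks assert end to end).

## Problem sizes used in the shipped analyses

The numbered drivers under `analysis/` run the whole pipeline at desk
scale: ~95-atom complexes, 2–50 frame ensembles (1000 frames for occupancy
statistics), a 0.5 Å PB grid for the scan and 0.8 Å for ensemble surveys,
and 2000 Metropolis samples per TI node. These sizes were chosen so each
stage completes in seconds to a couple of minutes while every estimator
operates in the regime (autocorrelated frames, grid-converged PB, >10³
samples per node) its statistics assume.
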