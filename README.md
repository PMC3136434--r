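# bindfe — post-processing binding free-energy analysis for receptor–peptide complexes

`bindfe` is an R package for the free-energy analysis that happens *after*
sampling: given conformer ensembles of a receptor–peptide complex (and,
optionally, externally computed high-level gas-phase energies), it computes
binding free energies, per-residue interaction hotspots, and alchemical
free-energy differences. It is aimed at structural/computational biologists
who study peptide-mediated protein–protein interfaces — e.g. ranking a
family of short repeat peptides binding a common receptor groove and
locating the residues that carry the interface.

The package implements, as tested reusable functions:

* **Single-trajectory MM-PBSA.** Per snapshot,

  ΔG_bind = ⟨ΔE_EL + ΔE_vdW⟩ + ⟨ΔG_PB + ΔG_SA⟩ − TΔS,

  with receptor and ligand coordinates extracted from the complex frame so
  intramolecular terms cancel. Electrostatics and 12-6 van der Waals terms
  use infinite cutoffs; the polar solvation term comes from a compiled
  finite-difference Poisson–Boltzmann solver (dielectrics 1/80, 0.5 Å grid,
  sphere-union cavity, harmonic-mean boundary smoothing); the nonpolar term
  is γ·SASA + c from deterministic Shrake–Rupley areas; the entropy term is
  normal-mode analysis of minimized snapshots (Sackur–Tetrode, rigid-rotor
  and quantum harmonic-oscillator components). Ensemble means carry
  block-averaged standard errors and a running-average convergence monitor.
* **Computational alanine/glycine scanning.** Per-residue ΔΔG by geometric
  side-chain truncation at Cβ (alanine) or Cα (glycine, used at hotspot
  alanines) across snapshots, with the replacement hydrogen placed at
  1.09 Å along the severed bond. Pure truncation: no re-minimization, all
  other coordinates bit-identical.
* **A hybrid (QM-PBSA-style) assembly.** The MM gas term is replaced by
  supplied high-level energies; the MM polar term is weighted via a
  power-law fit |G_PB| = A·ε^b against the solute dielectric;
  representative snapshots are selected so the sampled subset reproduces
  the full-trajectory MM statistics (mean, spread, H-bond occupancies);
  per-atom MM-vs-high-level force errors are profiled.
* **Three-stage thermodynamic integration.** Decharge → soft-core vdW
  transformation → recharge, integrated by 9-node Gauss–Legendre
  quadrature with analytic soft-core dV/dλ, per-node block-averaged errors
  and staged convergence diagnostics.
* **Trajectory analytics.** Hydrogen-bond occupancy under a geometric
  criterion, block averaging for autocorrelated series, (log-binned)
  distance distributions, and backbone RMSD with optimal superposition
  plus an equilibration monitor.
* **A synthetic-data generator.** Toy receptor–hairpin complexes with a
  4-residue "FxxA-like" hotspot, a +1/+2/+3 charge series against an
  anionic receptor patch, telegraph-process intermittent hydrogen bonds
  and Gaussian positional fluctuation — with stored analytic ground truth,
  so the entire pipeline runs and is validated at desk scale without MD or
  DFT engines.

## Worked example

```r
library(bindfe)

# a toy receptor-hairpin complex with a 4-residue hotspot and +1 ligand
fx  <- build_complex(fixture_spec(seed = 1, ligand_net_charge = 1,
                                  fluctuation_sigma = 0.05, n_frames = 10))
ens <- sample_ensemble(fx)

# single-trajectory MM-PBSA over the ensemble (0.8 A survey grid)
dec <- snapshot_decomposition(ens, settings = pb_settings(grid_spacing = 0.8,
                                                          grid_padding = 6))
binding_free_energy(dec)
#> <binding_free_energy over 10 snapshots>
#>   EL   -58.861  vdW   -22.067  PB    60.702  SA    -3.827  (kcal/mol)
#>   enthalpy   -24.053 +/- 0.070   -T.dS     0.000   dG   -24.053

# per-residue truncation scan on the reference pose
rigid <- sample_ensemble(build_complex(
  fixture_spec(seed = 1, ligand_net_charge = 1, fluctuation_sigma = 0,
               n_frames = 1, intermittent_bonds = list())))
sc <- residue_scan(rigid, positions = 6:9,
                   settings = pb_settings(grid_spacing = 0.8, grid_padding = 6))
print(sc[, c("label", "wild_type", "mutation", "ddG")], digits = 3)
#>   label wild_type mutation  ddG
#> 1    06       PHE      ala 6.62
#> 2    07       THR      ala 4.14
#> 3    08       THR      ala 3.19
#> 4    09       ALA      gly 2.98
```

Reading the output: favourable electrostatic (−58.9) and dispersion
(−22.1) attraction is partly cancelled by the polar desolvation penalty
(+60.7), leaving a −24 kcal/mol enthalpy with a small nonpolar (buried
surface) bonus; the entropy term is zero here because none was supplied.
The scan shows the binding concentrated in the hotspot module: truncating
the phenylalanine-like side chain costs 6.6 kcal/mol, the two
threonine-like contacts ~4.1 and 3.2, and the hotspot alanine (probed by
glycine truncation) 3.0 — each within the documented PB/SA perturbation of
the generator's analytic side-chain interaction energies.

## The analysis workflow

`analysis/` contains numbered drivers that run the full study on the
synthetic systems and write tables under `results/`:

| script | what it does |
|---|---|
| `01_simulate.R` | builds the +1/+2/+3 charge series with ground truth, writes PDB + parameter tables |
| `02_mmpbsa.R` | MM-PBSA over the series, convergence traces, ΔG relative to the +1 ligand |
| `03_alanine_scan.R` | 15-position alanine/glycine scan at production PB settings vs the analytic truth |
| `04_qmpbsa.R` | dielectric power-law fit, hybrid assemblies, snapshot selection, force-error profile |
| `05_ti.R` | harmonic closed-form TI recovery and a three-stage null mutation |
| `06_trajectory.R` | H-bond occupancy vs telegraph target, block averages, distance histogram, RMSD monitor |

Run them in order with `Rscript analysis/01_simulate.R`, etc.

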