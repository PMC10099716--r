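# bafdyn

Analysis toolkit for the conformational ensembles and binding
thermodynamics of barrier-to-autointegration factor (BAF), a homodimeric
dsDNA- and lamin-binding nuclear protein, and its dominant Gly16Arg
variant. The variant introduces an inter-monomer salt bridge (Arg16
guanidinium to the partner chain's C-terminal Leu89 carboxylate) that
restricts the ensemble of the transiently folded helix alpha-1 (residues
5-12), with measurable thermodynamic consequences for DNA binding.

The package is written for structural biologists who want the complete
post-simulation and calorimetry analysis chain as tested, scriptable
functions:

* **Structure/trajectory I/O** — PDB (with HELIX parsing), multi-model
  PDB and XYZ frame streams; chain-qualified C-alpha region selection.
* **Superposition & RMSD distributions** — Kabsch least-squares fit on a
  rigid core (helices alpha-3 to alpha-6, derived from HELIX records),
  per-monomer region RMSD series, density histograms with median and
  prominence-filtered KDE modes. The headline statistic: helix alpha-1
  RMSD to the reference crystal structure is **bimodal (3.0 / 5.0 A) for
  wild type** and **unimodal (3.0 A) for Gly16Arg**.
* **Salt-bridge tracing** — min-atom-pair or centroid distances, both
  chain orderings, occupancy at the 4.0 A donor-N/acceptor-O criterion,
  and frame-wide bridge scans.
* **Quasi-harmonic configurational entropy** — mass-weighted covariance
  of superposed fluctuations; each eigenmode `lambda_i` contributes as a
  quantum harmonic oscillator with `omega_i = sqrt(kB*T/lambda_i)`:

  `S = R * sum_i [ u_i/(exp(u_i)-1) - ln(1-exp(-u_i)) ]`, `u_i = hbar*omega_i/(kB*T)`

  with convergence-versus-sampling diagnostics.
* **ITC thermodynamics** — one-set-of-sites (Wiseman) isotherm
  simulation with perfusion-cell dilution and half-step correction;
  variable-projection nonlinear fitting of (Kd, dH, n, offset);
  `dG = R*T*ln(Kd)` and the decomposition `-T*dS = dG - dH`.
* **Synthetic-ensemble generator** — a seeded toy dimer whose frames
  reproduce the distributional structure above (basins, flexible
  N-terminus, enforceable bridge), so the whole pipeline runs at desk
  scale without microsecond MD.

## Worked example

```r
library(bafdyn)

ref  <- build_toy_dimer(89)                 # two 89-residue chains + bridge proxies
core <- core_regions_from_helices(ref)      # helices alpha-3..alpha-6 per chain

# Gly16Arg-like regime: single 3.0 A basin, bridge held
traj <- sample_ensemble(ref, ensemble_recipe("restricted", n_frames = 6000,
                                             seed = 1))
rmsd <- region_rmsd_series(traj, ref, core, region_spec("helix-a1", "*", 5, 12))
make_distribution(rmsd$rmsd)
#> rmsd_distribution: n = 11760, median = 3.02 A, 1 mode(s) at 3.03 A

trace_bridge(traj, toy_bridge_pair(ref))
#> salt_bridge_trace (min-atom-pair, cutoff 4.0 A): occupancy A->B 1.000, B->A 1.000

# DNA titration of the variant: 29 x 10 uL, 10 uM cell, 33 uM syringe, 288 K
iso <- simulate_isotherm(titration_schedule(10e-6, 33e-6),
                         kd = 16.3e-9, dh = -18.1, n = 0.5)
fit_isotherm(iso)
#> binding_fit: Kd = 16.3 nM, dH = -18.10 kcal/mol, n = 0.500, dG = -10.26,
#>   -TdS = 7.84 kcal/mol (T = 288 K, c = 307)
```

The distribution median and single mode sit on the 3.0 A basin; the
enforced bridge is fully occupied in both chain orderings; and the fitted
titration returns the simulated Kd with the free energy −10.26 kcal/mol
splitting into the enthalpy −18.1 and an entropic penalty of 7.84
kcal/mol. The wild-type comparison (`kd = 117e-9, dh = -49.5`) gives
dG = −9.13 and a 40.4 kcal/mol penalty: same affinity scale, radically
different decomposition — the signature of the pre-ordered variant.

## Analysis workflow

The numbered drivers under `analysis/` run the full study and write
tables under `results/`:

```sh
Rscript analysis/01_simulate_ensembles.R     # 3 regimes x 6000 frames, RMSD series
Rscript analysis/02_rmsd_distributions.R     # medians, modes, bimodal-vs-unimodal
Rscript analysis/03_salt_bridge.R            # occupancy per regime
Rscript analysis/04_configurational_entropy.R
Rscript analysis/05_itc_thermodynamics.R     # 4 titrations + decomposition
Rscript analysis/06_full_report.R            # end-to-end checked report
```

`vignettes/baf-ensemble-analysis.Rmd` documents the models, parameter
choices and limitations.

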