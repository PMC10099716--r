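---
title: "Conformational ensembles and binding thermodynamics of the BAF dimer: methods"
author: "bafdyn"
output: rmarkdown::html_document
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Barrier-to-autointegration factor (BAF, encoded by *BANF1*) is a small
homodimeric nuclear protein that binds double-stranded DNA through each of
its monomers and anchors chromatin to the nuclear lamina via the lamin A/C
IgFold domain. Its N-terminal region, including the transiently folded
helix alpha-1 (residues 5-12), fluctuates between an *open* ensemble
(unphosphorylated wild type) and a *closed* one (induced by VRK1
di-phosphorylation). The dominant disease variant Gly16Arg introduces an
inter-monomer salt bridge -- the arginine-16 guanidinium of one monomer to
the C-terminal Leu89 carboxylate of the other -- that restricts this
ensemble without phosphorylation: in microsecond molecular-dynamics
sampling the helix alpha-1 region RMSD to the crystal structure collapses
from a bimodal distribution (peaks near 3.0 and 5.0 Angstrom) to a
unimodal one (3.0 Angstrom). The restriction has a thermodynamic
signature measurable by isothermal titration calorimetry (ITC): DNA
binding of the pre-ordered variant pays a far smaller entropic penalty
(7.81 versus 40.4 kcal/mol), yielding a sevenfold affinity gain (Kd 16.3
versus 117 nM) despite a much less favourable enthalpy; lamin IgFold
binding weakens threefold (2.7 to 9.0 uM).

`bafdyn` implements the complete post-simulation analysis chain for this
system -- superposition, region-RMSD distributions, salt-bridge tracing,
quasi-harmonic entropy, and one-set-of-sites ITC simulation/fitting -- and
pairs it with a seeded synthetic-trajectory generator so that every stage
is exercised end to end at desk scale, without rerunning microsecond MD.

## The synthetic-ensemble generator

`build_toy_dimer()` lays one C-alpha per residue on an idealized helical
trace (radius 2.3 A, 100 degrees and 1.5 A rise per residue), two facing
chains, plus two proxy side-chain atoms per chain: a guanidinium nitrogen
(`NH1`) on residue 16 and a carboxylate oxygen (`OXT`) on the C-terminal
residue. `sample_ensemble()` then draws i.i.d. frames:

* every atom receives isotropic Gaussian jitter (`core_jitter`, default
  0.15 A) -- the rigid core;
* independently per chain and frame, a basin is drawn from
  `basin_weights` and the helix alpha-1 C-alphas are displaced rigidly
  along a random direction by a magnitude from
  `N(basin_center, basin_width)` truncated at zero, so the realized
  core-superposed region RMSD is Gaussian around the basin centre. The
  RMSD is *imposed by construction* but always *verified by the analysis
  code itself* (superposition + region RMSD), never assumed;
* residues 1-4 get their own, larger displacement
  (`N(6, 2)` A by default) in every mode: the free N-terminus is highly
  flexible in all variants, which is what keeps it accessible to the VRK1
  kinase. The paper-level evidence for this is graphical only, so the 6
  +/- 2 A default is our one-time choice of a realistic magnitude for a
  fully disordered four-residue terminus; only the qualitative "broad in
  every variant" statement is asserted anywhere;
* when a salt bridge is configured, each frame holds it with
  `hold_probability`; a held frame places the acceptor proxy at exactly
  the target distance (3.0 A by default) from the donor. Enforcement is
  therefore structural, not probabilistic, which makes occupancy
  properties exact.

The three regime presets are `open` (basins 3.0/5.0 A, equal weights --
the 50/50 split is a generator default, not a literature value),
`restricted` (single 3.0 A basin, bridge held in both chain orderings),
and `closed` (basins 1.5/3.0 A, weights 0.3/0.7, so that a minority of
conformers sit below 2 A as seen for di-phosphorylated wild type). The
default 6000 frames mirror the size of the monomeric-structure sets the
MD analysis extracts; both chains are analysed independently, so one run
yields 12000 monomeric samples.

What the generator deliberately does **not** emulate: temporal
autocorrelation (frames are i.i.d.; every downstream statistic here is
distributional), atomistic BAF geometry, solvent, force-field energetics,
or any coupling between the salt bridge and the basin occupancies -- in
the generator the restriction and the bridge are imposed jointly rather
than caused by one another. Passing tests therefore demonstrate that the
*analysis machinery* recovers known distributional structure, not that
the biology emerges from physics. Absolute entropy values are likewise
not calibrated to real BAF; only their convergence behaviour and
Gaussian-limit correctness are meaningful.

## Superposition and RMSD distributions

Superposition is unweighted least squares on core C-alphas (Kabsch via
SVD, reflection branch corrected; optional weights exist but default to
unit, since the analysis is defined on C-alpha positions, not masses).
The core is defined as helices alpha-3 to alpha-6. Their residue spans
are not tabulated anywhere authoritative for this construct, so
`core_regions_from_helices()` derives them from the reference structure's
own HELIX records -- the last four helices per chain -- and an explicit
`region_spec` list can always override this.

`region_rmsd_series()` fits each chain of each frame on the reference
core and evaluates RMSD over the target region *without re-fitting*; a
configurable leading fraction of frames (default 2%) is discarded as
equilibration, mirroring the practice of dropping the first stretch of a
production run. Both monomers pool into one distribution (per-chain
output is available via a single-chain `region_spec`).

`make_distribution()` reports a density-normalised 0.1 A histogram, the
median, and KDE modes. Mode detection is deliberately deterministic:
Gaussian KDE with Silverman's rule-of-thumb bandwidth, local maxima
filtered by **topographic prominence** at 10% of the global maximum
density. Prominence (height above the highest saddle towards a taller
peak) rather than raw height is essential: with 12000 samples the KDE
develops micro-wiggles near a peak top whose heights pass any
height-only threshold. A constant sample (zero bandwidth) is
special-cased to a single mode at the value. All three knobs
(`bin_width`, `bandwidth`, `prominence`) are arguments.

## Salt-bridge tracing

`bridge_distance()` offers two conventions because the exact atom
convention behind the published distance traces is not stated:
`min-atom-pair` (minimum donor-N x acceptor-O distance; robust to
guanidinium two-fold symmetry; the default) and `group-centroid`. The
method is an explicit, recorded argument on every result. Formation uses
the standard structural-biology criterion of 4.0 A donor nitrogen to
acceptor oxygen; "stable" is reported at occupancy >= 0.9. Both chain
orderings (A donor to B acceptor and the reverse) are traced
independently; the swapped ordering is skipped, not faked, when the
topology lacks the partner-chain groups.

## Quasi-harmonic configurational entropy

After core superposition removes overall rotation and translation,
`mass_weighted_covariance()` builds
`C[i,j] = sqrt(m_i m_j) <dx_i dx_j>` over the selected atoms (one
monomer's C-alphas in the standard analysis). Each eigenvalue `lambda_i`
(amu A^2) defines an effective harmonic mode with
`omega_i = sqrt(kB T / lambda_i)`, and the molar entropy sums the quantum
harmonic oscillator formula

```
S = R * sum_i [ u_i/(exp(u_i)-1) - ln(1-exp(-u_i)) ],   u_i = hbar*omega_i/(kB*T)
```

in cal mol^-1 K^-1. Numerical choices:

* temperature defaults to 310 K, the simulation thermostat;
* the eigenvalue floor (default 1e-8 amu A^2) discards the ~6 near-null
  rigid-body modes left by superposition; the discarded count is always
  reported, never silent;
* constants are CODATA 2018, exported as `baf_constants` and echoed into
  pipeline reports;
* `entropy_convergence()` recomputes S on the first k frames at
  increasing checkpoints and flags convergence when the last two differ
  by < 1% relative -- the completeness-of-sampling check. Because a
  finite-sample covariance underestimates dispersion, the series
  approaches its limit from below.

## ITC: one-set-of-sites simulation and fitting

`simulate_isotherm()` implements the standard single-site-class
(Wiseman) model with perfusion-cell bookkeeping: each injection `dV`
dilutes both totals by `(1 - dV/V0)` and adds titrant `Xs*dV/V0`; the
bound concentration comes from the exact quadratic solution of the 1:n
equilibrium; the injection heat is the difference in cell heat content
plus the standard half-step displacement correction, an optional constant
dilution offset, and optional Gaussian noise. The cell volume is not a
published quantity for these experiments; 1.4 mL, the nominal VP-ITC
active volume, is the configurable default. Heats are per mole of
injectant, the Origin convention.

`fit_isotherm()` exploits the model's structure: at fixed (Kd, n) the
heats are *linear* in (dH, offset), so the fit profiles those two out
with an exact linear solve and optimises only log10(Kd) -- plus n when
floated -- with a multi-start over ten decades of Kd. This variable
projection makes noiseless round trips exact to ~1e-8 relative and
removes any dependence on starting enthalpy guesses. Safeguards: >= 5
injections required; an isotherm with no heat variation raises an
unidentifiability error rather than returning an arbitrary Kd; the
Wiseman c-value (`n*[cell]/Kd`) triggers a warning outside 1-1000. A
`drop_first` flag discards the first injection (universal ITC practice)
but defaults to off.

Derived thermodynamics use `dG = R T ln(Kd)` (natural log, 1 M standard
state, R = 1.9872e-3 kcal/mol/K) and the identity `-T dS = dG - dH`,
which every `binding_fit` satisfies to 1e-6 kcal/mol by construction.

Two bookkeeping decisions were genuinely open:

* **Lamin stoichiometry.** The cell species is counted as monomeric BAF
  and n is fixed at 0.5 -- one IgFold site per dimer -- matching how the
  micromolar interaction must be fitted at c near 1.
* **DNA stoichiometry.** No published value exists. We simulate truth
  n = 0.5 (one 22-nt duplex per dimer) and float n in fits. The decisive
  argument is the experimental design itself: with 10 uM cell, 33 uM
  syringe and 29 x 10 uL injections the titration only reaches molar
  ratio ~0.68, so n = 1 would never reach saturation and Kd would be
  ill-conditioned; n = 0.5 is the bookkeeping under which these printed
  concentrations produce a complete sigmoid. The lamin enthalpy is also
  unpublished; -10 kcal/mol is used as a plausible scenario value (it
  does not affect Kd recovery).

## NMR descriptors

`het_noe()` is the saturated/reference intensity ratio (with replicate
aggregation in `het_noe_table()`). `two_state_projection()` places a peak
on the open-to-closed axis in (1H, 15N) shift space after scaling
nitrogen shifts by 0.14 (the conventional combined-chemical-shift
weight); the fractional position is clipped to [0, 1] and the
perpendicular residual is returned as a collinearity diagnostic. This is
a geometric descriptor only -- no exchange kinetics or thermodynamic
populations are fitted, matching the qualitative "intermediate peak
position" reading of the spectra. Consequence of the scaling choice: the
fraction is invariant under a shared uniform rescaling and per-axis
offsets of all three peaks, but not under arbitrary anisotropic maps.

## Pipeline, problem sizes, and what the tests show

`run_pipeline()` sequences generation, RMSD distributions, bridge
tracing, entropy and both ITC scenarios under one configuration
(`default_run_config()`), records per-stage artifacts with MD5 checksums,
and evaluates the qualitative contrasts as named pass/fail checks
(bimodal-versus-unimodal helix alpha-1; residues 1-4 broad everywhere;
bridge occupancy high only when enforced; sevenfold and threefold
affinity changes). Reports contain no timestamps, so identical
configurations and seeds produce byte-identical JSON. A variant removed
from the configuration yields an explicit skip record; a failing stage is
recorded and the remaining stages still run. The numbered scripts under
`analysis/` are thin narrative drivers over these same functions and
write their tables under `results/`.

Problem sizes: headline ensemble analyses use the full 6000-frame /
89-residue-per-chain configuration. Unit and pipeline tests use 120-1500
frames, where every qualitative contrast is already stable; distributional
recovery tests (mode locations, entropy-versus-analytic, basin
occupancies) use the full 6000 frames with fixed seeds.

## Known limitations

* The generator's i.i.d. frames cannot exercise autocorrelation-aware
  statistics (effective sample size, block averaging); the entropy
  convergence curve tests sampling sufficiency only in the i.i.d. sense.
* Region-RMSD displacement is rigid per frame, so intra-region
  deformation of helix alpha-1 is not represented; only the RMSD
  magnitude distribution is meaningful.
* Absolute quasi-harmonic entropies of the toy dimer are not comparable
  to real BAF values; differences between regimes are small because only
  8 of 89 monomer residues change regime.
* The ITC module fits integrated heats; baseline integration of raw
  power traces, competitive titrations, and multi-site models are out of
  scope.
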