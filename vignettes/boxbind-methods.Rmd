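---
title: "Models and methods behind boxbind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind boxbind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boxbind)
```

`boxbind` packages the quantitative steps of a clathrin adaptor-selectivity
study: scanning disordered regions for clathrin-binding motifs (CBMs),
estimating apparent dissociation constants from nanoDSF thermal shifts,
testing native-MS binding-site models, comparing FRET efficiencies between
strains, and superposing Cα structures. This vignette explains each model,
its assumptions, the tunable parameters, and the choices made where the
design was genuinely open.

## Motif scanning

A motif is an ordered list of allowed-residue classes, one per position;
`x` is a 20-letter wildcard. Scanning slides the motif over the sequence
and reports every (possibly overlapping) window whose residues all fall in
their class — no scoring, no gaps, exactly the semantics of SLiM-style
pattern searches. Coordinates are 1-based and inclusive throughout.

Two CBM variants ship in `cbm_motifs()`: `[TSNV]L[IL]D[ILMFW]`
(`CBM_core`) and the Asp-extended `[DSNTV]L[IL]D[ILMFW]` (`CBM`). The
extended variant is the default because it is the more complete statement
of the yeast motif and is required to match the Asp-flanked instances in
Ent5 and Apl2; the narrower variant is retained so both definitions can be
compared on the same proteome.

Disorder filtering keeps a hit iff the arithmetic mean score over the
matched span passes the cutoff: mean disorder probability ≥ 0.5 by
default, or — for AlphaFold confidence tracks, where low values mean
disorder — mean pLDDT strictly below 50. The span mean is a choice (common
SLiM-scanner practice); per-residue aggregation would be the natural
alternative and gives slightly stricter filtering near span edges.
Sequence letters outside the 20-letter alphabet (X, B, Z, U) never match a
finite class but do match wildcards — a conservative treatment of
ambiguity codes. The iterative literature/ELM refinement loop that
produced the motif is not automated; the scanner applies fixed motifs.

## Thermal-shift affinity estimation

nanoDSF reports intrinsic fluorescence along a thermal ramp; the melting
temperature `T_m` is taken at the extremum of the first derivative of the
trace. Traces are smoothed with a Savitzky–Golay filter (window 9 points,
order 3; the instrument's own smoothing is not public, so a standard
derivative-preserving filter is used) and a transition is declared only
when the derivative extremum exceeds 3× the median absolute derivative —
below that, the trace is indistinguishable from a sloping baseline and
`detect_tm()` raises a `NoTransition` error rather than reporting noise.

The binding model is thermodynamic linkage for a two-state unfolder with
1:1 folded-state binding:

* ΔG_u(T) = ΔH_u(1 − T/T_m0) + ΔC_p[(T − T_m0) − T·ln(T/T_m0)]
* K_u(T) = exp(−ΔG_u/RT), f_u = K_u/(1 + K_u)
* at the shifted midpoint: K_u(T_m) = 1 + [L]_free/K_D

Free ligand uses depletion at the midpoint, where exactly half the protein
is folded: [L]_free solves L_free = L_t − (P_t/2)·L_free/(K_D + L_free)
(closed-form positive quadratic root). With ΔC_p = 0 the midpoint equation
is closed-form in T; otherwise it is bracketed on [T_m0, T_m0 + 60 K].

`fit_kd_tmshift()` least-squares fits (log10 K_D, ΔH_u, T_m0) to the
observed T_m ladder, multistarting from K_D ∈ {1, 10, 100, 1000} µM with
log10 K_D bounded to [−2, 5] (µM scale). Assumptions worth stating:

* **Binding enthalpy ≈ 0.** The reported K_D is apparent and refers to the
  melting-temperature regime; without ITC-style data the van't Hoff
  temperature correction of K_D is not identifiable from a T_m ladder.
* **ΔC_p fixed (default 0), not fitted.** It is weakly identifiable from
  T_m data alone; it is user-settable for sensitivity analysis.
* **CI95 by profile likelihood.** The profile of the residual sum of
  squares over log10 K_D is scanned on a 0.1-wide grid, re-optimising
  (ΔH_u, T_m0) at each point, with an F-based threshold for one parameter
  at 95%. This reproduces the asymmetric intervals typical of Tm-shift
  fits at a fraction of bootstrap cost; when the profile never re-crosses
  the threshold before the upper bound, the interval is flagged open —
  which is exactly what a shift-free titration produces.

Temperatures are Kelvin internally and Celsius at I/O boundaries;
concentrations are µM throughout.

## Native-MS occupancy and competition

The input boundary is a table of species intensities per stoichiometry
(0..n_max) per titration point — deconvolution of raw spectra is
instrument-specific and out of scope. Intensities are used as
concentration proxies with equal response factors across stoichiometries,
the standard native-MS assumption. `n_max` defaults to 4 (a sparsely
populated fourth binding event may be unspecific), while fitting defaults
to `n_sites = 3`; observed mass beyond the fitted site count is compared
against zero.

The null model is n non-interacting identical sites: per-site occupancy p
solves the ligand-depleted isotherm (a quadratic), species fractions are
binomial C(n,i)·p^i·(1−p)^(n−i). Two exact properties anchor the tests:
the Scatchard identity ν/[L]free = (n − ν)/K_D holds algebraically for
this model at any ligand concentration, and stepwise constants
K_i = K_D·i/(n − i + 1) collapse the sequential-binding model onto the
binomial law (the statistical-factor identity).

`fit_identical_sites()` minimises the summed squared fraction residuals
over a single K_D; the minimised sum per degree of freedom is the
deviation statistic. Its null distribution is calibrated by parametric
simulation (multinomial counts at user-set N), not an asymptotic
chi-square — native-MS counts are small and the statistic's null scale
depends on N. A fitted deviation above the simulated 95th percentile
flags site heterogeneity or cooperativity, the quantitative counterpart
of spotting curvature in a Scatchard plot.

Competition between two ligands for one site is solved by damped
fixed-point iteration on the free concentrations (damping 0.5, relative
tolerance 1e−12, cap 10,000 iterations), conserving mass to ~1e−9.
Displacement asymmetry is measured on the *relative* scale — the fraction
of the baseline complex lost, 1 − f_B(a)/f_B(0). On the absolute scale
the stronger titrant's advantage genuinely inverts at high doses (the
stronger binder leaves a larger baseline pool to displace in the mirror
experiment, verified against an independent equilibrium solver), so the
relative measure is the faithful formalisation of "displaces more
effectively".

## FRET statistics

Acceptor-photobleaching efficiency is donor dequenching,
E = 100·(D_post − D_pre)/D_post. Inputs arrive background-subtracted
(an optional `background` column is subtracted when present); image
processing and ROI segmentation are upstream. QC keeps an ROI iff the
acceptor bleach fraction reaches 0.85 (inclusive — "at least 85%");
negative efficiencies are retained because discarding them biases group
means upward. Dropped ROIs are reported with reasons.

Group comparisons use Yuen's trimmed-means test: trimmed means with
⌊γn⌋ removed per tail, winsorized variances, and Welch–Satterthwaite
degrees of freedom; at γ = 0 it reduces exactly to Welch's t-test (a
tested identity). The default trim γ = 0.2 follows the convention of the
robust-statistics literature the test comes from. Pairwise tests against
the reference group are Holm–Bonferroni corrected (via `p.adjust`), with
significance stars at 0.05/0.01/0.001/0.0001 on adjusted p-values. The
omnibus heteroscedastic trimmed-means ANOVA and its explanatory-measure
effect size are deliberately omitted: only the pairwise-vs-reference
comparisons are computed, and guessing the plotting package's exact
effect-size estimator would be worse than leaving it out.

## Structure comparison

`load_calpha()` reads PDB or mmCIF through bio3d, keeping Cα atoms of one
chain (first protein chain when unspecified), altloc blank or 'A', first
occurrence on duplicates, optionally restricted to an author residue-number
range such as 5–336. Superposition pairs residues by author number over
the intersection of the selections — the compared models are the same
protein in different complexes, so sequence alignment is unnecessary.
The optimal rotation is the closed-form SVD solution with the reflection
correction (det = +1 enforced); tests check it against a numerical
optimiser over axis-angle parameters and against bio3d's own fitting as
independent routes. At least 3 non-collinear shared residues are
required.

## Synthetic data: what it does and does not emulate

Every generator is seeded, returns a truth manifest, and implements its
forward model independently of the fitting code, so recovery tests are
genuine round trips:

* `gen_toy_proteome()` — uniform-residue background with motif instances
  planted in spans whose disorder score is 0.9 (or 0.1 for ordered
  decoys); the manifest includes an exhaustive self-scan so background
  collisions are accounted for. Real proteomes have biased composition
  and autocorrelated disorder; the generator does not emulate either, so
  passing tests show scanner correctness, not realistic hit-rate
  calibration.
* `gen_melting_titration()` — apo + 11-point 1:1 dilutions from 3.75 mM
  at P_t = 8 µM, the assay design; linear native/unfolded baselines and
  Gaussian signal noise on a 0.5 °C grid. The study conditions for the
  recovery experiments use T_m0 = 318.15 K and ΔH_u = 250 kJ/mol — the
  enthalpy is calibrated so the strongest binder's saturating shift
  reproduces the >15 °C stabilisation the assay shows for CBM peptides.
  Real traces add photobleaching drifts and aggregation signatures not
  modelled here.
* `gen_species_titration()` — multinomial counts (default N = 5000) from
  either the identical-sites law or a stepwise sequential-equilibrium
  partition function at P_t = 1.75 µM. Real spectra add charge-state and
  desolvation effects that live outside the species-intensity boundary.
* `gen_fret_rois()` — lognormal donor intensities, per-ROI efficiencies
  Normal(E, sd), bleach fractions Normal(0.92, 0.03); group sizes ~100
  match the per-pair event counts of the imaging design. Spatial
  correlation between ROIs of one cell is not modelled.

## Problem sizes and numerical choices

The recovery studies run at the design sizes: 3 affinities (34, 138,
598 µM) × 20 seeds with σ(T_m) = 0.3 K for the thermal shift; 6-point
ligand grids at N = 5000 counts with a 200-simulation null calibration
and 20 cooperative seeds for native MS; 1000 replicates of the 8-group,
n = 100 null design for the family-wise error; 80-residue helices for
superposition. Tolerances: Scatchard identity and mass balance at 1e−9,
Yuen/Welch agreement at 1e−10, fixed-point solvers at 1e−12 relative.
Degenerate inputs fail loudly: flat melting traces raise `NoTransition`,
all-apo titrations refuse to fit, shift-free ladders report an open upper
confidence bound, collinear coordinate sets raise geometry errors.

## Known limitations

* The apparent K_D from T_m shifts has no reference temperature; comparing
  it to isothermal methods requires the ΔH_b ≈ 0 caveat above.
* The deviation statistic flags departure from the identical-sites null
  but does not distinguish site heterogeneity from cooperativity — the
  same ambiguity the underlying experiment has.
* The motif scanner reports matches, not binding: flanking-charge effects
  that modulate affinity are visible only to the downstream assays.
* Disorder tracks are inputs; no predictor is bundled.
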