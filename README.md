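# boxbind

Quantitative analysis of clathrin-box adaptor binding in budding yeast.

Clathrin-mediated endocytosis and Golgi trafficking depend on adaptor
proteins docking short linear clathrin-binding motifs (CBMs), carried in
intrinsically disordered regions, onto the binding boxes of the clathrin
heavy-chain N-terminal domain (NTD, a WD40 β-propeller). `boxbind`
implements the analysis chain used to dissect that selectivity, for
structural biologists and biophysicists working with nanoDSF, native mass
spectrometry, FRET microscopy and crystal structures:

- **Motif scanning** — positional character-class motifs (CBM
  `[DSNTV]L[IL]D[ILMFW]` and the narrower `[TSNV]` variant, Arrestin
  `[LI][LI]GxL`, W-box `WxxW`) scanned over FASTA proteomes, restricted to
  disordered regions (disorder probability ≥ 0.5, or pLDDT < 50).
- **Thermal-shift affinity estimation** — melting temperatures from the
  extremum of the smoothed first derivative of nanoDSF traces, and apparent
  K_D from the thermodynamic-linkage (Tm-shift) model: two-state unfolding
  with ΔG_u(T) = ΔH_u(1 − T/T_m0) + ΔC_p[(T − T_m0) − T ln(T/T_m0)] coupled
  to 1:1 folded-state binding, so the shifted midpoint satisfies
  K_u(T_m) = 1 + [L]_free/K_D.
- **Native-MS occupancy** — species fractions, average occupancy
  ν = Σ i·f_i, Scatchard coordinates (ν, ν/[L]free); a non-interacting
  identical-sites null model (binomial fractions with ligand depletion),
  a simulation-calibrated deviation statistic that flags cooperativity, and
  an exact two-ligand one-site competition solver for displacement
  titrations.
- **FRET statistics** — acceptor-photobleaching efficiencies
  E = (D_post − D_pre)/D_post with an ≥85% bleach QC gate, Yuen trimmed-mean
  two-sample tests (winsorized variances, Welch–Satterthwaite df) and
  Holm–Bonferroni correction against a reference group.
- **Structure comparison** — Cα extraction from PDB/mmCIF and closed-form
  Kabsch superposition (proper rotation, reflection-corrected) with RMSD
  over a residue range.
- **Synthetic data** — seeded generators for every input (toy proteomes with
  planted motifs, melting titrations, multinomial species counts, FRET ROI
  tables, helical coordinate sets), each with a truth manifest, so the full
  pipeline runs without downloads.

## Worked example

Scan the classic adaptor peptides for the CBM:

```r
library(boxbind)
peps <- c(Ent1 = "GYTLIDL", Ent2 = "GVSLIDL", Ent5.1 = "IPDLIDLDD")
scan_proteome(peps, cbm_motifs()$CBM)
#> Proteome scan: 3 hits in 3 proteins
#>   protein_id motif_name start end matched disorder_mean
#> 1       Ent1        CBM     3   7   TLIDL            NA
#> 2       Ent2        CBM     3   7   SLIDL            NA
#> 3     Ent5.1        CBM     3   7   DLIDL            NA
```

Each peptide carries one CBM instance starting at residue 3; `disorder_mean`
stays `NA` because no disorder track was supplied.

Simulate an 11-point 1:1 dilution titration (top 3.75 mM, 8 µM protein,
true K_D = 138 µM) and fit it back:

```r
m <- thermo_model(Tm0_K = 318.15, dHu_kJmol = 250)
g <- gen_melting_titration(m, Kd_uM = 138, Pt_uM = 8, noise_sd = 0.003,
                           seed = 4)
fit_kd_tmshift(g$curves, Pt_uM = 8)
#> Tm-shift binding fit (two-state, 1:1 ligand-coupled stability)
#>   Kd_app: 156.515 uM  (CI95 97.2405 - 252.528 uM)
#>   Tm0: 318.178 K   dHu: 234.605 kJ/mol   dCp:       0 kJ/(mol K)
#>   12 titration points, residual norm 0.970169 K
```

The recovered K_D (157 µM) brackets the generating value within its profile
CI; the residual norm reflects the 0.5 °C temperature grid of the simulated
traces. A displacement titration in the style of a sub-saturating
competition experiment:

```r
competition_curve(1.75,
  fixed   = list(label = "Ent2", conc_uM = 20, Kd_uM = 177),
  titrant = list(label = "Ent1", grid_uM = c(0, 5, 10, 15, 20, 25, 30, 50),
                 Kd_uM = 138))
#>   titrant_uM frac_bound_titrant frac_bound_fixed frac_free
#> 1          0         0.00000000       0.10071825 0.8992817
#> 2          5         0.03121967       0.09759803 0.8711823
#> 3         10         0.06056639       0.09466359 0.8447700
#> ...
```

A command-line wrapper with `scan`, `tmfit`, `nms-occupancy`,
`nms-compete`, `fret`, `rmsd` and `simulate` subcommands lives at
`inst/scripts/boxbind.R` (see `?boxbind_run`).

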