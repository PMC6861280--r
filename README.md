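# telophen

Quantitative phenotyping machinery for telomere-dysfunction studies in
progeria (HGPS) models. Progerin, the truncated lamin A that causes
Hutchinson–Gilford progeria, triggers a DNA-damage response at telomeres;
the downstream readouts — damage foci colocalizing with telomere markers,
deformed nuclear envelopes, induced telomeric noncoding RNAs, skin damage,
shortened lifespan — are what this package quantifies. It is aimed at
imaging and molecular-biology groups who need these measurements as tested,
scriptable R functions rather than one-off macros.

Five analysis modules, plus seeded synthetic-data generators with ground
truth for every input:

* **TIF calling** — nuclei from DAPI, foci per channel as supra-threshold
  8-connected components per optical section, and telomere
  dysfunction-induced foci (TIFs) by the colocalization rule: a DDR-marker
  focus and a telomere-marker focus colocalize when **≥ 5 pixels overlap
  within the same z-section**; a cell is positive with ≥ 1 TIF.
  (`segment_nuclei`, `detect_foci`, `call_tifs`, `rnascope_positive`)
* **Nuclear circularity** — lamin A/C segmentation and the circularity
  index `C = 4πA/P²` (1 = perfect circle, 0 = straight line), with a
  Crofton boundary-length estimator. (`segment_lamin`,
  `circularity_from_labels`, `circularity_profile`)
* **qPCR quantification** — triplicate collapse and comparative-Ct folds
  `E^-(ΔCt - mean ΔCt_calibrator)` against Rplp0/mir17 references.
  (`collapse_replicates`, `relative_expression`, `group_summary`)
* **Histopathology** — severity (0–3) × extent (1–3) per skin variable,
  cumulative score 0–45 over five variables, automated nuclear IHC
  positivity with low/intermediate/high intensity bins.
  (`sample_damage_score`, `damage_score_table`, `ihc_nuclear_positivity`)
* **Statistics** — pooled-variance Student's t, one-way ANOVA + Tukey,
  chi-squared with Wilson CIs, Kaplan–Meier curves with log-rank
  (Mantel–Cox) tests and median/maximum lifespan percent changes.
  (`compare_means`, `compare_proportions`, `survival_analysis`)

## Worked example

Simulate a field with a known TIF burden and recover it:

```r
library(telophen)

cfg <- sim_config(seed = 7, n_nuclei = 10, width = 256, height = 256,
                  telo_foci = c(0, 6), coloc_fraction = 1)
sim    <- simulate_tif_stack(cfg)
nuclei <- segment_nuclei(sim$stack)
params <- coloc_params()            # min_overlap = 5, robust threshold
telo   <- detect_foci(sim$stack, "telomere_marker", nuclei, params)
ddr    <- detect_foci(sim$stack, "ddr_marker", nuclei, params)
tifs   <- call_tifs(ddr, telo, params, nuclei = seq_len(max(nuclei)))
head(tifs$records)
#>   nucleus n_tif positive
#> 1       1     2     TRUE
#> 2       2     1     TRUE
#> 3       3     3     TRUE
#> 4       4     0    FALSE
#> 5       5     3     TRUE
#> 6       6     3     TRUE
```

`n_tif` is the merged per-nucleus TIF count and `positive` the ≥ 1-TIF
flag; on this field the counts match the generator's planted truth
(`sim$truth$tif_counts`) nucleus for nucleus.

The numbered scripts under `analysis/` run the full workflow — simulate
inputs, call TIFs per group, score circularity, compute qPCR folds, damage
scores and survival — writing tables under `results/` and printing the
group statistics, e.g. `Rscript analysis/01_simulate.R` then
`Rscript analysis/06_survival.R`:

```
                        group median max_lifespan pct_change_median
HGPS_ctrlASO     HGPS_ctrlASO      8           13               0.0
HGPS_antiTeloG HGPS_antiTeloG     11           16              37.5
log-rank (Mantel-Cox) vs control:
           group    chisq df    p_value
1 HGPS_antiTeloG 5.891298  1 0.01521588
```

a 13-animal-per-group cohort with control median survival 8 days and a
treated median drawn 1.24× longer, analysed with the package's
Kaplan–Meier report.

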