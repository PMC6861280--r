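---
title: "telophen: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{telophen: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

telophen quantifies the cellular and tissue phenotypes that characterise
progerin-driven premature aging: DNA-damage foci at telomeres, nuclear
envelope deformation, induction of telomeric noncoding RNAs, skin
histopathology, and survival. This vignette documents the models behind
each module, the conventions adopted where the underlying assays leave them
open, and what the synthetic-data validation does and does not demonstrate.

## TIF calling by two-channel colocalization

A telomere dysfunction-induced focus (TIF) is a DDR-marker focus (53BP1,
pKAP1) that colocalizes with a telomere marker (TRF1/TRF2). The pipeline
operates on deconvolved multi-channel z-stacks and applies the rule at the
level of supra-threshold pixels: two foci colocalize when **five or more
pixels overlap between the two channels within the same z-section**. A cell
is scored positive when it shows at least one TIF.

Conventions adopted where the assay leaves them open:

* **Thresholding.** Channel thresholds are computed within the nuclear mask.
  The default is a robust background model, `median + k * MAD` with `k = 7`
  after a light per-section Gaussian pre-filter (sigma 0.7 px). Otsu
  thresholding — the obvious parameter-free alternative — assumes a bimodal
  histogram; diffraction-limited foci occupy on the order of 2% of nuclear
  voxels, the intensity histogram is unimodal with a long tail, and Otsu
  collapses into the background mode (measured on simulated fields: it calls
  over a third of the nucleus foreground). Otsu, percentile, and fixed
  thresholds remain selectable. The MAD multiplier and the pre-filter were
  calibrated jointly on simulated ground truth: smaller `k` merges nearby
  foci through their summed tails, larger `k` erodes footprints until
  genuine pairs fall below the 5-pixel overlap rule.
* **Focus definition.** Foci are 8-connected components of supra-threshold
  pixels per z-section, linked across adjacent sections when their (y, x)
  footprints overlap by at least one pixel, so one physical focus counts
  once while the colocalization rule itself stays strictly per-section.
  Components below 4 pixels total are discarded as noise. Both choices are
  exposed in `coloc_params()`.
* **Merging.** One colocalization event is emitted per (DDR focus, telomere
  focus, section); events sharing a focus merge into a single TIF, so the
  per-nucleus count is the number of connected components in the bipartite
  event graph and never exceeds the smaller per-channel focus count.
* **Nucleus assignment** is by centroid containment; foci whose centroid
  falls in background are discarded; ties are never split.
* Coordinates are `[y, x, z]`, 1-based in R; label 0 is background.

## Nuclear circularity

The lamin A/C channel is threshold-segmented, rims are hole-filled into
nucleus regions, and each region is scored with the circularity index

$$C = \frac{4\pi A}{P^2},$$

1.0 for a perfect circle, approaching 0 for elongated shapes, and exactly 0
for the degenerate zero-area (straight line) limit. The formula itself is
the standard ImageJ convention, adopted because it reproduces the stated
endpoints; values are clamped to the unit interval since discrete-boundary
estimators can marginally overshoot 1.

The perimeter uses a **Crofton boundary-length estimator** (transition
counts along four scan directions with Crofton weights). The naive
boundary-pixel chain overestimates smooth perimeters by up to 8%
(pixelation bias), which would bias $C$ down by ~15% for a circle; the
Crofton estimate of a radius-100 disk is within 0.03% of $2\pi r$. The
polygonal chain length remains available (`perimeter_method = "chain"`).
Circularity is computed on one representative section (the
maximum-foreground z-section), configurable to the maximum projection.
Regions under 100 px are treated as debris.

## Comparative-Ct quantification

Replicate Ct values (triplicate reactions) are averaged per reaction;
reactions whose replicate range exceeds 0.5 cycles are flagged, and
undetermined wells are dropped by default (imputation at a fixed cycle is
optional; a fully undetermined reaction stays in the table as a missing
record). Relative expression uses the comparative-Ct method with Rplp0 as
reference for mRNA and strand-specific dilncRNA assays and mir17 for
small-RNA assays:

$$\Delta Ct = Ct_{target} - Ct_{ref}, \qquad
  \text{fold} = E^{-(\Delta Ct - \overline{\Delta Ct}_{calibrator})}$$

with amplification efficiency $E = 2$ by default (configurable). Strand
tags and assay class are metadata: the arithmetic is identical across assay
chemistries. Folds are calibrated per experiment; the calibrator group's
*geometric* mean fold is 1 by construction (the arithmetic mean exceeds 1
under noise by Jensen's inequality — the package summarises arithmetic
means and sd because those are what error bars on such plots show). A
uniform Ct shift applied to every target of a sample — the signature of a
loading difference — cancels exactly in $\Delta Ct$.

## Histopathology scoring and nuclear IHC

Five skin variables (epidermal hyperplasia, basal layer disarray,
keratinocyte nuclear atypia, keratinocyte apoptotic/necrotic figures,
dermal stromal remodeling) are graded by severity (0 absent - 3 severe)
and extent (1 focal - 3 diffuse). The per-variable score is the product
severity x extent; the sample's cumulative score is the sum over the five
variables (0-45). Sum, rather than another aggregate, is adopted for
"cumulative"; extent is disregarded when severity is 0 (an absent lesion
has no extent).

Automated nuclear IHC positivity consumes a stain-intensity image (color
unmixing is out of scope), nucleus masks and a manually segmented epidermis
mask: per-nucleus mean intensity, positive above threshold (Otsu over the
per-nucleus means by default — here the distribution *is* bimodal — or a
fixed value), positives binned low/intermediate/high by tertiles of the
positive means or fixed edges. The three bins always partition the positive
count.

## Group statistics and survival

As declared for these readouts: two-tailed Student's t with pooled variance
for two groups (Welch by flag); one-way ANOVA with Tukey HSD post-hoc for
more (Bonferroni/Holm selectable — the specific correction is not pinned
down by the assays, Tukey is the all-pairs default); Pearson chi-squared
without continuity correction on positive/negative counts (counts in such
experiments are hundreds of cells; Yates by flag) with Wilson 95% intervals
(better small-sample coverage than Wald); Kaplan-Meier product-limit curves
with the log-rank (Mantel-Cox) test. Median survival is the smallest time
with $S(t) \le 0.5$ (not reached when everything is censored); maximum
lifespan is the largest *event* time — the longest-surviving animal rather
than an upper percentile, flagged as a convention. Lifespan changes are
reported as $100 \times (\text{treated} - \text{control}) / \text{control}$
for both median and maximum. Degenerate log-rank designs (all animals in
both groups dying on the same day) report NA rather than failing.

## The synthetic-data generators

The generators produce every input the pipeline consumes, with
machine-readable ground truth, under one explicitly seeded private RNG
stream per simulation (the caller's RNG state is untouched; identical
config + seed is byte-identical).

**Imaging fields.** Fields of ~25 non-overlapping nuclei (radius 11-16 px)
over 5 optical sections emulate fibroblast monolayers. Foci are isotropic
2D Gaussians (sigma 1.5 px) whose amplitude halves per section away from
their centre — a deconvolved confocal-like spot that keeps the per-section
overlap rule exercisable. Noise is Poisson shot noise on signal plus
background (10 counts) with additive Gaussian read noise (sd 2); SNR is
defined as peak spot amplitude over background sd, default 8. Planted TIF
pairs share a z-section and centroid up to 0.5 px, guaranteeing
supra-threshold overlap of at least 5 px; non-colocalizing DDR foci stay
at least 3 sigma from every telomere focus (in practice 5 sigma, see
below), so ground truth is unambiguous. The colocalized fraction is applied
deterministically per nucleus (`round(f * n)`). Same-channel foci are
planted at least 5 sigma apart: closer spots cease to be resolvable by any
threshold detector once their tails sum above threshold, and a validation
generator must plant counts the rule can in principle recover — at 4 sigma,
raising SNR eventually *merges* spots and recovery degrades for the wrong
reason.

**Envelope fields.** Lamin rims follow $r(\theta) = R(1 + a\sin(k\theta +
\phi))$ (default 4 lobes) or ellipses of configurable axis ratio; the true
circularity of each boundary is recorded analytically (quadrature for
sinusoids, Ramanujan's perimeter approximation for ellipses). Amplitude 0
gives circles with true circularity exactly 1.

**Tables.** Ct values follow `baseline - log2(fold) + sample shift +
technical noise` with the reference gene at fold 1 and triplicate
structure; the per-group fold defaults (4 for dilncRNA targets) are free
parameters chosen as realistic inductions — the underlying assays report
them only graphically. Histology draws severity/extent per variable from
per-group ordinal distributions (controls concentrated at absent/focal,
disease at moderate-severe/diffuse, treatment intermediate). Survival
times come from Weibull (default shape 4), exponential or fixed families
with the group median matched exactly; the defaults encode a control
median of 8 days — the short-lived progeria cohort scale — with a treated
median scaled by 1.24 and n = 13 per group. Times are rounded to integer
days, the resolution at which such cohorts are followed; `round_days =
FALSE` disables this where exact non-integer medians are needed (e.g.
verifying the +24% arithmetic, since 9.92 days is not representable in
whole days).

**What passing on synthetic data shows — and what it does not.** The
generators validate the *quantification machinery*: that the colocalization
rule, the circularity estimator, the fold-change arithmetic and the
statistics recover planted truth under realistic noise. They deliberately
omit optical PSF structure, chromatic shift, tissue autofluorescence,
segmentation-hard nucleus clumping, amplification-efficiency drift and
real histological texture; recovery rates measured here are therefore
upper bounds on real-data performance, and thresholds calibrated on these
fields (the 7-MAD default) should be re-examined on real acquisitions.

## Problem sizes and numerical choices

Validation uses field sizes chosen for thorough coverage at desk scale:
100-nucleus recovery runs (four 360 px fields), 200-seed fold-change
recovery, 1000 random focus pairs against the brute-force oracle, 2000
ANOVA null simulations, 1000 log-rank null and 500 power simulations.
Determinism: all simulations take explicit integer seeds; degenerate
inputs (constant channels, empty masks, zero-area outlines, all-censored
groups, all-undetermined reactions) return defined values or flagged
records rather than errors, as documented per function.
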