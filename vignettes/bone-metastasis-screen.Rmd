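---
title: "Screening bone-metastasis predisposition and adaptation genes"
author: "osteoscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening bone-metastasis predisposition and adaptation genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteoscreen)
```

## The screen

Bone is the most frequent distant site of breast-cancer metastasis.
Two distinct questions drive this package. First, *predisposition*:
which genes, measured in the primary tumour, mark a tumour that will
later seed bone specifically — rather than distant sites in general?
Second, *adaptation*: once disseminated cells colonise the bone niche,
which expression changes support the colonisation programme (homing,
immune escape, neo-angiogenesis, osteoclastogenesis,
osteoblastogenesis)?

The predisposition screen is a filtering cascade over two independent
cohorts (a discovery and a validation cohort), each a log2 expression
matrix plus per-sample metastasis annotation (NONE / OTHER / BONE) and
bone-metastasis-free survival (BMFS):

1. **Per-gene differential expression.** For each contrast
   (bone-metastasis vs metastasis-free, other-site vs metastasis-free),
   each gene is tested with Student/Welch t when both arms pass a
   Shapiro–Wilk normality check, otherwise with the Mann–Whitney test;
   significance is raw two-sided p < 0.05.
2. **Cross-cohort validation.** Candidates are genes significant in
   *both* cohorts with the *same* direction of change (direction from
   the difference of arm means of log2 expression).
3. **Bone specificity.** Genes that are also differentially expressed
   in tumours with other-site metastasis are excluded, leaving genes
   specific to spread to bone.
4. **Survival filter.** Each candidate is dichotomised at its median
   expression and the arms compared by log-rank on BMFS; other-site
   metastases are censored for the bone endpoint.
5. **Axis scoring.** Surviving genes are correlated (Spearman) with
   curated marker panels of the five colonisation axes; per-axis scores
   are the *sum* of the marker correlation coefficients.

The adaptive screen tests lesions instead of primaries: a gene is an
adaptive DEG when it is significant with concordant direction in both
BONE_MET vs PRIMARY and BONE_MET vs OTHER_MET, and the resulting up-
and down-regulated strata are ranked per axis by summed correlation
(descending for upregulated genes, most-negative-first for
downregulated genes).

## Statistical choices

Several details of this kind of screen are conventionally left
unstated; the package fixes them explicitly.

* **Normality gate.** Shapiro–Wilk per group at `alpha_norm = 0.05`;
  the t-test is used only when *both* groups pass. Groups smaller than
  3 or with zero variance cannot be assessed and fall back to
  Mann–Whitney. The gate is a pragmatic stand-in for the typical SPSS
  workflow behind screens of this type.
* **t flavour.** Welch by default (robust to unequal arm variances);
  `test = "student"` gives the pooled-variance test.
* **Mann–Whitney p.** Tie-corrected normal approximation without
  continuity correction; for pooled sizes up to 10, exact enumeration
  over all group labelings.
* **Spearman p.** The t-approximation on n − 2 degrees of freedom;
  an exact permutation mode exists for n ≤ 8. Correlations with
  undefined rank variance (constant vectors) are errors, and such
  markers are recorded as missing rather than imputed.
* **Kaplan–Meier ties.** Events are ordered before censorings at the
  same time: a subject censored at t remains at risk for the event at
  t (the standard convention, matching `survival::survfit`).
* **Median split.** High arm is expression strictly above the per-gene
  median, so ties at the median go to the low arm and arm sizes are
  ⌊n/2⌋ vs ⌈n/2⌉. `split = "upper_quartile"` is available. The risk
  direction compares restricted mean survival between the arms.
* **Multiplicity.** Following the raw-p convention of such screens, no
  multiple-testing correction is applied by default at any stage; a
  Benjamini–Hochberg switch (`bh = TRUE`) exists on the DEG and
  survival stages but is deliberately off.
* **Two-cohort exclusion set.** With two cohorts there are two
  plausible other-site DEG exclusion sets. The pipeline uses the
  direction-concordant cross-cohort intersection of the other-site
  DEGs, symmetric with how candidates themselves are constructed; a
  single-cohort exclusion can be reproduced by calling
  `bone_specific()` directly with any DEG table.
* **Survival stage role.** The survival filter annotates the
  bone-specific candidate table (`survival_p`, `survival_passed`)
  rather than truncating it, and the axis scoring runs on the
  survival-passed subset. All stage counts are reported and are
  non-increasing along the cascade within each direction stratum.
* **Gene identity.** Uppercased symbol string matching; no alias
  resolution beyond the three curated marker synonyms
  (CXCR7/ACKR3, TNFSF11/RANKL, TNFRSF11B/OPG) that the built-in
  panels need. Cross-platform alias mapping is out of scope, and the
  input is assumed already normalised, log2-scale, and complete —
  imputation is the caller's job.

## Marker panels and axis scores

`default_panels()` ships the five curated panels (8 homing, 7 immune
escape, 8 angiogenesis, 10 osteoclastic, 9 osteoblastic markers). An
axis score is the plain sum of all available marker rhos — including
non-significant ones, since a significance filter would bias the sum
toward extremes; a `significant_only` mode exists but is off by
default. Markers absent from a cohort reduce the marker count instead
of contributing zeros, which would otherwise shrink sums
asymmetrically across cohorts.

Raw summed scores are comparable only within a panel (panels differ in
size), so the dominant-axis classification in `classify_top_axis()`
compares `|summed score| / markers used` across axes, with exact ties
broken by the fixed axis order `r paste(axis_labels(), collapse = ", ")`.
Correlations are computed over all samples of the supplied matrix;
restricting to a subset is a matter of subsetting the matrix first.

## The synthetic cohort model

`generate_cohort()` emulates the statistical structure the screen
assumes, not any particular platform. Log2 expression is Gaussian:

    x[g, s] = baseline + shift_g(class(s)) + loading_g * F_axis(s) + e,
    e ~ N(0, noise_sd^2),  F_axis ~ N(0, 1) per sample and axis.

* Planted BONE_SPECIFIC genes shift only BONE-class samples;
  PAN_METASTATIC genes shift BONE and OTHER; the shift magnitude and
  direction are configured per gene.
* One latent factor per axis is shared between AXIS_LINKED genes and
  the panel markers of that axis (markers load with `marker_loading`,
  1 by default). For loadings `a`, `b` and noise SD σ the population
  Pearson correlation is `ab / sqrt((a² + σ²)(b² + σ²))` and the
  Spearman value follows from the bivariate-normal identity
  `rho_s = (6/π) asin(rho_p / 2)` — a closed-form target the test
  suite checks empirically.
* BMFS is exponential with hazard
  `base_hazard * exp(Σ log_hr_g * z_g(s))` over SURVIVAL_LINKED genes
  (z is standardised expression), under independent uniform
  administrative censoring whose horizon is calibrated so the baseline
  censoring probability equals `censor_rate`. `log_hr_for_split_hr()`
  converts a target median-split hazard ratio into the per-SD
  coefficient. Only BONE-class samples carry the bone-metastasis
  event, so survival-focused simulations use all-BONE cohorts (a
  case-series design).

The default configuration — 100 metastasis-free, 30 other-site and 20
bone-metastasis samples, 1000 background genes, unit noise around a
log2 baseline of 8, baseline hazard 0.02/month, 40% censoring — is a
deliberately modest, discovery-like cohort. Everything is
deterministic given the config seed; `generate_pair()` derives the
validation seed from the discovery seed so a pair is reproducible from
one integer.

What the generator does *not* emulate: count noise and
mean–variance coupling, batch and platform effects, correlated
background genes, competing-risk structure, or symbol set differences
between cohorts. Passing recovery tests therefore demonstrates that
the cascade's logic and power behave as designed under its stated
assumptions — not that the screen is robust to real-data artefacts.

## Verification scale

The test suite verifies the primitives against brute-force oracles
(all-permutation midrank Pearson at n ≤ 6, full labeling enumeration
for Mann–Whitney at n ≤ 10, hand product-limit and log-rank toys) and
against independent reference implementations, and the end-to-end
properties at these problem sizes: null calibration with 2000 genes
(two arms of 40; survival at n = 200 with ~60% events);
planted-cascade recovery with 10 + 10 planted genes over 1000
background genes across 20 seeds; survival power at a median-split
hazard ratio of 3 over 50 replicates; axis-assignment recovery with
25 planted genes at loadings 1.5 and 300 samples over 20 seeds. These
sizes give binomial standard errors small enough for the asserted
bands while keeping the full suite around a minute.

## Limitations

The screen inherits the limitations of its design: raw p-values with
no error-rate control across thousands of genes, a dichotomised
survival analysis rather than a proportional-hazards model, marker
panels treated as fixed ground truth, and symbol-level matching
between cohorts. The package is a faithful, testable implementation
of that design, not an endorsement of it over, say, moderated
statistics with FDR control and Cox regression.
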