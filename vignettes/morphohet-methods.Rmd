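---
title: "Quantifying intratumoral morphological heterogeneity with morphohet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intratumoral morphological heterogeneity with morphohet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphohet)
```

## The problem

Colorectal adenocarcinoma (CRC) is morphologically heterogeneous: a single
tumor typically mixes several "pure" histological growth patterns, called
morphotypes. morphohet works with six of them — complex tubular (CT),
solid/trabecular (TB), mucinous (MU), papillary (PP), desmoplastic (DE) and
serrated (SE) — mapped to raster label values 1–6 in that fixed canonical
order (0 is background). The package quantifies how these morphotypes are
distributed within a tumor sampled by four standardised H&E sections
(serosa-side invasion front, mesocolon-side invasion front, luminal
transition, tumor centre), and relates the resulting quantities to clinical
covariates and survival.

The input to the pipeline is a *label map* per section: a single-channel
integer raster in which an upstream segmentation step (human or AI) has
assigned every tumor pixel one of the six classes. Producing label maps is
out of scope; everything downstream of them is implemented and tested here.

## From label map to section profile

`extract_regions()` decomposes the non-background pixels into connected
components per class (8-connectivity by default, the natural choice for
blob-like histological regions; 4-connectivity is available). Components are
computed on the pixel adjacency graph via igraph; the test suite checks the
counts against an independent brute-force flood fill.

Small predicted regions are the least trustworthy, so
`filter_small_regions()` keeps only regions occupying **at least 5%** of the
section's tumor area (inclusive boundary; `min_frac` is configurable). Two
choices here were genuinely open and are ours:

* the filter applies per connected fragment, not per morphotype aggregate —
  fragment-level accounting matches the idea that isolated small fragments
  are likely misclassifications;
* the denominator of the 5% rule is the total classified tumor area before
  filtering ("tumor area" itself is defined as the classified area, i.e.
  pixels with labels 1–6), and proportions are renormalised over the
  retained area afterwards, so every section profile sums to 1.

`section_profile()` then yields the six-way proportion vector
`p = (p_CT, ..., p_SE)`. A section where nothing survives the filter is
flagged `empty` and excluded from tumor-level summaries with a warning.

## Heterogeneity measures

**Shannon index and NSI.** For a proportion vector `p`,
`H = -sum(p_k * ln p_k)` (natural log; `0 ln 0 = 0`). The normalized
Shannon index is `NSI = H / ln 6`; `ln 6 = 1.79` (2 d.p.) is the maximum,
attained by the uniform profile (16.67% per morphotype), and 0 means the
section is purely one morphotype. The natural logarithm is fixed — the
printed maximum 1.79 only makes sense in nats — so no log-base option is
offered. Tumor-level NSI is the NSI of the arithmetic mean of the section
profiles (`tumor_summary()`), which standardises the effect of the number
of sections. Tumor NSI classes are low (`< 0.3`), medium (`0.3–0.7`) and
high (`> 0.7`); the boundaries are assigned to "medium" because the
published inequalities are strict on both ends and leave them unassigned.

**Dominance and DMC patterns.** Within a section, morphotypes with positive
proportion are ranked dominant / secondary / tertiary / … by decreasing
proportion (`dominance_ranking()`). Exact ties are broken by the canonical
order CT, TB, MU, PP, DE, SE and flagged — reproducibility is preferred over
an arbitrary unstated choice. The dominant morphotype combination (DMC) of
a tumor is the multiset of its four section dominants; its distribution
pattern is the multiplicity partition `4`, `3+1`, `2+2`, `2+1+1` or
`1+1+1+1` (`dmc_pattern()` represents all five even though four distinct
dominants were never observed in the motivating cohort). Tumors with fewer
than four valid sections keep their proportion and NSI summaries but are
excluded from DMC tabulations.

**Clustering.** `cluster_tumor_profiles()` applies agglomerative
hierarchical clustering (Ward linkage on Euclidean distances, both
configurable, `k = 9` by default) to the tumor mean profiles. Because it is
ambiguous whether published clusters were cut from per-tumor profiles or
from DMC-group medians, the default clusters per-tumor mean profiles and a
`mode = "group_median"` variant clusters the morphotype-wise median profile
of each DMC group instead.

## Agreement metrics

`modified_iou()` implements the asymmetric overlap `|P ∩ A| / |A|` between
a predicted region `P` and an annotated region `A` — the recall of the
annotation, which equals 1 whenever `A ⊆ P`. It is evaluated per morphotype
on the union of that morphotype's pixels; `training_agreement_gate()`
encodes the model-acceptance rule that every category must exceed 0.9
(strictly). Whether that gate is pooled across training images or evaluated
per image is unstated in the source material; we pool per category, and
per-image use is just a matter of calling the function per image.

`cohen_kappa()` computes chance-corrected agreement on presence/absence
calls (not ranks), per morphotype and rater pair (`kappa_matrix()` for all
pairs); when both raters are constant the expected agreement is 1 and kappa
is flagged undefined rather than silently set. Rank agreement is reported
separately as a plain `concordance_rate()` with numerator and denominator.

## Association testing

`associate_cohort()` tests each tumor-level outcome (six mean morphotype
proportions and tumor NSI) against each clinical covariate: Mann–Whitney U
for two groups, Kruskal–Wallis for more, with pairwise Mann–Whitney
follow-ups emitted only when the omnibus test is significant at 0.05.
Categorical outcomes (the DMC pattern class against stage and left/right
side) use Pearson's chi-square without continuity correction; cells with
expected counts below 5 raise a flag rather than switching silently to an
exact test. "Side" collapses right + transverse versus left + rectosigmoid
+ rectum; the published left/right split is not defined operationally, so
this is our documented choice.

All p-values of one pipeline run form a single Benjamini–Hochberg family
with significance at FDR < 10%. The family definition is itself a design
choice (the alternative — one family per covariate — is available by
calling the tests directly); degenerate tests with undefined p-values are
dropped from the family with a warning. `wall_location_test()` collapses
the four colonic-wall layers into superficial (mucosa, submucosa) versus
deep (muscularis, fat) before the chi-square.

## Survival stratification

Kaplan–Meier estimation and the log-rank test are delegated to the
`survival` package (`survfit`/`survdiff`) behind `km_estimate()` and
`logrank_test()`. The data-driven dichotomisation of a morphotype
proportion (`optimal_cutoff()`) is an explicit exhaustive search emulating
the first split of a regression survival tree: every midpoint between
consecutive distinct marker values is a candidate, both sides must retain
at least `min_leaf_frac = 0.1` of the cohort, and the split maximising the
two-group log-rank statistic wins. An explicit search is transparent,
dependency-free and deterministic, and its inner log-rank statistic is an
O−E implementation tested for equality against `survdiff`. Because the
cutoff is selected to maximise the statistic, the reported p-value is
selection-biased; it is flagged `exploratory = TRUE`, and the test suite
demonstrates the bias on pure-noise markers (naive rejection far above 5%).
No permutation correction is applied by default.

`stratified_survival_report()` runs this for DE, PP and CT against OS and
RFS, in the full cohort and the stage I–III subset (stage IV rows removed
before analysis).

## The synthetic cohort generator

The study's slide-level data are not public, so `sim_config()` /
`emit_study()` generate a fully synthetic study with the statistical
structure the analysis assumes; it is first-class, tested code, not a
fixture. What it emulates, and the defaults (chosen once, as study
conditions, and documented here):

* **Cohort shape.** 161 tumors × 4 sections = 644 label maps, the shape of
  the motivating cohort.
* **Proportions.** Tumor mean profiles are Dirichlet with concentrations
  (2.4, 0.45, 0.60, 0.80, 0.65, 0.50), giving a CT-dominated cohort
  (mean CT share ≈ 45%, echoing CT's reported prevalence) with realistic
  spread; section profiles are Dirichlet(40 × tumor mean), so sections
  resemble their tumor without being copies.
* **Space.** Each section raster (200 × 200 px by default) holds an
  elliptical tumor mask partitioned by quota-constrained multi-source
  region growth from 24 seed patches: contiguous patches, realized
  proportions within a few pixels of the target (tolerance 0.03 is
  enforced, the observed error is orders of magnitude smaller). Real
  spatial statistics of CRC sections (fragment size distributions,
  layer preferences) are *not* emulated — passing tests show the pipeline's
  arithmetic is right, not that the generator looks like tissue.
* **Clinical structure.** Planted effects mirror the reported directions:
  MU and TB raise MSI odds (logit slopes 8 and 5), DE shifts AJCC stage
  upward (cumulative-logit slope 6), MU raises right-sided odds, MU/TB
  raise grade; stage cutpoints reproduce the reported stage mix
  (15/42/27/17%), MSI intercept gives ≈ 20% MSI. Survival is exponential
  with log-hazard `log(0.02) + 3·p_DE − 3·p_PP` per month and 30%
  independent censoring (uniform over the subject's event time). The
  magnitudes were picked so the planted associations are as unambiguous at
  n = 161 as the published ones (p < 0.0001 scale); they are not estimates
  of real effect sizes.
* **Determinism.** All randomness flows from one master seed;
  `emit_study()` derives per-stream seeds so tables are byte-identical
  across reruns.

The generator's truth (all planted coefficients) is written to
`sim_truth.csv` for recovery tests.

## Numerical choices and degenerate inputs

* Proportion vectors must sum to 1 within 1e-6; profile sums in outputs are
  exact to 1e-9.
* The 5% area filter is inclusive (`area ≥ min_frac × tumor area`), with a
  1e-9 float guard.
* Empty sections, all-background rasters, cohorts without clinical data,
  constant markers, and both-raters-constant kappa are all handled
  explicitly (flags, warnings or structured errors — never silent
  defaults).
* Cluster count is capped at the number of tumors in `run_all()`.

## Problem sizes used in the checks

The test suite exercises oracle equivalence on 50 × 50 rasters, all 1,296
ordered dominant quadruples, 100 random survival datasets, 60 null and 60
effect-bearing cohorts of 161 tumors, and 40 render/quantify round trips at
120 × 120 px; the acceptance script scales the cohort replications to 200
and the round trip to 100 profiles. These sizes give Monte-Carlo error
small enough for the stated bands while keeping a full run in minutes on
one CPU.

## Known limitations

* Cohort-level published numbers (e.g. 90.2% CT section prevalence, the 39
  observed DMC groups, specific survival p-values) depend on the original,
  non-deposited slides and are not reproduced by the synthetic cohort.
* The generator does not model section-to-section spatial correlation,
  unclassified stroma, or layer-dependent patch placement beyond
  contiguity.
* Exploratory cutoff p-values are reported uncorrected (flagged); users
  needing honest inference should validate cutoffs on independent data.
* No multivariable (Cox) adjustment and no Fleiss-style multi-rater kappa
  are provided; the analyses mirror univariate, pairwise designs.
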