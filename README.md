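# morphohet

Quantification of intratumoral morphological heterogeneity of colorectal
adenocarcinoma (CRC) from per-section morphotype label maps.

## The problem

A CRC rarely shows a single growth pattern. Given four H&E sections per
tumor (serosa-side front, mesocolon-side front, luminal transition,
centre), each segmented into six morphotypes — complex tubular (CT),
solid/trabecular (TB), mucinous (MU), papillary (PP), desmoplastic (DE),
serrated (SE), coded 1–6 in a raster with 0 = background — morphohet
answers: how much of each morphotype does a tumor contain, how heterogeneous
is it, which morphotype combinations occur, and do the proportions relate
to clinical variables and survival?

The core quantities, for a section proportion vector
`p = (p_CT, …, p_SE)`:

* **Shannon index** `H = −Σ p_k ln p_k` and **normalized Shannon index**
  `NSI = H / ln 6`, where `ln 6 ≈ 1.79` is the maximum (six uniform
  morphotypes, 16.67% each); NSI = 0 means a pure section, NSI = 1 maximal
  heterogeneity. Tumor NSI is the NSI of the mean of the section profiles;
  classes are low (< 0.3), medium (0.3–0.7), high (> 0.7).
* **Dominance**: morphotypes ranked by proportion per section; the
  **dominant morphotype combination (DMC)** of a tumor is the multiset of
  its four section dominants, with distribution pattern `4`, `3+1`, `2+2`,
  `2+1+1` or `1+1+1+1`.
* **Region filter**: predicted regions smaller than 5% of the section's
  tumor area are discarded before proportions are computed.
* **Agreement**: per-morphotype Cohen's kappa between raters and the
  asymmetric overlap `|P∩A|/|A|` (annotation recall) with the strict > 0.9
  training gate.
* **Associations**: Kruskal–Wallis / Mann–Whitney and Pearson chi-square
  against clinical covariates, one Benjamini–Hochberg family, significance
  at FDR < 10%.
* **Survival**: Kaplan–Meier + log-rank, with exhaustive single-split
  optimal-cutoff dichotomisation of morphotype proportions (flagged
  exploratory), for OS and RFS in the full cohort and stage I–III.

Because the motivating study's slides are not public, the package ships a
tested synthetic-cohort generator (Dirichlet profiles, contiguous
seeded-growth label maps, planted clinical and survival effects) so the
entire pipeline runs end to end from nothing.

## Worked example

```r
library(morphohet)

cfg <- sim_config(n_tumors = 8, raster_dim = c(120, 120))
study <- tempfile()
emit_study(cfg, study, seed = 2024)          # 32 label maps + tables
res <- run_all(study, out_dir = file.path(study, "results"), seed = 2024)

head(res$tumor_summary[, c("tumor_id", "p_CT", "p_DE", "tumor_nsi",
                           "nsi_class", "dmc", "pattern_class")], 4)
#>   tumor_id  p_CT   p_DE tumor_nsi nsi_class       dmc pattern_class
#> 1     T001 0.419 0.3078    0.6037    medium 3xCT+1xDE           3+1
#> 2     T002 0.982 0.0000    0.0501       low      4xCT             4
#> 3     T003 0.963 0.0000    0.0878       low      4xCT             4
#> 4     T004 0.877 0.0793    0.2527       low      4xCT             4
```

Tumor T001 is morphologically mixed: CT dominates three sections and DE
one (`3xCT+1xDE`), and its tumor NSI of 0.60 puts it in the medium
heterogeneity class; T002–T004 are near-pure CT tumors with low NSI. The
survival stage reports, per morphotype and endpoint, the data-driven
cutoff and the (exploratory, selection-biased) log-rank test:

```r
res$survival[res$survival$endpoint == "OS" & res$survival$subset == "all", ]
#>   morphotype endpoint subset cutoff n_low n_high logrank_statistic logrank_p exploratory
#> 1         DE       OS    all 0.2384     6      2              3.17    0.0748        TRUE
#> 2         PP       OS    all 0.0184     7      1              1.09    0.2966        TRUE
#> 3         CT       OS    all 0.9202     6      2              3.80    0.0512        TRUE
```

(At n = 8 nothing is significant, as it should be; at the default
n = 161 the planted DE hazard effect is detected essentially always.)
`figure_tables(res)` adds the dominance-frequency, DMC-group, NSI-per-DMC
and dominant co-occurrence tables; `write_results_bundle()` persists
everything as CSV plus a run-metadata JSON.

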