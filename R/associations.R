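#' Pearson chi-square test for a contingency table
#'
#' Plain Pearson chi-square (no continuity correction). Cells with expected
#' count below 5 are flagged in the result rather than switching to an exact
#' test.
#'
#' @param tab Contingency table (matrix of non-negative counts, at least
#'   2 x 2 after dropping nothing).
#' @return List: `test = "chi_square"`, `statistic`, `df`, `p_value`, `n`,
#'   `low_expected` flag.
#' @export
test_categorical <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2) stop("contingency table must be at least 2x2")
  if (any(tab < 0)) stop("counts must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("contingency table has a zero marginal (empty row or column)")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(test = "chi_square", statistic = unname(ct$statistic),
       df = unname(ct$parameter), p_value = ct$p.value, n = sum(tab),
       low_expected = any(ct$expected < 5))
}

#' Compare a morphotype proportion (or NSI) between clinical groups
#'
#' Two groups: Mann-Whitney U test. More than two: Kruskal-Wallis omnibus,
#' followed by pairwise Mann-Whitney tests only when the omnibus test is
#' significant at `pairwise_alpha`.
#'
#' @param values Numeric outcome (e.g. tumor-level proportion of one
#'   morphotype).
#' @param groups Factor (or coercible) of group labels; unused levels are
#'   dropped.
#' @param pairwise_alpha Omnibus significance gate for pairwise follow-up
#'   (default 0.05).
#' @return List: `test` (`"mann_whitney"` or `"kruskal_wallis"`),
#'   `statistic`, `p_value`, `n_per_group`, and `pairwise` (`data.frame` or
#'   `NULL`; only present when the omnibus was significant).
#' @export
test_proportion_vs_groups <- function(values, groups, pairwise_alpha = 0.05) {
  groups <- droplevels(as.factor(groups))
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- droplevels(groups[ok])
  n_per <- table(groups)
  if (length(n_per) < 2) stop("need at least two groups")
  if (any(n_per < 2)) {
    stop("every group needs at least 2 observations (smallest has ", min(n_per), ")")
  }
  if (length(n_per) == 2) {
    wt <- suppressWarnings(stats::wilcox.test(values ~ groups, exact = FALSE))
    return(list(test = "mann_whitney", statistic = unname(wt$statistic),
                p_value = wt$p.value, n_per_group = n_per, pairwise = NULL))
  }
  kw <- stats::kruskal.test(values, groups)
  pairwise <- NULL
  if (kw$p.value < pairwise_alpha) {
    lv <- levels(groups)
    rows <- list()
    for (i in seq_len(length(lv) - 1)) for (j in (i + 1):length(lv)) {
      sel <- groups %in% lv[c(i, j)]
      wt <- suppressWarnings(stats::wilcox.test(values[sel] ~ droplevels(groups[sel]),
                                                exact = FALSE))
      rows[[length(rows) + 1]] <- data.frame(
        group_a = lv[i], group_b = lv[j],
        statistic = unname(wt$statistic), p_value = wt$p.value)
    }
    pairwise <- do.call(rbind, rows)
  }
  list(test = "kruskal_wallis", statistic = unname(kw$statistic),
       p_value = kw$p.value, n_per_group = n_per, pairwise = pairwise)
}

#' Benjamini-Hochberg FDR adjustment with significance calls
#'
#' Step-up adjusted p-values; a result is called significant when its
#' adjusted value falls below the FDR level (10% in this pipeline).
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @param fdr_level Significance level on the adjusted scale, default 0.10.
#' @return List with `p_adjusted` and logical `significant`.
#' @export
adjust_fdr <- function(p_values, fdr_level = 0.10) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must be finite and in [0, 1]")
  }
  adj <- stats::p.adjust(p_values, method = "BH")
  list(p_adjusted = adj, significant = adj < fdr_level)
}

#' Morphotype location across the colonic wall: superficial vs deep
#'
#' Collapses the four wall layers to two depth classes — mucosa and
#' submucosa (superficial) versus muscularis propria and fat tissue (deep) —
#' and tests morphotype x depth independence with Pearson's chi-square.
#'
#' @param location_calls `data.frame` with columns `morphotype` and `layer`
#'   (levels `mucosa, submucosa, muscularis, fat`), one row per call.
#' @return As [test_categorical()], plus the collapsed `table`.
#' @export
wall_location_test <- function(location_calls) {
  layers <- c(mucosa = "superficial", submucosa = "superficial",
              muscularis = "deep", fat = "deep")
  lay <- as.character(location_calls$layer)
  bad <- setdiff(unique(lay), names(layers))
  if (length(bad) > 0) {
    stop("unknown wall layer label(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(names(layers), collapse = ", "))
  }
  depth <- factor(layers[lay], levels = c("superficial", "deep"))
  morph <- factor(canonical_morphotype(location_calls$morphotype),
                  levels = MORPHOTYPE_CODES)
  tab <- table(droplevels(morph), depth)
  res <- test_categorical(tab)
  res$table <- tab
  res
}

#' Run the cohort association battery
#'
#' Tests each tumor-level outcome (the six mean morphotype proportions and
#' the tumor NSI) against each clinical covariate with Kruskal-Wallis /
#' Mann-Whitney, plus two chi-square tests of the DMC distribution pattern
#' (against AJCC stage and against left/right side). All p-values form one
#' BH family, with significance at FDR < `fdr_level`.
#'
#' @param summaries Tumor summary table ([summarize_tumors()]).
#' @param clinical Validated clinical table ([read_clinical_table()]).
#' @param covariates Clinical covariates to test (default: gender, T, N, M,
#'   AJCC stage, grade, site, MSI).
#' @param fdr_level BH significance level, default 0.10.
#' @return `data.frame`: `outcome, covariate, test, statistic, p_value,
#'   p_adjusted, significant, n`.
#' @export
associate_cohort <- function(summaries, clinical,
                             covariates = c("gender", "t_stage", "n_stage", "m_stage",
                                            "ajcc_stage", "grade", "site", "msi"),
                             fdr_level = 0.10) {
  df <- merge(summaries, clinical, by = "tumor_id")
  if (nrow(df) == 0) stop("tumor summaries and clinical table share no tumor_id")
  outcomes <- c(profile_cols(), "tumor_nsi")
  rows <- list()
  for (oc in outcomes) for (cv in covariates) {
    res <- tryCatch(test_proportion_vs_groups(df[[oc]], df[[cv]]),
                    error = function(e) NULL)
    if (is.null(res)) next
    rows[[length(rows) + 1]] <- data.frame(
      outcome = oc, covariate = cv, test = res$test,
      statistic = res$statistic, p_value = res$p_value,
      n = sum(res$n_per_group))
  }
  # DMC distribution pattern vs stage and vs side (chi-square), among
  # tumors with a complete 4-section pattern
  pat <- df[!is.na(df$pattern_class), , drop = FALSE]
  if (nrow(pat) > 0) {
    side <- factor(ifelse(pat$site %in% c("right", "transverse"), "right", "left"),
                   levels = c("left", "right"))
    for (spec in list(list(cv = "ajcc_stage", g = droplevels(pat$ajcc_stage)),
                      list(cv = "side", g = droplevels(side)))) {
      tab <- table(factor(pat$pattern_class), spec$g)
      tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
      res <- tryCatch(test_categorical(tab), error = function(e) NULL)
      if (is.null(res)) next
      rows[[length(rows) + 1]] <- data.frame(
        outcome = "pattern_class", covariate = spec$cv, test = res$test,
        statistic = res$statistic, p_value = res$p_value, n = res$n)
    }
  }
  if (length(rows) == 0) {
    warning("no association test was feasible (cohort too small or degenerate)")
    return(data.frame(outcome = character(0), covariate = character(0),
                      test = character(0), statistic = numeric(0),
                      p_value = numeric(0), n = integer(0),
                      p_adjusted = numeric(0), significant = logical(0)))
  }
  out <- do.call(rbind, rows)
  # degenerate tests (e.g. a constant outcome in a tiny cohort) yield NA
  # p-values; they carry no evidence and are excluded from the BH family
  if (anyNA(out$p_value)) {
    warning(sum(is.na(out$p_value)),
            " degenerate test(s) with undefined p-values dropped")
    out <- out[!is.na(out$p_value), , drop = FALSE]
  }
  fdr <- adjust_fdr(out$p_value, fdr_level = fdr_level)
  out$p_adjusted <- fdr$p_adjusted
  out$significant <- fdr$significant
  out[order(out$p_adjusted, out$outcome, out$covariate), ]
}
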