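#' Shannon diversity of a morphotype proportion profile
#'
#' The Shannon index `H = -sum(p_k * ln p_k)` (natural logarithm; zero
#' entries contribute nothing). For six morphotypes the maximum is
#' `ln 6 = 1.79` (2 d.p.), attained by the uniform profile.
#'
#' @param proportions Non-negative numeric vector summing to 1 (within 1e-6).
#' @return Shannon entropy in nats.
#' @export
shannon_index <- function(proportions) {
  p <- check_proportions(proportions)
  p <- p[p > 0]
  h <- -sum(p * log(p))
  if (h == 0) h <- 0 # normalise the sign of floating-point negative zero
  h
}

#' Normalized Shannon index (NSI)
#'
#' Shannon entropy of the six-way morphotype profile divided by its maximum
#' `ln 6`, giving an index between 0 (section composed of a single
#' morphotype) and 1 (all six morphotypes in equal 16.67% proportions).
#'
#' @inheritParams shannon_index
#' @return NSI in \[0, 1\].
#' @export
nsi <- function(proportions) {
  shannon_index(proportions) / NSI_HMAX
}

# maximum Shannon entropy over six classes, the NSI normalisation constant
NSI_HMAX <- log(6)

check_proportions <- function(p) {
  p <- as.numeric(p)
  if (any(is.na(p)) || any(p < 0)) stop("proportions must be non-negative and non-missing")
  if (abs(sum(p) - 1) > 1e-6) {
    stop("proportions must sum to 1 (got ", format(sum(p)), ")")
  }
  p
}

#' Classify tumor heterogeneity from the NSI
#'
#' Three classes: low (`NSI < 0.3`), medium (`0.3 <= NSI <= 0.7`) and high
#' (`NSI > 0.7`). The boundaries 0.3 and 0.7 are assigned to "medium".
#'
#' @param tumor_nsi NSI value(s) in \[0, 1\].
#' @return Factor with levels `low`, `medium`, `high`.
#' @export
nsi_class <- function(tumor_nsi) {
  if (any(is.na(tumor_nsi)) || any(tumor_nsi < 0 | tumor_nsi > 1)) {
    stop("tumor_nsi must lie in [0, 1]")
  }
  cls <- ifelse(tumor_nsi < 0.3, "low", ifelse(tumor_nsi > 0.7, "high", "medium"))
  factor(cls, levels = c("low", "medium", "high"))
}

#' Dominance ranking of a section profile
#'
#' Orders the morphotypes present in a section (proportion > 0) by
#' decreasing proportion; the first is the dominant, then secondary,
#' tertiary, and so on. Exact ties are broken by the canonical morphotype
#' order (CT, TB, MU, PP, DE, SE) and flagged.
#'
#' @param profile Length-6 proportion vector in canonical order, or a
#'   one-row section profile as returned by [section_profile()].
#' @return List with `ordered_morphotypes` (character), `proportions`
#'   (matching order) and `tie_flag`.
#' @export
dominance_ranking <- function(profile) {
  p <- as_profile_vector(profile)
  if (sum(p) <= 0) stop("empty profile: no morphotype has positive proportion")
  present <- which(p > 0)
  ord <- present[order(-p[present], present)]
  sorted <- p[ord]
  tie <- any(duplicated(sorted))
  list(ordered_morphotypes = MORPHOTYPE_CODES[ord],
       proportions = unname(sorted), tie_flag = tie)
}

# Coerce a length-6 vector or a profile table row to a canonical p-vector.
as_profile_vector <- function(profile) {
  if (is.data.frame(profile)) {
    stopifnot(nrow(profile) == 1, all(profile_cols() %in% names(profile)))
    p <- as.numeric(profile[1, profile_cols()])
  } else {
    p <- as.numeric(profile)
    if (length(p) != 6) stop("profile must have 6 entries (canonical order CT,TB,MU,PP,DE,SE)")
  }
  if (any(p < 0)) stop("proportions must be non-negative")
  p
}

#' Dominant-morphotype combination (DMC) and its distribution pattern
#'
#' The DMC of a tumor is the multiset of the four section-level dominant
#' morphotypes; its distribution pattern is the multiplicity partition:
#' `"4"` (one morphotype dominant in all sections), `"3+1"`, `"2+2"`,
#' `"2+1+1"` or `"1+1+1+1"` (four distinct dominants — representable,
#' although never observed in the study cohort).
#'
#' @param dominants Character vector of exactly 4 morphotype codes.
#' @return List with `multiset` (named counts, canonical order),
#'   `pattern_class`, `n_distinct` and a human-readable `label` such as
#'   `"3xCT+1xPP"` (multiplicity-major, canonical-order ties).
#' @export
dmc_pattern <- function(dominants) {
  if (length(dominants) != 4) {
    stop("a DMC is formed from exactly 4 section-level dominant morphotypes (got ",
         length(dominants), ")")
  }
  dominants <- canonical_morphotype(dominants)
  counts <- table(factor(dominants, levels = MORPHOTYPE_CODES))
  nz <- counts[counts > 0]
  mult <- sort(as.integer(nz), decreasing = TRUE)
  pattern <- paste(mult, collapse = "+")
  ord <- order(-as.integer(nz), match(names(nz), MORPHOTYPE_CODES))
  label <- paste(sprintf("%dx%s", as.integer(nz)[ord], names(nz)[ord]),
                 collapse = "+")
  list(multiset = nz, pattern_class = pattern,
       n_distinct = length(nz), label = label)
}

#' Summarise a tumor from its section profiles
#'
#' The tumor profile is the arithmetic mean of the section proportion
#' vectors (over non-empty sections), and the tumor NSI is the NSI of that
#' mean profile. DMC fields are filled only when the tumor has exactly 4
#' valid sections; tumors with fewer are kept in proportion/NSI analyses but
#' flagged and excluded from DMC pattern tabulations.
#'
#' @param profiles `data.frame` of section profiles (rows of
#'   [section_profile()]) belonging to one tumor.
#' @return One-row `data.frame`: `tumor_id, p_CT..p_SE` (mean profile),
#'   `tumor_nsi, nsi_class, n_valid_sections, dmc, pattern_class`, plus the
#'   per-section NSIs as attribute `section_nsis`.
#' @export
tumor_summary <- function(profiles) {
  stopifnot(is.data.frame(profiles), nrow(profiles) >= 1)
  if (length(unique(profiles$tumor_id)) != 1) {
    stop("tumor_summary expects the sections of a single tumor")
  }
  valid <- profiles[!profiles$empty, , drop = FALSE]
  if (nrow(valid) == 0) stop("tumor ", profiles$tumor_id[1],
                             " has no section with a non-empty profile")
  pmat <- as.matrix(valid[, profile_cols()])
  mean_p <- colMeans(pmat)
  section_nsis <- apply(pmat, 1, nsi)
  names(section_nsis) <- valid$section_id
  t_nsi <- nsi(mean_p)
  dmc <- NA_character_; pattern <- NA_character_
  if (nrow(valid) == 4) {
    dominants <- vapply(seq_len(4), function(i) {
      dominance_ranking(as.numeric(pmat[i, ]))$ordered_morphotypes[1]
    }, character(1))
    d <- dmc_pattern(dominants)
    dmc <- d$label; pattern <- d$pattern_class
  }
  out <- data.frame(
    tumor_id = valid$tumor_id[1],
    as.list(stats::setNames(unname(mean_p), profile_cols())),
    tumor_nsi = t_nsi, nsi_class = as.character(nsi_class(t_nsi)),
    n_valid_sections = nrow(valid), dmc = dmc, pattern_class = pattern
  )
  attr(out, "section_nsis") <- section_nsis
  out
}

#' Summarise every tumor in a section-profile table
#'
#' @param section_profiles Stacked section-profile rows for a cohort.
#' @param warn_empty Warn about sections dropped for empty profiles.
#' @return `data.frame` with one [tumor_summary()] row per tumor, ordered by
#'   `tumor_id`.
#' @export
summarize_tumors <- function(section_profiles, warn_empty = TRUE) {
  n_empty <- sum(section_profiles$empty)
  if (warn_empty && n_empty > 0) {
    warning(n_empty, " section(s) with empty profiles excluded from tumor summaries")
  }
  ids <- sort(unique(section_profiles$tumor_id))
  rows <- lapply(ids, function(id) {
    tumor_summary(section_profiles[section_profiles$tumor_id == id, , drop = FALSE])
  })
  do.call(rbind, rows)
}

#' Hierarchical clustering of tumor mean profiles
#'
#' Agglomerative clustering of the tumor mean proportion vectors
#' (Ward linkage on Euclidean distance by default), cut into `k` clusters.
#' Deterministic given its inputs. With `mode = "group_median"` the
#' morphotype-wise median profile of each DMC group is clustered instead and
#' every tumor inherits its group's cluster.
#'
#' @param summaries Tumor summary table from [summarize_tumors()].
#' @param k Number of clusters (default 9).
#' @param method Linkage passed to [stats::hclust()] (default `"ward.D2"`).
#' @param metric Distance metric passed to [stats::dist()].
#' @param mode `"per_tumor"` (default) or `"group_median"`.
#' @return Integer cluster assignment named by `tumor_id`.
#' @export
cluster_tumor_profiles <- function(summaries, k = 9, method = "ward.D2",
                                   metric = "euclidean", mode = c("per_tumor", "group_median")) {
  mode <- match.arg(mode)
  pmat <- as.matrix(summaries[, profile_cols()])
  rownames(pmat) <- summaries$tumor_id
  if (mode == "group_median") {
    grp <- summaries$dmc
    grp[is.na(grp)] <- "(incomplete)"
    med <- t(vapply(split(seq_len(nrow(pmat)), grp),
                    function(i) apply(pmat[i, , drop = FALSE], 2, stats::median),
                    numeric(6)))
    if (k > nrow(med)) stop("k (", k, ") exceeds the number of DMC groups (", nrow(med), ")")
    hc <- stats::hclust(stats::dist(med, method = metric), method = method)
    gcl <- stats::cutree(hc, k = k)
    return(stats::setNames(unname(gcl[grp]), summaries$tumor_id))
  }
  if (k > nrow(pmat)) stop("k (", k, ") exceeds the number of tumors (", nrow(pmat), ")")
  hc <- stats::hclust(stats::dist(pmat, method = metric), method = method)
  stats::cutree(hc, k = k)
}
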