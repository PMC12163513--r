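#' Kaplan-Meier estimate of the survivor function
#'
#' Product-limit estimator with the at-risk table at each event time, via
#' [survival::survfit()].
#'
#' @param times Follow-up times (months), non-negative.
#' @param events Event indicators, 0 = censored, 1 = event.
#' @return `data.frame` step function: `time, n_risk, n_event, n_censor,
#'   surv` (one row per distinct observed time).
#' @export
km_estimate <- function(times, events) {
  check_survival_input(times, events)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, surv = fit$surv)
}

check_survival_input <- function(times, events) {
  if (length(times) == 0) stop("no survival data supplied")
  if (length(times) != length(events)) stop("times and events differ in length")
  if (any(is.na(times)) || any(times < 0)) stop("times must be non-negative and non-missing")
  if (any(!events %in% c(0, 1))) stop("events must be 0/1")
  invisible(TRUE)
}

#' Log-rank test for survival differences between groups
#'
#' Standard log-rank chi-square with `k - 1` degrees of freedom, via
#' [survival::survdiff()].
#'
#' @inheritParams km_estimate
#' @param groups Group labels (at least 2 non-empty groups).
#' @return List: `statistic`, `df`, `p_value`, `n_per_group`.
#' @export
logrank_test <- function(times, events, groups) {
  check_survival_input(times, events)
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2) stop("need at least two non-empty groups")
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
  df <- nlevels(groups) - 1
  list(statistic = unname(sd$chisq), df = df,
       p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
       n_per_group = table(groups))
}

# Two-group log-rank chi-square, vectorised over event times. Used by the
# exhaustive cutoff search, where survdiff's formula interface would be the
# bottleneck; its agreement with survdiff is covered by the test suite.
logrank_chisq2 <- function(times, events, in_high) {
  ord <- order(times)
  t_s <- times[ord]; e_s <- events[ord]; g_s <- in_high[ord]
  n <- length(t_s)
  ut <- unique(t_s[e_s == 1])
  if (length(ut) == 0) return(0)
  # at-risk counts just before each event time
  n_risk <- n - findInterval(ut, t_s, left.open = TRUE)
  cg <- cumsum(g_s)
  n1_risk <- sum(g_s) - c(0, cg)[findInterval(ut, t_s, left.open = TRUE) + 1]
  d <- as.numeric(rowsum(e_s, t_s)[match(ut, sort(unique(t_s))), 1])
  d1 <- as.numeric(rowsum(e_s * g_s, t_s)[match(ut, sort(unique(t_s))), 1])
  O <- sum(d1)
  E <- sum(d * n1_risk / n_risk)
  keep <- n_risk > 1
  V <- sum((d * (n1_risk / n_risk) * (1 - n1_risk / n_risk) *
              (n_risk - d) / (n_risk - 1))[keep])
  if (V <= 0) return(0)
  (O - E)^2 / V
}

#' Optimal dichotomisation cutoff for a continuous marker
#'
#' Exhaustive single-split search emulating the first split of a regression
#' survival tree: every midpoint between consecutive distinct values of the
#' marker (a morphotype proportion) is a candidate cutoff, subject to both
#' resulting groups holding at least `min_leaf_frac` of the cohort, and the
#' split maximising the two-group log-rank statistic is selected. The
#' returned p-value is naive (not corrected for the search) and therefore
#' flagged exploratory.
#'
#' @param proportions Marker values (e.g. tumor-level proportion of DE).
#' @param times,events Survival outcome.
#' @param min_leaf_frac Minimum fraction of subjects per side, default 0.1.
#' @return List: `cutoff`, `statistic`, `p_value`, `exploratory = TRUE`,
#'   `n_low`, `n_high`, `candidates` (data.frame of all admissible splits).
#' @export
optimal_cutoff <- function(proportions, times, events, min_leaf_frac = 0.1) {
  check_survival_input(times, events)
  if (length(proportions) != length(times)) stop("marker and outcome lengths differ")
  v <- sort(unique(proportions))
  if (length(v) < 2) stop("all marker values are identical; no split exists")
  mids <- (v[-1] + v[-length(v)]) / 2
  n <- length(proportions)
  min_leaf <- ceiling(min_leaf_frac * n)
  stats_v <- rep(NA_real_, length(mids))
  for (i in seq_along(mids)) {
    hi <- proportions > mids[i]
    if (sum(hi) < min_leaf || sum(!hi) < min_leaf) next
    stats_v[i] <- logrank_chisq2(times, events, hi)
  }
  if (all(is.na(stats_v))) {
    stop("no admissible split: min_leaf_frac = ", min_leaf_frac,
         " leaves no cutoff with both groups large enough")
  }
  best <- which.max(stats_v)
  hi <- proportions > mids[best]
  list(cutoff = mids[best], statistic = stats_v[best],
       p_value = stats::pchisq(stats_v[best], 1, lower.tail = FALSE),
       exploratory = TRUE, n_low = sum(!hi), n_high = sum(hi),
       candidates = data.frame(cutoff = mids, statistic = stats_v)[!is.na(stats_v), ])
}

#' Survival stratification report over morphotypes, endpoints and subsets
#'
#' For each requested morphotype, endpoint (OS / RFS) and cohort subset
#' (full cohort / stage I-III), dichotomises the tumors at the optimal
#' log-rank cutoff of that morphotype's mean proportion and reports the
#' stratified Kaplan-Meier curves and the (exploratory) log-rank test.
#'
#' @param cohort Tumor summaries joined with clinical data (must contain
#'   `p_<morphotype>`, `ajcc_stage`, `os_time/os_event`,
#'   `rfs_time/rfs_event`).
#' @param morphotypes_used Morphotypes to stratify by (default DE, PP, CT).
#' @param endpoints Any of `"OS"`, `"RFS"`.
#' @param subsets Any of `"all"`, `"stage_I_III"`.
#' @param min_leaf_frac Passed to [optimal_cutoff()].
#' @return List with `table` (`data.frame`: morphotype, endpoint, subset,
#'   cutoff, n_low, n_high, logrank_statistic, logrank_p, exploratory) and
#'   `curves` (named list of per-arm [km_estimate()] step functions).
#' @export
stratified_survival_report <- function(cohort,
                                       morphotypes_used = c("DE", "PP", "CT"),
                                       endpoints = c("OS", "RFS"),
                                       subsets = c("all", "stage_I_III"),
                                       min_leaf_frac = 0.1) {
  morphotypes_used <- canonical_morphotype(morphotypes_used)
  endpoints <- match.arg(endpoints, c("OS", "RFS"), several.ok = TRUE)
  subsets <- match.arg(subsets, c("all", "stage_I_III"), several.ok = TRUE)
  need <- c("ajcc_stage", "os_time", "os_event", "rfs_time", "rfs_event")
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols) > 0) {
    stop("cohort is missing endpoint column(s): ", paste(missing_cols, collapse = ", "))
  }
  rows <- list(); curves <- list()
  for (sub in subsets) {
    d <- if (sub == "stage_I_III") cohort[cohort$ajcc_stage != "IV", , drop = FALSE] else cohort
    for (ep in endpoints) {
      tm <- if (ep == "OS") d$os_time else d$rfs_time
      ev <- if (ep == "OS") d$os_event else d$rfs_event
      for (m in morphotypes_used) {
        x <- d[[paste0("p_", m)]]
        oc <- tryCatch(optimal_cutoff(x, tm, ev, min_leaf_frac = min_leaf_frac),
                       error = function(e) NULL)
        if (is.null(oc)) next
        hi <- x > oc$cutoff
        key <- paste(m, ep, sub, sep = ".")
        curves[[paste0(key, ".low")]] <- km_estimate(tm[!hi], ev[!hi])
        curves[[paste0(key, ".high")]] <- km_estimate(tm[hi], ev[hi])
        rows[[length(rows) + 1]] <- data.frame(
          morphotype = m, endpoint = ep, subset = sub, cutoff = oc$cutoff,
          n_low = oc$n_low, n_high = oc$n_high,
          logrank_statistic = oc$statistic, logrank_p = oc$p_value,
          exploratory = TRUE)
      }
    }
  }
  list(table = do.call(rbind, rows), curves = curves)
}
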