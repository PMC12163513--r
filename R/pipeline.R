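#' Run the full heterogeneity pipeline on a study bundle
#'
#' Reads a study directory (`sections.csv` + label-map rasters, and
#' optionally `clinical.csv`), then executes the stages in order: section
#' quantification (region extraction, minimum-area filter, proportion
#' profiles), tumor summaries (mean profiles, NSI, DMC patterns,
#' hierarchical clustering), clinical association battery with BH FDR, and
#' survival stratification. If `clinical.csv` is absent the association and
#' survival stages are skipped with a warning and the morphology stages
#' still run. Results are written as the standard bundle
#' ([write_results_bundle()]) when `out_dir` is given.
#'
#' @param study_dir Directory containing `sections.csv` (and usually
#'   `clinical.csv`).
#' @param out_dir Optional output directory for the results bundle.
#' @param config List of pipeline settings: `min_frac` (region filter,
#'   default 0.05), `connectivity` (default 8), `fdr_level` (default 0.10),
#'   `k_clusters` (default 9, capped at the cohort size), `min_leaf_frac`
#'   (default 0.1).
#' @param seed Integer recorded in the run metadata (the analysis itself is
#'   deterministic).
#' @return List with `section_profiles`, `tumor_summary`, `associations`,
#'   `survival` (table + curves), `config`, `seed`; invisibly when writing.
#' @export
run_all <- function(study_dir, out_dir = NULL, config = list(), seed = 1) {
  defaults <- list(min_frac = 0.05, connectivity = 8, fdr_level = 0.10,
                   k_clusters = 9, min_leaf_frac = 0.1)
  config <- utils::modifyList(defaults, config)
  sections_path <- file.path(study_dir, "sections.csv")
  if (!file.exists(sections_path)) {
    stop("[stage quantify] study bundle lacks sections.csv: ", study_dir)
  }
  sections <- read_sections_table(sections_path)
  profs <- lapply(seq_len(nrow(sections)), function(i) {
    map <- read_label_map(sections$path[i], section_id = sections$section_id[i],
                          tumor_id = sections$tumor_id[i], role = sections$role[i])
    quantify_section(map, min_frac = config$min_frac,
                     connectivity = config$connectivity)
  })
  section_profiles <- do.call(rbind, profs)
  section_profiles <- section_profiles[order(section_profiles$tumor_id,
                                             section_profiles$section_id), ]
  summaries <- summarize_tumors(section_profiles)
  k <- min(config$k_clusters, nrow(summaries))
  summaries$cluster_id <- unname(cluster_tumor_profiles(summaries, k = k))
  results <- list(section_profiles = section_profiles, tumor_summary = summaries,
                  associations = NULL, survival = NULL,
                  config = config, seed = seed)
  clinical_path <- file.path(study_dir, "clinical.csv")
  if (file.exists(clinical_path)) {
    clinical <- read_clinical_table(clinical_path)
    results$associations <- associate_cohort(summaries, clinical,
                                             fdr_level = config$fdr_level)
    cohort <- merge(summaries, clinical, by = "tumor_id")
    surv <- tryCatch(
      stratified_survival_report(cohort, min_leaf_frac = config$min_leaf_frac),
      error = function(e) {
        warning("[stage survival] skipped: ", conditionMessage(e))
        NULL
      })
    if (!is.null(surv)) {
      results$survival <- surv$table
      results$km_curves <- surv$curves
    }
  } else {
    warning("[stage associate/survive] clinical.csv not found; association and survival stages skipped")
  }
  if (!is.null(out_dir)) {
    write_results_bundle(results, out_dir)
    return(invisible(results))
  }
  results
}

#' Summary tables underlying the cohort figures
#'
#' From a completed [run_all()] result, tabulates (i) morphotype frequency
#' by dominance rank at section and at tumor level, (ii) DMC group
#' frequencies with their distribution pattern classes, (iii) the tumor-NSI
#' distribution per DMC group, and (iv) the pairwise co-occurrence matrix of
#' dominant morphotypes across each tumor's sections.
#'
#' @param results List from [run_all()].
#' @param max_rank Deepest dominance rank tabulated (default 3:
#'   dominant/secondary/tertiary).
#' @return List of `data.frame`s / matrices: `section_dominance`,
#'   `tumor_dominance`, `dmc_groups`, `nsi_by_dmc`, `dominant_cooccurrence`.
#' @export
figure_tables <- function(results, max_rank = 3) {
  sp <- results$section_profiles
  sp <- sp[!sp$empty, , drop = FALSE]
  rank_names <- c("dominant", "secondary", "tertiary", "quaternary",
                  "quinary", "senary")[seq_len(max_rank)]
  sec_counts <- matrix(0L, 6, max_rank,
                       dimnames = list(MORPHOTYPE_CODES, rank_names))
  dom_list <- list()
  for (i in seq_len(nrow(sp))) {
    r <- dominance_ranking(sp[i, , drop = FALSE])
    top <- r$ordered_morphotypes[seq_len(min(max_rank, length(r$ordered_morphotypes)))]
    for (j in seq_along(top)) {
      sec_counts[top[j], j] <- sec_counts[top[j], j] + 1L
    }
    dom_list[[i]] <- data.frame(tumor_id = sp$tumor_id[i],
                                dominant = r$ordered_morphotypes[1])
  }
  doms <- do.call(rbind, dom_list)
  # tumor level: a morphotype counts once per tumor at the best rank it holds
  tum_counts <- matrix(0L, 6, max_rank,
                       dimnames = list(MORPHOTYPE_CODES, rank_names))
  for (id in unique(sp$tumor_id)) {
    sub <- sp[sp$tumor_id == id, , drop = FALSE]
    best <- rep(Inf, 6); names(best) <- MORPHOTYPE_CODES
    for (i in seq_len(nrow(sub))) {
      r <- dominance_ranking(sub[i, , drop = FALSE])
      top <- r$ordered_morphotypes[seq_len(min(max_rank, length(r$ordered_morphotypes)))]
      for (j in seq_along(top)) best[top[j]] <- min(best[top[j]], j)
    }
    for (m in MORPHOTYPE_CODES) {
      if (is.finite(best[m])) tum_counts[m, best[m]] <- tum_counts[m, best[m]] + 1L
    }
  }
  ts <- results$tumor_summary
  complete <- ts[!is.na(ts$pattern_class), , drop = FALSE]
  dmc_groups <- as.data.frame(table(dmc = complete$dmc), stringsAsFactors = FALSE)
  names(dmc_groups) <- c("dmc", "n_tumors")
  dmc_groups$pattern_class <-
    complete$pattern_class[match(dmc_groups$dmc, complete$dmc)]
  dmc_groups <- dmc_groups[order(-dmc_groups$n_tumors, dmc_groups$dmc), ]
  nsi_by_dmc <- stats::aggregate(tumor_nsi ~ dmc, data = complete,
                                 FUN = function(x) c(n = length(x),
                                                     median = stats::median(x),
                                                     min = min(x), max = max(x)))
  nsi_by_dmc <- do.call(data.frame, nsi_by_dmc)
  names(nsi_by_dmc) <- c("dmc", "n", "median_nsi", "min_nsi", "max_nsi")
  co <- matrix(0L, 6, 6, dimnames = list(MORPHOTYPE_CODES, MORPHOTYPE_CODES))
  for (id in unique(doms$tumor_id)) {
    d <- unique(doms$dominant[doms$tumor_id == id])
    for (a in d) for (b in d) co[a, b] <- co[a, b] + 1L
  }
  list(section_dominance = sec_counts, tumor_dominance = tum_counts,
       dmc_groups = dmc_groups, nsi_by_dmc = nsi_by_dmc,
       dominant_cooccurrence = co)
}
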