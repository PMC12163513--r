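# Independent oracles used across the suite. These are deliberately naive
# implementations (explicit loops, no shared code with the package).

# Brute-force flood fill: number of connected components of `value` pixels.
flood_fill_components <- function(pixels, value, connectivity = 8) {
  nr <- nrow(pixels); nc <- ncol(pixels)
  seen <- matrix(FALSE, nr, nc)
  target <- pixels == value
  offs <- if (connectivity == 8) {
    expand.grid(dr = -1:1, dc = -1:1)[-5, ]
  } else {
    data.frame(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  }
  n_comp <- 0
  for (r in seq_len(nr)) for (cl in seq_len(nc)) {
    if (!target[r, cl] || seen[r, cl]) next
    n_comp <- n_comp + 1
    stack <- list(c(r, cl))
    seen[r, cl] <- TRUE
    while (length(stack) > 0) {
      cur <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (k in seq_len(nrow(offs))) {
        r2 <- cur[1] + offs$dr[k]; c2 <- cur[2] + offs$dc[k]
        if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
            target[r2, c2] && !seen[r2, c2]) {
          seen[r2, c2] <- TRUE
          stack[[length(stack) + 1]] <- c(r2, c2)
        }
      }
    }
  }
  n_comp
}

# Hand product-limit estimator: survival at each distinct event time.
product_limit_oracle <- function(times, events) {
  ev_times <- sort(unique(times[events == 1]))
  s <- 1
  out <- data.frame(time = ev_times, surv = NA_real_)
  for (i in seq_along(ev_times)) {
    t <- ev_times[i]
    n_risk <- sum(times >= t)
    d <- sum(times == t & events == 1)
    s <- s * (1 - d / n_risk)
    out$surv[i] <- s
  }
  out
}

# Hand two-group log-rank chi-square (observed minus expected, loop form).
logrank_oracle <- function(times, events, group2) {
  ev_times <- sort(unique(times[events == 1]))
  O <- E <- V <- 0
  for (t in ev_times) {
    at_risk <- times >= t
    n <- sum(at_risk); n2 <- sum(at_risk & group2)
    d <- sum(times == t & events == 1)
    d2 <- sum(times == t & events == 1 & group2)
    O <- O + d2
    E <- E + d * n2 / n
    if (n > 1) V <- V + d * (n2 / n) * (1 - n2 / n) * (n - d) / (n - 1)
  }
  if (V == 0) return(0)
  (O - E)^2 / V
}

# Enumerate the multiplicity partition of a 4-element combination the long
# way: count each code with a loop, then sort the positive counts.
partition_oracle <- function(dominants) {
  codes <- unique(dominants)
  counts <- integer(0)
  for (cd in codes) {
    n <- 0
    for (d in dominants) if (d == cd) n <- n + 1
    counts <- c(counts, n)
  }
  paste(sort(counts, decreasing = TRUE), collapse = "+")
}

# Build a section-profile data.frame suitable for summarize_tumors() from a
# matrix of proportions (one row per section).
make_profiles_df <- function(pmat, tumor_id = "T001", roles = NULL) {
  n <- nrow(pmat)
  if (is.null(roles)) roles <- rep_len(section_roles(), n)
  df <- data.frame(tumor_id = tumor_id,
                   section_id = sprintf("%s_S%d", tumor_id, seq_len(n)),
                   role = roles)
  colnames(pmat) <- paste0("p_", morphotypes())
  cbind(df, as.data.frame(pmat), empty = FALSE)
}

# Random label map fixture with given fill probability per class.
random_label_map <- function(nr, nc, p_zero = 0.4, seed = 1) {
  set.seed(seed)
  vals <- sample(0:6, nr * nc, replace = TRUE,
                 prob = c(p_zero, rep((1 - p_zero) / 6, 6)))
  label_map(matrix(as.integer(vals), nr, nc), section_id = "S1",
            tumor_id = "T001", role = "central")
}

# Tumor summaries for a cohort drawn without rendering rasters (profiles
# treated as exact section measurements).
cohort_summaries <- function(prof) {
  sp <- prof$section_profiles
  sp$empty <- FALSE
  summarize_tumors(sp, warn_empty = FALSE)
}

null_sim_config <- function(...) {
  sim_config(beta_mu_msi = 0, beta_tb_msi = 0, beta_de_stage = 0,
             beta_mu_site = 0, beta_mu_grade = 0, beta_tb_grade = 0,
             beta_de_hazard = 0, beta_pp_hazard = 0, ...)
}
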