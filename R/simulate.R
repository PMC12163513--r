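#' Configuration of the synthetic study generator
#'
#' Parameterises a fully synthetic cohort with the statistical structure the
#' analysis assumes: tumor-level morphotype proportions drawn from a
#' Dirichlet distribution, section profiles drawn around the tumor mean with
#' a concentration parameter, spatially contiguous label-map patches grown
#' from random seeds inside an elliptical tumor mask, clinical covariates
#' with planted effects (MU/TB raise the odds of MSI and right-sided
#' location, DE shifts stage upward) and exponential survival with a
#' positive DE and negative (protective) PP log-hazard contribution, under
#' independent uniform censoring.
#'
#' Defaults emulate the study conditions: 161 tumors x 4 sections (644
#' label maps), a CT-dominated cohort, and effect sizes strong enough to be
#' unambiguous at n = 161.
#'
#' @param n_tumors Number of tumors (default 161).
#' @param sections_per_tumor Sections per tumor (default 4).
#' @param raster_dim Label-map dimensions in pixels (default 200 x 200).
#' @param n_seed_patches Number of growth seeds per section (default 24).
#' @param tumor_alpha Length-6 Dirichlet concentration for tumor means,
#'   canonical order.
#' @param section_concentration Scalar; section profile ~
#'   Dirichlet(concentration x tumor mean). Higher means sections closer to
#'   the tumor mean.
#' @param beta_mu_msi,beta_tb_msi Logit coefficients of p_MU / p_TB on MSI.
#' @param beta_de_stage Cumulative-logit coefficient of p_DE on AJCC stage.
#' @param beta_mu_site Logit coefficient of p_MU on right-sided location.
#' @param beta_mu_grade,beta_tb_grade Cumulative-logit coefficients of
#'   p_MU / p_TB on grade.
#' @param beta_de_hazard,beta_pp_hazard Log-hazard coefficients of p_DE
#'   (positive, harmful) and p_PP (negative, protective).
#' @param baseline_hazard Baseline exponential hazard per month.
#' @param censoring_rate Fraction of subjects censored, in \[0, 1).
#' @param render_tolerance Maximum absolute deviation allowed between a
#'   rendered section's realized proportions and its target profile.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_tumors = 161,
                       sections_per_tumor = 4,
                       raster_dim = c(200, 200),
                       n_seed_patches = 24,
                       tumor_alpha = c(2.4, 0.45, 0.60, 0.80, 0.65, 0.50),
                       section_concentration = 40,
                       beta_mu_msi = 8, beta_tb_msi = 5,
                       beta_de_stage = 6, beta_mu_site = 6,
                       beta_mu_grade = 2, beta_tb_grade = 2,
                       beta_de_hazard = 3, beta_pp_hazard = -3,
                       baseline_hazard = 0.02,
                       censoring_rate = 0.3,
                       render_tolerance = 0.03) {
  if (any(tumor_alpha <= 0) || length(tumor_alpha) != 6) {
    stop("tumor_alpha must be 6 positive concentrations (canonical order)")
  }
  if (section_concentration <= 0) stop("section_concentration must be positive")
  if (censoring_rate < 0 || censoring_rate >= 1) stop("censoring_rate must be in [0, 1)")
  if (n_tumors < 1 || sections_per_tumor < 1) stop("cohort must be non-empty")
  if (any(raster_dim < 8)) stop("raster_dim too small to render patches")
  structure(list(
    n_tumors = as.integer(n_tumors),
    sections_per_tumor = as.integer(sections_per_tumor),
    raster_dim = as.integer(raster_dim), n_seed_patches = as.integer(n_seed_patches),
    tumor_alpha = tumor_alpha, section_concentration = section_concentration,
    beta_mu_msi = beta_mu_msi, beta_tb_msi = beta_tb_msi,
    beta_de_stage = beta_de_stage, beta_mu_site = beta_mu_site,
    beta_mu_grade = beta_mu_grade, beta_tb_grade = beta_tb_grade,
    beta_de_hazard = beta_de_hazard, beta_pp_hazard = beta_pp_hazard,
    baseline_hazard = baseline_hazard, censoring_rate = censoring_rate,
    render_tolerance = render_tolerance), class = "sim_config")
}

# Dirichlet sampler via normalised gammas; rows sum to 1.
rdirichlet <- function(n, alpha) {
  x <- matrix(stats::rgamma(n * length(alpha), shape = alpha, rate = 1),
              nrow = n, byrow = TRUE)
  # guard against all-zero rows with extremely small alphas
  zero <- rowSums(x) == 0
  if (any(zero)) x[zero, which.max(alpha)] <- 1
  x / rowSums(x)
}

#' Draw tumor- and section-level morphotype profiles
#'
#' Tumor mean profiles are Dirichlet(`tumor_alpha`); each section profile is
#' Dirichlet(`section_concentration` x tumor mean), so the tumor mean
#' controls location and the concentration controls between-section
#' dispersion.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; the draw is reproducible given the seed.
#' @return List: `tumor_profiles` (n_tumors x 6 matrix, rownames tumor ids)
#'   and `section_profiles` (`data.frame` with tumor_id, section_id, role,
#'   p_CT..p_SE).
#' @export
draw_profiles <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  n <- config$n_tumors; s <- config$sections_per_tumor
  tumor_ids <- sprintf("T%03d", seq_len(n))
  tp <- rdirichlet(n, config$tumor_alpha)
  rownames(tp) <- tumor_ids; colnames(tp) <- MORPHOTYPE_CODES
  roles <- rep_len(section_roles(), s)
  alpha_sec <- pmax(config$section_concentration *
                      tp[rep(seq_len(n), each = s), , drop = FALSE], 1e-8)
  x <- matrix(stats::rgamma(n * s * 6, shape = as.vector(t(alpha_sec)), rate = 1),
              nrow = n * s, byrow = TRUE)
  zero <- rowSums(x) == 0
  if (any(zero)) x[cbind(which(zero), max.col(alpha_sec[zero, , drop = FALSE]))] <- 1
  sp <- x / rowSums(x)
  colnames(sp) <- profile_cols()
  ids <- rep(tumor_ids, each = s)
  section_profiles <- data.frame(
    tumor_id = ids,
    section_id = sprintf("%s_S%d", ids, rep(seq_len(s), n)),
    role = rep(roles, n),
    as.data.frame(sp))
  list(tumor_profiles = tp, section_profiles = section_profiles)
}

#' Render a section profile as a contiguous label map
#'
#' Realises a target proportion vector as a raster: an elliptical tumor mask
#' is partitioned by quota-constrained multi-source region growth — each
#' morphotype with positive target proportion receives seeds (in proportion
#' to its share of `n_seed_patches`, at least one) and grows breadth-first
#' until its pixel quota (target proportion x mask area) is met; pixels left
#' unreachable are attached to an adjacent region. Background is 0 outside
#' the mask. The realized proportions are recorded in the attribute
#' `realized_profile` and typically deviate from the target by far less than
#' `render_tolerance`.
#'
#' @param profile Length-6 target proportion vector (sums to 1).
#' @param config A [sim_config()] (raster size, patch count).
#' @param seed Integer seed for seed-pixel placement and growth order.
#' @param section_id,tumor_id,role Metadata for the resulting map.
#' @return A [label_map()] with attribute `realized_profile`.
#' @export
render_section <- function(profile, config, seed, section_id = "S1",
                           tumor_id = "T001", role = "central") {
  stopifnot(inherits(config, "sim_config"))
  p <- check_proportions(profile)
  set.seed(seed)
  nr <- config$raster_dim[1]; nc <- config$raster_dim[2]
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  mask <- ((rows - (nr + 1) / 2) / (0.45 * nr))^2 +
    ((cols - (nc + 1) / 2) / (0.45 * nc))^2 <= 1
  idx_mask <- which(mask)
  A <- length(idx_mask)
  present <- which(p > 0)
  quota <- integer(6)
  quota[present] <- floor(p[present] * A)
  rem <- A - sum(quota)
  if (rem > 0) { # distribute the rounding remainder by largest fractional part
    fr <- p * A - floor(p * A)
    give <- order(-fr)[seq_len(rem)]
    quota[give] <- quota[give] + 1L
  }
  n_seeds <- pmax(1L, round(config$n_seed_patches * p[present]))
  if (sum(n_seeds) > A) stop("raster too small for the requested patch count")
  lab <- integer(nr * nc) # 0 = unassigned / background
  remaining <- quota
  frontiers <- vector("list", 6)
  seed_px <- sample(idx_mask, sum(n_seeds))
  off <- 0
  for (ii in seq_along(present)) {
    k <- present[ii]
    sp <- seed_px[(off + 1):(off + n_seeds[ii])]
    off <- off + n_seeds[ii]
    sp <- sp[seq_len(min(length(sp), remaining[k]))]
    lab[sp] <- k
    remaining[k] <- remaining[k] - length(sp)
    frontiers[[k]] <- sp
  }
  nb4 <- function(ix) {
    r <- (ix - 1L) %% nr + 1L
    cl <- (ix - 1L) %/% nr + 1L
    c(ix[r > 1] - 1L, ix[r < nr] + 1L, ix[cl > 1] - nr, ix[cl < nc] + nr)
  }
  in_mask <- logical(nr * nc); in_mask[idx_mask] <- TRUE
  repeat {
    progress <- FALSE
    for (k in present[order(-remaining[present])]) {
      if (remaining[k] == 0) next
      if (length(frontiers[[k]]) == 0) {
        # frontier enclosed before the quota was met: reseed in free space
        free <- idx_mask[lab[idx_mask] == 0L]
        if (length(free) == 0) next
        sp <- if (length(free) == 1) free else sample(free, 1)
        lab[sp] <- k
        remaining[k] <- remaining[k] - 1L
        frontiers[[k]] <- sp
        progress <- TRUE
        next
      }
      cand <- unique(nb4(frontiers[[k]]))
      cand <- cand[in_mask[cand] & lab[cand] == 0L]
      if (length(cand) == 0) {
        # state changed (frontier retired); the next round will reseed
        frontiers[[k]] <- integer(0)
        progress <- TRUE
        next
      }
      if (length(cand) > remaining[k]) cand <- sample(cand, remaining[k])
      lab[cand] <- k
      remaining[k] <- remaining[k] - length(cand)
      frontiers[[k]] <- cand
      progress <- TRUE
    }
    if (!progress || sum(remaining) == 0) break
  }
  # pixels trapped away from any live frontier: attach to an adjacent region
  repeat {
    un <- idx_mask[lab[idx_mask] == 0L]
    if (length(un) == 0) break
    filled <- FALSE
    for (ix in un) {
      nbl <- lab[nb4(ix)]
      nbl <- nbl[nbl > 0L]
      if (length(nbl) > 0) { lab[ix] <- nbl[1]; filled <- TRUE }
    }
    if (!filled) { lab[un] <- present[1]; break }
  }
  pixels <- matrix(as.integer(lab), nr, nc)
  map <- label_map(pixels, section_id = section_id, tumor_id = tumor_id,
                   role = role)
  realized <- tabulate(pixels[pixels > 0L], 6) / A
  if (max(abs(realized - p)) > config$render_tolerance) {
    warning(sprintf("rendered section %s deviates from target by %.3f (> tolerance %.3f)",
                    section_id, max(abs(realized - p)), config$render_tolerance))
  }
  attr(map, "realized_profile") <- stats::setNames(realized, MORPHOTYPE_CODES)
  map
}

#' Draw clinical covariates and survival outcomes given tumor profiles
#'
#' Planted structure: MSI odds rise with p_MU and p_TB; AJCC stage is
#' ordinal (cumulative logit) shifted upward by p_DE, with T/N/M derived
#' consistently from stage; right-sided location odds rise with p_MU; grade
#' rises with p_MU and p_TB. Survival times are exponential with log-hazard
#' `log(baseline) + beta_DE * p_DE + beta_PP * p_PP`; RFS events precede OS.
#' Censoring is independent: each subject is censored with probability
#' `censoring_rate`, at a time uniform on (0, event time).
#'
#' @param profiles Output of [draw_profiles()] (or any matrix-bearing list
#'   with `tumor_profiles`).
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return List: `clinical` (validated clinical `data.frame`) and `truth`
#'   (`data.frame` of the planted coefficients, for recovery tests).
#' @export
draw_clinical <- function(profiles, config, seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  tp <- profiles$tumor_profiles
  n <- nrow(tp)
  p_mu <- tp[, "MU"]; p_tb <- tp[, "TB"]; p_de <- tp[, "DE"]; p_pp <- tp[, "PP"]
  age <- round(stats::rnorm(n, 66, 11))
  age[age < 30] <- 30
  gender <- sample(c("M", "F"), n, replace = TRUE, prob = c(0.55, 0.45))
  # MSI: intercept set for ~20% MSI at zero effect (cohort was 79.4% MSS)
  eta_msi <- -1.4 + config$beta_mu_msi * (p_mu - mean(p_mu)) +
    config$beta_tb_msi * (p_tb - mean(p_tb))
  msi <- ifelse(stats::runif(n) < stats::plogis(eta_msi), "MSI", "MSS")
  # stage: cumulative logit, cutpoints matched to the reported stage mix
  eta_st <- config$beta_de_stage * (p_de - mean(p_de))
  cuts <- stats::qlogis(cumsum(c(0.15, 0.42, 0.27))) # I, II, III shares; IV = rest
  u <- stats::runif(n)
  cum1 <- stats::plogis(cuts[1] - eta_st)
  cum2 <- stats::plogis(cuts[2] - eta_st)
  cum3 <- stats::plogis(cuts[3] - eta_st)
  stage <- ifelse(u < cum1, "I", ifelse(u < cum2, "II", ifelse(u < cum3, "III", "IV")))
  t_stage <- ifelse(stage == "I", sample(c("T1", "T2"), n, TRUE, c(0.3, 0.7)),
                    ifelse(stats::runif(n) < 0.85, "T3", "T4"))
  n_stage <- ifelse(stage %in% c("I", "II"), "N0",
                    ifelse(stats::runif(n) < 0.6, "N1", "N2"))
  m_stage <- ifelse(stage == "IV", "M1", "M0")
  eta_site <- -0.6 + config$beta_mu_site * (p_mu - mean(p_mu))
  right <- stats::runif(n) < stats::plogis(eta_site)
  site <- ifelse(right,
                 sample(c("right", "transverse"), n, TRUE, c(0.75, 0.25)),
                 sample(c("left", "rectosigmoid", "rectum"), n, TRUE, c(0.5, 0.3, 0.2)))
  eta_gr <- config$beta_mu_grade * (p_mu - mean(p_mu)) +
    config$beta_tb_grade * (p_tb - mean(p_tb))
  gu <- stats::runif(n)
  g1 <- stats::plogis(stats::qlogis(0.12) - eta_gr)
  g2 <- stats::plogis(stats::qlogis(0.71) - eta_gr)
  grade <- ifelse(gu < g1, "1", ifelse(gu < g2, "2", "3"))
  # survival: exponential OS; RFS earlier than OS by a uniform factor
  haz <- config$baseline_hazard *
    exp(config$beta_de_hazard * p_de + config$beta_pp_hazard * p_pp)
  os_t <- stats::rexp(n, rate = haz)
  rfs_t <- os_t * stats::runif(n, 0.5, 1)
  cens <- stats::runif(n) < config$censoring_rate
  os_event <- as.integer(!cens)
  os_time <- ifelse(cens, os_t * stats::runif(n), os_t)
  rcens <- stats::runif(n) < config$censoring_rate
  rfs_event <- as.integer(!rcens)
  rfs_time <- ifelse(rcens, rfs_t * stats::runif(n), rfs_t)
  clinical <- data.frame(
    tumor_id = rownames(tp), age = age, gender = gender, t_stage = t_stage,
    n_stage = n_stage, m_stage = m_stage, ajcc_stage = stage, grade = grade,
    site = site, msi = msi,
    os_time = round(os_time, 3), rfs_time = round(rfs_time, 3),
    os_event = os_event, rfs_event = rfs_event)
  truth <- data.frame(
    parameter = c("beta_mu_msi", "beta_tb_msi", "beta_de_stage", "beta_mu_site",
                  "beta_de_hazard", "beta_pp_hazard", "baseline_hazard",
                  "censoring_rate"),
    value = c(config$beta_mu_msi, config$beta_tb_msi, config$beta_de_stage,
              config$beta_mu_site, config$beta_de_hazard, config$beta_pp_hazard,
              config$baseline_hazard, config$censoring_rate))
  list(clinical = validate_clinical(clinical), truth = truth)
}

#' Write a complete synthetic study bundle to disk
#'
#' Draws profiles, renders one label map per section, draws clinical
#' covariates, and writes `sections.csv`, `clinical.csv`, `sim_truth.csv`
#' and one PNG raster per section into `out_dir`. The bundle is directly
#' consumable by [run_all()]. Identical config and seed yield byte-identical
#' tables.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed; per-stream seeds are derived from it.
#' @return The study directory path, invisibly.
#' @export
emit_study <- function(config, out_dir, seed = 1) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  if (!ok) stop("cannot create study directory: ", out_dir)
  raster_dir <- file.path(out_dir, "rasters")
  dir.create(raster_dir, showWarnings = FALSE)
  streams <- derive_seeds(seed, 3 + config$n_tumors * config$sections_per_tumor)
  prof <- draw_profiles(config, streams[1])
  clin <- draw_clinical(prof, config, streams[2])
  sp <- prof$section_profiles
  paths <- character(nrow(sp))
  for (i in seq_len(nrow(sp))) {
    map <- render_section(as.numeric(sp[i, profile_cols()]), config,
                          seed = streams[3 + i],
                          section_id = sp$section_id[i],
                          tumor_id = sp$tumor_id[i], role = sp$role[i])
    paths[i] <- file.path("rasters", paste0(sp$section_id[i], ".png"))
    write_label_map(map, file.path(out_dir, paths[i]))
  }
  sections <- data.frame(tumor_id = sp$tumor_id, section_id = sp$section_id,
                         role = sp$role, path = paths)
  utils::write.csv(sections, file.path(out_dir, "sections.csv"), row.names = FALSE)
  utils::write.csv(clin$clinical, file.path(out_dir, "clinical.csv"), row.names = FALSE)
  truth <- rbind(clin$truth,
                 data.frame(parameter = paste0("alpha_", MORPHOTYPE_CODES),
                            value = config$tumor_alpha),
                 data.frame(parameter = "section_concentration",
                            value = config$section_concentration))
  utils::write.csv(truth, file.path(out_dir, "sim_truth.csv"), row.names = FALSE)
  invisible(out_dir)
}

# Deterministic derivation of sub-stream seeds from one master seed,
# kept within the 32-bit integer range.
derive_seeds <- function(seed, n) {
  (as.integer(seed) + 1013L * seq_len(n)) %% .Machine$integer.max
}
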