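test_that("sim_config validates its invariants", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(tumor_alpha = c(1, 1, 1, 1, 1, -1)), "positive")
  expect_error(sim_config(censoring_rate = 1), "censoring_rate")
  expect_error(sim_config(n_tumors = 0), "non-empty")
  expect_error(sim_config(section_concentration = 0), "positive")
})

test_that("profile draws are seeded, simplex-valued and concentration-controlled", {
  cfg <- sim_config(n_tumors = 20)
  a <- draw_profiles(cfg, seed = 7)
  b <- draw_profiles(cfg, seed = 7)
  expect_identical(a, b)
  expect_equal(unname(rowSums(a$tumor_profiles)), rep(1, 20), tolerance = 1e-9)
  pm <- as.matrix(a$section_profiles[, paste0("p_", morphotypes())])
  expect_equal(unname(rowSums(pm)), rep(1, 80), tolerance = 1e-9)

  # very high concentration: sections hug the tumor mean
  tight <- draw_profiles(sim_config(n_tumors = 100, section_concentration = 1e5),
                         seed = 11)
  dev <- 0
  for (i in 1:100) {
    rows <- (4 * (i - 1) + 1):(4 * i)
    sm <- as.matrix(tight$section_profiles[rows, paste0("p_", morphotypes())])
    dev <- max(dev, max(abs(t(sm) - tight$tumor_profiles[i, ])))
  }
  expect_lt(dev, 0.02)

  # a spiked alpha makes CT dominant essentially everywhere
  spike <- draw_profiles(sim_config(n_tumors = 50,
                                    tumor_alpha = c(100, 0.01, 0.01, 0.01, 0.01, 0.01)),
                         seed = 13)
  dom <- apply(spike$tumor_profiles, 1, which.max)
  expect_gte(mean(dom == 1), 0.98)
})

test_that("rendered sections realise their target profile", {
  cfg <- sim_config(raster_dim = c(120, 120))
  # degenerate profile: every tumor pixel is CT
  m <- render_section(c(1, 0, 0, 0, 0, 0), cfg, seed = 3)
  expect_true(all(m$pixels %in% c(0L, 1L)))
  expect_gt(sum(m$pixels == 1L), 0)

  # a 50/50 profile within the documented tolerance
  m2 <- render_section(c(0.5, 0.5, 0, 0, 0, 0), cfg, seed = 5)
  realized <- attr(m2, "realized_profile")
  expect_lt(max(abs(realized - c(0.5, 0.5, 0, 0, 0, 0))), 0.03)

  # same seed, same raster
  m3 <- render_section(c(0.5, 0.5, 0, 0, 0, 0), cfg, seed = 5)
  expect_identical(m2$pixels, m3$pixels)

  expect_error(render_section(c(0.7, 0.2, 0, 0, 0, 0), cfg, seed = 1),
               "sum to 1")
})

test_that("quantify recovers rendered profiles end to end (min_frac = 0)", {
  cfg <- sim_config(raster_dim = c(120, 120))
  set.seed(17)
  worst <- 0
  for (i in 1:25) {
    a <- rexp(6) + 0.05
    p <- a / sum(a)
    m <- render_section(p, cfg, seed = 1000 + i)
    prof <- quantify_section(m, min_frac = 0)
    got <- as.numeric(prof[, paste0("p_", morphotypes())])
    worst <- max(worst, max(abs(got - p)))
  }
  expect_lt(worst, cfg$render_tolerance)
})

test_that("realized-vs-target deviation is bounded by the shrinking pixel quantum", {
  # quota-constrained growth realises each proportion to within a few pixels
  # of the mask area A, so the deviation bound scales as 1/A
  p <- c(0.35, 0.2, 0.15, 0.15, 0.1, 0.05)
  mad_for <- function(side) {
    cfg <- sim_config(raster_dim = c(side, side))
    devs <- vapply(1:8, function(i) {
      m <- render_section(p, cfg, seed = 300 + i)
      max(abs(attr(m, "realized_profile") - p))
    }, numeric(1))
    mean(devs)
  }
  for (side in c(40, 80, 160)) {
    area <- pi * (0.45 * side)^2
    expect_lt(mad_for(side), 6 / area, label = paste("side", side))
  }
})

test_that("clinical draws respect censoring and plant the configured effects", {
  cfg <- sim_config(n_tumors = 120, censoring_rate = 0)
  prof <- draw_profiles(cfg, seed = 19)
  clin <- draw_clinical(prof, cfg, seed = 23)$clinical
  expect_true(all(clin$os_event == 1))
  expect_true(all(clin$rfs_event == 1))
  expect_true(all(clin$rfs_time <= clin$os_time))
  expect_true(all((clin$ajcc_stage == "IV") == (clin$m_stage == "M1")))

  # planted effect directions recovered in sign (MU higher in MSI,
  # DE higher hazard => shorter observed survival among high-DE tumors)
  tp <- prof$tumor_profiles
  expect_gt(mean(tp[clin$msi == "MSI", "MU"]), mean(tp[clin$msi == "MSS", "MU"]))
  hi_de <- tp[, "DE"] > stats::median(tp[, "DE"])
  expect_lt(stats::median(clin$os_time[hi_de]), stats::median(clin$os_time[!hi_de]))
})

test_that("null configuration leaves covariates independent of profiles", {
  set.seed(29)
  pvals <- replicate(40, {
    cfg <- null_sim_config(n_tumors = 100)
    s <- sample.int(1e6, 1)
    prof <- draw_profiles(cfg, seed = s)
    clin <- draw_clinical(prof, cfg, seed = s + 1)$clinical
    stats::wilcox.test(prof$tumor_profiles[, "MU"] ~ clin$msi,
                       exact = FALSE)$p.value
  })
  expect_lt(mean(pvals < 0.05), 0.2)  # near-nominal, loose MC band at 40 reps
  expect_gt(mean(pvals > 0.2), 0.5)   # p-values spread out, not piled at 0
})

test_that("emit_study writes a complete, deterministic, consumable bundle", {
  cfg <- sim_config(n_tumors = 2, raster_dim = c(80, 80))
  d1 <- tempfile(); d2 <- tempfile()
  emit_study(cfg, d1, seed = 31)
  emit_study(cfg, d2, seed = 31)
  expect_true(file.exists(file.path(d1, "sections.csv")))
  expect_true(file.exists(file.path(d1, "clinical.csv")))
  expect_true(file.exists(file.path(d1, "sim_truth.csv")))
  expect_equal(length(list.files(file.path(d1, "rasters"))), 8)
  for (f in c("sections.csv", "clinical.csv", "sim_truth.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  sections <- read_sections_table(file.path(d1, "sections.csv"))
  m <- read_label_map(sections$path[1], sections$section_id[1],
                      sections$tumor_id[1], sections$role[1])
  expect_s3_class(m, "label_map")
  unlink(c(d1, d2), recursive = TRUE)
})
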