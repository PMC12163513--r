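test_that("Kaplan-Meier estimates match hand product-limit values", {
  # all censored: survival stays 1
  km <- km_estimate(c(3, 5, 8), c(0, 0, 0))
  expect_true(all(km$surv == 1))

  # events at t = 1, 2 with n = 2: S(1) = 0.5, S(2) = 0
  km2 <- km_estimate(c(1, 2), c(1, 1))
  expect_equal(km2$surv, c(0.5, 0))
  expect_equal(km2$n_risk, c(2, 1))

  expect_error(km_estimate(numeric(0), numeric(0)), "no survival data")
  expect_error(km_estimate(c(1, -2), c(1, 1)), "non-negative")
  expect_error(km_estimate(c(1, 2), c(1, 2)), "0/1")
})

test_that("KM curves are non-increasing, start at 1 and match the oracle on random data", {
  set.seed(71)
  for (i in 1:100) {
    n <- sample(5:60, 1)
    times <- round(rexp(n, 0.2), 1)
    events <- rbinom(n, 1, 0.7)
    km <- km_estimate(times, events)
    expect_true(all(diff(km$surv) <= 1e-12))
    expect_true(all(km$surv <= 1 + 1e-12))
    oracle <- product_limit_oracle(times, events)
    got <- km$surv[match(oracle$time, km$time)]
    expect_equal(got, oracle$surv, tolerance = 1e-10)
  }
})

test_that("without censoring the KM curve equals the empirical survivor function", {
  set.seed(73)
  times <- sample(1:30, 40, replace = TRUE)
  km <- km_estimate(times, rep(1, 40))
  emp <- vapply(km$time, function(t) mean(times > t), numeric(1))
  expect_equal(km$surv, emp, tolerance = 1e-12)
})

test_that("log-rank test behaves analytically and matches the O-E oracle", {
  t0 <- c(1, 2, 3, 4, 5, 6)
  same <- logrank_test(rep(t0, 2), rep(1, 12), rep(c("a", "b"), each = 6))
  expect_equal(same$statistic, 0, tolerance = 1e-10)
  expect_equal(same$p_value, 1, tolerance = 1e-10)

  set.seed(79)
  for (i in 1:50) {
    n <- sample(20:80, 1)
    times <- round(rexp(n, 0.1), 2)
    events <- rbinom(n, 1, 0.7)
    g <- rbinom(n, 1, 0.5) == 1
    if (length(unique(g)) < 2 || sum(events) == 0) next
    res <- logrank_test(times, events, g)
    expect_equal(res$statistic, logrank_oracle(times, events, g),
                 tolerance = 1e-8)
    # label swap leaves the statistic unchanged
    expect_equal(logrank_test(times, events, !g)$statistic, res$statistic,
                 tolerance = 1e-10)
  }
  expect_error(logrank_test(c(1, 2), c(1, 1), c("a", "a")), "two non-empty")
})

test_that("log-rank detects a hazard ratio of 3 reliably", {
  set.seed(83)
  hits <- replicate(200, {
    times <- c(rexp(100, 0.1), rexp(100, 0.3))
    logrank_test(times, rep(1, 200), rep(c("a", "b"), each = 100))$p_value < 0.01
  })
  expect_gte(mean(hits), 0.95)
})

test_that("the exhaustive cutoff search recovers a planted changepoint", {
  set.seed(89)
  for (i in 1:10) {
    n <- 120
    x <- runif(n)
    hazard <- ifelse(x > 0.5, 0.5, 0.05)
    times <- rexp(n, hazard)
    oc <- optimal_cutoff(x, times, rep(1, n))
    # within one midpoint of the true boundary at 0.5
    xs <- sort(unique(x))
    gap <- max(diff(xs[abs(xs - 0.5) < 0.1]))
    expect_lt(abs(oc$cutoff - 0.5), 2 * gap + 0.02)
    expect_true(oc$exploratory)
  }
})

test_that("cutoff search respects the minimum-leaf constraint and determinism", {
  x <- (1:10) / 10
  times <- c(5, 3, 8, 2, 7, 1, 9, 4, 6, 10)
  oc <- optimal_cutoff(x, times, rep(1, 10), min_leaf_frac = 0.5)
  expect_equal(nrow(oc$candidates), 1) # only the median split is admissible
  expect_equal(oc$cutoff, 0.55)
  expect_equal(oc$n_low, 5); expect_equal(oc$n_high, 5)
  expect_identical(optimal_cutoff(x, times, rep(1, 10), min_leaf_frac = 0.5), oc)
  expect_error(optimal_cutoff(rep(0.3, 10), times, rep(1, 10)), "identical")
})

test_that("post-selection p-values under a pure-noise marker are anti-conservative", {
  set.seed(97)
  naive <- replicate(300, {
    n <- 60
    optimal_cutoff(runif(n), rexp(n, 0.1), rbinom(n, 1, 0.8))$p_value
  })
  # far above the nominal 5%: this is why the result is flagged exploratory
  expect_gt(mean(naive < 0.05), 0.15)
})

test_that("the stratification report covers morphotypes, endpoints and subsets", {
  cfg <- sim_config(n_tumors = 80)
  prof <- draw_profiles(cfg, seed = 101)
  clin <- draw_clinical(prof, cfg, seed = 102)$clinical
  cohort <- merge(cohort_summaries(prof), clin, by = "tumor_id")
  rep <- stratified_survival_report(cohort)
  expect_equal(nrow(rep$table), 3 * 2 * 2)
  expect_true(all(rep$table$n_low >= 8 & rep$table$n_high >= 8))
  # stage I-III subset removes all stage IV rows
  n_iv <- sum(cohort$ajcc_stage == "IV")
  sub <- rep$table[rep$table$subset == "stage_I_III", ]
  expect_true(all(sub$n_low + sub$n_high == nrow(cohort) - n_iv))
  # per-arm curves exist and start at or below 1
  expect_true(all(vapply(rep$curves, function(cv) all(cv$surv <= 1 + 1e-12),
                         logical(1))))
  expect_error(stratified_survival_report(cohort[, setdiff(names(cohort), "os_time")]),
               "missing endpoint")
  # planted DE hazard: the high-DE arm has the worse curve in the full cohort
  oc <- optimal_cutoff(cohort$p_DE, cohort$os_time, cohort$os_event)
  hi <- cohort$p_DE > oc$cutoff
  km_hi <- km_estimate(cohort$os_time[hi], cohort$os_event[hi])
  km_lo <- km_estimate(cohort$os_time[!hi], cohort$os_event[!hi])
  s_at <- function(km, t) { i <- findInterval(t, km$time); if (i == 0) 1 else km$surv[i] }
  t_star <- stats::median(cohort$os_time)
  expect_lt(s_at(km_hi, t_star), s_at(km_lo, t_star))
})
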