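test_that("Shannon index hits its analytic anchors", {
  uniform <- rep(1 / 6, 6)
  expect_equal(round(shannon_index(uniform), 2), 1.79) # printed maximum
  expect_equal(shannon_index(c(1, 0, 0, 0, 0, 0)), 0)
  expect_equal(shannon_index(c(0.5, 0.5, 0, 0, 0, 0)), log(2))
  expect_equal(nsi(uniform), 1)
  expect_equal(nsi(c(1, 0, 0, 0, 0, 0)), 0)
  expect_equal(nsi(c(0.5, 0.5, 0, 0, 0, 0)), log(2) / log(6))
  expect_error(shannon_index(c(0.5, 0.4, 0, 0, 0, 0)), "sum to 1")
  expect_error(nsi(c(-0.1, 1.1, 0, 0, 0, 0)), "non-negative")
})

test_that("NSI is permutation-invariant and maximal only at uniformity", {
  set.seed(11)
  for (i in 1:20) {
    p <- rexp(6); p <- p / sum(p)
    expect_equal(nsi(sample(p)), nsi(p), tolerance = 1e-12)
  }
  # randomized simplex search never exceeds the uniform value
  vals <- replicate(1e4, { p <- rexp(6); nsi(p / sum(p)) })
  expect_true(all(vals <= 1 + 1e-12))
  expect_lt(max(vals), 1) # strictly below: uniform draw has probability 0
})

test_that("dominance ranking sorts by proportion with canonical tie-break", {
  r <- dominance_ranking(c(0.5, 0, 0, 0.3, 0.2, 0))
  expect_equal(r$ordered_morphotypes, c("CT", "PP", "DE"))
  expect_false(r$tie_flag)

  r <- dominance_ranking(c(0.4, 0.4, 0.2, 0, 0, 0))
  expect_equal(r$ordered_morphotypes, c("CT", "TB", "MU"))
  expect_true(r$tie_flag)

  expect_equal(dominance_ranking(c(1, 0, 0, 0, 0, 0))$ordered_morphotypes, "CT")
  expect_error(dominance_ranking(rep(0, 6)), "empty")
})

test_that("DMC patterns match the documented examples", {
  d <- dmc_pattern(c("CT", "CT", "CT", "PP"))
  expect_equal(d$pattern_class, "3+1")
  expect_equal(d$label, "3xCT+1xPP")
  expect_equal(dmc_pattern(c("CT", "CT", "PP", "PP"))$pattern_class, "2+2")
  expect_equal(dmc_pattern(c("CT", "CT", "CT", "CT"))$pattern_class, "4")
  expect_equal(dmc_pattern(c("CT", "PP", "DE", "MU"))$pattern_class, "1+1+1+1")
  expect_error(dmc_pattern(c("CT", "CT")), "exactly 4")
  expect_error(dmc_pattern(rep("XX", 4)), "unknown morphotype")
})

test_that("DMC patterns agree with exhaustive enumeration of all 1296 quadruples", {
  codes <- morphotypes()
  grid <- expand.grid(codes, codes, codes, codes, stringsAsFactors = FALSE)
  expect_equal(nrow(grid), 1296)
  for (i in seq_len(nrow(grid))) {
    quad <- unlist(grid[i, ], use.names = FALSE)
    expect_equal(dmc_pattern(quad)$pattern_class, partition_oracle(quad))
  }
})

test_that("tumor summaries average section profiles and classify NSI", {
  p <- c(0.6, 0.1, 0.1, 0.1, 0.05, 0.05)
  df <- make_profiles_df(matrix(p, 4, 6, byrow = TRUE))
  s <- tumor_summary(df)
  expect_equal(as.numeric(s[, paste0("p_", morphotypes())]), p)
  expect_equal(s$tumor_nsi, nsi(p))
  expect_equal(s$dmc, "4xCT")
  expect_equal(s$pattern_class, "4")

  # four pure single-morphotype sections
  e <- diag(6)[1:4, ]
  s2 <- tumor_summary(make_profiles_df(e))
  expect_equal(as.numeric(s2[, paste0("p_", morphotypes())]),
               c(0.25, 0.25, 0.25, 0.25, 0, 0))
  expect_equal(s2$tumor_nsi, log(4) / log(6), tolerance = 1e-12)
  expect_equal(s2$pattern_class, "1+1+1+1")

  # mean matches an independent arithmetic oracle
  set.seed(5)
  pm <- t(replicate(4, { x <- rexp(6); x / sum(x) }))
  s3 <- tumor_summary(make_profiles_df(pm))
  expect_equal(as.numeric(s3[, paste0("p_", morphotypes())]),
               apply(pm, 2, function(col) sum(col) / 4), tolerance = 1e-12)
  expect_true(s3$tumor_nsi >= 0 && s3$tumor_nsi <= 1)

  # fewer than 4 valid sections: NSI kept, DMC withheld
  s4 <- tumor_summary(make_profiles_df(pm[1:3, ]))
  expect_true(is.na(s4$pattern_class))
  expect_equal(s4$n_valid_sections, 3)
})

test_that("NSI classes use the documented boundary rule", {
  expect_equal(as.character(nsi_class(c(0.2, 0.5, 0.8))),
               c("low", "medium", "high"))
  expect_equal(as.character(nsi_class(c(0.3, 0.7))), c("medium", "medium"))
  expect_error(nsi_class(1.2), "0, 1")
})

test_that("hierarchical clustering recovers planted profile groups and is deterministic", {
  set.seed(21)
  g1 <- t(replicate(10, { p <- c(10, 1, 1, 1, 1, 1) + rexp(6, 10); p / sum(p) }))
  g2 <- t(replicate(10, { p <- c(1, 1, 10, 1, 1, 1) + rexp(6, 10); p / sum(p) }))
  summ <- do.call(rbind, lapply(1:20, function(i) {
    tumor_summary(make_profiles_df(matrix(rbind(g1, g2)[i, ], 4, 6, byrow = TRUE),
                                   tumor_id = sprintf("T%03d", i)))
  }))
  cl <- cluster_tumor_profiles(summ, k = 2)
  expect_equal(length(unique(cl[1:10])), 1)
  expect_equal(length(unique(cl[11:20])), 1)
  expect_true(cl[1] != cl[11])
  # duplicated rows land in the same cluster; k = n gives singletons
  expect_equal(unname(cluster_tumor_profiles(summ, k = 20)), 1:20)
  dup <- summ; dup$tumor_id <- paste0(dup$tumor_id, "b")
  both <- rbind(summ, dup)
  cl2 <- cluster_tumor_profiles(both, k = 3)
  expect_equal(unname(cl2[1:20]), unname(cl2[21:40]))
  expect_error(cluster_tumor_profiles(summ, k = 21), "exceeds")
})
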