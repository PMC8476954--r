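test_that("LBP change labels follow the sign of morning minus evening", {
  expect_equal(as.character(lbp_change_label(5, 7)), "exacerbated")
  expect_equal(as.character(lbp_change_label(5, 5)), "no_change")
  expect_equal(as.character(lbp_change_label(7, 3)), "improved")
  expect_true(is.na(lbp_change_label(NA, 3)))
  expect_error(lbp_change_label(11, 3), "0, 10")
})

test_that("feature table joins, drops and orders columns as the classifier expects", {
  coh <- simulate_cohort(cohort_spec(signals = FALSE, seed = 5))
  feat <- truth_features(coh)
  expect_equal(nrow(feat) + attr(feat, "dropped"), 88)
  expect_equal(names(feat),
               c("participant_id", "date", "sex", "sitting_hours",
                 "motif_rate_30min", "sleepiness", "fullness", "label"))
  expect_setequal(feature_columns(),
                  c("sex", "sitting_hours", "motif_rate_30min", "sleepiness",
                    "fullness"))
  # a zero-sitting day is dropped and counted
  gt <- coh$ground_truth[1:3, ]
  summ <- data.frame(participant_id = gt$participant_id, date = gt$date,
                     sitting_hours = c(5, 0, 4),
                     motif_rate_30min = c(1, 2, 3))
  f2 <- build_feature_table(summ, coh$questionnaire, coh$metadata)
  expect_equal(nrow(f2), 2)
  expect_equal(attr(f2, "dropped"), 1L)
  # unmatched keys are an error naming the offender
  summ$date[1] <- "1999-01-01"
  expect_error(build_feature_table(summ, coh$questionnaire, coh$metadata),
               "1999-01-01")
})

test_that("Kruskal-Wallis H matches the fixture and an independent computation", {
  groups <- list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  kw <- kruskal_wallis(groups)
  expect_equal(kw$H, 7.2, tolerance = 1e-12)
  expect_equal(kw$df, 2)
  # all-equal values: H = 0
  expect_equal(kruskal_wallis(list(c(2, 2), c(2, 2, 2)))$H, 0)
  # oracle agreement on random instances, ties included
  set.seed(51)
  for (i in 1:50) {
    g <- lapply(1:3, function(j) sample(1:8, sample(4:9, 1), replace = TRUE))
    expect_equal(kruskal_wallis(g)$H, kw_oracle(g), tolerance = 1e-10)
  }
  # invariance under a strictly monotone transform
  g <- list(rnorm(8), rnorm(6), rnorm(7))
  expect_equal(kruskal_wallis(g)$H,
               kruskal_wallis(lapply(g, function(v) exp(3 * v + 1)))$H,
               tolerance = 1e-12)
  expect_error(kruskal_wallis(list(1:3)), "two groups")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "non-empty")
})

test_that("Dunn z agrees with the textbook formula and handles identical groups", {
  two <- dunn_posthoc(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(two$z, 0)
  expect_equal(two$p, 1)
  set.seed(52)
  for (i in 1:50) {
    g <- lapply(1:3, function(j) sample(1:10, sample(4:9, 1), replace = TRUE))
    names(g) <- c("x", "y", "z")
    d <- dunn_posthoc(g)
    expect_equal(d$z[1], dunn_oracle_z(g, 1, 2), tolerance = 1e-8)
    expect_equal(d$z[3], dunn_oracle_z(g, 2, 3), tolerance = 1e-8)
    expect_equal(d$p, 2 * pnorm(-abs(d$z)), tolerance = 1e-12)
  }
  # Holm adjustment available
  g <- list(a = 1:5, b = 6:10, c = 11:15)
  expect_true(all(dunn_posthoc(g, "holm")$p >= dunn_posthoc(g)$p))
  expect_error(dunn_posthoc(list(a = 1:3)), "two groups")
})

test_that("planted cohort effect shows up as the improved-vs-exacerbated contrast", {
  coh <- simulate_cohort(cohort_spec(days_per_participant = 6L,
                                     signals = FALSE, seed = 6))
  feat <- truth_features(coh)
  grp <- split(feat$motif_rate_30min, feat$label)
  kw <- kruskal_wallis(grp)
  d <- dunn_posthoc(grp)
  pair <- paste(d$group1, d$group2)
  expect_equal(pair[which.min(d$p)], "exacerbated improved")
  expect_lt(d$z[pair == "exacerbated improved"], 0)  # improved ranks higher
  expect_lt(kw$p, 0.05)
})
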