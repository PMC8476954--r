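test_that("state sequence simulation honours rate, degenerate and error cases", {
  specs <- four_seated_specs()
  # zero rate: no instances
  sim0 <- simulate_state_sequence(specs, 1000, dwell = 30,
                                  planted_motif = c(1L, 2L, 1L),
                                  motif_rate = 0, seed = 1)
  expect_equal(nrow(sim0$instances), 0)
  # single state, no motif: constant path
  sim1 <- simulate_state_sequence(specs[1], 200, dwell = 10, seed = 2)
  expect_equal(unique(sim1$states), 1L)
  # unknown state in motif
  expect_error(simulate_state_sequence(specs, 100, planted_motif = c(1L, 9L, 1L)),
               "unknown state")
  # planted count within the Poisson 95% band of its expectation 8
  sim <- simulate_state_sequence(specs, 7200, dwell = 60,
                                 planted_motif = c(1L, 2L, 1L),
                                 motif_rate = 2, seed = 3)
  expect_gte(nrow(sim$instances), qpois(0.025, 8))
  expect_lte(nrow(sim$instances), qpois(0.975, 8))
  # instances are non-overlapping, ordered, and carry the motif's states
  inst <- sim$instances
  expect_true(all(inst$start[-1] > inst$end[-nrow(inst)]))
  for (i in seq_len(nrow(inst))) {
    r <- rle(sim$states[inst$start[i]:inst$end[i]])
    expect_equal(r$values, c(1L, 2L, 1L))
  }
})

test_that("emitted COP matches the state library", {
  specs <- default_state_specs()
  # variance ordering: stable sit < big sway
  cop1 <- emit_cop(rep(1L, 3000), specs, seed = 1)
  cop3 <- emit_cop(rep(3L, 3000), specs, seed = 1)
  expect_lt(var(cop1$x), var(cop3$x))
  expect_lt(var(cop1$y), var(cop3$y))
  # empirical precision recovers the spec within 10% (Frobenius relative)
  cop <- emit_cop(rep(2L, 10000), specs, seed = 2)
  emp_prec <- solve(cov(cbind(cop$x, cop$y)))
  truep <- specs[[2]]$precision
  expect_lt(norm(emp_prec - truep, "F") / norm(truep, "F"), 0.1)
  # off-chair emits absent samples
  copo <- emit_cop(rep(4L, 50), specs, seed = 3)
  expect_true(all(!copo$present))
  expect_true(all(is.na(copo$x)))
})

test_that("load-cell emission inverts the COP formula", {
  specs <- default_state_specs()
  cop <- emit_cop(c(rep(1L, 100), rep(4L, 20), rep(2L, 100)), specs, seed = 4)
  # noise-free round trip is exact
  lc <- emit_loadcells(cop, body_weight = 60, hz = 1, seed = 1, noise_sd = 0)
  back <- compute_cop(lc)
  pres <- cop$present
  expect_equal(back$x[pres], cop$x[pres])
  expect_equal(back$y[pres], cop$y[pres])
  expect_equal(back$present, cop$present)
  # symmetric corner solution at the center
  c0 <- data.frame(t = 0, x = 0, y = 0, present = TRUE)
  lc0 <- emit_loadcells(c0, 60, hz = 1, seed = 1, noise_sd = 0)
  expect_equal(unlist(lc0[1, c("a1", "a2", "a3", "a4")], use.names = FALSE),
               rep(15, 4))
  # with 0.1 kg sensor noise the round-trip RMSE stays below 0.1 per axis
  lcn <- emit_loadcells(cop, 60, hz = 1, seed = 5, noise_sd = 0.1)
  backn <- compute_cop(lcn)
  expect_lt(sqrt(mean((backn$x[pres] - cop$x[pres])^2)), 0.1)
  expect_lt(sqrt(mean((backn$y[pres] - cop$y[pres])^2)), 0.1)
  # higher-rate output replicates each second hz times
  lch <- emit_loadcells(cop[1:5, ], 60, hz = 10, seed = 1, noise_sd = 0)
  expect_equal(nrow(lch), 50)
  expect_equal(diff(lch$t[1:2]), 0.1)
})

test_that("cohort simulation matches the study scale and stays in range", {
  spec <- cohort_spec(signals = FALSE, seed = 7)
  coh <- simulate_cohort(spec)
  expect_equal(nrow(coh$ground_truth), 88)   # 22 participants x 4 days
  q <- coh$questionnaire
  expect_true(all(q$lbp >= 0 & q$lbp <= 10))
  expect_true(all(q$sleepiness >= 0 & q$sleepiness <= 10))
  expect_true(all(q$fullness >= 0 & q$fullness <= 10))
  expect_setequal(unique(q$time_slot), c("0900", "1130", "1400", "1700"))
  # questionnaire label reproduces the drawn category
  feat <- truth_features(coh)
  m <- merge(feat, coh$ground_truth, by = c("participant_id", "date"))
  expect_equal(as.character(m$label.x), as.character(m$label.y))
  # identical seed, identical dataset
  coh2 <- simulate_cohort(cohort_spec(signals = FALSE, seed = 7))
  expect_identical(coh, coh2)
})

test_that("planted effect orders motif rates and vanishes at zero effect", {
  spec <- cohort_spec(n_participants = 40L, days_per_participant = 6L,
                      signals = FALSE, seed = 8)
  gt <- simulate_cohort(spec)$ground_truth
  mu <- tapply(gt$true_motif_rate, gt$label, mean)
  expect_gt(mu[["improved"]], mu[["no_change"]])
  expect_gt(mu[["no_change"]], mu[["exacerbated"]])
  # no-effect cohort: label independent of rate (chi-squared on a median split)
  gt0 <- simulate_cohort(cohort_spec(n_participants = 42L,
                                     days_per_participant = 12L,
                                     effect_size = 0, signals = FALSE,
                                     seed = 9))$ground_truth
  hi <- gt0$true_motif_rate > median(gt0$true_motif_rate)
  p <- suppressWarnings(chisq.test(table(hi, gt0$label))$p.value)
  expect_gt(p, 0.05)
})

test_that("cohort CSV files round-trip through the readers", {
  spec <- cohort_spec(n_participants = 2L, days_per_participant = 1L,
                      sitting_mean = 0.05, sitting_sd = 0.01, day_hours = 0.1,
                      seed = 10)
  coh <- simulate_cohort(spec)
  dir <- withr::local_tempdir()
  write_cohort_csv(coh, dir)
  files <- list.files(dir, pattern = "^loadcell_", full.names = TRUE)
  expect_equal(length(files), 2)
  back <- read_loadcell_csv(files[1])
  orig <- coh$loadcells[[1]]
  expect_equal(nrow(back), nrow(orig))
  expect_equal(back$a1, orig$a1, tolerance = 1e-6)
})
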