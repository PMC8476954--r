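# shared simulation helpers for the test suite

# four seated states with distinct covariance structure (no off-chair),
# used for segmentation-recovery checks
four_seated_specs <- function() {
  specs <- default_state_specs(include_off_chair = FALSE)
  specs[[4]] <- state_spec(
    4L,
    solve(matrix(c(0.8^2, -0.7 * 0.64, -0.7 * 0.64, 0.8^2), 2, 2)),
    label = "slight_sway")
  specs
}

# best label-permutation accuracy and the permutation itself
align_states <- function(assign, truth, K) {
  perms <- all_perms(seq_len(K))
  accs <- vapply(perms, function(p) mean(p[assign] == truth), numeric(1))
  list(acc = max(accs), perm = perms[[which.max(accs)]])
}

all_perms <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  out
}

macro_f1 <- function(pred, truth, K) {
  f1 <- vapply(seq_len(K), function(k) {
    tp <- sum(pred == k & truth == k)
    pr <- tp / max(sum(pred == k), 1)
    re <- tp / max(sum(truth == k), 1)
    if (pr + re == 0) 0 else 2 * pr * re / (pr + re)
  }, numeric(1))
  mean(f1)
}

# per-day feature table built from the generator's ground truth (bypassing
# the signal path), for classifier-level checks
truth_features <- function(cohort) {
  gt <- cohort$ground_truth
  summ <- data.frame(participant_id = gt$participant_id, date = gt$date,
                     sitting_hours = gt$sitting_hours,
                     motif_rate_30min = gt$true_motif_rate)
  build_feature_table(summ, cohort$questionnaire, cohort$metadata)
}

# independent textbook Kruskal-Wallis H (tie-corrected), for oracle checks
kw_oracle <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, g, sum)^2 / lengths(groups)) - 3 * (N + 1)
  ties <- table(x)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# independent Dunn z for one pair (i, j), written as an explicit loop
dunn_oracle_z <- function(groups, i, j) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  mi <- mean(r[g == i]); mj <- mean(r[g == j])
  ties <- table(x)
  s2 <- (N * (N + 1) / 12) - sum(ties^3 - ties) / (12 * (N - 1))
  (mi - mj) / sqrt(s2 * (1 / sum(g == i) + 1 / sum(g == j)))
}
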