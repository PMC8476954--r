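test_that("run-length compression is exactly invertible", {
  cs <- compress_states(c(1, 1, 2, 2, 2, 1))
  expect_equal(cs$states, c(1, 2, 1))
  expect_equal(cs$lengths, c(2, 3, 1))
  expect_equal(compress_states(rep(7, 5))$states, 7)
  set.seed(21)
  for (i in 1:100) {
    s <- sample(1:4, sample(1:80, 1), replace = TRUE)
    expect_identical(decompress_states(compress_states(s)), s)
  }
})

test_that("candidate enumeration matches a brute-force scan", {
  # independent oracle: regex-style scan with explicit greedy bookkeeping
  oracle_count <- function(cs, m) {
    cnt <- 0L; i <- 1L
    stride <- length(m) - (m[1] == m[length(m)])
    while (i <= length(cs) - length(m) + 1L) {
      if (all(cs[i:(i + length(m) - 1L)] == m)) {
        cnt <- cnt + 1L
        i <- i + stride
      } else i <- i + 1L
    }
    cnt
  }
  # hand-counted fixture: alternation with shared boundary entries
  cs <- list(states = c(1L, 2L, 1L, 2L, 1L, 2L, 1L), lengths = rep(2L, 7))
  cand <- enumerate_candidates(cs, L = 1, max_len = 6)
  got <- cand[cand$key == "1-2-1", ]
  expect_equal(got$count, 3L)
  set.seed(22)
  for (i in 1:50) {
    s <- decompress_states(list(states = sample(1:3, 40, TRUE), lengths = rep(1L, 40)))
    comp <- compress_states(s)
    cand <- enumerate_candidates(comp, L = 1, max_len = 5)
    for (j in seq_len(nrow(cand)))
      expect_equal(cand$count[j], oracle_count(comp$states, cand$motif[[j]]))
  }
  # a threshold above every count empties the list
  expect_equal(nrow(enumerate_candidates(cs, L = 100)), 0)
  # all survivors satisfy the structural constraints
  cand <- enumerate_candidates(cs, L = 1)
  expect_true(all(cand$length > 2))
  expect_true(all(vapply(cand$motif, function(m)
    all(m[-1] != m[-length(m)]), logical(1))))
})

test_that("motif score is occurrence frequency", {
  expect_equal(score_motif(c(1, 2, 1), 0), 0)
  expect_gt(score_motif(c(1, 2, 1), 10), score_motif(c(1, 2, 1), 5))
  expect_equal(score_motif(c(1, 2, 1), 7), 7)
})

test_that("motif-aware decoding matches exhaustive enumeration", {
  # brute force over all valid expanded paths on a tiny instance
  brute <- function(X, thetas, motif, beta, gamma) {
    K <- length(thetas)
    E <- K + length(motif)
    exp_state <- c(seq_len(K), motif)
    is_base <- c(rep(TRUE, K), rep(FALSE, length(motif)))
    pos <- c(rep(0L, K), seq_along(motif))
    ll <- sapply(thetas, function(th) log_likelihood(X, th))
    Tn <- nrow(X)
    best <- Inf; best_s <- NULL
    paths <- as.matrix(expand.grid(rep(list(seq_len(E)), Tn)))
    for (r in seq_len(nrow(paths))) {
      p <- paths[r, ]
      # validity: start at entry, end at exit, legal transitions
      ok <- is_base[p[1]] || pos[p[1]] == 1L
      ok <- ok && (is_base[p[Tn]] || pos[p[Tn]] == length(motif))
      if (ok && Tn > 1) for (t in 2:Tn) {
        a <- p[t - 1]; b <- p[t]
        legal <- if (is_base[b] || pos[b] == 1L)
          is_base[a] || pos[a] == length(motif) || a == b
        else (!is_base[a] && pos[a] == pos[b] - 1L) || a == b
        if (!legal) { ok <- FALSE; break }
      }
      if (!ok) next
      cost <- sum(-ll[cbind(seq_len(Tn), exp_state[p])]) +
        beta * sum(exp_state[p][-1] != exp_state[p][-Tn]) +
        (-log(gamma)) * sum(is_base[p])
      if (cost < best) { best <- cost; best_s <- exp_state[p] }
    }
    list(cost = best, s = best_s)
  }
  set.seed(23)
  for (i in 1:5) {
    X <- matrix(rnorm(16), 8, 2)
    thetas <- lapply(1:2, function(k)
      sitmotif:::new_toeplitz_precision(crossprod(matrix(rnorm(4), 2, 2)) + diag(2),
                                        rnorm(2), 2, 1, TRUE, FALSE))
    motif <- c(1L, 2L, 1L)
    aw <- assign_with_motifs(X, thetas, list(motif), beta = 0.5, gamma = 0.6)
    ll <- sapply(thetas, function(th) log_likelihood(X, th))
    got_cost <- sum(-ll[cbind(1:8, aw$s)]) +
      0.5 * sum(aw$s[-1] != aw$s[-8]) + (-log(0.6)) * sum(!aw$in_motif)
    expect_equal(got_cost, brute(X, thetas, motif, 0.5, 0.6)$cost,
                 tolerance = 1e-9)
  }
})

test_that("gamma = 1 reduces to plain penalized assignment", {
  specs <- four_seated_specs()[1:3]
  sim <- simulate_state_sequence(specs, 900, dwell = 40, seed = 24)
  cop <- emit_cop(sim$states, specs, seed = 25)
  w <- stack_windows(cop, 5)
  tm <- fit_ticc(w, ticc_config(K = 3, w = 5, seed = 24))
  aw <- assign_with_motifs(w, tm$thetas, list(c(1L, 2L, 1L), c(2L, 3L, 2L)),
                           beta = 50, gamma = 1)
  expect_identical(aw$s, assign_states(w, tm$thetas, 50))
})

test_that("lower gamma pulls more measurements into motif instances", {
  specs <- four_seated_specs()[1:3]
  dyn <- office_dynamics()
  sim <- simulate_state_sequence(specs, 3000, dwell = dyn$dwell,
                                 planted_motif = c(1L, 2L, 1L), motif_rate = 3,
                                 trans = dyn$trans, seed = 26)
  cop <- emit_cop(sim$states, specs, seed = 27)
  w <- stack_windows(cop, 5)
  tm <- fit_ticc(w, ticc_config(K = 3, w = 5, seed = 26))
  fr <- vapply(c(1, 0.8, 0.4, 0.1), function(g)
    mean(assign_with_motifs(w, tm$thetas, list(c(1L, 2L, 1L)), 50, g)$in_motif),
    numeric(1))
  expect_true(all(diff(fr) >= 0))
  expect_gt(fr[4], fr[1])
})

test_that("gamma = 0 is rejected", {
  expect_error(masa_config(gamma = 0), "gamma")
  expect_error(assign_with_motifs(matrix(rnorm(10), 5, 2),
                                  list(sitmotif:::new_toeplitz_precision(
                                    diag(2), c(0, 0), 2, 1, TRUE, FALSE)),
                                  list(), 1, 0), "gamma")
})

test_that("fitted MASA model recovers a planted motif and audits constraints", {
  specs <- four_seated_specs()[1:3]
  dyn <- office_dynamics()
  sim <- simulate_state_sequence(specs, 10000, dwell = dyn$dwell,
                                 planted_motif = c(1L, 2L, 1L), motif_rate = 2,
                                 trans = dyn$trans, seed = 28)
  cop <- emit_cop(sim$states, specs, seed = 29)
  w <- stack_windows(cop, 5)
  tm <- fit_ticc(w, ticc_config(K = 3, w = 5, seed = 28))
  mm <- fit_masa(w, tm, masa_config(seed = 28))
  al <- align_states(tm$assignments, sim$states[w$t], 3)
  expect_equal(al$perm[mm$common_motif], c(1L, 2L, 1L))
  # objective trace is non-decreasing
  expect_true(all(diff(mm$objective) >= -1e-6 * abs(mm$objective[-1])))
  # constraint audit
  expect_true(all(mm$motifs$length > 2))
  expect_true(all(mm$motifs$count > mm$config$L))
  inst <- mm$instances[order(mm$instances$start), ]
  for (id in unique(inst$motif_id)) {
    ii <- inst[inst$motif_id == id, ]
    if (nrow(ii) > 1) expect_true(all(ii$start[-1] > ii$end[-nrow(ii)]))
  }
  # determinism
  mm2 <- fit_masa(w, tm, masa_config(seed = 28))
  expect_identical(mm$assignments, mm2$assignments)
  expect_identical(mm$motifs$key, mm2$motifs$key)
})

test_that("structureless data yields no strong motif", {
  # i.i.d. states with 1-sample runs: nothing recurs above chance structure
  specs <- four_seated_specs()[1:3]
  set.seed(30)
  states <- sample(1:3, 600, replace = TRUE)
  cop <- emit_cop(states, specs, seed = 31)
  w <- stack_windows(cop, 5)
  tm <- fit_ticc(w, ticc_config(K = 3, w = 5, beta = 0.5, seed = 30))
  mm <- fit_masa(w, tm, masa_config(L = 20L, seed = 30))
  expect_true(is.null(mm$motifs) || all(mm$motifs$count <= 40))
})

test_that("occurrence rate converts instances per sitting half-hour", {
  expect_equal(motif_occurrence_rate(4, 1), 2)
  expect_equal(motif_occurrence_rate(0, 2), 0)
  expect_equal(motif_occurrence_rate(data.frame(start = 1:3, end = 2:4), 1.5), 1)
  expect_warning(out <- motif_occurrence_rate(3, 0), "sitting")
  expect_true(is.na(out))
})

test_that("instance finding splits shared boundary runs without overlap", {
  s <- c(rep(1, 10), rep(2, 4), rep(1, 8), rep(2, 4), rep(1, 10))
  inst <- find_instances(s, c(1L, 2L, 1L))
  expect_equal(nrow(inst), 2)
  expect_equal(inst$start[1], 1)
  expect_equal(inst$end[2], 36)
  expect_gt(inst$start[2], inst$end[1])   # disjoint after the split
  expect_equal(nrow(find_instances(rep(1, 20), c(1L, 2L, 1L))), 0)
})
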