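test_that("window stacking respects runs and gaps", {
  s <- data.frame(t = 0:9, x = rnorm(10), y = rnorm(10), present = TRUE)
  w <- stack_windows(s, 5)
  expect_equal(nrow(w$X), 6)        # T - w + 1
  expect_equal(ncol(w$X), 10)
  expect_equal(w$t, 5:10)
  # w = 1 returns the raw samples
  w1 <- stack_windows(s, 1)
  expect_equal(w1$X[, 1], s$x)
  # an absent sample splits the series; short left run yields no window
  s$present[5] <- FALSE
  w2 <- stack_windows(s, 5)
  expect_equal(nrow(w2$X), 1)       # only samples 6..10 form one window
  expect_equal(unique(w2$run), 1L)
})

test_that("Gaussian log likelihood matches its closed form and integrates to 1", {
  th <- sitmotif:::new_toeplitz_precision(diag(10), rep(0, 10), 2, 5, TRUE, FALSE)
  expect_equal(log_likelihood(rep(0, 10), th), -5 * log(2 * pi))
  # monotone decay in distance from the mean
  d <- seq(0, 3, by = 0.5)
  ll <- vapply(d, function(a) log_likelihood(rep(a, 10), th), numeric(1))
  expect_true(all(diff(ll) < 0))
  # 2-D density integrates to 1 by quadrature
  P <- matrix(c(2, 0.5, 0.5, 1), 2, 2)
  th2 <- sitmotif:::new_toeplitz_precision(P, c(0.3, -0.2), 2, 1, TRUE, FALSE)
  g <- seq(-6, 6, length.out = 301)
  h <- g[2] - g[1]
  grid <- as.matrix(expand.grid(g, g))
  total <- sum(exp(log_likelihood(grid, th2))) * h^2
  expect_equal(total, 1, tolerance = 1e-3)
})

test_that("penalized assignment is the exact DP optimum", {
  brute_min <- function(cost, beta) {
    Tn <- nrow(cost); K <- ncol(cost)
    paths <- as.matrix(expand.grid(rep(list(seq_len(K)), Tn)))
    min(apply(paths, 1, function(p)
      sum(cost[cbind(seq_len(Tn), p)]) + beta * sum(diff(p) != 0)))
  }
  set.seed(11)
  for (i in 1:20) {
    Tn <- sample(4:8, 1); K <- sample(2:3, 1)
    X <- matrix(rnorm(Tn * 2), Tn, 2)
    thetas <- lapply(seq_len(K), function(k)
      sitmotif:::new_toeplitz_precision(crossprod(matrix(rnorm(4), 2, 2)) + diag(2),
                                        rnorm(2), 2, 1, TRUE, FALSE))
    beta <- runif(1, 0, 3)
    s <- assign_states(X, thetas, beta)
    cost <- -sapply(thetas, function(th) log_likelihood(X, th))
    got <- sum(cost[cbind(seq_len(Tn), s)]) + beta * sum(diff(s) != 0)
    expect_equal(got, brute_min(cost, beta))
  }
  # beta = 0 reduces to the pointwise argmax
  X <- matrix(rnorm(40), 20, 2)
  thetas <- lapply(1:3, function(k)
    sitmotif:::new_toeplitz_precision(diag(2) * k, rnorm(2), 2, 1, TRUE, FALSE))
  s0 <- assign_states(X, thetas, 0)
  ll <- sapply(thetas, function(th) log_likelihood(X, th))
  expect_equal(s0, apply(ll, 1, which.max))
  # an overwhelming penalty forces a constant path
  sInf <- assign_states(X, thetas, 1e9)
  expect_equal(length(unique(sInf)), 1L)
})

test_that("block-Toeplitz precision fitting has its closed-form limits", {
  set.seed(12)
  # unpenalized w = 1: inverse sample covariance
  X <- matrix(rnorm(2000), 1000, 2)
  tp <- fit_toeplitz_precision(X, lam = 0, w = 1)
  S <- crossprod(sweep(X, 2, colMeans(X))) / nrow(X)
  expect_equal(tp$theta, solve(S), tolerance = 1e-6)
  # heavy penalty (large relative to the member count, since the penalty is
  # applied once per cluster against a summed likelihood) zeroes off-diagonals
  Xc <- matrix(rnorm(600), 300, 2) %*% chol(matrix(c(1, .8, .8, 1), 2, 2))
  tps <- fit_toeplitz_precision(Xc, lam = 5000, w = 1)
  expect_equal(tps$theta[1, 2], 0)
  expect_gt(tps$theta[1, 1], 0)
  # assembled matrix is exactly block Toeplitz and positive definite
  X5 <- matrix(rnorm(5000), 500, 10)
  tp5 <- fit_toeplitz_precision(X5, lam = 0.001, w = 5)
  expect_identical(tp5$theta, assemble_toeplitz(tp5$blocks))
  expect_gt(min(eigen(tp5$theta, symmetric = TRUE, only.values = TRUE)$values), 0)
  # ridge fallback flagged when members are scarce
  tiny <- fit_toeplitz_precision(matrix(rnorm(50), 5, 10), 0.001, 5)
  expect_true(tiny$fallback)
})

test_that("AR(1) windows recover the analytic marginal precision", {
  set.seed(13)
  phi <- 0.5
  x <- as.numeric(arima.sim(list(ar = phi), 5000, sd = 1))
  X <- cbind(x[-5000], x[-1])          # w = 2, n = 1
  tp <- fit_toeplitz_precision(X, lam = 0.001, w = 2)
  s2 <- 1 / (1 - phi^2)
  target <- solve(matrix(c(s2, phi * s2, phi * s2, s2), 2, 2))
  expect_lt(norm(tp$theta - target, "F") / norm(target, "F"), 0.05)
})

test_that("TICC recovers two planted states and is deterministic", {
  base <- four_seated_specs()
  specs <- list(base[[1]],
                state_spec(2L, base[[3]]$precision, label = "big_sway"))
  sim <- simulate_state_sequence(specs, 1200, dwell = 60, seed = 14)
  cop <- emit_cop(sim$states, specs, seed = 15)
  w <- stack_windows(cop, 5)
  cfg <- ticc_config(K = 2, w = 5, beta = 50, lam = 0.001, seed = 16)
  m <- fit_ticc(w, cfg)
  truth <- sim$states[w$t]
  expect_gte(align_states(m$assignments, truth, 2)$acc, 0.95)
  m2 <- fit_ticc(w, cfg)
  expect_identical(m$assignments, m2$assignments)
  # K = 1 equals a single precision fit
  cfg1 <- ticc_config(K = 1, w = 5, seed = 1)
  m1 <- fit_ticc(w, cfg1)
  expect_equal(unique(m1$assignments), 1L)
  direct <- fit_toeplitz_precision(w$X, cfg1$lam, 5)
  expect_equal(m1$thetas[[1]]$theta, direct$theta, tolerance = 1e-8)
  # config validation
  expect_error(fit_ticc(list(X = w$X[1:5, ], run = rep(1L, 5)), cfg), "windows")
})

test_that("BIC follows its formula and penalizes duplicated clusters", {
  # direct formula: -2 lnL + k ln n
  X <- matrix(rnorm(400), 200, 2)
  w <- list(X = X, run = rep(1L, 200), t = 1:200, day = rep(1L, 200))
  m <- fit_ticc(w, ticc_config(K = 1, w = 1, lam = 0, seed = 1))
  ll <- sum(log_likelihood(X, m$thetas[[1]]))
  k_expected <- sum(abs(m$thetas[[1]]$theta[upper.tri(diag(2), diag = TRUE)]) > 1e-5) + 2
  expect_equal(ticc_bic(m, w), -2 * ll + k_expected * log(200))
  # duplicating a cluster leaves L unchanged but raises k, hence BIC
  m_dup <- m
  m_dup$thetas <- c(m$thetas, m$thetas)
  m_dup$config$K <- 2L
  expect_gt(ticc_bic(m_dup, w), ticc_bic(m, w))
})

test_that("K selection returns a full table and the single-K degenerate case", {
  set.seed(17)
  specs <- four_seated_specs()
  sim <- simulate_state_sequence(specs, 800, dwell = 50, seed = 17)
  cop <- emit_cop(sim$states, specs, seed = 18)
  w <- stack_windows(cop, 5)
  sel <- select_k(w, 3, ticc_config(w = 5, seed = 17))
  expect_equal(sel$k_best, 3)
  expect_equal(nrow(sel$table), 1)
  sel2 <- select_k(w, 2:3, ticc_config(w = 5, seed = 17))
  expect_equal(nrow(sel2$table), 2)
  expect_true(sel2$k_best %in% 2:3)
})
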