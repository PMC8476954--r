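#' TICC configuration
#'
#' Hyperparameters of the Toeplitz inverse-covariance clustering of the COP
#' series: `K` states, window `w` (5 samples), switching penalty `beta` (50)
#' and sparsity `lam` (0.001, a scalar broadcast over the off-diagonal of the
#' precision matrix).
#'
#' @param K number of clusters (>= 1).
#' @param w window length in samples (>= 1).
#' @param beta switching penalty (>= 0).
#' @param lam l1 sparsity level (>= 0).
#' @param max_iter maximum EM iterations.
#' @param tol stop when the fraction of changed assignments falls below this.
#' @param n_init number of seeded initializations; the fit with the lowest
#'   final objective is kept.
#' @param seed integer seed for the initialization.
#' @return object of class `ticc_config`.
#' @export
ticc_config <- function(K = 4L, w = 5L, beta = 50, lam = 0.001,
                        max_iter = 50L, tol = 0.001, n_init = 1L, seed = 1L) {
  stopifnot(K >= 1, w >= 1, beta >= 0, lam >= 0, n_init >= 1)
  structure(list(K = as.integer(K), w = as.integer(w), beta = beta, lam = lam,
                 max_iter = as.integer(max_iter), tol = tol,
                 n_init = as.integer(n_init), seed = as.integer(seed)),
            class = "ticc_config")
}

#' Stack a COP series into overlapping windows
#'
#' Each window concatenates `w` consecutive present samples
#' `(x, y)_{t-w+1}, ..., (x, y)_t` into an `n*w`-dimensional vector (sample-major
#' ordering, so block `k` offsets in the precision matrix correspond to a lag
#' of `k` seconds). The series is split at absent samples; runs shorter than
#' `w` contribute no windows.
#'
#' @param series a `cop_series` (or any data.frame with `x`, `y`, `present`),
#'   or a list of them (e.g. days); list elements become separate runs.
#' @param w window length.
#' @return list with `X` (matrix, one window per row), `run` (integer run id
#'   per window; the switching penalty does not apply across runs), `t` (end
#'   index of each window within its series), `day` (series index).
#' @export
stack_windows <- function(series, w) {
  stopifnot(w >= 1)
  if (is.data.frame(series)) series <- list(series)
  Xs <- list(); runs <- integer(0); ts <- integer(0); days <- integer(0)
  run_id <- 0L
  for (d in seq_along(series)) {
    s <- series[[d]]
    ok <- s$present & !is.na(s$x) & !is.na(s$y)
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in seq_along(r$lengths)) {
      if (!r$values[k] || r$lengths[k] < w) next
      run_id <- run_id + 1L
      idx <- starts[k]:ends[k]
      M <- cbind(s$x[idx], s$y[idx])
      nr <- length(idx) - w + 1L
      W <- matrix(0, nr, 2L * w)
      for (j in seq_len(w))
        W[, c(2L * j - 1L, 2L * j)] <- M[j:(j + nr - 1L), , drop = FALSE]
      Xs[[length(Xs) + 1L]] <- W
      runs <- c(runs, rep(run_id, nr))
      ts <- c(ts, idx[w:length(idx)])
      days <- c(days, rep(d, nr))
    }
  }
  list(X = if (length(Xs)) do.call(rbind, Xs) else matrix(0, 0, 2L * w),
       run = runs, t = ts, day = days)
}

# canonical parameter-group ids for a symmetric block-Toeplitz nw x nw matrix
# (n x n blocks, block (I,J) = A^(I-J) below the diagonal); group 0 entries are
# the unpenalized diagonal of A^(0)
toeplitz_groups <- function(n, w) {
  nw <- n * w
  i <- rep(seq_len(nw), times = nw)
  j <- rep(seq_len(nw), each = nw)
  I <- (i - 1L) %/% n; a <- (i - 1L) %% n
  J <- (j - 1L) %/% n; b <- (j - 1L) %% n
  k <- I - J
  aa <- ifelse(k >= 0L, a, b)
  bb <- ifelse(k >= 0L, b, a)
  k <- abs(k)
  sw <- k == 0L & aa > bb
  tmp <- aa[sw]; aa[sw] <- bb[sw]; bb[sw] <- tmp
  gid <- (k * n + aa) * n + bb + 1L
  diag_entry <- k == 0L & aa == bb
  list(gid = matrix(gid, nw, nw), penalized = matrix(!diag_entry, nw, nw))
}

#' Fit one cluster's block-Toeplitz sparse precision
#'
#' Solves the block-Toeplitz-constrained graphical lasso for the member
#' windows of one cluster: minimize
#' `(N/2) * (tr(S Theta) - log det Theta) + || lam o Theta ||_1`
#' subject to `Theta` symmetric block Toeplitz, by ADMM. The Theta-update is
#' the eigendecomposition closed form; the consensus update averages the
#' entries tied by the Toeplitz structure and soft-thresholds off-diagonal
#' groups. The cluster mean is estimated and windows are centered before
#' fitting. Returns a positive-definite, structure-exact precision.
#'
#' @param X member windows (matrix, rows = windows). With fewer than `n*w`
#'   members a ridge-regularized sample covariance is used (flagged in the
#'   result).
#' @param lam scalar l1 level (diagonal unpenalized).
#' @param w window length; `n` inferred as `ncol(X)/w`.
#' @param rho ADMM step size.
#' @param max_iter,abstol,reltol ADMM controls.
#' @param warn warn on non-convergence (the `converged` flag is always set;
#'   model fitters silence the per-solve warning and summarize instead).
#' @return object of class `toeplitz_precision` with elements `theta`
#'   (assembled matrix), `blocks` (list `A0..A(w-1)`), `mean`, `log_det`,
#'   `converged`, `fallback`.
#' @export
fit_toeplitz_precision <- function(X, lam, w, rho = 1,
                                   max_iter = 1000L, abstol = 1e-5, reltol = 1e-4,
                                   warn = TRUE) {
  X <- as.matrix(X)
  nw <- ncol(X)
  n <- nw %/% w
  stopifnot(n * w == nw)
  N <- nrow(X)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  S <- crossprod(Xc) / N
  fallback <- FALSE
  if (N < nw) {
    S <- S + diag(1e-3, nw)
    fallback <- TRUE
  }
  if (lam == 0 && w == 1L) {
    theta <- solve((S + t(S)) / 2)
    theta <- (theta + t(theta)) / 2
    return(new_toeplitz_precision(theta, mu, n, w, TRUE, fallback))
  }
  gr <- toeplitz_groups(n, w)
  gvec <- match(as.vector(gr$gid), sort(unique(as.vector(gr$gid))))
  gsize <- tabulate(gvec)
  pen <- as.vector(gr$penalized)
  # per-group threshold: sum of per-entry penalties / (rho * group size)
  # objective scaled by 1/N for ADMM conditioning (same minimizer):
  # (1/2)(tr(S Theta) - logdet Theta) + (1/N) ||lam o Theta||_1
  lam_g <- rowsum(ifelse(pen, lam, 0), gvec)[, 1]
  a <- 1 / 2
  # start rho on the scale of the solution so the proximal term bites
  rho <- rho * max(1, 1 / mean(diag(S)))
  Z <- diag(nw); U <- matrix(0, nw, nw)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # Theta-update: min a(tr(S Th) - logdet Th) + rho/2 ||Th - (Z - U)||^2
    D <- (rho * (Z - U) - a * S) / rho
    D <- (D + t(D)) / 2
    if (!all(is.finite(D))) {
      if (warn)
        warning("block-Toeplitz ADMM hit non-finite values; returning last iterate",
                call. = FALSE)
      break
    }
    e <- eigen(D, symmetric = TRUE)
    th <- (e$values + sqrt(e$values^2 + 4 * a / rho)) / 2
    Theta <- e$vectors %*% (th * t(e$vectors))
    # Z-update: Toeplitz-average then group soft-threshold
    V <- Theta + U
    vbar <- rowsum(as.vector(V), gvec)[, 1] / gsize
    zg <- soft_threshold(vbar, lam_g / (N * rho * gsize))
    Z_new <- matrix(zg[gvec], nw, nw)
    s_norm <- rho * norm(Z_new - Z, "F")
    Z <- Z_new
    U <- U + Theta - Z
    r_norm <- norm(Theta - Z, "F")
    eps_pri <- nw * abstol + reltol * max(norm(Theta, "F"), norm(Z, "F"))
    eps_dual <- nw * abstol + reltol * rho * norm(U, "F")
    if (r_norm < eps_pri && s_norm < eps_dual) { converged <- TRUE; break }
    # standard adaptive penalty (keeps primal and dual residuals balanced)
    if (r_norm > 10 * s_norm) { rho <- 2 * rho; U <- U / 2 }
    else if (s_norm > 10 * r_norm) { rho <- rho / 2; U <- 2 * U }
  }
  if (!converged && warn)
    warning("block-Toeplitz ADMM did not converge in ", max_iter,
            " iterations; returning best iterate", call. = FALSE)
  ev <- eigen(Z, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8) Z <- Z + diag(1e-8 - min(ev) + 1e-8, nw)
  new_toeplitz_precision(Z, mu, n, w, converged, fallback)
}

new_toeplitz_precision <- function(theta, mu, n, w, converged, fallback) {
  blocks <- lapply(0:(w - 1L), function(k)
    theta[(k * n + 1L):(k * n + n), 1:n, drop = FALSE])
  names(blocks) <- paste0("A", 0:(w - 1L))
  ld <- determinant(theta, logarithm = TRUE)
  structure(list(theta = theta, blocks = blocks, mean = mu, n = n, w = w,
                 log_det = as.numeric(ld$modulus), converged = converged,
                 fallback = fallback),
            class = "toeplitz_precision")
}

#' Assemble a block-Toeplitz matrix from its blocks
#'
#' @param blocks list `A0..A(w-1)` of n x n matrices (`A0` symmetric).
#' @return the `nw x nw` symmetric block-Toeplitz matrix with block `(I, J)`
#'   equal to `A^(I-J)` for `I > J` and its transpose above the diagonal.
#' @export
assemble_toeplitz <- function(blocks) {
  w <- length(blocks)
  n <- nrow(blocks[[1]])
  theta <- matrix(0, n * w, n * w)
  for (I in seq_len(w)) for (J in seq_len(w)) {
    k <- I - J
    B <- if (k >= 0) blocks[[k + 1L]] else t(blocks[[-k + 1L]])
    theta[((I - 1L) * n + 1L):(I * n), ((J - 1L) * n + 1L):(J * n)] <- B
  }
  theta
}

#' Gaussian log likelihood of windows under a cluster precision
#'
#' `-(1/2)(X - mu)' Theta (X - mu) + (1/2) log det Theta - (nw/2) log(2 pi)`.
#'
#' @param X window matrix (rows) or a single `nw`-vector.
#' @param theta a `toeplitz_precision`.
#' @return numeric vector of log densities.
#' @export
log_likelihood <- function(X, theta) {
  if (is.null(dim(X))) X <- matrix(X, 1)
  nw <- ncol(X)
  Xc <- sweep(X, 2, theta$mean)
  q <- rowSums((Xc %*% theta$theta) * Xc)
  -0.5 * q + 0.5 * theta$log_det - (nw / 2) * log(2 * pi)
}

# log-likelihood matrix: windows x clusters
ll_matrix <- function(X, thetas) {
  vapply(thetas, function(th) log_likelihood(X, th), numeric(nrow(X)))
}

#' Penalized state assignment by dynamic programming
#'
#' Finds the exact minimizer of
#' `sum_t [ -ll(X_t, Theta_{s_t}) + beta * 1(s_{t-1} != s_t) ]`
#' independently within each run (the penalty does not cross gaps). Ties are
#' broken toward the lower state id, then toward the previous state.
#'
#' @param windows result of [stack_windows()], or a window matrix.
#' @param thetas list of `toeplitz_precision` objects.
#' @param beta switching penalty (>= 0).
#' @param run optional run id vector when `windows` is a bare matrix.
#' @return integer state sequence, one entry per window.
#' @export
assign_states <- function(windows, thetas, beta, run = NULL) {
  if (is.list(windows) && !is.data.frame(windows) && !is.null(windows$X)) {
    X <- windows$X; run <- windows$run
  } else {
    X <- as.matrix(windows)
    if (is.null(run)) run <- rep(1L, nrow(X))
  }
  m <- nrow(X)
  if (m == 0) return(integer(0))
  K <- length(thetas)
  cost <- -ll_matrix(X, thetas)   # m x K
  s <- integer(m)
  for (r in unique(run)) {
    idx <- which(run == r)
    Tn <- length(idx)
    C <- matrix(0, Tn, K)
    bp <- matrix(0L, Tn, K)
    C[1, ] <- cost[idx[1], ]
    if (Tn > 1) for (t in 2:Tn) {
      prev <- C[t - 1, ]
      for (k in seq_len(K)) {
        cand <- prev + beta
        cand[k] <- prev[k]
        j <- which.min(cand)           # lowest state id at ties
        C[t, k] <- cand[j] + cost[idx[t], k]
        bp[t, k] <- j
      }
    }
    path <- integer(Tn)
    path[Tn] <- which.min(C[Tn, ])
    if (Tn > 1) for (t in Tn:2) path[t - 1] <- bp[t, path[t]]
    s[idx] <- path
  }
  s
}

# Eq.-style clustering objective: sparsity + sum over windows of
# (-ll + beta * switch indicator)
ticc_objective <- function(X, s, run, thetas, beta, lam) {
  ll <- ll_matrix(X, thetas)
  pick <- ll[cbind(seq_len(nrow(X)), s)]
  switches <- sum(s[-1] != s[-length(s)] & run[-1] == run[-length(run)])
  sparsity <- sum(vapply(thetas, function(th) {
    lam * sum(abs(th$theta[row(th$theta) != col(th$theta)]))
  }, numeric(1)))
  sparsity - sum(pick) + beta * switches
}

#' Fit the TICC model
#'
#' Alternates penalized dynamic-programming assignment ([assign_states()]) and
#' per-cluster block-Toeplitz sparse precision fitting
#' ([fit_toeplitz_precision()]) from a seeded Gaussian-mixture initialization,
#' until fewer than `tol` of assignments change or `max_iter` is reached.
#' Clusters that empty out are re-seeded from the worst-fit windows.
#'
#' @param windows result of [stack_windows()].
#' @param config a [ticc_config()].
#' @return object of class `ticc_model`: `thetas`, `assignments`, `objective`
#'   (per-iteration trace, non-increasing up to solver tolerance), `config`,
#'   `windows_n`.
#' @export
fit_ticc <- function(windows, config) {
  n_init <- config$n_init %||% 1L
  if (n_init > 1L) {
    seeds <- c(config$seed, vapply(seq_len(n_init - 1L), function(j)
      child_seed(config$seed, j), integer(1)))
    fits <- lapply(seeds, function(sd) {
      cfg <- config; cfg$seed <- sd; cfg$n_init <- 1L
      fit_ticc(windows, cfg)
    })
    best <- which.min(vapply(fits, function(f)
      utils::tail(f$objective, 1), numeric(1)))
    out <- fits[[best]]
    out$config <- config
    return(out)
  }
  X <- windows$X; run <- windows$run
  K <- config$K; w <- config$w
  nw <- ncol(X); n <- nw %/% w
  if (nrow(X) < K * nw)
    stopf("need at least K*n*w = %d windows, got %d", K * nw, nrow(X))
  set.seed(config$seed)
  s <- gmm_init(X, K)
  thetas <- NULL
  trace <- numeric(0)
  reseeded <- 0L
  for (it in seq_len(config$max_iter)) {
    for (k in seq_len(K)) {
      if (sum(s == k) == 0) {
        # re-seed an empty cluster from the worst-fit windows
        if (!is.null(thetas)) {
          best_ll <- apply(ll_matrix(X, thetas), 1, max)
          worst <- order(best_ll)[seq_len(min(2L * nw, nrow(X)))]
          s[worst] <- k
          reseeded <- reseeded + 1L
        } else s[sample.int(nrow(X), 2L * nw)] <- k
      }
    }
    thetas <- lapply(seq_len(K), function(k)
      fit_toeplitz_precision(X[s == k, , drop = FALSE], config$lam, w,
                             warn = FALSE))
    s_new <- assign_states(list(X = X, run = run), thetas, config$beta)
    trace <- c(trace, ticc_objective(X, s_new, run, thetas, config$beta, config$lam))
    changed <- mean(s_new != s)
    s <- s_new
    if (changed < config$tol) break
  }
  nc <- sum(!vapply(thetas, `[[`, logical(1), "converged"))
  if (nc > 0)
    warning(nc, " cluster precision solve(s) stopped before full ADMM ",
            "convergence; best iterates kept", call. = FALSE)
  structure(list(thetas = thetas, assignments = s, run = run,
                 objective = trace, config = config, windows_n = nrow(X),
                 reseeded = reseeded),
            class = "ticc_model")
}

# seeded GMM initialization on the stacked windows; large inputs are fitted
# on a subsample and extended to all windows by GMM prediction
gmm_init <- function(X, K, subsample = 2000L) {
  if (K == 1L) return(rep(1L, nrow(X)))
  sub <- if (nrow(X) > subsample) sample.int(nrow(X), subsample) else seq_len(nrow(X))
  fit <- tryCatch(
    Mclust(X[sub, , drop = FALSE], G = K, modelNames = "VVV", verbose = FALSE),
    error = function(e) NULL)
  if (!is.null(fit) && !is.null(fit$classification)) {
    cls <- tryCatch(
      as.integer(stats::predict(fit, newdata = X)$classification),
      error = function(e) NULL)
    if (!is.null(cls) && length(unique(cls)) == K) return(cls)
  }
  as.integer(stats::kmeans(X, centers = K, nstart = 5)$cluster)
}

#' Bayesian information criterion of a fitted TICC model
#'
#' `BIC = -2 ln L + k ln n`, with `L` the maximized likelihood of the windows
#' under their assigned clusters, `n` the number of windows, and `k` the
#' number of free parameters: per cluster, the unique nonzero entries
#' (|entry| > 1e-5) of the Toeplitz blocks (upper triangle of `A0` plus full
#' `A1..A(w-1)`) plus the `nw` mean parameters.
#'
#' @param model a `ticc_model`.
#' @param windows the windows it was fitted on.
#' @return the BIC value (smaller is better).
#' @export
ticc_bic <- function(model, windows) {
  X <- windows$X
  ll <- ll_matrix(X, model$thetas)
  logL <- sum(ll[cbind(seq_len(nrow(X)), model$assignments)])
  k <- sum(vapply(model$thetas, function(th) {
    nz <- 0L
    A0 <- th$blocks[[1]]
    nz <- nz + sum(abs(A0[upper.tri(A0, diag = TRUE)]) > 1e-5)
    if (th$w > 1) for (j in 2:th$w) nz <- nz + sum(abs(th$blocks[[j]]) > 1e-5)
    nz + length(th$mean)
  }, numeric(1)))
  -2 * logL + k * log(nrow(X))
}

#' Select the number of states by a BIC sweep
#'
#' Fits the model at each `K` in `k_range` and returns the BIC-minimizing `K`
#' together with the full table. Per-K fitting errors are recorded in the
#' table rather than propagated.
#'
#' @param windows result of [stack_windows()].
#' @param k_range integer vector of candidate `K`.
#' @param config a [ticc_config()]; its `K` is overridden per candidate.
#' @return list with `k_best` and `table` (columns `K`, `bic`, `error`).
#' @export
select_k <- function(windows, k_range, config) {
  stopifnot(length(k_range) >= 1)
  rows <- lapply(k_range, function(K) {
    cfg <- config; cfg$K <- as.integer(K)
    res <- tryCatch({
      m <- fit_ticc(windows, cfg)
      list(bic = ticc_bic(m, windows), error = NA_character_)
    }, error = function(e) list(bic = NA_real_, error = conditionMessage(e)))
    data.frame(K = K, bic = res$bic, error = res$error)
  })
  tab <- do.call(rbind, rows)
  ok <- which(!is.na(tab$bic))
  if (length(ok) == 0) stopf("all K values failed to fit")
  list(k_best = tab$K[ok[which.min(tab$bic[ok])]], table = tab)
}

#' Label fitted states semantically
#'
#' Post hoc naming by marginal variance: among clusters holding at least
#' `min_frac` of the windows, the smallest implied marginal variance is
#' labeled stable sitting and the largest big sway; everything else is
#' slight sway. Near-empty clusters are never labeled stable or big. This is
#' descriptive only and does not affect the model.
#'
#' @param model a `ticc_model`.
#' @param min_frac minimum occupancy share for the stable/big labels.
#' @return character vector of labels, one per cluster.
#' @export
label_states <- function(model, min_frac = 0.02) {
  v <- vapply(model$thetas, function(th) sum(diag(solve(th$theta))), numeric(1))
  share <- tabulate(model$assignments, length(v)) / length(model$assignments)
  lab <- rep("slight_sway", length(v))
  occ <- which(share >= min_frac)
  if (length(occ) == 0) occ <- seq_along(v)
  lab[occ[which.min(v[occ])]] <- "stable_sit"
  lab[occ[which.max(v[occ])]] <- "big_sway"
  lab
}

#' @export
print.ticc_model <- function(x, ...) {
  cat(sprintf("TICC model: K = %d, w = %d, beta = %g, lam = %g\n",
              x$config$K, x$config$w, x$config$beta, x$config$lam))
  cat(sprintf("  %d windows, %d EM iterations, final objective %.3f\n",
              x$windows_n, length(x$objective), utils::tail(x$objective, 1)))
  cat("  cluster sizes:", paste(tabulate(x$assignments, x$config$K), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.toeplitz_precision <- function(x, ...) {
  cat(sprintf("block-Toeplitz precision: n = %d, w = %d, log det = %.3f%s\n",
              x$n, x$w, x$log_det,
              if (x$fallback) " (ridge fallback)" else ""))
  invisible(x)
}
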