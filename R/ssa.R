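#' Social spider algorithm configuration
#'
#' Population metaheuristic in which candidate solutions (spiders) emit
#' fitness "vibrations" on a shared web; each spider follows the strongest
#' vibration it perceives, attenuated by distance, with a partially
#' randomized (masked) walk. `r_a` controls attenuation, `p_c` the mask
#' change probability base, `p_m` the per-dimension mask probability.
#'
#' @param pop_size number of spiders (>= 2).
#' @param max_iter iterations.
#' @param r_a vibration attenuation rate (> 0).
#' @param p_c probability base of keeping the dimension mask.
#' @param p_m per-dimension mask probability.
#' @param seed integer seed.
#' @return object of class `ssa_config`.
#' @export
ssa_config <- function(pop_size = 20L, max_iter = 10L, r_a = 1, p_c = 0.7,
                       p_m = 0.1, seed = 1L) {
  stopifnot(pop_size >= 2, max_iter >= 1, r_a > 0,
            p_c > 0, p_c < 1, p_m > 0, p_m < 1)
  structure(list(pop_size = as.integer(pop_size), max_iter = as.integer(max_iter),
                 r_a = r_a, p_c = p_c, p_m = p_m, seed = as.integer(seed)),
            class = "ssa_config")
}

#' Minimize a function with the social spider algorithm
#'
#' Box-constrained continuous minimization. Per iteration: fitness is turned
#' into vibration source intensity `log(1/(f - C) + 1)` (with `C` below the
#' current minimum), propagated to every spider attenuated by
#' `exp(-d / (sd_bar * r_a))` over Manhattan distance `d`; each spider adopts
#' the strongest perceived vibration as its target if it beats the stored
#' one, refreshes its dimension mask with probability `1 - p_c^c` (where `c`
#' counts iterations since the target changed), and random-walks toward the
#' masked target. Positions are clamped to the box. Non-finite objective
#' values cause the position to be resampled. The best-ever position is
#' tracked (elitist report), so the best-so-far trace is non-increasing.
#'
#' @param fn objective to minimize (takes a numeric vector).
#' @param lower,upper finite bound vectors.
#' @param config an [ssa_config()].
#' @return list with `par`, `value`, `trace` (best-so-far per iteration) and
#'   `resampled` (count of non-finite evaluations).
#' @export
ssa_optimize <- function(fn, lower, upper, config = ssa_config()) {
  stopifnot(length(lower) == length(upper), all(is.finite(lower)),
            all(is.finite(upper)), all(upper > lower))
  d <- length(lower)
  set.seed(config$seed)
  np <- config$pop_size
  P <- matrix(stats::runif(np * d, rep(lower, each = np), rep(upper, each = np)),
              np, d)
  prev_move <- matrix(0, np, d)
  mask <- matrix(FALSE, np, d)
  eval_all <- function(M) {
    f <- apply(M, 1, function(p) {
      v <- suppressWarnings(fn(p))
      if (length(v) != 1 || !is.finite(v)) NA_real_ else v
    })
    f
  }
  resampled <- 0L
  f <- eval_all(P)
  while (anyNA(f)) {
    bad <- which(is.na(f))
    resampled <- resampled + length(bad)
    P[bad, ] <- matrix(stats::runif(length(bad) * d, rep(lower, each = length(bad)),
                                    rep(upper, each = length(bad))),
                       length(bad), d)
    f[bad] <- eval_all(P[bad, , drop = FALSE])
  }
  best_par <- P[which.min(f), ]
  best_val <- min(f)
  tgt_fit <- rep(Inf, np)
  tgt_pos <- P
  inactive <- rep(0L, np)
  trace <- numeric(config$max_iter)
  for (it in seq_len(config$max_iter)) {
    # vibration source intensity: decreasing in fitness, positive
    C <- min(f) - 1e-10 * max(1, abs(min(f)))
    intensity <- log(1 / (f - C) + 1)
    sd_bar <- mean(apply(P, 2, stats::sd))
    if (!is.finite(sd_bar) || sd_bar <= 0) sd_bar <- 1e-12
    D <- as.matrix(stats::dist(P, method = "manhattan"))
    recv <- outer(rep(1, np), intensity) * exp(-D / (sd_bar * config$r_a))
    # attenuation picks which current vibration each spider hears best;
    # the stored target is replaced when that source is fitter than it
    best_src <- apply(recv, 1, which.max)
    upd <- f[best_src] < tgt_fit
    tgt_fit[upd] <- f[best_src[upd]]
    tgt_pos[upd, ] <- P[best_src[upd], , drop = FALSE]
    inactive <- ifelse(upd, 0L, inactive + 1L)
    # dimension mask refresh
    refresh <- stats::runif(np) > config$p_c^inactive
    if (any(refresh)) {
      mask[refresh, ] <- matrix(stats::runif(sum(refresh) * d) < config$p_m,
                                sum(refresh), d)
      # a mask of all ones degenerates to a pure random walk; flip one bit
      allone <- refresh & rowSums(mask) == d
      if (any(allone))
        mask[cbind(which(allone), sample.int(d, sum(allone), replace = TRUE))] <- FALSE
    }
    # masked following position: target where mask is 0, a random spider where 1
    rnd <- matrix(0, np, d)
    for (j in seq_len(d)) rnd[, j] <- P[sample.int(np, np, replace = TRUE), j]
    P_fo <- ifelse(mask, rnd, tgt_pos)
    R <- matrix(stats::runif(np * d), np, d)
    move <- prev_move * stats::runif(np) + (P_fo - P) * R
    P_new <- clamp(P + move, rep(lower, each = np), rep(upper, each = np))
    prev_move <- P_new - P
    P <- P_new
    f <- eval_all(P)
    while (anyNA(f)) {
      bad <- which(is.na(f))
      resampled <- resampled + length(bad)
      P[bad, ] <- matrix(stats::runif(length(bad) * d,
                                      rep(lower, each = length(bad)),
                                      rep(upper, each = length(bad))),
                         length(bad), d)
      f[bad] <- eval_all(P[bad, , drop = FALSE])
    }
    if (min(f) < best_val) {
      best_val <- min(f)
      best_par <- P[which.min(f), ]
    }
    trace[it] <- best_val
  }
  list(par = best_par, value = best_val, trace = trace, resampled = resampled)
}
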