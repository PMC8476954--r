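#' MASA configuration
#'
#' Controls of the motif-aware state assignment: `gamma` in (0, 1] is the
#' per-measurement cost of lying outside any motif instance (log gamma is
#' added for non-motif measurements, so lower gamma pushes more measurements
#' into motifs), `L` the minimum non-overlapping occurrence count a candidate
#' motif must exceed, `max_len` the maximum motif length in compressed states.
#'
#' @param gamma non-motif cost in (0, 1]; 1 disables the motif pull.
#' @param L minimum occurrence count (a motif must appear more than `L` times).
#' @param beta switching penalty, shared with the clustering step.
#' @param max_len maximum motif length (compressed states).
#' @param n_motifs number of top-scored candidates carried into assignment.
#' @param max_iter,tol EM controls.
#' @param seed integer seed.
#' @return object of class `masa_config`.
#' @export
masa_config <- function(gamma = 0.9, L = 5L, beta = 50, max_len = 6L,
                        n_motifs = 3L, max_iter = 10L, tol = 1e-4, seed = 1L) {
  if (gamma < 0 || gamma > 1) stopf("gamma must be in [0, 1]")
  if (gamma == 0) stopf("gamma = 0 forbids any non-motif assignment; use gamma > 0")
  stopifnot(L >= 1, max_len > 2)
  structure(list(gamma = gamma, L = as.integer(L), beta = beta,
                 max_len = as.integer(max_len), n_motifs = as.integer(n_motifs),
                 max_iter = as.integer(max_iter), tol = tol,
                 seed = as.integer(seed)),
            class = "masa_config")
}

#' Run-length compress a state sequence
#'
#' Merges neighboring occurrences of the same state into one.
#'
#' @param s integer state sequence.
#' @return list with `states` (compressed sequence) and `lengths` (run
#'   lengths); [decompress_states()] is the exact inverse.
#' @export
compress_states <- function(s) {
  r <- rle(s)
  list(states = r$values, lengths = r$lengths)
}

#' @rdname compress_states
#' @param compressed result of [compress_states()].
#' @export
decompress_states <- function(compressed) {
  rep(compressed$states, times = compressed$lengths)
}

# greedy left-to-right count of non-overlapping occurrences of pattern `m`
# in compressed sequence `cs` (both integer vectors). When the pattern starts
# and ends on the same state, adjacent occurrences may share that boundary
# entry: the underlying run of measurements is split between the two
# instances, which keeps them non-overlapping in measurement space.
count_nonoverlapping <- function(cs, m) {
  lm <- length(m)
  n <- length(cs)
  if (n < lm) return(0L)
  # candidate start positions where the full pattern matches
  hit <- rep(TRUE, n - lm + 1L)
  for (j in seq_len(lm)) hit <- hit & cs[j:(n - lm + j)] == m[j]
  starts <- which(hit)
  stride <- lm - (m[1] == m[lm])
  cnt <- 0L; nextfree <- 1L
  for (s in starts) {
    if (s >= nextfree) { cnt <- cnt + 1L; nextfree <- s + stride }
  }
  cnt
}

#' Enumerate candidate motifs from compressed state sequences
#'
#' All contiguous subsequences of length > 2 and <= `max_len` of the
#' compressed sequence(s), counted by greedy left-to-right non-overlapping
#' matching; candidates with count > `L` survive. With several sequences
#' (days) counts are summed, matching per-cohort motif discovery.
#'
#' @param compressed a [compress_states()] result, or a list of them.
#' @param L minimum occurrence count (strict).
#' @param max_len maximum motif length.
#' @return data.frame with list-column `motif`, plus `key`, `length`, `count`,
#'   ordered by decreasing count.
#' @export
enumerate_candidates <- function(compressed, L, max_len = 6L) {
  stopifnot(L >= 1)
  if (!is.null(compressed$states)) compressed <- list(compressed)
  seqs <- lapply(compressed, `[[`, "states")
  all_keys <- unlist(lapply(seqs, function(cs) {
    n <- length(cs)
    unlist(lapply(3:max_len, function(len) {
      if (n < len) return(character(0))
      E <- stats::embed(cs, len)[, len:1, drop = FALSE]
      do.call(paste, c(as.data.frame(E), sep = "-"))
    }))
  }))
  # raw occurrence count bounds the non-overlapping count from above
  tab <- table(all_keys)
  keys <- names(tab)[tab > L]
  if (length(keys) == 0)
    return(data.frame(motif = I(list()), key = character(0),
                      length = integer(0), count = integer(0)))
  motifs <- lapply(strsplit(keys, "-", fixed = TRUE), as.integer)
  counts <- vapply(motifs, function(m)
    sum(vapply(seqs, count_nonoverlapping, integer(1), m = m)), integer(1))
  keep <- counts > L
  motifs <- motifs[keep]; keys <- keys[keep]; counts <- counts[keep]
  # a two-state alternation has no intrinsic phase (1-2-1 and 2-1-2 describe
  # the same recurring pattern); keep only the phase anchored on the state
  # with the larger total dwell time (in sitting data, stable sitting)
  if (length(motifs) > 0) {
    wt <- tapply(unlist(lapply(compressed, `[[`, "lengths")),
                 unlist(lapply(compressed, `[[`, "states")), sum)
    canon <- vapply(motifs, function(m) {
      st <- unique(m)
      if (length(st) != 2) return(TRUE)
      anchor <- st[order(-wt[as.character(st)], st)][1]
      m[1] == anchor
    }, logical(1))
    motifs <- motifs[canon]; keys <- keys[canon]; counts <- counts[canon]
  }
  out <- data.frame(key = keys, length = lengths(motifs), count = counts)
  out$motif <- I(motifs)
  out <- out[order(-out$count, out$length, out$key),
             c("motif", "key", "length", "count")]
  rownames(out) <- NULL
  out
}

#' Score a motif
#'
#' The strength of a motif is how often it appears in the dataset: the score
#' is its non-overlapping occurrence count. It is strictly increasing in the
#' count and zero for an unseen motif. Rankings break score ties toward the
#' shorter motif. (Length or null-model surprisal multipliers were
#' deliberately left out: a surprisal factor promotes rare-state variants of
#' the dominant alternation over the alternation itself, and a length factor
#' lets any longer pattern containing the motif hijack its occurrences.)
#'
#' @param motif integer state sequence.
#' @param count number of (non-overlapping) instances.
#' @return the score (>= 0).
#' @export
score_motif <- function(motif, count) {
  if (count == 0) return(0)
  as.numeric(count)
}

#' Locate motif instances in a state sequence
#'
#' Greedy left-to-right matching of the motif against the run-length
#' compressed sequence, mapped back to measurement indices. Adjacent
#' occurrences sharing a boundary run (motif starting and ending on the same
#' state) split that run between the two instances, so instances never
#' overlap in measurement space.
#'
#' @param s integer state sequence (one run; split at gaps beforehand).
#' @param motif integer state sequence of the motif.
#' @param offset index offset added to the returned positions.
#' @return data.frame with `start`, `end` (inclusive measurement indices).
#' @export
find_instances <- function(s, motif, offset = 0L) {
  comp <- compress_states(s)
  cs <- comp$states
  lens <- comp$lengths
  run_start <- cumsum(c(1L, lens[-length(lens)]))
  run_end <- cumsum(lens)
  lm <- length(motif)
  n <- length(cs)
  out <- data.frame(start = integer(0), end = integer(0))
  if (n < lm) return(out)
  hit <- rep(TRUE, n - lm + 1L)
  for (j in seq_len(lm)) hit <- hit & cs[j:(n - lm + j)] == motif[j]
  starts <- which(hit)
  stride <- lm - (motif[1] == motif[lm])
  picked <- integer(0); nextfree <- 1L
  for (p in starts) {
    if (p >= nextfree) { picked <- c(picked, p); nextfree <- p + stride }
  }
  if (length(picked) == 0) return(out)
  m_start <- run_start[picked]
  m_end <- run_end[picked + lm - 1L]
  # split a run shared by two adjacent instances at its midpoint
  if (length(picked) > 1) {
    shared <- which(picked[-1] == picked[-length(picked)] + stride &
                      stride < lm)
    for (i in shared) {
      rs <- run_start[picked[i] + lm - 1L]; re <- run_end[picked[i] + lm - 1L]
      mid <- rs + (re - rs) %/% 2
      m_end[i] <- mid
      m_start[i + 1L] <- mid + 1L
    }
  }
  data.frame(start = m_start + offset, end = m_end + offset)
}

#' Motif-aware state assignment
#'
#' Decodes the state sequence maximizing the per-measurement part of the
#' motif-aware objective, `sum_t [ ll(X_t | Theta_{S_t})
#' - beta 1(S_{t-1} != S_t) + log(gamma) 1(S_t outside any motif) ]`,
#' exactly, by dynamic programming over an expanded state space: the K
#' ordinary states plus one position per motif entry. A motif instance must be
#' traversed completely (entered at its first position, left from its last),
#' so emitted instances are complete and non-overlapping by construction.
#'
#' @param windows result of [stack_windows()] (or bare matrix with `run`).
#' @param thetas list of `toeplitz_precision` objects.
#' @param motifs list of integer motif vectors (each length > 2, adjacent
#'   entries distinct), possibly empty.
#' @param beta switching penalty.
#' @param gamma non-motif cost in (0, 1].
#' @param run run ids when `windows` is a bare matrix.
#' @return list with `s` (underlying state per window), `instances`
#'   (data.frame `motif_id`, `start`, `end`, window row indices, inclusive)
#'   and `in_motif` (logical per window).
#' @export
assign_with_motifs <- function(windows, thetas, motifs, beta, gamma, run = NULL) {
  if (is.list(windows) && !is.data.frame(windows) && !is.null(windows$X)) {
    X <- windows$X; run <- windows$run
  } else {
    X <- as.matrix(windows)
    if (is.null(run)) run <- rep(1L, nrow(X))
  }
  if (gamma <= 0) stopf("gamma = 0 forbids any non-motif assignment; use gamma > 0")
  K <- length(thetas)
  m <- nrow(X)
  if (m == 0) return(list(s = integer(0),
                          instances = data.frame(motif_id = integer(0),
                                                 start = integer(0), end = integer(0)),
                          in_motif = logical(0)))
  for (mo in motifs) {
    if (length(mo) <= 2) stopf("motifs must contain more than two states")
    if (any(mo[-1] == mo[-length(mo)])) stopf("motif has equal adjacent states")
    if (any(!mo %in% seq_len(K))) stopf("motif references unknown state id")
  }
  # expanded state table: base states then motif positions
  exp_state <- seq_len(K)                 # underlying state of each expanded state
  exp_motif <- rep(0L, K)                 # 0 = base
  exp_pos <- rep(0L, K)
  for (i in seq_along(motifs)) {
    exp_state <- c(exp_state, motifs[[i]])
    exp_motif <- c(exp_motif, rep(i, length(motifs[[i]])))
    exp_pos <- c(exp_pos, seq_along(motifs[[i]]))
  }
  E <- length(exp_state)
  is_base <- exp_motif == 0L
  is_entry <- is_base | exp_pos == 1L
  is_exit <- is_base
  for (i in seq_along(motifs))
    is_exit[which(exp_motif == i & exp_pos == length(motifs[[i]]))] <- TRUE
  nonmotif_cost <- ifelse(is_base, -log(gamma), 0)
  # infinitesimal entry cost by motif list position: exact-cost ties between
  # overlapping motif representations resolve toward the earlier (stronger)
  # motif instead of arbitrarily
  entry_eps <- ifelse(!is_base & exp_pos == 1L, 1e-9 * exp_motif, 0)
  ll <- ll_matrix(X, thetas)
  cost_e <- -ll[, exp_state, drop = FALSE] +
    matrix(nonmotif_cost + entry_eps, m, E, byrow = TRUE)
  # allowed predecessor list per expanded state
  preds <- vector("list", E)
  for (e in seq_len(E)) {
    if (is_entry[e]) {
      p <- which(is_exit)                         # from any base or motif end
    } else {
      p <- which(exp_motif == exp_motif[e] & exp_pos == exp_pos[e] - 1L)
    }
    preds[[e]] <- unique(c(e, p))                 # self first: dwell preferred
  }
  trans_pen <- lapply(seq_len(E), function(e)
    ifelse(preds[[e]] == e, 0, beta * (exp_state[preds[[e]]] != exp_state[e])))
  s <- integer(m); emask <- integer(m); epath <- integer(m)
  for (r in unique(run)) {
    idx <- which(run == r)
    Tn <- length(idx)
    C <- matrix(Inf, Tn, E); bp <- matrix(0L, Tn, E)
    start_ok <- is_entry
    C[1, start_ok] <- cost_e[idx[1], start_ok]
    if (Tn > 1) for (t in 2:Tn) {
      prev <- C[t - 1, ]
      for (e in seq_len(E)) {
        cand <- prev[preds[[e]]] + trans_pen[[e]]
        j <- which.min(cand)
        C[t, e] <- cand[j] + cost_e[idx[t], e]
        bp[t, e] <- preds[[e]][j]
      }
    }
    # path must end on an exit state (complete instance or base)
    final <- C[Tn, ]; final[!is_exit] <- Inf
    if (!any(is.finite(final)))
      stopf("no feasible assignment; check gamma > 0 and motif set")
    path <- integer(Tn)
    # prefer base states at ties so that gamma = 1 reduces to plain assignment
    ord <- order(final)
    path[Tn] <- ord[1]
    if (Tn > 1) for (t in Tn:2) path[t - 1] <- bp[t, path[t]]
    s[idx] <- exp_state[path]
    emask[idx] <- exp_motif[path]
    epath[idx] <- path
  }
  # instances: one per complete traversal of a motif's positions; adjacent
  # traversals of the same motif are split at the exit -> entry transition
  inst <- data.frame(motif_id = integer(0), start = integer(0), end = integer(0))
  if (length(motifs) > 0 && any(emask > 0L)) {
    mlen <- lengths(motifs)
    new_run <- c(TRUE, run[-1] != run[-m])
    prev_pos <- c(0L, exp_pos[epath[-m]])
    prev_mask <- c(0L, emask[-m])
    starts <- which(emask > 0L &
                      (new_run | prev_mask != emask |
                         (exp_pos[epath] == 1L & prev_pos == mlen[pmax(emask, 1L)])))
    ends <- c(starts[-1] - 1L, m)
    # trim each end to the last index of its own segment
    seg_end <- integer(length(starts))
    bound <- which(c(emask[-1] != emask[-m] | run[-1] != run[-m], TRUE))
    for (i in seq_along(starts))
      seg_end[i] <- min(c(bound[bound >= starts[i]], ends[i]))
    inst <- data.frame(motif_id = emask[starts], start = starts, end = seg_end)
  }
  list(s = s, instances = inst, in_motif = emask > 0L)
}

# full motif-aware objective (maximization form)
masa_objective <- function(X, s, run, thetas, beta, gamma, in_motif,
                           motif_scores, lam) {
  ll <- ll_matrix(X, thetas)
  pick <- sum(ll[cbind(seq_len(nrow(X)), s)])
  switches <- sum(s[-1] != s[-length(s)] & run[-1] == run[-length(run)])
  Rtheta <- sum(vapply(thetas, function(th)
    lam * sum(abs(th$theta[row(th$theta) != col(th$theta)])), numeric(1)))
  pick - beta * switches + log(gamma) * sum(!in_motif) + sum(motif_scores) - Rtheta
}

#' Fit the motif-aware state assignment model
#'
#' Starting from a fitted clustering, iterates: candidate motif enumeration on
#' the run-length-compressed assignment, motif-aware decoding
#' ([assign_with_motifs()]) with the top-scored candidates, and per-cluster
#' precision refitting, until the motif-aware objective stops improving.
#' A candidate motif set is only adopted if it does not decrease the
#' objective, so the objective trace is non-decreasing.
#'
#' @param windows result of [stack_windows()].
#' @param ticc_model a fitted `ticc_model`.
#' @param config a [masa_config()].
#' @return object of class `masa_model`: `thetas`, `assignments`, `motifs`
#'   (data.frame with scores, the top row is the common motif), `instances`,
#'   `objective` (trace), `config`.
#' @export
fit_masa <- function(windows, ticc_model, config) {
  X <- windows$X; run <- windows$run
  lam <- ticc_model$config$lam
  thetas <- ticc_model$thetas
  s <- ticc_model$assignments
  in_motif <- rep(FALSE, nrow(X))
  motifs_df <- NULL
  inst <- data.frame(motif_id = integer(0), start = integer(0), end = integer(0))
  obj <- masa_objective(X, s, run, thetas, config$beta, config$gamma, in_motif,
                        0, lam)
  trace <- obj
  current_motifs <- list()
  for (it in seq_len(config$max_iter)) {
    comp <- lapply(split(seq_along(s), run), function(idx) compress_states(s[idx]))
    cand <- enumerate_candidates(comp, config$L, config$max_len)
    if (nrow(cand) > 0) {
      cand$score <- mapply(score_motif, cand$motif, cand$count)
      cand <- cand[order(-cand$score, cand$length, cand$key), ]
      top <- utils::head(cand, config$n_motifs)
      new_motifs <- top$motif
    } else {
      cand$score <- numeric(0)
      new_motifs <- list()
    }
    aw <- assign_with_motifs(list(X = X, run = run), thetas, new_motifs,
                             config$beta, config$gamma)
    thetas_new <- lapply(seq_along(thetas), function(k) {
      members <- X[aw$s == k, , drop = FALSE]
      if (nrow(members) >= 2) fit_toeplitz_precision(members, lam,
                                                     ticc_model$config$w,
                                                     warn = FALSE)
      else thetas[[k]]
    })
    sc <- if (length(new_motifs))
      vapply(seq_along(new_motifs), function(i)
        score_motif(new_motifs[[i]], sum(aw$instances$motif_id == i)),
        numeric(1)) else numeric(0)
    obj_new <- masa_objective(X, aw$s, run, thetas_new, config$beta,
                              config$gamma, aw$in_motif, sc, lam)
    if (obj_new < obj - 1e-9 * max(1, abs(obj))) break  # keep monotone trace
    s <- aw$s; thetas <- thetas_new; in_motif <- aw$in_motif
    current_motifs <- new_motifs
    trace <- c(trace, obj_new)
    if (abs(obj_new - obj) < config$tol * max(1, abs(obj))) { obj <- obj_new; break }
    obj <- obj_new
  }
  # final ranking: re-enumerate on the converged assignment; the score is the
  # occurrence count of each retained motif, and instances come from greedy
  # pattern matching against the final state sequence
  comp <- lapply(split(seq_along(s), run), function(idx) compress_states(s[idx]))
  cand <- enumerate_candidates(comp, config$L, config$max_len)
  motifs_df <- NULL
  inst <- data.frame(motif_id = integer(0), start = integer(0), end = integer(0))
  if (nrow(cand) > 0) {
    cand$score <- mapply(score_motif, cand$motif, cand$count)
    cand <- cand[order(-cand$score, cand$length, cand$key), ]
    motifs_df <- utils::head(cand, config$n_motifs)
    rownames(motifs_df) <- NULL
    run_idx <- split(seq_along(s), run)
    inst <- do.call(rbind, lapply(seq_len(nrow(motifs_df)), function(i) {
      per_run <- lapply(run_idx, function(idx)
        find_instances(s[idx], motifs_df$motif[[i]], offset = idx[1] - 1L))
      found <- do.call(rbind, per_run)
      if (nrow(found) == 0) return(NULL)
      cbind(motif_id = i, found)
    }))
    if (is.null(inst))
      inst <- data.frame(motif_id = integer(0), start = integer(0), end = integer(0))
  }
  structure(list(thetas = thetas, assignments = s, run = run,
                 motifs = motifs_df, instances = inst, objective = trace,
                 in_motif = in_motif, config = config,
                 common_motif = if (!is.null(motifs_df) && nrow(motifs_df) > 0)
                   motifs_df$motif[[1]] else NULL),
            class = "masa_model")
}

#' Motif occurrence rate per 30 minutes of sitting
#'
#' @param n_instances number of motif instances on the day (or an instance
#'   data.frame, in which case its rows are counted).
#' @param sitting_hours hours of presence on the chair (> 0).
#' @return occurrences per 30 min; `NA` (with a warning) for zero sitting time.
#' @export
motif_occurrence_rate <- function(n_instances, sitting_hours) {
  if (is.data.frame(n_instances)) n_instances <- nrow(n_instances)
  if (sitting_hours <= 0) {
    warning("zero sitting time; motif rate undefined", call. = FALSE)
    return(NA_real_)
  }
  n_instances / (sitting_hours * 2)
}

#' @export
print.masa_model <- function(x, ...) {
  cat(sprintf("MASA model: gamma = %g, L = %d, %d instances\n",
              x$config$gamma, x$config$L, nrow(x$instances)))
  if (!is.null(x$common_motif))
    cat("  common motif:", paste(x$common_motif, collapse = "-"), "\n")
  else cat("  no motif survived the constraints\n")
  invisible(x)
}
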