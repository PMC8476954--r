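#' Exact Shapley feature attribution
#'
#' Exact coalition enumeration of
#' `phi_j = sum_{S subset F \ {j}} |S|!(|F|-|S|-1)!/|F|! * [f_{S+j} - f_S]`,
#' where `f_S(x)` is the interventional expectation: the model prediction
#' with the features in `S` fixed at the row's values and the rest
#' marginalized over the background rows. Supports vector-valued prediction
#' functions (per-class probabilities). Satisfies the efficiency axiom
#' `sum_j phi_j = f(x) - E[f]` exactly and the null-player axiom.
#'
#' @param predict_fn function taking a feature matrix and returning a numeric
#'   vector per row (matrix for multi-output, e.g. class probabilities).
#' @param row a single feature vector (named like the background columns).
#' @param background matrix/data.frame of background rows.
#' @return list with `phi` (matrix features x outputs), `base` (E[f]),
#'   `fx` (prediction at `row`).
#' @export
exact_shapley <- function(predict_fn, row, background) {
  background <- as.matrix(background)
  if (nrow(background) == 0) stopf("background must contain at least one row")
  p <- ncol(background)
  if (p > 12) stopf("exact enumeration supports at most 12 features")
  row <- as.numeric(row)
  stopifnot(length(row) == p)
  nS <- 2^p
  # value of every coalition: mean prediction with S fixed at `row`
  vals <- vector("list", nS)
  for (s in seq_len(nS) - 1L) {
    members <- which(bitwAnd(s, bitwShiftL(1L, 0:(p - 1L))) > 0L)
    Z <- background
    if (length(members)) Z[, members] <- matrix(row[members], nrow(Z),
                                                length(members), byrow = TRUE)
    pr <- predict_fn(Z)
    if (is.null(dim(pr))) pr <- matrix(pr, ncol = 1)
    vals[[s + 1L]] <- colMeans(pr)
  }
  n_out <- length(vals[[1]])
  phi <- matrix(0, p, n_out)
  fact <- factorial(0:p)
  for (j in seq_len(p)) {
    bit_j <- bitwShiftL(1L, j - 1L)
    for (s in seq_len(nS) - 1L) {
      if (bitwAnd(s, bit_j) > 0L) next
      sz <- sum(bitwAnd(s, bitwShiftL(1L, 0:(p - 1L))) > 0L)
      wgt <- fact[sz + 1L] * fact[p - sz] / fact[p + 1L]
      phi[j, ] <- phi[j, ] + wgt * (vals[[s + bit_j + 1L]] - vals[[s + 1L]])
    }
  }
  if (!is.null(colnames(background))) rownames(phi) <- colnames(background)
  colnames(phi) <- names(vals[[1]])
  list(phi = phi, base = vals[[1]], fx = vals[[nS]])
}

#' Shapley summary over evaluation rows
#'
#' Computes [exact_shapley()] for each row and aggregates the mean absolute
#' attribution per feature (per output and overall), the usual importance
#' ranking display.
#'
#' @param predict_fn,background as in [exact_shapley()].
#' @param rows matrix/data.frame of evaluation rows.
#' @return list with `mean_abs` (features x outputs), `overall` (named,
#'   sorted decreasing), `per_row` (list of phi matrices).
#' @export
shapley_summary <- function(predict_fn, rows, background) {
  rows <- as.matrix(rows)
  per_row <- lapply(seq_len(nrow(rows)), function(i)
    exact_shapley(predict_fn, rows[i, ], background)$phi)
  acc <- Reduce(`+`, lapply(per_row, abs)) / length(per_row)
  overall <- sort(rowMeans(acc), decreasing = TRUE)
  list(mean_abs = acc, overall = overall, per_row = per_row)
}
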