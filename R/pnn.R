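#' Fit a feature-weighted probabilistic neural network
#'
#' A Parzen-window density classifier: each class density is a Gaussian-kernel
#' sum over the class exemplars with smoothing `sigma`, and per-feature
#' weights `omega` rescale the kernel axes (the contour of the kernel becomes
#' elliptical; a larger weight makes the feature more influential). With all
#' weights at 1 this is the standard Parzen estimate. Features are
#' standardized (zero mean, unit sd computed on the training data) before the
#' kernel, and identically at prediction.
#'
#' @param x numeric matrix or data.frame of training features.
#' @param y class labels (factor or coercible).
#' @param sigma smoothing parameter (> 0).
#' @param omega per-feature weights (>= 0), default all 1.
#' @param standardize standardize features (default `TRUE`).
#' @return object of class `pnn_model`.
#' @export
pnn_fit <- function(x, y, sigma, omega = NULL, standardize = TRUE) {
  x <- as.matrix(x)
  if (sigma <= 0) stopf("sigma must be > 0")
  y <- as.factor(y)
  n <- ncol(x)
  if (is.null(omega)) omega <- rep(1, n)
  stopifnot(length(omega) == n, all(omega >= 0))
  if (standardize) {
    center <- colMeans(x)
    scale <- apply(x, 2, stats::sd)
    scale[scale == 0 | is.na(scale)] <- 1
  } else {
    center <- rep(0, n); scale <- rep(1, n)
  }
  xs <- sweep(sweep(x, 2, center), 2, scale, "/")
  exemplars <- split.data.frame(xs, y)
  if (any(vapply(exemplars, nrow, integer(1)) < 1))
    stopf("every class needs at least one exemplar")
  structure(list(exemplars = exemplars, classes = levels(y), sigma = sigma,
                 omega = omega, center = center, scale = scale, n = n),
            class = "pnn_model")
}

# log kernel-sum densities, rows = queries, cols = classes
pnn_log_density_matrix <- function(x, model) {
  x <- as.matrix(x)
  xs <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  n <- model$n; sigma <- model$sigma; w <- model$omega
  const <- -(n / 2) * log(2 * pi) - n * log(sigma)
  out <- matrix(NA_real_, nrow(xs), length(model$classes))
  xw <- sweep(xs, 2, w, "*")
  for (g in seq_along(model$classes)) {
    ew <- sweep(model$exemplars[[g]], 2, w, "*")
    # squared weighted distances query x exemplar
    d2 <- outer(rowSums(xw^2), rep(1, nrow(ew))) +
      outer(rep(1, nrow(xw)), rowSums(ew^2)) - 2 * xw %*% t(ew)
    ex <- -pmax(d2, 0) / (2 * sigma^2)
    mx <- apply(ex, 1, max)
    lse <- mx + log(rowSums(exp(ex - mx)))
    out[, g] <- const - log(nrow(ew)) + lse
  }
  colnames(out) <- model$classes
  out
}

#' Class-conditional PNN density at a point
#'
#' `p_g(x) = 1/((2 pi)^(n/2) sigma^n) * (1/l_g) *
#'   sum_i exp(-sum_j (w_j x_j - w_j x_ij)^2 / (2 sigma^2))`,
#' evaluated in log space with log-sum-exp.
#'
#' @param x a feature vector (or matrix of rows).
#' @param class class label (must be one of the model's classes).
#' @param model a `pnn_model`.
#' @param log return the log density.
#' @return density value(s).
#' @export
pnn_density <- function(x, class, model, log = FALSE) {
  if (is.null(dim(x))) x <- matrix(x, 1)
  g <- match(as.character(class), model$classes)
  if (is.na(g)) stopf("unknown class: %s", class)
  ld <- unname(pnn_log_density_matrix(x, model)[, g])
  if (log) ld else exp(ld)
}

#' Classify with a fitted PNN
#'
#' Picks the class maximizing `prior_g * p_g(x)`. Priors default to the
#' empirical class proportions of the training exemplars (the Bayes rule for
#' class-conditional kernel densities); pass `priors = "uniform"` or a
#' numeric vector to override. Ties go to the lowest class index.
#'
#' @param x feature vector or matrix of rows.
#' @param model a `pnn_model`.
#' @param priors `NULL` (empirical), `"uniform"`, or a numeric vector.
#' @return list with `class` (factor) and `prob` (matrix of normalized
#'   posterior scores).
#' @export
pnn_classify <- function(x, model, priors = NULL) {
  if (is.null(dim(x))) x <- matrix(x, 1)
  G <- length(model$classes)
  if (is.null(priors)) {
    l_g <- vapply(model$exemplars, nrow, integer(1))
    priors <- l_g / sum(l_g)
  } else if (identical(priors, "uniform")) priors <- rep(1 / G, G)
  priors <- priors / sum(priors)
  ld <- pnn_log_density_matrix(x, model)
  lp <- sweep(ld, 2, log(priors), "+")
  prob <- t(apply(lp, 1, function(r) {
    e <- exp(r - max(r)); e / sum(e)
  }))
  if (G == 1) prob <- matrix(prob, ncol = 1)
  colnames(prob) <- model$classes
  idx <- apply(lp, 1, which.max)   # first maximum = lowest class index
  list(class = factor(model$classes[idx], levels = model$classes), prob = prob)
}

#' Categorical cross-entropy
#'
#' `L = (1/N) sum_i -sum_g y_ig log p_ig`, probabilities renormalized per row
#' and floored at 1e-12.
#'
#' @param labels true labels (factor with levels matching `prob` columns).
#' @param prob matrix of class scores, one row per sample.
#' @return mean cross-entropy.
#' @export
cross_entropy <- function(labels, prob) {
  prob <- as.matrix(prob)
  prob <- prob / rowSums(prob)
  prob <- pmax(prob, 1e-12)
  labels <- factor(labels, levels = colnames(prob))
  p_true <- prob[cbind(seq_len(nrow(prob)), as.integer(labels))]
  mean(-log(p_true))
}

#' Inner-cross-validation objective for (sigma, omega)
#'
#' The tuning objective: the same `(sigma, omega)` is applied simultaneously
#' to all inner folds (PNN fitted on each fold's training part, scored by
#' cross-entropy on its validation part) and the fold losses are averaged.
#' A soft barrier discourages oversmoothing-prone small sigma: if
#' `sigma < 0.1` the penalty `10 * (0.1 - sigma) / 0.1` is added.
#'
#' @param params numeric vector `c(sigma, omega_1..omega_n)`.
#' @param x,y training features and labels.
#' @param folds integer fold id per row (fixed before optimization).
#' @param priors optional priors passed to the classifier.
#' @param standardize passed to [pnn_fit()]; set `FALSE` when the features
#'   were already standardized on the outer training set.
#' @return penalized mean validation cross-entropy.
#' @export
pnn_cv_objective <- function(params, x, y, folds, priors = NULL,
                             standardize = TRUE) {
  sigma <- params[1]
  omega <- params[-1]
  if (sigma <= 0) return(1e6)
  x <- as.matrix(x); y <- as.factor(y)
  losses <- vapply(sort(unique(folds)), function(f) {
    tr <- folds != f
    if (length(unique(y[tr])) < nlevels(y)) return(NA_real_)
    m <- pnn_fit(x[tr, , drop = FALSE], y[tr], sigma, omega,
                 standardize = standardize)
    pr <- pnn_classify(x[!tr, , drop = FALSE], m, priors)$prob
    cross_entropy(y[!tr], pr)
  }, numeric(1))
  pen <- if (sigma < 0.1) 10 * (0.1 - sigma) / 0.1 else 0
  mean(losses, na.rm = TRUE) + pen
}
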