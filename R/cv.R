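#' Stratified fold assignment
#'
#' Deals the shuffled members of each class round-robin over `k` folds, so
#' fold class proportions match the data within one sample.
#'
#' @param y labels.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer fold id per sample.
#' @export
make_stratified_folds <- function(y, k, seed = 1L) {
  y <- as.factor(y)
  cnt <- table(y)
  if (any(cnt < k))
    stopf(paste("class '%s' has %d member(s), fewer than %d folds;",
                "collect more data or re-seed the split"),
          names(cnt)[which.min(cnt)], min(cnt), k)
  set.seed(seed)
  folds <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    folds[idx] <- rep_len(sample(k), length(idx))
  }
  folds
}

# support-weighted one-vs-rest precision / recall / F1 plus accuracy
classification_metrics <- function(truth, pred) {
  truth <- as.factor(truth)
  pred <- factor(pred, levels = levels(truth))
  cm <- table(truth = truth, pred = pred)
  support <- rowSums(cm)
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  wt <- support / sum(support)
  c(accuracy = sum(tp) / sum(cm),
    precision = sum(wt * prec),
    recall = sum(wt * rec),
    f1 = sum(wt * f1))
}

#' Nested cross-validated SSA-PNN training
#'
#' For each of `outer_k` stratified outer folds: the social spider algorithm
#' tunes `(sigma, omega)` by minimizing the `inner_k`-fold validation
#' cross-entropy ([pnn_cv_objective()]) computed entirely inside the outer
#' training set; a final PNN is then fitted on the whole outer training set
#' with the tuned parameters and evaluated once on the untouched outer test
#' fold. Features are standardized on the outer training data. Outer-test
#' rows never reach the tuning objective.
#'
#' @param x feature matrix/data.frame (numeric).
#' @param y labels.
#' @param outer_k,inner_k fold counts (default 6 and 5).
#' @param ssa a [ssa_config()].
#' @param sigma_bounds,omega_bounds search boxes for sigma and each weight.
#' @param priors optional class priors.
#' @param seed integer seed for the fold splits.
#' @param return_models keep the per-fold fitted PNN and its standardization
#'   (needed by [shapley_cv()]).
#' @return list with `metrics` (accuracy, weighted precision/recall/F1 over
#'   the pooled outer-test predictions), `confusion` (raw counts),
#'   `confusion_norm` (row-normalized), `fold_params` (tuned sigma and omega
#'   per fold), `predictions`, and `fold_models` when requested.
#' @export
nested_cv_train <- function(x, y, outer_k = 6L, inner_k = 5L,
                            ssa = ssa_config(), sigma_bounds = c(0.01, 10),
                            omega_bounds = c(0, 5), priors = NULL, seed = 1L,
                            return_models = FALSE) {
  x <- as.matrix(x); y <- as.factor(y)
  n <- ncol(x)
  outer <- make_stratified_folds(y, outer_k, seed = seed)
  pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  fold_params <- list()
  fold_models <- list()
  for (f in sort(unique(outer))) {
    tr <- outer != f
    xt <- x[tr, , drop = FALSE]; yt <- y[tr]
    center <- colMeans(xt)
    scl <- apply(xt, 2, stats::sd); scl[scl == 0 | is.na(scl)] <- 1
    xt_s <- sweep(sweep(xt, 2, center), 2, scl, "/")
    inner <- make_stratified_folds(yt, inner_k, seed = child_seed(seed, f))
    obj <- function(p) pnn_cv_objective(p, xt_s, yt, inner, priors = priors,
                                        standardize = FALSE)
    cfg <- ssa; cfg$seed <- child_seed(seed, 100L + f)
    opt <- ssa_optimize(obj, lower = c(sigma_bounds[1], rep(omega_bounds[1], n)),
                        upper = c(sigma_bounds[2], rep(omega_bounds[2], n)),
                        config = cfg)
    sigma <- opt$par[1]; omega <- opt$par[-1]
    model <- pnn_fit(xt_s, yt, sigma, omega, standardize = FALSE)
    xe_s <- sweep(sweep(x[!tr, , drop = FALSE], 2, center), 2, scl, "/")
    pred[!tr] <- pnn_classify(xe_s, model, priors)$class
    fold_params[[length(fold_params) + 1L]] <-
      list(fold = f, sigma = sigma, omega = omega, inner_loss = opt$value)
    if (return_models)
      fold_models[[length(fold_models) + 1L]] <-
        list(fold = f, model = model, center = center, scale = scl,
             train = which(tr), test = which(!tr), priors = priors)
  }
  cm <- table(truth = y, pred = pred)
  list(metrics = classification_metrics(y, pred),
       confusion = cm,
       confusion_norm = sweep(cm, 1, pmax(rowSums(cm), 1), "/"),
       fold_params = fold_params,
       predictions = pred,
       fold_models = if (return_models) fold_models else NULL)
}

#' Fold-aggregated exact Shapley attribution
#'
#' Explains the cross-validated predictions: for each outer fold the
#' fold-specific PNN is attributed on its own held-out rows (background = the
#' fold's training rows), and mean absolute attributions are pooled across
#' folds. Aggregating over the fold models averages out weight
#' configurations that a single flat tuning run can land on, leaving the
#' consistently used features on top.
#'
#' @param cv result of [nested_cv_train()] with `return_models = TRUE`.
#' @param x the feature matrix the CV was run on.
#' @return list with `mean_abs` (features x classes, pooled over all rows)
#'   and `overall` (named vector, sorted decreasing).
#' @export
shapley_cv <- function(cv, x) {
  if (is.null(cv$fold_models)) stopf("run nested_cv_train with return_models = TRUE")
  x <- as.matrix(x)
  acc <- NULL; nrows <- 0L
  for (fm in cv$fold_models) {
    xs <- sweep(sweep(x, 2, fm$center), 2, fm$scale, "/")
    pf <- function(M) pnn_classify(M, fm$model, fm$priors)$prob
    sh <- shapley_summary(pf, xs[fm$test, , drop = FALSE],
                          xs[fm$train, , drop = FALSE])
    w <- length(fm$test)
    acc <- if (is.null(acc)) sh$mean_abs * w else acc + sh$mean_abs * w
    nrows <- nrows + w
  }
  acc <- acc / nrows
  rownames(acc) <- colnames(x)
  list(mean_abs = acc, overall = sort(rowMeans(acc), decreasing = TRUE))
}

#' Repeated stratified nested cross-validation
#'
#' Re-randomizes the fold splits per repeat and reports the distribution of
#' the four metrics (mean and sd), the aggregation used for headline
#' performance tables.
#'
#' @param x,y features and labels.
#' @param reps number of repeats.
#' @param ... passed to [nested_cv_train()].
#' @param seed base seed; repeat `r` uses a derived child seed.
#' @return list with `per_rep` (data.frame of metrics per repeat) and
#'   `summary` (data.frame: metric, mean, sd).
#' @export
repeat_cv <- function(x, y, reps = 200L, ..., seed = 1L) {
  stopifnot(reps >= 1)
  rows <- lapply(seq_len(reps), function(r) {
    res <- nested_cv_train(x, y, ..., seed = child_seed(seed, r))
    res$metrics
  })
  per_rep <- as.data.frame(do.call(rbind, rows))
  summary <- data.frame(metric = names(per_rep),
                        mean = vapply(per_rep, mean, numeric(1)),
                        sd = vapply(per_rep, stats::sd, numeric(1)),
                        row.names = NULL)
  list(per_rep = per_rep, summary = summary)
}
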