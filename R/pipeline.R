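#' Run the end-to-end sitting-behavior analysis
#'
#' Executes the whole chain on a cohort of per-day load-cell recordings:
#' preprocessing to 1 Hz COP series, state segmentation (fixed `K` or a BIC
#' sweep), motif discovery, per-day feature assembly, repeated nested
#' cross-validated SSA-PNN classification, exact Shapley attribution, and the
#' Kruskal-Wallis / Dunn comparison of motif rates across the three LBP-change
#' groups.
#'
#' @param cohort a [simulate_cohort()] result, or `NULL` to simulate from
#'   `spec`.
#' @param spec a [cohort_spec()] used when `cohort` is `NULL`.
#' @param ticc a [ticc_config()].
#' @param masa a [masa_config()].
#' @param k_sweep optional integer vector; when given, `K` is selected by BIC
#'   over this range before the final fit.
#' @param ssa an [ssa_config()] for the classifier tuning.
#' @param cv_reps repeats of the nested cross-validation.
#' @param outer_k,inner_k fold counts of the nested cross-validation.
#' @param seed integer seed.
#' @return a report list: `k`, `bic_table`, `ticc`, `masa`, `features`,
#'   `cv` (metric summary), `shapley` (overall ranking), `group_test`
#'   (Kruskal-Wallis + Dunn), `dropped_days`.
#' @export
run_pipeline <- function(cohort = NULL, spec = NULL, ticc = ticc_config(),
                         masa = masa_config(), k_sweep = NULL,
                         ssa = ssa_config(), cv_reps = 10L,
                         outer_k = 6L, inner_k = 5L, seed = 1L) {
  if (is.null(cohort)) {
    if (is.null(spec)) stopf("pipeline: provide a cohort or a cohort_spec")
    cohort <- simulate_cohort(spec)
  }
  if (is.null(cohort$loadcells)) stopf("pipeline: cohort has no load-cell signals")
  # stage: preprocess
  days <- lapply(cohort$loadcells, function(lc)
    downsample_1hz(compute_cop(lc)))
  # stage: segmentation
  windows <- stack_windows(days, ticc$w)
  bic_table <- NULL
  if (!is.null(k_sweep)) {
    sel <- tryCatch(select_k(windows, k_sweep, ticc),
                    error = function(e) stopf("segment stage failed: %s",
                                              conditionMessage(e)))
    ticc$K <- sel$k_best
    bic_table <- sel$table
  }
  tm <- tryCatch(fit_ticc(windows, ticc),
                 error = function(e) stopf("segment stage failed: %s",
                                           conditionMessage(e)))
  # stage: motifs
  mm <- tryCatch(fit_masa(windows, tm, masa),
                 error = function(e) stopf("motif stage failed: %s",
                                           conditionMessage(e)))
  # stage: per-day features
  day_keys <- names(days)
  inst_day <- if (nrow(mm$instances) > 0) windows$day[mm$instances$start] else integer(0)
  common_id <- if (!is.null(mm$motifs) && nrow(mm$motifs) > 0)
    which.max(mm$motifs$score) else NA_integer_
  summaries <- do.call(rbind, lapply(seq_along(days), function(d) {
    sit <- sitting_time(days[[d]])
    n_inst <- if (is.na(common_id)) 0L else
      sum(inst_day == d & mm$instances$motif_id == common_id)
    parts <- strsplit(day_keys[d], "_", fixed = TRUE)[[1]]
    data.frame(participant_id = parts[1], date = parts[2],
               sitting_hours = sit,
               motif_rate_30min = if (sit > 0)
                 motif_occurrence_rate(n_inst, sit) else NA_real_,
               has_motif = n_inst > 0)
  }))
  features <- build_feature_table(summaries, cohort$questionnaire,
                                  cohort$metadata)
  x <- as.matrix(features[, feature_columns()])
  y <- features$label
  # stage: classification
  cv <- repeat_cv(x, y, reps = cv_reps, outer_k = outer_k, inner_k = inner_k,
                  ssa = ssa, seed = child_seed(seed, 11L))
  # stage: attribution, pooled over the outer-fold models of one split
  cv_once <- nested_cv_train(x, y, outer_k = outer_k, inner_k = inner_k,
                             ssa = ssa, seed = child_seed(seed, 12L),
                             return_models = TRUE)
  shap <- shapley_cv(cv_once, x)
  # stage: group comparison of motif rates
  grp <- split(features$motif_rate_30min, features$label)
  grp <- grp[lengths(grp) > 0]
  kw <- kruskal_wallis(grp)
  dunn <- if (length(grp) >= 2) dunn_posthoc(grp) else NULL
  list(k = ticc$K, bic_table = bic_table, ticc = tm, masa = mm,
       features = features,
       motif_prevalence = mean(summaries$has_motif),
       cv = cv$summary, cv_per_rep = cv$per_rep,
       confusion = cv_once$confusion, confusion_norm = cv_once$confusion_norm,
       shapley = shap$overall, shapley_mean_abs = shap$mean_abs,
       group_test = list(kruskal_wallis = kw, dunn = dunn),
       dropped_days = attr(features, "dropped"),
       fold_params = cv_once$fold_params)
}
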