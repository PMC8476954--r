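#' Label the within-day change of low-back pain
#'
#' `d = morning - evening`: negative means the pain worsened over the day
#' (`exacerbated`), zero `no_change`, positive `improved`.
#'
#' @param morning,evening LBP scores on the 0--10 scale (vectors allowed).
#' @return factor with levels `exacerbated`, `no_change`, `improved`; `NA`
#'   where either score is missing.
#' @export
lbp_change_label <- function(morning, evening) {
  if (any(stats::na.omit(c(morning, evening)) < 0) ||
      any(stats::na.omit(c(morning, evening)) > 10))
    stopf("LBP scores must lie in [0, 10]")
  d <- morning - evening
  out <- ifelse(is.na(d), NA_character_,
                ifelse(d < 0, "exacerbated", ifelse(d == 0, "no_change", "improved")))
  factor(out, levels = c("exacerbated", "no_change", "improved"))
}

#' Assemble the per-day feature table
#'
#' Joins the per-day behavioral summaries (sitting hours, motif occurrence
#' rate) with the questionnaire-derived label and morning symptom scores and
#' the participant metadata. The label uses the first answered LBP slot of the
#' day as "morning" and the last answered slot as "end of day"; sleepiness and
#' fullness are taken from the morning slot. Days without both label slots or
#' with zero sitting time are dropped (count reported as attribute
#' `dropped`).
#'
#' @param day_summaries data.frame with `participant_id`, `date`,
#'   `sitting_hours`, `motif_rate_30min`.
#' @param questionnaire long data.frame as produced by [simulate_cohort()]:
#'   `participant_id`, `date`, `time_slot`, `lbp`, `sleepiness`, `fullness`.
#' @param metadata data.frame with `participant_id`, `sex`.
#' @return data.frame with the classifier schema, in fixed column order:
#'   `participant_id`, `date`, `sex`, `sitting_hours`, `motif_rate_30min`,
#'   `sleepiness`, `fullness`, `label`.
#' @export
build_feature_table <- function(day_summaries, questionnaire, metadata) {
  key <- function(d) paste(d$participant_id, d$date, sep = "|")
  qs <- split(questionnaire, key(questionnaire))
  rows <- list(); dropped <- 0L
  unmatched <- setdiff(key(day_summaries), names(qs))
  if (length(unmatched) > 0)
    stopf("no questionnaire for day(s): %s",
          paste(utils::head(unmatched, 5), collapse = ", "))
  if (!all(day_summaries$participant_id %in% metadata$participant_id))
    stopf("metadata missing participant(s): %s",
          paste(utils::head(setdiff(day_summaries$participant_id,
                                    metadata$participant_id), 5), collapse = ", "))
  for (i in seq_len(nrow(day_summaries))) {
    ds <- day_summaries[i, ]
    q <- qs[[key(ds)]]
    q <- q[order(q$time_slot), ]
    answered <- which(!is.na(q$lbp))
    if (length(answered) < 2 || is.na(ds$sitting_hours) || ds$sitting_hours <= 0) {
      dropped <- dropped + 1L
      next
    }
    morning <- answered[1]; evening <- answered[length(answered)]
    lab <- lbp_change_label(q$lbp[morning], q$lbp[evening])
    rows[[length(rows) + 1L]] <- data.frame(
      participant_id = ds$participant_id, date = ds$date,
      sex = metadata$sex[match(ds$participant_id, metadata$participant_id)],
      sitting_hours = ds$sitting_hours,
      motif_rate_30min = ds$motif_rate_30min,
      sleepiness = q$sleepiness[morning], fullness = q$fullness[morning],
      label = lab)
  }
  out <- do.call(rbind, rows)
  attr(out, "dropped") <- dropped
  out
}

#' Feature column order expected by the classifier
#' @export
feature_columns <- function() {
  c("sex", "sitting_hours", "motif_rate_30min", "sleepiness", "fullness")
}

#' Kruskal-Wallis rank test
#'
#' Rank-based omnibus comparison of two or more groups, with tie correction;
#' p-value from the chi-squared approximation with `groups - 1` degrees of
#' freedom (computed by [stats::kruskal.test()]).
#'
#' @param groups list of numeric vectors (each non-empty).
#' @return list with `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stopf("need at least two groups")
  if (any(lengths(groups) == 0)) stopf("all groups must be non-empty")
  if (length(unique(unlist(groups))) == 1)   # all values tied: H = 0 by definition
    return(list(H = 0, df = length(groups) - 1, p = 1))
  kt <- stats::kruskal.test(groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter), p = kt$p.value)
}

#' Dunn's post-hoc pairwise comparisons
#'
#' Pairwise z statistics from the pooled ranks with tie correction:
#' `z_ij = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T/(12(N-1))) (1/n_i + 1/n_j))`
#' with `T = sum(t^3 - t)` over tie groups; two-sided normal p-values,
#' unadjusted by default (Holm available).
#'
#' @param groups named list of numeric vectors (>= 2 groups).
#' @param p_adjust `"none"` (default) or any [stats::p.adjust()] method.
#' @return data.frame with `group1`, `group2`, `z`, `p`.
#' @export
dunn_posthoc <- function(groups, p_adjust = "none") {
  if (length(groups) < 2) stopf("need at least two groups")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_term
  rbar <- tapply(r, g, mean)[names(groups)]
  n <- lengths(groups)
  pairs <- utils::combn(names(groups), 2)
  z <- apply(pairs, 2, function(pr) {
    (rbar[pr[1]] - rbar[pr[2]]) /
      sqrt(s2 * (1 / n[pr[1]] + 1 / n[pr[2]]))
  })
  p <- 2 * stats::pnorm(-abs(z))
  p <- stats::p.adjust(p, method = p_adjust)
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = as.numeric(z),
             p = as.numeric(p), row.names = NULL)
}
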