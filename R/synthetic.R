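#' Define a sitting state for simulation
#'
#' A state is a recurring sitting pattern with its own 2-D Gaussian structure
#' on the COP increments: a symmetric positive-definite precision matrix (the
#' inverse covariance, which encodes the partial correlation between the
#' left-right and front-back axes), an optional per-second mean drift, and a
#' semantic label. The `off_chair` label marks the away-from-chair state, which
#' emits absent samples instead of COP coordinates.
#'
#' @param state_id integer id (1-based).
#' @param precision 2x2 symmetric positive-definite matrix.
#' @param mean_drift numeric length-2 per-second drift of the state mean.
#' @param label one of `"stable_sit"`, `"slight_sway"`, `"big_sway"`,
#'   `"off_chair"`.
#' @return an object of class `state_spec`.
#' @export
state_spec <- function(state_id, precision, mean_drift = c(0, 0),
                       label = c("stable_sit", "slight_sway", "big_sway", "off_chair")) {
  label <- match.arg(label)
  precision <- as.matrix(precision)
  stopifnot(nrow(precision) == ncol(precision), length(mean_drift) == nrow(precision))
  if (max(abs(precision - t(precision))) > 1e-8) stopf("precision must be symmetric")
  if (min(eigen(precision, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stopf("precision must be positive definite")
  structure(list(state_id = as.integer(state_id), precision = precision,
                 mean_drift = mean_drift, label = label),
            class = "state_spec")
}

#' Default four-state library for seated simulation
#'
#' Three seated states with increasing sway amplitude and different axis
#' couplings (stable sit, slight sway, big sway) plus the off-chair state.
#' Variances are on the kg-scaled COP coordinate of [compute_cop()].
#'
#' @param include_off_chair include the off-chair state as state 4.
#' @return list of `state_spec` objects.
#' @export
default_state_specs <- function(include_off_chair = TRUE) {
  prec <- function(sd1, sd2, rho) {
    S <- matrix(c(sd1^2, rho * sd1 * sd2, rho * sd1 * sd2, sd2^2), 2, 2)
    solve(S)
  }
  specs <- list(
    state_spec(1L, prec(0.15, 0.15, 0.20), label = "stable_sit"),
    state_spec(2L, prec(0.50, 0.40, -0.50), label = "slight_sway"),
    state_spec(3L, prec(1.50, 1.20, 0.60), label = "big_sway")
  )
  if (include_off_chair)
    specs[[4]] <- state_spec(4L, diag(2), label = "off_chair")
  specs
}

#' Background dynamics of a seated office day
#'
#' Default semi-Markov background for the three seated states: long stable
#' bouts (mean 15 min) punctuated by brief excursions -- either a slight sway
#' or a big repositioning sway (mean 30 s / 45 s) -- that return to stable
#' sitting. Recurring slight-sway micro-adjustment patterns (the motif) are
#' planted on top of this background by [simulate_state_sequence()].
#'
#' @return list with `dwell` (mean run length per state, s) and `trans`
#'   (background transition matrix over states 1..3).
#' @export
office_dynamics <- function() {
  trans <- matrix(c(0, 0.5, 0.5,
                    0.9, 0, 0.1,
                    0.9, 0.1, 0), 3, 3, byrow = TRUE)
  list(dwell = c(900, 30, 45), trans = trans)
}

#' Cohort specification for the synthetic study
#'
#' Bundles the knobs of the simulated cohort. `effect_size` scales the
#' category-specific shift of each day's true motif occurrence rate
#' (`improved` up by `1.7 * effect_size`, `exacerbated` down by
#' `0.4 * effect_size`, `no_change` untouched), so a positive effect makes
#' high motif rates more likely on improved days; at `effect_size = 1` the
#' category means reproduce the cohort pattern the analysis is designed to
#' detect (about 1.6 / 2.0 / 3.7 per 30 min).
#'
#' @param n_participants number of participants (>= 1).
#' @param days_per_participant recording days per participant.
#' @param motif planted motif as an integer state sequence (default `c(1,2,1)`,
#'   the stable-sit / slight-sway alternation).
#' @param base_rate baseline motif occurrences per 30 min of sitting.
#' @param effect_size scale of the category shifts (>= 0; 0 = no association).
#' @param noise_sd sd of the day-level motif rate around its category mean;
#'   one value per category (exacerbated, no change, improved) or a scalar.
#' @param label_probs probabilities of (exacerbated, no_change, improved) days.
#' @param sitting_mean,sitting_sd day sitting time distribution (hours).
#' @param day_hours length of the recorded office day (hours).
#' @param hz load-cell output rate (Hz).
#' @param sensor_noise_sd additive per-channel sensor noise (kg).
#' @param signals generate per-day load-cell series (set `FALSE` to produce
#'   only questionnaire and ground-truth tables, e.g. for classifier studies).
#' @param seed integer seed; all randomness flows through it.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 22L, days_per_participant = 4L,
                        motif = c(1L, 2L, 1L), base_rate = 2.0, effect_size = 1.0,
                        noise_sd = c(1.25, 1.92, 1.59),
                        label_probs = c(40, 43, 7) / 90,
                        sitting_mean = 5.58, sitting_sd = 1.93,
                        day_hours = 8, hz = 1L, sensor_noise_sd = 0.05,
                        signals = TRUE, seed = 1L) {
  if (n_participants < 1) stopf("n_participants must be >= 1")
  if (effect_size < 0) stopf("effect_size must be >= 0 (higher rate => improved)")
  stopifnot(length(label_probs) == 3, all(label_probs >= 0))
  structure(list(n_participants = as.integer(n_participants),
                 days_per_participant = as.integer(days_per_participant),
                 motif = as.integer(motif), base_rate = base_rate,
                 effect_size = effect_size, noise_sd = rep_len(noise_sd, 3L),
                 label_probs = label_probs / sum(label_probs),
                 sitting_mean = sitting_mean, sitting_sd = sitting_sd,
                 day_hours = day_hours, hz = as.integer(hz),
                 sensor_noise_sd = sensor_noise_sd, signals = isTRUE(signals),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a semi-Markov state path with planted motif instances
#'
#' Background dynamics are semi-Markov: geometric run lengths with mean
#' `dwell` (a scalar, or one mean per state), transitions to a different
#' state drawn uniformly or from the rows of `trans`. Motif instances (the
#' motif's states in order, each run 1--60 s, whole instance under 3 min) are
#' planted at Poisson-distributed count with expectation
#' `motif_rate * T / 1800` at uniformly random non-overlapping positions.
#'
#' @param specs list of `state_spec`s.
#' @param T sequence length in samples (1 Hz).
#' @param dwell mean background run length(s) in seconds; scalar or one value
#'   per spec (in spec order).
#' @param planted_motif integer state sequence to plant, or `NULL`.
#' @param motif_rate planted occurrences per 30 min.
#' @param trans optional background transition matrix (rows/cols in spec
#'   order, diagonal ignored); `NULL` means uniform over the other states.
#' @param seed integer seed.
#' @return list with `states` (integer length `T`) and `instances`
#'   (data.frame `start`, `end`, inclusive 1-based indices).
#' @export
simulate_state_sequence <- function(specs, T, dwell = 30, planted_motif = NULL,
                                    motif_rate = 0, trans = NULL, seed = 1L) {
  stopifnot(T > 0, all(dwell > 0))
  ids <- vapply(specs, function(s) s$state_id, integer(1))
  if (!is.null(planted_motif) && !all(planted_motif %in% ids))
    stopf("planted motif references unknown state id(s): %s",
          paste(setdiff(planted_motif, ids), collapse = ", "))
  dwell <- rep_len(dwell, length(ids))
  if (!is.null(trans))
    stopifnot(nrow(trans) == length(ids), ncol(trans) == length(ids))
  set.seed(seed)
  # background path
  states <- integer(T)
  pos <- 1L
  k <- sample(seq_along(ids), 1L)
  while (pos <= T) {
    len <- min(stats::rgeom(1, 1 / dwell[k]) + 1L, T - pos + 1L)
    states[pos:(pos + len - 1L)] <- ids[k]
    pos <- pos + len
    if (length(ids) > 1L) {
      p <- if (is.null(trans)) rep(1, length(ids)) else trans[k, ]
      p[k] <- 0
      k <- sample(seq_along(ids), 1L, prob = p)
    }
  }
  instances <- data.frame(start = integer(0), end = integer(0))
  if (!is.null(planted_motif) && motif_rate > 0) {
    n_inst <- stats::rpois(1, motif_rate * T / 1800)
    occupied <- rep(FALSE, T)
    starts <- integer(0); ends <- integer(0)
    tries <- 0L
    while (length(starts) < n_inst && tries < 50L * max(n_inst, 1L)) {
      tries <- tries + 1L
      runs <- sample(1:60, length(planted_motif), replace = TRUE)
      while (sum(runs) >= 180) runs <- pmax(1L, runs - 10L)  # keep instance < 3 min
      len <- sum(runs)
      if (len > T) next
      s <- sample.int(T - len + 1L, 1L)
      if (any(occupied[s:(s + len - 1L)])) next
      occupied[s:(s + len - 1L)] <- TRUE
      states[s:(s + len - 1L)] <- rep(planted_motif, times = runs)
      starts <- c(starts, s); ends <- c(ends, s + len - 1L)
    }
    ord <- order(starts)
    instances <- data.frame(start = starts[ord], end = ends[ord])
  }
  list(states = states, instances = instances)
}

#' Emit a COP series from a state path
#'
#' Draws each sample from the zero-mean Gaussian of its state's precision
#' (plus within-run accumulated drift). Off-chair states emit absent samples.
#'
#' @param state_seq integer state path at 1 Hz.
#' @param specs list of `state_spec`s covering every state in `state_seq`.
#' @param seed integer seed.
#' @param t0 first timestamp (s).
#' @return a `cop_series` data.frame (`t`, `x`, `y`, `present`).
#' @export
emit_cop <- function(state_seq, specs, seed = 1L, t0 = 0) {
  ids <- vapply(specs, function(s) s$state_id, integer(1))
  if (!all(state_seq %in% ids)) stopf("state path contains state with no spec")
  set.seed(seed)
  T <- length(state_seq)
  x <- numeric(T); y <- numeric(T); present <- rep(TRUE, T)
  spec_of <- specs[match(state_seq, ids)]
  r <- rle(state_seq)
  pos <- 1L
  for (k in seq_along(r$lengths)) {
    len <- r$lengths[k]
    sp <- specs[[match(r$values[k], ids)]]
    idx <- pos:(pos + len - 1L)
    if (sp$label == "off_chair") {
      x[idx] <- NA_real_; y[idx] <- NA_real_; present[idx] <- FALSE
    } else {
      Sig <- solve(sp$precision)
      L <- chol(Sig)
      z <- matrix(stats::rnorm(2L * len), len, 2L) %*% L
      drift <- outer(seq_len(len) - 1, sp$mean_drift)
      x[idx] <- z[, 1] + drift[, 1]
      y[idx] <- z[, 2] + drift[, 2]
    }
    pos <- pos + len
  }
  out <- data.frame(t = t0 + seq_len(T) - 1, x = x, y = y, present = present)
  class(out) <- c("cop_series", "data.frame")
  out
}

#' Render a COP series as four-channel load-cell output
#'
#' Inverts the corner-weighted COP formula: given total body weight `W` on the
#' seat and COP `(x, y)`, the symmetric corner solution is
#' `A_i = W/4 + cx_i * x + cy_i * y` with corner coordinates as in
#' [compute_cop()]. Additive Gaussian sensor noise is applied per channel and
#' negative loads are clipped at zero. Absent samples emit zero load (plus
#' noise). A COP outside the representable corner hull is clipped, with the
#' number of clips returned as an attribute.
#'
#' @param cop a `cop_series` at 1 Hz.
#' @param body_weight seated weight in kg (> 0).
#' @param hz output rate; each 1 Hz sample is replicated `hz` times.
#' @param seed integer seed.
#' @param noise_sd per-channel sensor noise sd in kg (default 0.05).
#' @return data.frame (`t`, `a1`..`a4`) with attribute `clip_count`.
#' @export
emit_loadcells <- function(cop, body_weight, hz = 1L, seed = 1L, noise_sd = 0.05) {
  stopifnot(body_weight > 0, hz >= 1)
  set.seed(seed)
  n <- nrow(cop)
  x <- ifelse(cop$present, cop$x, 0)
  y <- ifelse(cop$present, cop$y, 0)
  W <- ifelse(cop$present, body_weight, 0)
  A <- cbind(W / 4 - x + y, W / 4 - x - y, W / 4 + x + y, W / 4 + x - y)
  clip_count <- sum(A < 0)
  A <- pmax(A, 0)
  rep_idx <- rep(seq_len(n), each = hz)
  t_out <- rep(cop$t, each = hz) + rep(seq_len(hz) - 1L, times = n) / hz
  A <- A[rep_idx, , drop = FALSE]
  if (noise_sd > 0)
    A <- pmax(A + matrix(stats::rnorm(length(A), 0, noise_sd), nrow(A), 4), 0)
  out <- data.frame(t = t_out, a1 = A[, 1], a2 = A[, 2], a3 = A[, 3], a4 = A[, 4])
  attr(out, "clip_count") <- clip_count
  out
}

# split P present seconds into a day with absent breaks; returns state path with
# off-chair interleaved, instance indices remapped to day positions
interleave_absences <- function(seated, instances, day_T, off_id) {
  P <- length(seated)
  A <- day_T - P
  if (A <= 0) return(list(states = seated, instances = instances))
  n_abs <- max(1L, round(A / 1800))
  cuts <- sort(sample.int(max(A - 1L, 1L), min(n_abs - 1L, max(A - 1L, 0L))))
  abs_lens <- diff(c(0L, cuts, A))
  abs_lens <- abs_lens[abs_lens > 0]
  # positions in the seated sequence where breaks are inserted (after these idx)
  ins_at <- sort(sample.int(P - 1L, length(abs_lens)))
  states <- integer(0)
  shift <- integer(P)  # cumulative shift applied to each seated index
  prev <- 0L; cum <- 0L
  for (k in seq_along(ins_at)) {
    seg <- seated[(prev + 1L):ins_at[k]]
    states <- c(states, seg, rep(off_id, abs_lens[k]))
    shift[(prev + 1L):ins_at[k]] <- cum
    cum <- cum + abs_lens[k]
    prev <- ins_at[k]
  }
  states <- c(states, seated[(prev + 1L):P])
  shift[(prev + 1L):P] <- cum
  if (nrow(instances) > 0) {
    # drop instances split by a break; remap the rest
    keep <- shift[instances$start] == shift[instances$end]
    instances <- data.frame(start = instances$start[keep] + shift[instances$start[keep]],
                            end = instances$end[keep] + shift[instances$end[keep]])
  }
  list(states = states, instances = instances)
}

#' Simulate a full study cohort
#'
#' Generates, per participant-day: a label category for the within-day change
#' of low-back pain (LBP), a true motif occurrence rate shifted by category
#' (`improved` highest when `effect_size > 0`), sitting time, questionnaire
#' scores at the four daily slots (9:00, 11:30, 14:00, 17:00; 0--10 scale) and,
#' if `spec$signals`, a load-cell recording with the planted motif occurring at
#' the day's true rate within the seated time.
#'
#' The questionnaire is generated so that the sign of morning-minus-evening
#' LBP reproduces the day's label; sleepiness and fullness are drawn
#' independently of the label.
#'
#' @param spec a [cohort_spec()].
#' @param specs state library, default [default_state_specs()].
#' @return list with `loadcells` (named list of per-day frames or `NULL`),
#'   `questionnaire` (long data.frame), `ground_truth` (per-day truth:
#'   sex, sitting hours, true motif rate and instances, label) and `metadata`
#'   (per-participant sex, weight).
#' @export
simulate_cohort <- function(spec, specs = default_state_specs()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  labels <- c("exacerbated", "no_change", "improved")
  shift <- c(exacerbated = -0.4, no_change = 0, improved = 1.7)
  n_days <- spec$n_participants * spec$days_per_participant
  sex <- stats::rbinom(spec$n_participants, 1, 0.5)
  weight <- stats::rnorm(spec$n_participants, 65.06, 9.97)
  metadata <- data.frame(participant_id = sprintf("P%02d", seq_len(spec$n_participants)),
                         sex = sex, weight = round(pmax(weight, 40), 1))
  gt <- list(); quest <- list(); cells <- list()
  seated_specs <- Filter(function(s) s$label != "off_chair", specs)
  off_id <- {
    off <- Filter(function(s) s$label == "off_chair", specs)
    if (length(off)) off[[1]]$state_id else NA_integer_
  }
  row <- 0L
  for (p in seq_len(spec$n_participants)) {
    for (d in seq_len(spec$days_per_participant)) {
      row <- row + 1L
      day_seed <- child_seed(spec$seed, row)
      set.seed(day_seed)
      lab <- sample(labels, 1, prob = spec$label_probs)
      ci <- match(lab, labels)
      es <- spec$effect_size
      rate <- max(0, stats::rnorm(1, spec$base_rate + shift[[lab]] * es,
                                  spec$noise_sd[ci]))
      # the planted association is the motif rate only; sitting time and the
      # other symptoms are drawn independently of the label
      sit_lo <- min(0.5, 0.5 * spec$day_hours)
      sit_h <- clamp(stats::rnorm(1, spec$sitting_mean, spec$sitting_sd),
                     sit_lo, max(sit_lo, spec$day_hours - 0.25))
      date <- sprintf("2017-10-%02d", d)
      key <- sprintf("%s_%s", metadata$participant_id[p], date)
      # questionnaire
      morning <- sample(2:8, 1)
      delta <- switch(lab, improved = sample(1:3, 1),
                      exacerbated = -sample(1:3, 1), no_change = 0L)
      evening <- clamp(morning - delta, 0, 10)
      lbp <- clamp(c(morning,
                     morning - round(delta * 0.4) + sample(-1:1, 2, replace = TRUE),
                     evening), 0, 10)
      if (lab == "no_change") lbp[4] <- lbp[1]
      sleep <- clamp(round(stats::rnorm(4, 6.56, 1.96)), 0, 10)
      full <- clamp(round(stats::rnorm(4, 4.27, 3.63)), 0, 10)
      quest[[row]] <- data.frame(participant_id = metadata$participant_id[p],
                                 date = date,
                                 time_slot = c("0900", "1130", "1400", "1700"),
                                 lbp = lbp, sleepiness = sleep, fullness = full)
      n_inst <- NA_integer_
      if (spec$signals) {
        P <- round(sit_h * 3600)
        seq_seed <- child_seed(day_seed, 1L)
        dyn <- office_dynamics()
        sim <- simulate_state_sequence(seated_specs, P, dwell = dyn$dwell,
                                       planted_motif = spec$motif,
                                       motif_rate = rate, trans = dyn$trans,
                                       seed = seq_seed)
        day_T <- round(spec$day_hours * 3600)
        set.seed(child_seed(day_seed, 2L))
        if (!is.na(off_id)) {
          day <- interleave_absences(sim$states, sim$instances, day_T, off_id)
        } else day <- sim
        cop <- emit_cop(day$states, specs, seed = child_seed(day_seed, 3L),
                        t0 = 9 * 3600)
        cells[[key]] <- emit_loadcells(cop, body_weight = metadata$weight[p],
                                       hz = spec$hz, seed = child_seed(day_seed, 4L),
                                       noise_sd = spec$sensor_noise_sd)
        attr(cells[[key]], "instances") <- day$instances
        n_inst <- nrow(day$instances)
        # the realized sitting time after interleaving absences
        sit_h <- P / 3600
      }
      gt[[row]] <- data.frame(participant_id = metadata$participant_id[p],
                              date = date, sex = sex[p], sitting_hours = sit_h,
                              true_motif_rate = rate, n_instances = n_inst,
                              label = lab)
    }
  }
  list(loadcells = if (spec$signals) cells else NULL,
       questionnaire = do.call(rbind, quest),
       ground_truth = do.call(rbind, gt),
       metadata = metadata)
}

#' Write a simulated cohort to CSV files
#'
#' Load-cell files are written one per participant-day with ISO-8601
#' timestamps; the questionnaire and ground-truth tables as single CSVs.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of written paths.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (key in names(cohort$loadcells)) {
    df <- cohort$loadcells[[key]]
    out <- data.frame(
      timestamp = format(as.POSIXct(df$t, origin = "2017-10-01", tz = "UTC"),
                         "%Y-%m-%dT%H:%M:%OS2"),
      a1_kg = df$a1, a2_kg = df$a2, a3_kg = df$a3, a4_kg = df$a4)
    p <- file.path(dir, paste0("loadcell_", key, ".csv"))
    utils::write.csv(out, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  qp <- file.path(dir, "questionnaire.csv")
  utils::write.csv(cohort$questionnaire, qp, row.names = FALSE)
  gp <- file.path(dir, "ground_truth.csv")
  utils::write.csv(cohort$ground_truth, gp, row.names = FALSE)
  invisible(c(paths, qp, gp))
}
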