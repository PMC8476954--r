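#' Read a four-channel load-cell CSV
#'
#' Parses a raw load-cell recording with columns `timestamp` (ISO-8601 or
#' numeric seconds), `a1_kg`, `a2_kg`, `a3_kg`, `a4_kg`. The four channels are
#' the corner sensors of the seat: A1 front-left, A2 back-left, A3 front-right,
#' A4 back-right. Rows are sorted by time; duplicate timestamps are rejected.
#'
#' @param path path to a CSV file.
#' @return a `data.frame` with columns `t` (numeric seconds), `a1`..`a4` (kg).
#' @export
read_loadcell_csv <- function(path) {
  if (!file.exists(path)) stopf("load-cell file not found: %s", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "a1_kg", "a2_kg", "a3_kg", "a4_kg")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0)
    stopf("load-cell CSV missing column(s): %s", paste(missing, collapse = ", "))
  ts <- raw$timestamp
  if (is.character(ts)) {
    t <- as.numeric(as.POSIXct(ts, tz = "UTC",
                               tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS")))
  } else {
    t <- as.numeric(ts)
  }
  if (anyNA(t)) stopf("unparsable timestamp at row(s): %s",
                      paste(utils::head(which(is.na(t)), 5L), collapse = ", "))
  for (col in need[-1]) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    if (anyNA(v)) stopf("non-numeric load in column %s at row(s): %s", col,
                        paste(utils::head(which(is.na(v)), 5L), collapse = ", "))
    raw[[col]] <- v
  }
  ord <- order(t)
  t <- t[ord]
  if (anyDuplicated(t)) stopf("duplicate timestamp at sorted row(s): %s",
                              paste(utils::head(which(duplicated(t)), 5L), collapse = ", "))
  data.frame(t = t, a1 = raw$a1_kg[ord], a2 = raw$a2_kg[ord],
             a3 = raw$a3_kg[ord], a4 = raw$a4_kg[ord])
}

#' Calibrate raw load-cell frames
#'
#' Applies the per-channel linear calibration `A_i <- gain_i * (raw_i - zero_i)`
#' established against reference weights; negative calibrated loads are clipped
#' to zero and counted.
#'
#' @param frames data.frame with columns `t`, `a1`..`a4`.
#' @param zero_offsets numeric length-4 zero levels (kg), default 0.
#' @param gains numeric length-4 gains, all > 0, default 1.
#' @return calibrated frames; attribute `clip_count` holds the number of
#'   clipped values.
#' @export
calibrate <- function(frames, zero_offsets = rep(0, 4), gains = rep(1, 4)) {
  stopifnot(length(zero_offsets) == 4, length(gains) == 4)
  if (any(gains <= 0)) stopf("all gains must be > 0")
  clip <- 0L
  for (i in 1:4) {
    col <- paste0("a", i)
    v <- gains[i] * (frames[[col]] - zero_offsets[i])
    clip <- clip + sum(v < 0)
    frames[[col]] <- pmax(v, 0)
  }
  attr(frames, "clip_count") <- clip
  frames
}

#' Compute the chair center of pressure from corner loads
#'
#' The COP is the corner-weighted load sum divided by four:
#' `x = (-A1 - A2 + A3 + A4)/4` (left-right) and
#' `y = (A1 - A2 + A3 - A4)/4` (front-back), with corner coordinates
#' A1 (-1, 1), A2 (-1, -1), A3 (1, 1), A4 (1, -1). The result is a kg-scaled
#' coordinate, i.e. it is not normalized by the total load; an optional
#' load-normalized variant divides by `A1+A2+A3+A4` instead of 4.
#'
#' @param frames data.frame with calibrated columns `a1`..`a4` (and `t`).
#' @param presence_threshold_kg total-load threshold for presence (default 5).
#' @param normalize if `TRUE`, divide by total load instead of 4.
#' @return a COP series data.frame with columns `t`, `x`, `y`, `present`.
#'   Absent samples carry `NA` coordinates.
#' @export
compute_cop <- function(frames, presence_threshold_kg = 5, normalize = FALSE) {
  tot <- frames$a1 + frames$a2 + frames$a3 + frames$a4
  denom <- if (normalize) ifelse(tot > 0, tot, NA_real_) else 4
  x <- (-frames$a1 - frames$a2 + frames$a3 + frames$a4) / denom
  y <- (frames$a1 - frames$a2 + frames$a3 - frames$a4) / denom
  present <- detect_presence(frames, presence_threshold_kg)
  x[!present] <- NA_real_
  y[!present] <- NA_real_
  out <- data.frame(t = frames$t, x = x, y = y, present = present)
  class(out) <- c("cop_series", "data.frame")
  out
}

#' Detect whether someone is on the chair
#'
#' Presence is declared when the summed corner load reaches the threshold
#' (inclusive).
#'
#' @param frames data.frame with columns `a1`..`a4`.
#' @param threshold_kg positive total-load threshold in kg (default 5).
#' @return logical vector, one entry per frame.
#' @export
detect_presence <- function(frames, threshold_kg = 5) {
  if (threshold_kg <= 0) stopf("threshold_kg must be > 0")
  (frames$a1 + frames$a2 + frames$a3 + frames$a4) >= threshold_kg
}

#' Downsample a timestamped series to 1 Hz
#'
#' Keeps the first sample within each 1-second bin anchored at the first
#' timestamp of the series, and inserts absent placeholder rows for empty bins
#' (dropouts), so the output is regularly spaced at 1 s. Idempotent.
#'
#' @param series data.frame with a numeric `t` column (seconds); any other
#'   columns are carried through. A logical `present` column, if there, is set
#'   to `FALSE` on inserted gap rows.
#' @return data.frame at 1 Hz spacing.
#' @export
downsample_1hz <- function(series) {
  if (nrow(series) == 0) return(series)
  t0 <- series$t[1]
  bin <- floor(series$t - t0)
  keep <- !duplicated(bin)
  out <- series[keep, , drop = FALSE]
  bins <- bin[keep]
  full <- seq(0L, max(bins))
  idx <- match(full, bins)
  res <- out[idx, , drop = FALSE]
  res$t <- t0 + full
  gap <- is.na(idx)
  if (any(gap)) {
    if ("present" %in% names(res)) res$present[gap] <- FALSE
    for (col in setdiff(names(res), c("t", "present"))) res[[col]][gap] <- NA
  }
  rownames(res) <- NULL
  class(res) <- class(series)
  res
}

#' Total sitting time of a COP series
#'
#' @param series COP series with a logical `present` column at 1 Hz.
#' @return hours of presence (count of present samples / 3600).
#' @export
sitting_time <- function(series) {
  sum(series$present, na.rm = TRUE) / 3600
}

#' @export
print.cop_series <- function(x, ...) {
  cat(sprintf("COP series: %d samples, %.2f h sitting, %d absent\n",
              nrow(x), sitting_time(x), sum(!x$present)))
  invisible(x)
}
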