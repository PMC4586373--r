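#' Interpolate artifact gaps and assess recording validity
#'
#' Replaces every run of artifact-flagged intervals by linearly
#' interpolated intervals between the nearest non-artifact neighbours,
#' re-flagged `"interpolated"`, and reports the interpolated fraction.
#' A recording with more than 5\% interpolated intervals is marked
#' invalid and should be discarded from analysis.
#'
#' The number of replacement intervals for a gap of total duration `D`
#' ms is `round(D / m)` where `m` is the mean of the two anchor
#' intervals, so total recording duration is preserved to within one
#' interval; replacement values lie on the straight line between the
#' anchors. A gap touching one end of the recording is filled flat at
#' the single available anchor. A series with no non-artifact interval
#' at all is unrecoverable and rejected.
#'
#' @param series An `nn_series`.
#'
#' @return A list with elements `series` (the interpolated
#'   `nn_series`) and `report`, itself a list with
#'   `interpolated_fraction`, `valid` (`fraction <= 0.05`) and
#'   `reason`.
#' @export
#' @examples
#' x <- nn_series(c(800, 1620, 820), flags = c("normal", "artifact", "normal"))
#' interpolate_artifacts(x)$series$intervals
interpolate_artifacts <- function(series) {
  validate_nn_series(series)
  is_art <- series$flags == "artifact"
  if (all(is_art)) {
    stop("series is unrecoverable: every interval is artifact-flagged",
         call. = FALSE)
  }
  if (!any(is_art)) {
    frac <- mean(series$flags == "interpolated")
    return(list(series = series, report = validity_report(frac)))
  }
  runs <- rle(is_art)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  new_iv <- list()
  new_fl <- list()
  prev_end <- 0L
  for (r in seq_along(runs$lengths)) {
    i0 <- starts[r]; i1 <- ends[r]
    if (!runs$values[r]) {
      new_iv[[r]] <- series$intervals[i0:i1]
      new_fl[[r]] <- series$flags[i0:i1]
      next
    }
    D <- sum(series$intervals[i0:i1])
    va <- if (i0 > 1L) series$intervals[i0 - 1L] else NA_real_
    vb <- if (i1 < length(series$intervals)) series$intervals[i1 + 1L] else NA_real_
    if (is.na(va) && is.na(vb)) {
      stop("series is unrecoverable: artifact run touches both ends with no ",
           "normal anchor", call. = FALSE)
    }
    if (is.na(va)) va <- vb
    if (is.na(vb)) vb <- va
    m <- max(1L, as.integer(round(D / ((va + vb) / 2))))
    vals <- va + seq_len(m) * (vb - va) / (m + 1)
    new_iv[[r]] <- vals
    new_fl[[r]] <- rep("interpolated", m)
  }
  out <- series
  out$intervals <- unlist(new_iv, use.names = FALSE)
  out$flags <- unlist(new_fl, use.names = FALSE)
  out <- rebuild_beat_times(out)
  validate_nn_series(out)
  frac <- mean(out$flags == "interpolated")
  list(series = out, report = validity_report(frac))
}

validity_report <- function(fraction) {
  valid <- fraction <= 0.05
  list(
    interpolated_fraction = fraction,
    valid = valid,
    reason = if (valid) "ok" else
      sprintf("interpolated fraction %.3f exceeds 0.05", fraction)
  )
}

#' Segment-level artifact rules for (ultra-)short windows
#'
#' Applies the acceptance rules for artifacts inside an analysis
#' segment: (a) a single artifact interval at the very beginning or
#' end of the segment is dropped and the remainder used (rule
#' `"trim"`); (b) any interior artifact, or more than one artifact,
#' excludes the whole segment (rule `"exclude"`), because SDNN and
#' RMSSD require an uninterrupted run of successive differences. A
#' clean segment passes unchanged (rule `"none"`).
#'
#' The decision depends only on the flags, never on interval values.
#'
#' @param segment An `nn_series` extracted by [extract_segment()].
#'
#' @return A list with `series` (the possibly trimmed `nn_series`, or
#'   `NULL` if excluded) and `rule` (one of `"none"`, `"trim"`,
#'   `"exclude"`).
#' @export
apply_segment_artifact_rules <- function(segment) {
  if (is.null(segment) || n_intervals(segment) == 0L) {
    stop("empty segment is degenerate input", call. = FALSE)
  }
  n <- n_intervals(segment)
  art <- which(segment$flags == "artifact")
  if (length(art) == 0L) {
    return(list(series = segment, rule = "none"))
  }
  if (length(art) == 1L && (art == 1L || art == n)) {
    keep <- setdiff(seq_len(n), art)
    out <- segment
    out$intervals <- out$intervals[keep]
    out$flags <- out$flags[keep]
    out$beat_times <- if (art == 1L) out$beat_times[-1L] else
      out$beat_times[-(n + 1L)]
    return(list(series = out, rule = "trim"))
  }
  list(series = NULL, rule = "exclude")
}
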