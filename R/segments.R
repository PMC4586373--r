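#' Select the analysis windows from a gold-standard recording
#'
#' From a total recording of 239-302 s, returns the six analysis
#' windows: the total recording itself, a 30 s and a 120 s window
#' anchored at the start, and three randomly placed, pairwise
#' non-overlapping 10 s windows. The 10 s starts are drawn from a
#' continuous uniform over the feasible range by rejection sampling
#' until mutually disjoint, then labelled `10s_1`, `10s_2`, `10s_3`
#' in start-time order. Only the three 10 s windows are constrained
#' disjoint; they may overlap the 30 s and 120 s windows.
#'
#' @param series An `nn_series` whose duration lies in [239, 302] s.
#' @param seed Integer seed for the 10 s placement.
#'
#' @return A data.frame with columns `label`, `start`, `duration`
#'   (seconds), one row per window.
#' @export
#' @examples
#' x <- nn_series(rep(1000, 300))
#' select_segments(x, seed = 1)
select_segments <- function(series, seed) {
  validate_nn_series(series)
  dur <- duration(series)
  if (dur < 120) {
    shortest <- if (dur < 10) "10s" else if (dur < 30) "30s" else "120s"
    stop(sprintf(
      "recording of %.1f s cannot supply the %s window", dur, shortest),
      call. = FALSE)
  }
  if (dur < 239 || dur > 302) {
    stop(sprintf(
      "recording duration %.1f s outside the gold-standard range [239, 302] s",
      dur), call. = FALSE)
  }
  starts <- with_rng_seed(seed, {
    repeat {
      s <- sort(stats::runif(3, 0, dur - 10))
      if (s[2] - s[1] >= 10 && s[3] - s[2] >= 10) break
    }
    s
  })
  data.frame(
    label = c("10s_1", "10s_2", "10s_3", "30s", "120s", "total"),
    start = c(starts, 0, 0, 0),
    duration = c(10, 10, 10, 30, 120, dur),
    stringsAsFactors = FALSE
  )
}

#' Extract a window from an NN-interval series
#'
#' Returns the sub-series of intervals whose *terminating* beat time
#' (relative to the recording start) lies in `(start, start +
#' duration]`. The half-open convention assigns every interval to
#' exactly one window in a tiling of the recording, which the
#' interval-count bookkeeping of the variance decomposition relies
#' on. Beat times are re-based to the first bounding beat of the
#' window.
#'
#' @param series An `nn_series`.
#' @param start Window start in seconds from recording start.
#' @param duration Window length in seconds.
#' @param label Optional window label attached as attribute
#'   `"label"`.
#'
#' @return An `nn_series` with at least 2 intervals (fewer is an
#'   error: SDNN is undefined below 2).
#' @export
extract_segment <- function(series, start, duration, label = NULL) {
  validate_nn_series(series)
  term <- series$beat_times[-1] - series$beat_times[1]
  sel <- which(term > start & term <= start + duration)
  if (length(sel) < 2L) {
    stop(sprintf(
      "window [%.1f, %.1f] s contains %d interval(s); at least 2 required",
      start, start + duration, length(sel)), call. = FALSE)
  }
  bt <- series$beat_times[c(sel[1], sel + 1L)]
  out <- nn_series(
    intervals = series$intervals[sel],
    subject_id = series$subject_id,
    flags = series$flags[sel],
    beat_times = bt - bt[1]
  )
  if (!is.null(label)) attr(out, "label") <- label
  out
}
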