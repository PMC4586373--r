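#' NN-interval series
#'
#' An `nn_series` holds one subject's beat-to-beat (normal-to-normal)
#' interval sequence: beat timestamps in seconds from recording start,
#' the intervals between successive beats in milliseconds, and one
#' quality flag per interval (`"normal"`, `"interpolated"` or
#' `"artifact"`).
#'
#' The interval vector has one element fewer than the beat-time vector,
#' and each interval equals the gap between its bounding beats (checked
#' to 0.5 ms, except for artifact-flagged intervals, which may be
#' aberrant until they are interpolated).
#'
#' @param intervals Numeric vector of NN intervals in milliseconds, all
#'   positive.
#' @param subject_id Identifier for the subject; any scalar coercible to
#'   character.
#' @param flags Character vector of per-interval quality flags, recycled
#'   from `"normal"` if omitted.
#' @param beat_times Optional numeric vector of beat times in seconds
#'   (length `length(intervals) + 1`). If omitted, beats are placed at
#'   the cumulative interval times starting from 0.
#'
#' @return An object of class `nn_series`.
#' @export
#' @examples
#' x <- nn_series(c(800, 820, 810), subject_id = "S1")
#' n_intervals(x)
#' duration(x)
nn_series <- function(intervals, subject_id = "S1", flags = NULL,
                      beat_times = NULL) {
  intervals <- as.double(intervals)
  if (is.null(flags)) flags <- rep("normal", length(intervals))
  if (is.null(beat_times)) beat_times <- c(0, cumsum(intervals) / 1000)
  x <- structure(
    list(
      subject_id = as.character(subject_id)[1],
      beat_times = as.double(beat_times),
      intervals = intervals,
      flags = as.character(flags)
    ),
    class = "nn_series"
  )
  validate_nn_series(x)
  x
}

#' @rdname nn_series
#' @param x An `nn_series`.
#' @export
validate_nn_series <- function(x) {
  if (!inherits(x, "nn_series")) stop("not an nn_series", call. = FALSE)
  nb <- length(x$beat_times)
  ni <- length(x$intervals)
  if (ni < 1L) stop("nn_series must contain at least one interval", call. = FALSE)
  if (nb != ni + 1L) {
    stop("beat_times must have one more element than intervals", call. = FALSE)
  }
  if (any(!is.finite(x$beat_times)) || any(!is.finite(x$intervals))) {
    stop("beat_times and intervals must be finite", call. = FALSE)
  }
  if (any(diff(x$beat_times) <= 0)) {
    stop("beat_times must be strictly increasing", call. = FALSE)
  }
  if (any(x$intervals <= 0)) stop("all intervals must be positive", call. = FALSE)
  bad_flag <- setdiff(unique(x$flags), c("normal", "interpolated", "artifact"))
  if (length(bad_flag)) {
    stop("unknown flag value(s): ", paste(bad_flag, collapse = ", "), call. = FALSE)
  }
  if (length(x$flags) != ni) {
    stop("flags must have one element per interval", call. = FALSE)
  }
  gap_ms <- diff(x$beat_times) * 1000
  chk <- x$flags != "artifact"
  if (any(abs(gap_ms[chk] - x$intervals[chk]) > 0.5)) {
    stop("intervals disagree with beat-time gaps by more than 0.5 ms",
         call. = FALSE)
  }
  invisible(x)
}

#' @rdname nn_series
#' @export
n_intervals <- function(x) length(x$intervals)

#' @rdname nn_series
#' @export
duration <- function(x) {
  x$beat_times[length(x$beat_times)] - x$beat_times[1]
}

#' @export
print.nn_series <- function(x, ...) {
  cat(sprintf(
    "<nn_series> subject %s: %d intervals over %.1f s (mean NN %.1f ms)\n",
    x$subject_id, n_intervals(x), duration(x), mean(x$intervals)
  ))
  tab <- table(factor(x$flags, levels = c("normal", "interpolated", "artifact")))
  cat(sprintf("  flags: %d normal, %d interpolated, %d artifact\n",
              tab[["normal"]], tab[["interpolated"]], tab[["artifact"]]))
  invisible(x)
}

# Rebuild beat times from the first beat time plus cumulative intervals.
rebuild_beat_times <- function(x) {
  x$beat_times <- x$beat_times[1] + c(0, cumsum(x$intervals) / 1000)
  x
}

#' Read and write NN-interval files
#'
#' Two plain-text formats are supported. The tabular dialect is a TSV
#' with columns `subject_id`, `beat_time_s`, `nn_ms`, `flag`, one row
#' per interval (the beat time is the interval's *starting* beat; the
#' final beat is implied by the last interval). The single-subject
#' format is PhysioNet-style: one NN interval in milliseconds per line,
#' with beats placed at cumulative interval times.
#'
#' @param series An `nn_series`, or for `write_nn_tsv` a list of them.
#' @param path File path.
#' @param subject_id Subject identifier to attach when reading the
#'   single-column format.
#'
#' @return Readers return an `nn_series` (`read_rr_txt`) or a named list
#'   of `nn_series` (`read_nn_tsv`); writers return `path` invisibly.
#' @export
write_nn_tsv <- function(series, path) {
  if (inherits(series, "nn_series")) series <- list(series)
  rows <- lapply(series, function(s) {
    data.frame(
      subject_id = s$subject_id,
      beat_time_s = sprintf("%.6f", s$beat_times[-length(s$beat_times)]),
      nn_ms = sprintf("%.6f", s$intervals),
      flag = s$flags,
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_nn_tsv
#' @export
read_nn_tsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = c("character", "numeric", "numeric",
                                          "character"))
  out <- lapply(split(tab, factor(tab$subject_id, levels = unique(tab$subject_id))),
                function(d) {
    nn_series(
      intervals = d$nn_ms,
      subject_id = d$subject_id[1],
      flags = d$flag,
      beat_times = c(d$beat_time_s, d$beat_time_s[nrow(d)] + d$nn_ms[nrow(d)] / 1000)
    )
  })
  out
}

#' @rdname write_nn_tsv
#' @export
write_rr_txt <- function(series, path) {
  writeLines(sprintf("%.6f", series$intervals), path)
  invisible(path)
}

#' @rdname write_nn_tsv
#' @export
read_rr_txt <- function(path, subject_id = "S1") {
  iv <- as.double(readLines(path))
  nn_series(iv, subject_id = subject_id)
}
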