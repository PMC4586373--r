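#' Time-domain HRV metrics
#'
#' `sdnn()` is the sample standard deviation of the NN intervals
#' (divisor N - 1, the divisor the interval-count-weighted variance
#' decomposition assumes). `rmssd()` is the root mean square of the
#' N - 1 successive interval differences (divisor N - 1). Both are in
#' milliseconds and require at least 2 intervals.
#'
#' @param x An `nn_series` or a numeric vector of intervals in ms.
#'
#' @return A single number in milliseconds.
#' @export
#' @examples
#' sdnn(c(800, 850, 900))   # 50
#' rmssd(c(800, 850, 900))  # 50
sdnn <- function(x) {
  iv <- interval_vector(x)
  if (length(iv) < 2L) stop("SDNN is undefined on fewer than 2 intervals",
                            call. = FALSE)
  stats::sd(iv)
}

#' @rdname sdnn
#' @export
rmssd <- function(x) {
  iv <- interval_vector(x)
  if (length(iv) < 2L) stop("RMSSD is undefined on fewer than 2 intervals",
                            call. = FALSE)
  sqrt(mean(diff(iv)^2))
}

interval_vector <- function(x) {
  if (inherits(x, "nn_series")) x$intervals else as.double(x)
}

#' One segment's HRV measures
#'
#' Bundles SDNN and RMSSD (raw ms and natural log) with the interval
#' count of the segment; the count is the N that weights the variance
#' decomposition and recombination formulas.
#'
#' @param x An `nn_series` or numeric interval vector.
#' @param label Segment label.
#'
#' @return A one-row data.frame with columns `label`, `n_intervals`,
#'   `sdnn`, `rmssd`, `ln_sdnn`, `ln_rmssd`.
#' @export
hrv_measure <- function(x, label = NA_character_) {
  iv <- interval_vector(x)
  s <- sdnn(iv)
  r <- rmssd(iv)
  data.frame(
    label = label,
    n_intervals = length(iv),
    sdnn = s,
    rmssd = r,
    ln_sdnn = log(s),
    ln_rmssd = log(r),
    stringsAsFactors = FALSE
  )
}

#' Average of the three 10 s measures
#'
#' The Avg10s measure is the arithmetic mean of the three 10 s SDNN
#' (and RMSSD) values on the raw millisecond scale; its log fields are
#' the logs of those means. The carried interval count is the mean of
#' the three (reporting only; the decomposition formulas receive it as
#' the short-segment N for the Avg10s label).
#'
#' @param m1,m2,m3 One-row measure data.frames from [hrv_measure()]
#'   for the three 10 s segments.
#'
#' @return A one-row measure data.frame labelled `"Avg10s"`.
#' @export
avg10s <- function(m1, m2, m3) {
  for (m in list(m1, m2, m3)) {
    if (!is.data.frame(m) || nrow(m) != 1L || is.null(m$sdnn)) {
      stop("avg10s() needs three one-row hrv_measure() data.frames",
           call. = FALSE)
    }
  }
  s <- mean(c(m1$sdnn, m2$sdnn, m3$sdnn))
  r <- mean(c(m1$rmssd, m2$rmssd, m3$rmssd))
  data.frame(
    label = "Avg10s",
    n_intervals = mean(c(m1$n_intervals, m2$n_intervals, m3$n_intervals)),
    sdnn = s,
    rmssd = r,
    ln_sdnn = log(s),
    ln_rmssd = log(r),
    stringsAsFactors = FALSE
  )
}

#' All labels of the per-subject HRV table, in reporting order
#' @export
hrv_labels <- function() {
  c("10s_1", "10s_2", "10s_3", "Avg10s", "30s", "120s", "total")
}

#' Build one subject's HRV table across all analysis windows
#'
#' Selects the six analysis windows ([select_segments()]), applies the
#' segment-level artifact rules to each ([apply_segment_artifact_rules()]),
#' computes SDNN/RMSSD per surviving segment and forms the Avg10s
#' aggregate. If any required segment is excluded (interior or multiple
#' artifacts, or fewer than 2 usable intervals) the subject is excluded
#' with a reason.
#'
#' The series is expected to have passed recording-level validity
#' ([interpolate_artifacts()]); artifact flags still present are
#' handled by the segment rules.
#'
#' @param series An `nn_series`.
#' @param seed Integer seed for the 10 s window placement.
#'
#' @return A 7-row data.frame (`subject_id`, `label`, `n_intervals`,
#'   `sdnn`, `rmssd`, `ln_sdnn`, `ln_rmssd`), or an object of class
#'   `subject_exclusion` (a list with `subject_id` and `reason`) if the
#'   subject cannot be analysed. The selected window table is attached
#'   as attribute `"segments"`.
#' @export
build_subject_table <- function(series, seed) {
  specs <- select_segments(series, seed)
  rows <- vector("list", nrow(specs))
  for (k in seq_len(nrow(specs))) {
    lab <- specs$label[k]
    seg <- tryCatch(
      extract_segment(series, specs$start[k], specs$duration[k], label = lab),
      error = function(e) e
    )
    if (inherits(seg, "error")) {
      return(subject_exclusion(series$subject_id, sprintf(
        "segment %s rejected: %s", lab, conditionMessage(seg))))
    }
    res <- apply_segment_artifact_rules(seg)
    if (is.null(res$series)) {
      return(subject_exclusion(series$subject_id, sprintf(
        "segment %s excluded by artifact rule (interior or multiple artifacts)",
        lab)))
    }
    if (n_intervals(res$series) < 2L) {
      return(subject_exclusion(series$subject_id, sprintf(
        "segment %s has fewer than 2 intervals after trimming", lab)))
    }
    rows[[k]] <- hrv_measure(res$series, label = lab)
  }
  names(rows) <- specs$label
  tab <- rbind(rows[["10s_1"]], rows[["10s_2"]], rows[["10s_3"]],
               avg10s(rows[["10s_1"]], rows[["10s_2"]], rows[["10s_3"]]),
               rows[["30s"]], rows[["120s"]], rows[["total"]])
  tab <- cbind(subject_id = series$subject_id, tab, stringsAsFactors = FALSE)
  attr(tab, "segments") <- specs
  tab
}

subject_exclusion <- function(subject_id, reason) {
  structure(list(subject_id = subject_id, reason = reason),
            class = "subject_exclusion")
}

#' @export
print.subject_exclusion <- function(x, ...) {
  cat(sprintf("<subject_exclusion> %s: %s\n", x$subject_id, x$reason))
  invisible(x)
}
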