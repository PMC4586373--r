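#' Variance decomposition and recombination of HRV values
#'
#' `decompose_remainder()` approximates the HRV value of the remainder
#' of a total recording once a short segment is removed, by the
#' interval-count-weighted variance decomposition
#' \deqn{HRV_{rem}^2 = \frac{HRV_{tot}^2 (N_{tot}-1) - HRV_{short}^2 (N_{short}-1)}
#'                          {N_{tot} - N_{short} - 1},}
#' applied identically to SDNN and RMSSD on the raw millisecond scale.
#' `recombine_hrv()` is its algebraic inverse, combining two
#' independent HRV values into the value of the pooled recording:
#' \deqn{HRV_{comb}^2 = \frac{HRV_{short}^2 (N_{short}-1) + HRV_{rem}^2 (N_{rem}-1)}
#'                           {N_{short} + N_{rem} - 1}.}
#'
#' For RMSSD the underlying variance identity is only approximate, so
#' the radicand of the decomposition can be negative; such pairs yield
#' `NA` and are dropped (never clamped to zero) by callers, with a
#' count.
#'
#' Both functions are vectorized over their arguments.
#'
#' @param hrv_total,hrv_short,hrv_rem HRV values (SDNN or RMSSD) in ms.
#' @param n_total,n_short,n_rem Interval counts of the corresponding
#'   segments.
#'
#' @return `decompose_remainder` returns a list with `value`
#'   (remainder HRV, `NA` where the radicand is negative) and `n`
#'   (remainder interval count `n_total - n_short`). `recombine_hrv`
#'   returns a list with `value` and `n` (`n_short + n_rem`).
#' @export
#' @examples
#' # removing a 2-interval segment with SDNN 14.142 from a 6-interval
#' # recording with SDNN 10.954 leaves a remainder SDNN of 11.547:
#' decompose_remainder(10.954451, 6, 14.142136, 2)
decompose_remainder <- function(hrv_total, n_total, hrv_short, n_short) {
  if (any(!is.finite(hrv_total)) || any(!is.finite(hrv_short)) ||
      any(hrv_total < 0) || any(hrv_short < 0)) {
    stop("HRV values must be finite and non-negative", call. = FALSE)
  }
  if (any(n_total <= n_short + 1)) {
    stop("n_total must exceed n_short + 1", call. = FALSE)
  }
  rad <- (hrv_total^2 * (n_total - 1) - hrv_short^2 * (n_short - 1)) /
    (n_total - n_short - 1)
  value <- ifelse(rad < 0, NA_real_, sqrt(pmax(rad, 0)))
  list(value = value, n = n_total - n_short)
}

#' @rdname decompose_remainder
#' @export
recombine_hrv <- function(hrv_short, n_short, hrv_rem, n_rem) {
  if (any(!is.finite(hrv_short)) || any(!is.finite(hrv_rem)) ||
      any(hrv_short < 0) || any(hrv_rem < 0)) {
    stop("HRV values must be finite and non-negative", call. = FALSE)
  }
  if (any(n_short < 2) || any(n_rem < 2)) {
    stop("both interval counts must be at least 2", call. = FALSE)
  }
  comb <- (hrv_short^2 * (n_short - 1) + hrv_rem^2 * (n_rem - 1)) /
    (n_short + n_rem - 1)
  list(value = sqrt(comb), n = n_short + n_rem)
}

#' Bootstrap null simulation of part-whole agreement
#'
#' Simulates the agreement statistics expected under the null
#' hypothesis that a short segment agrees with the total recording
#' *only* because it is part of it. Per subject, the remainder HRV is
#' approximated by [decompose_remainder()] on the raw ms scale
#' (negative-radicand pairs dropped and counted). Each repetition then
#' draws `n` short values and, independently, `n` remainder values
#' with replacement (each carrying its own interval count), recombines
#' every pair via [recombine_hrv()] into a simulated total, log-
#' transforms both members, and computes Pearson r, Bland-Altman bias
#' and limits of agreement, and Cohen's d between the drawn short
#' values and the simulated totals. The 2.5th and 97.5th percentiles
#' across repetitions form the 95\% reference range for each
#' statistic, and the observed statistics are classified against their
#' ranges as below / inside / above.
#'
#' Repetitions with zero variance in either member are redrawn with a
#' logged count. Per repetition the RNG draws the short-value indices
#' first, then the remainder indices.
#'
#' @param tables Stacked per-subject HRV tables from
#'   [build_subject_table()].
#' @param metric `"lnSDNN"` or `"lnRMSSD"` (the underlying raw metric
#'   is decomposed in ms; logs are taken afterwards).
#' @param label Short-segment label: `"10s_1"`, `"10s_2"`, `"10s_3"`,
#'   `"Avg10s"`, `"30s"` or `"120s"`. For `Avg10s` the short N is the
#'   mean 10 s interval count carried by that row.
#' @param n_reps Number of bootstrap repetitions (default 1000).
#' @param seed Integer seed.
#' @param observed Optional list with elements `r`, `bias`, `loa_low`,
#'   `loa_high`, `d` to classify; if omitted they are computed from
#'   `tables` on the complete finite pairs.
#'
#' @return A list of class `null_sim_result`: `metric`, `label`,
#'   `n_reps`, `n_used` (subjects entering resampling), `n_dropped`
#'   (negative radicand), `n_redrawn`, `observed`, `ranges` (data.frame
#'   `statistic`, `lo`, `hi`), `verdicts` (named character vector) and
#'   `sims` (the per-repetition statistics).
#' @export
bootstrap_null <- function(tables, metric = c("lnSDNN", "lnRMSSD"),
                           label = "10s_1", n_reps = 1000, seed = 1,
                           observed = NULL) {
  metric <- match.arg(metric)
  if (n_reps < 1) stop("n_reps must be at least 1", call. = FALSE)
  raw_col <- if (metric == "lnSDNN") "sdnn" else "rmssd"
  stopifnot(label %in% c("10s_1", "10s_2", "10s_3", "Avg10s", "30s", "120s"))

  short_rows <- tables[tables$label == label, ]
  total_rows <- tables[tables$label == "total", ]
  m <- merge(short_rows[, c("subject_id", raw_col, "n_intervals")],
             total_rows[, c("subject_id", raw_col, "n_intervals")],
             by = "subject_id", suffixes = c("_short", "_total"))
  sv <- m[[paste0(raw_col, "_short")]]
  tv <- m[[paste0(raw_col, "_total")]]
  ns <- m[[paste0("n_intervals_short")]]
  nt <- m[[paste0("n_intervals_total")]]

  if (is.null(observed)) {
    oko <- sv > 0 & tv > 0 & is.finite(sv) & is.finite(tv)
    ls <- log(sv[oko]); lt <- log(tv[oko])
    pr <- pearson_with_ci(ls, lt)
    bao <- bland_altman(lt, ls)
    observed <- list(r = pr$r, bias = bao$bias, loa_low = bao$loa_low,
                     loa_high = bao$loa_high,
                     d = bao$bias / stats::sd(lt))
  }

  ok <- sv > 0 & tv > 0 & nt > ns + 1
  dec <- decompose_remainder(tv[ok], nt[ok], sv[ok], ns[ok])
  keep <- !is.na(dec$value) & dec$value > 0
  n_dropped <- sum(!keep)
  s_val <- sv[ok][keep]
  s_n <- ns[ok][keep]
  r_val <- dec$value[keep]
  r_n <- dec$n[keep]
  n <- length(s_val)
  if (n < 3L) stop("fewer than 3 decomposable subjects", call. = FALSE)

  stats_names <- c("r", "bias", "loa_low", "loa_high", "d")
  sims <- matrix(NA_real_, nrow = n_reps, ncol = length(stats_names),
                 dimnames = list(NULL, stats_names))
  n_redrawn <- 0L
  with_rng_seed(seed, {
    for (rep in seq_len(n_reps)) {
      repeat {
        i <- sample.int(n, n, replace = TRUE)
        j <- sample.int(n, n, replace = TRUE)
        s <- s_val[i]
        comb <- recombine_hrv(s, s_n[i], r_val[j], r_n[j])$value
        ls <- log(s)
        lc <- log(comb)
        if (stats::sd(ls) > 0 && stats::sd(lc) > 0) break
        n_redrawn <- n_redrawn + 1L
      }
      d_i <- lc - ls
      bias <- mean(d_i)
      sdd <- stats::sd(d_i)
      sims[rep, ] <- c(stats::cor(ls, lc), bias, bias - 1.96 * sdd,
                       bias + 1.96 * sdd, bias / stats::sd(lc))
    }
  })
  ranges <- data.frame(
    statistic = stats_names,
    lo = apply(sims, 2, stats::quantile, probs = 0.025, type = 7),
    hi = apply(sims, 2, stats::quantile, probs = 0.975, type = 7),
    row.names = NULL, stringsAsFactors = FALSE
  )
  verdicts <- vapply(stats_names, function(sn) {
    o <- observed[[sn]]
    lo <- ranges$lo[ranges$statistic == sn]
    hi <- ranges$hi[ranges$statistic == sn]
    if (o < lo) "below" else if (o > hi) "above" else "inside"
  }, character(1))
  structure(
    list(metric = metric, label = label, n_reps = n_reps, n_used = n,
         n_dropped = n_dropped, n_redrawn = n_redrawn,
         observed = observed, ranges = ranges, verdicts = verdicts,
         sims = sims),
    class = "null_sim_result"
  )
}

#' @export
print.null_sim_result <- function(x, ...) {
  cat(sprintf("<null_sim_result> %s %s: %d reps, %d subjects (%d dropped)\n",
              x$metric, x$label, x$n_reps, x$n_used, x$n_dropped))
  df <- x$ranges
  df$observed <- unlist(x$observed[df$statistic])
  df$verdict <- x$verdicts[df$statistic]
  print(df, digits = 3)
  invisible(x)
}

#' Run the null simulation over every metric and short label
#'
#' Calls [bootstrap_null()] for each metric in {lnSDNN, lnRMSSD} and
#' each short label, using observed statistics from
#' [agreement_table()] when supplied, and returns one tidy table
#' (plot-ready: observed value, simulated reference range and verdict
#' per statistic).
#'
#' @param tables Stacked per-subject HRV tables.
#' @param n_reps Bootstrap repetitions per combination.
#' @param seed Base seed; each combination derives its own child seed.
#' @param agreement Optional `hrv_agreement` result providing the
#'   observed statistics.
#'
#' @return A data.frame with columns `metric`, `label`, `statistic`,
#'   `observed`, `null_lo`, `null_hi`, `verdict`, `n_used`,
#'   `n_dropped`.
#' @export
nullsim_table <- function(tables, n_reps = 1000, seed = 1,
                          agreement = NULL) {
  labels <- c("10s_1", "10s_2", "10s_3", "Avg10s", "30s", "120s")
  rows <- list()
  combo <- 0L
  for (mname in c("lnSDNN", "lnRMSSD")) {
    for (lab in labels) {
      combo <- combo + 1L
      obs <- NULL
      if (!is.null(agreement)) {
        a <- agreement$agreement
        arow <- a[a$metric == mname & a$label == lab, ]
        obs <- list(r = arow$r, bias = arow$bias, loa_low = arow$loa_low,
                    loa_high = arow$loa_high, d = arow$cohens_d)
      }
      res <- bootstrap_null(tables, metric = mname, label = lab,
                            n_reps = n_reps,
                            seed = derive_seed(seed, combo),
                            observed = obs)
      rows[[combo]] <- data.frame(
        metric = mname, label = lab,
        statistic = res$ranges$statistic,
        observed = unlist(res$observed[res$ranges$statistic]),
        null_lo = res$ranges$lo, null_hi = res$ranges$hi,
        verdict = res$verdicts[res$ranges$statistic],
        n_used = res$n_used, n_dropped = res$n_dropped,
        row.names = NULL, stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
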