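#' Pearson correlation with Fisher-z confidence interval
#'
#' @param x,y Paired numeric vectors, length >= 3, finite, each with
#'   non-zero variance.
#' @param conf Confidence level (default 0.95).
#'
#' @return List with `r` and `ci` (length-2 vector).
#' @export
pearson_with_ci <- function(x, y, conf = 0.95) {
  check_paired(x, y)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance", call. = FALSE)
  }
  n <- length(x)
  r <- stats::cor(x, y)
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  q <- stats::qnorm(1 - (1 - conf) / 2)
  list(r = r, ci = tanh(c(z - q * se, z + q * se)), n = n)
}

#' Bland-Altman bias and 95% limits of agreement
#'
#' Differences are taken gold minus short. The bias is their mean, the
#' limits of agreement are `bias +/- 1.96 * SD(d)` (sample SD, divisor
#' n - 1), and the bias CI is `bias +/- 1.96 * SD(d)/sqrt(n)`. The
#' returned plot table pairs each difference with the gold-standard
#' value, which is plotted on the x-axis.
#'
#' @param gold,short Paired numeric vectors (gold-standard and short
#'   segment values, typically on the natural-log scale).
#'
#' @return List with `bias`, `bias_ci`, `loa_low`, `loa_high`,
#'   `sd_diff`, `n` and `plot_data` (data.frame `gold`, `diff`).
#' @export
bland_altman <- function(gold, short) {
  check_paired(gold, short)
  d <- gold - short
  n <- length(d)
  bias <- mean(d)
  sdd <- stats::sd(d)
  list(
    bias = bias,
    bias_ci = bias + c(-1.96, 1.96) * sdd / sqrt(n),
    loa_low = bias - 1.96 * sdd,
    loa_high = bias + 1.96 * sdd,
    sd_diff = sdd,
    n = n,
    plot_data = data.frame(gold = gold, diff = d)
  )
}

#' Cohen's d for the bias relative to gold-standard spread
#'
#' The bias divided by the between-subject standard deviation of the
#' gold-standard (total recording) measure. Interpretation bands:
#' |d| < 0.2 very small, < 0.5 small, < 0.8 moderate, otherwise large.
#'
#' @param bias Mean paired difference (gold minus short).
#' @param sd_total SD of the gold-standard measure across subjects
#'   (> 0).
#'
#' @return List with `d` and `band`.
#' @export
cohens_d <- function(bias, sd_total) {
  if (!is.numeric(sd_total) || sd_total <= 0) {
    stop("cohens_d undefined: sd_total must be positive", call. = FALSE)
  }
  d <- bias / sd_total
  list(d = d, band = d_band(d))
}

d_band <- function(d) {
  a <- abs(d)
  if (a < 0.2) "very small" else if (a < 0.5) "small" else
    if (a < 0.8) "moderate" else "large"
}

# Nonparametric bootstrap CI for Cohen's d: resample subjects with
# replacement; each resample recomputes both the bias and the
# gold-standard SD.
cohens_d_boot_ci <- function(gold, short, n_boot = 2000, seed = 1,
                             conf = 0.95) {
  check_paired(gold, short)
  n <- length(gold)
  with_rng_seed(seed, {
    ds <- vapply(seq_len(n_boot), function(b) {
      i <- sample.int(n, n, replace = TRUE)
      s <- stats::sd(gold[i])
      if (s == 0) return(NA_real_)
      mean(gold[i] - short[i]) / s
    }, numeric(1))
    stats::quantile(ds, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                    na.rm = TRUE, names = FALSE, type = 7)
  })
}

#' Intraclass correlation, two-way random, absolute agreement, single rater
#'
#' Computes ICC(A,1) from the two-way ANOVA mean squares of the n x 2
#' table formed by the paired measurements, with the F-based 95%
#' confidence interval of McGraw and Wong. Absolute agreement penalizes
#' systematic offsets between the two measurements.
#'
#' @param a,b Paired numeric vectors, length >= 3.
#' @param conf Confidence level.
#'
#' @return List with `icc`, `ci`, `n` and the mean squares `msr`,
#'   `msc`, `mse`.
#' @export
icc_absolute <- function(a, b, conf = 0.95) {
  check_paired(a, b)
  n <- length(a)
  k <- 2
  m <- cbind(a, b)
  grand <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  if (stats::var(row_means) == 0) {
    stop("ICC undefined: zero between-subject variance", call. = FALSE)
  }
  ssr <- k * sum((row_means - grand)^2)
  ssc <- n * sum((col_means - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  alpha <- 1 - conf
  if (icc >= 1) {
    ci <- c(1, 1)
  } else {
    aa <- (k * icc) / (n * (1 - icc))
    bb <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (aa * msc + bb * mse)^2 /
      ((aa * msc)^2 / (k - 1) + (bb * mse)^2 / ((n - 1) * (k - 1)))
    fl <- stats::qf(1 - alpha / 2, n - 1, v)
    fu <- stats::qf(1 - alpha / 2, v, n - 1)
    lower <- n * (msr - fl * mse) /
      (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
    upper <- n * (fu * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * fu * msr)
    ci <- c(lower, upper)
  }
  list(icc = icc, ci = ci, n = n, msr = msr, msc = msc, mse = mse)
}

check_paired <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must be paired", call. = FALSE)
  if (length(x) < 3L) stop("at least 3 pairs required", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("values must be finite", call. = FALSE)
  }
  invisible(TRUE)
}

#' Agreement statistics of short segments against the gold standard
#'
#' For each metric (lnSDNN, lnRMSSD) and each short label (`10s_1`,
#' `10s_2`, `10s_3`, `Avg10s`, `30s`, `120s`) computes, against the
#' total-recording value across subjects: Pearson r with Fisher-z CI,
#' Bland-Altman bias with CI and 95% limits of agreement, and Cohen's
#' d (bias over the SD of the total-recording measure, bootstrap CI
#' over subjects). Also computes the three pairwise ICCs (absolute
#' agreement, two-way, single rater) among the 10 s windows per
#' metric. Only complete, finite pairs enter each comparison; dropped
#' non-finite values are counted in attribute `"n_dropped_nonfinite"`.
#'
#' @param tables Stacked per-subject HRV tables from
#'   [build_subject_table()] (rows = subject x label).
#' @param boot_seed Seed for the Cohen's d bootstrap.
#' @param n_boot Bootstrap resamples for the d CI.
#'
#' @return List of class `hrv_agreement` with data.frames `agreement`,
#'   `icc` and `ba_data`.
#' @export
agreement_table <- function(tables, boot_seed = 1, n_boot = 2000) {
  metrics <- c(lnSDNN = "ln_sdnn", lnRMSSD = "ln_rmssd")
  short_labels <- c("10s_1", "10s_2", "10s_3", "Avg10s", "30s", "120s")
  subjects <- unique(tables$subject_id)
  if (length(subjects) < 3L) stop("at least 3 complete subjects required",
                                  call. = FALSE)
  agr <- list()
  icc_rows <- list()
  ba <- list()
  dropped <- 0L
  combo <- 0L
  for (mname in names(metrics)) {
    col <- metrics[[mname]]
    wide <- stats::reshape(
      tables[, c("subject_id", "label", col)],
      idvar = "subject_id", timevar = "label", direction = "wide"
    )
    names(wide) <- sub(paste0("^", col, "\\."), "", names(wide))
    for (lab in short_labels) {
      combo <- combo + 1L
      ok <- is.finite(wide[[lab]]) & is.finite(wide[["total"]])
      dropped <- dropped + sum(!ok)
      gold <- wide[["total"]][ok]
      short <- wide[[lab]][ok]
      pr <- pearson_with_ci(short, gold)
      ba_res <- bland_altman(gold, short)
      sd_total <- stats::sd(gold)
      dd <- cohens_d(ba_res$bias, sd_total)
      d_ci <- cohens_d_boot_ci(gold, short, n_boot = n_boot,
                               seed = derive_seed(boot_seed, combo))
      agr[[length(agr) + 1L]] <- data.frame(
        metric = mname, label = lab, n = ba_res$n,
        r = pr$r, r_lo = pr$ci[1], r_hi = pr$ci[2],
        bias = ba_res$bias, bias_lo = ba_res$bias_ci[1],
        bias_hi = ba_res$bias_ci[2],
        loa_low = ba_res$loa_low, loa_high = ba_res$loa_high,
        cohens_d = dd$d, d_lo = d_ci[1], d_hi = d_ci[2],
        d_band = dd$band,
        stringsAsFactors = FALSE
      )
      ba[[length(ba) + 1L]] <- data.frame(
        metric = mname, label = lab,
        subject_id = wide$subject_id[ok],
        gold = gold, diff = gold - short,
        stringsAsFactors = FALSE
      )
    }
    pairs <- list(c("10s_1", "10s_2"), c("10s_1", "10s_3"),
                  c("10s_2", "10s_3"))
    for (pr2 in pairs) {
      ok <- is.finite(wide[[pr2[1]]]) & is.finite(wide[[pr2[2]]])
      res <- icc_absolute(wide[[pr2[1]]][ok], wide[[pr2[2]]][ok])
      icc_rows[[length(icc_rows) + 1L]] <- data.frame(
        metric = mname, pair = paste(pr2, collapse = " vs "),
        icc = res$icc, icc_lo = res$ci[1], icc_hi = res$ci[2],
        n = res$n, stringsAsFactors = FALSE
      )
    }
  }
  out <- list(
    agreement = do.call(rbind, agr),
    icc = do.call(rbind, icc_rows),
    ba_data = do.call(rbind, ba)
  )
  attr(out, "n_dropped_nonfinite") <- dropped
  class(out) <- "hrv_agreement"
  out
}

#' @export
print.hrv_agreement <- function(x, ...) {
  cat("<hrv_agreement>\n")
  print(x$agreement[, c("metric", "label", "n", "r", "bias", "loa_low",
                        "loa_high", "cohens_d")], digits = 3)
  invisible(x)
}
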