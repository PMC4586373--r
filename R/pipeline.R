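#' Analyse a population of NN-interval recordings
#'
#' Runs the full analysis in memory: recording-level artifact
#' interpolation and the 5\% validity rule, per-subject segment
#' selection and HRV tables, descriptive statistics per label,
#' agreement statistics against the gold standard, pairwise 10 s ICCs,
#' and Bland-Altman plot data. Exclusions (invalid recordings,
#' rejected segments) are collected with machine-readable reasons.
#'
#' @param population Named list of `nn_series` (e.g. from
#'   [generate_population()] or [read_nn_tsv()]).
#' @param segment_seed Base seed for 10 s window placement; subject
#'   `k` uses a child seed derived from it.
#' @param boot_seed Seed for the Cohen's d bootstrap.
#' @param n_boot Bootstrap resamples for the d CI.
#'
#' @return A list of class `hrv_analysis`: `subject_hrv` (stacked
#'   per-subject tables), `descriptives`, `agreement` (an
#'   `hrv_agreement`), `segments` (audit table of selected windows),
#'   `qc` (per-subject validity report) and `exclusions`.
#' @export
analyze_population <- function(population, segment_seed = 1,
                               boot_seed = 1, n_boot = 2000) {
  if (inherits(population, "nn_series")) population <- list(population)
  subj_tabs <- list()
  seg_tabs <- list()
  qc <- list()
  excl <- list()
  for (k in seq_along(population)) {
    series <- population[[k]]
    interp <- tryCatch(interpolate_artifacts(series), error = function(e) e)
    if (inherits(interp, "error")) {
      excl[[length(excl) + 1L]] <- data.frame(
        subject_id = series$subject_id, reason_code = "unrecoverable",
        reason = conditionMessage(interp), stringsAsFactors = FALSE)
      next
    }
    qc[[length(qc) + 1L]] <- data.frame(
      subject_id = series$subject_id,
      interpolated_fraction = interp$report$interpolated_fraction,
      valid = interp$report$valid, stringsAsFactors = FALSE)
    if (!interp$report$valid) {
      excl[[length(excl) + 1L]] <- data.frame(
        subject_id = series$subject_id, reason_code = "invalid_recording",
        reason = interp$report$reason, stringsAsFactors = FALSE)
      next
    }
    tab <- tryCatch(
      build_subject_table(interp$series, seed = derive_seed(segment_seed, k)),
      error = function(e) e
    )
    if (inherits(tab, "error")) {
      excl[[length(excl) + 1L]] <- data.frame(
        subject_id = series$subject_id, reason_code = "segmentation_error",
        reason = conditionMessage(tab), stringsAsFactors = FALSE)
      next
    }
    if (inherits(tab, "subject_exclusion")) {
      excl[[length(excl) + 1L]] <- data.frame(
        subject_id = tab$subject_id, reason_code = "segment_rejected",
        reason = tab$reason, stringsAsFactors = FALSE)
      next
    }
    segs <- attr(tab, "segments")
    segs <- cbind(subject_id = series$subject_id, segs,
                  stringsAsFactors = FALSE)
    subj_tabs[[length(subj_tabs) + 1L]] <- tab
    seg_tabs[[length(seg_tabs) + 1L]] <- segs
  }
  if (length(subj_tabs) < 3L) {
    stop("fewer than 3 complete subjects after exclusions", call. = FALSE)
  }
  subject_hrv <- do.call(rbind, subj_tabs)
  rownames(subject_hrv) <- NULL
  structure(
    list(
      subject_hrv = subject_hrv,
      descriptives = descriptives_table(subject_hrv),
      agreement = agreement_table(subject_hrv, boot_seed = boot_seed,
                                  n_boot = n_boot),
      segments = do.call(rbind, seg_tabs),
      qc = if (length(qc)) do.call(rbind, qc) else NULL,
      exclusions = if (length(excl)) do.call(rbind, excl) else
        data.frame(subject_id = character(), reason_code = character(),
                   reason = character(), stringsAsFactors = FALSE)
    ),
    class = "hrv_analysis"
  )
}

#' Descriptive statistics per recording label
#'
#' Mean (SD) of raw and natural-log SDNN and RMSSD for each label, in
#' reporting order, across subjects.
#'
#' @param subject_hrv Stacked per-subject HRV tables.
#'
#' @return A data.frame with one row per label.
#' @export
descriptives_table <- function(subject_hrv) {
  labs <- hrv_labels()
  rows <- lapply(labs, function(lab) {
    d <- subject_hrv[subject_hrv$label == lab, ]
    data.frame(
      label = lab,
      n = nrow(d),
      sdnn_mean = mean(d$sdnn), sdnn_sd = stats::sd(d$sdnn),
      ln_sdnn_mean = mean(d$ln_sdnn[is.finite(d$ln_sdnn)]),
      ln_sdnn_sd = stats::sd(d$ln_sdnn[is.finite(d$ln_sdnn)]),
      rmssd_mean = mean(d$rmssd), rmssd_sd = stats::sd(d$rmssd),
      ln_rmssd_mean = mean(d$ln_rmssd[is.finite(d$ln_rmssd)]),
      ln_rmssd_sd = stats::sd(d$ln_rmssd[is.finite(d$ln_rmssd)]),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' @export
print.hrv_analysis <- function(x, ...) {
  cat(sprintf("<hrv_analysis> %d subjects analysed, %d excluded\n",
              length(unique(x$subject_hrv$subject_id)),
              nrow(x$exclusions)))
  print(x$descriptives[, c("label", "n", "sdnn_mean", "rmssd_mean")],
        digits = 4)
  invisible(x)
}

#' Generate a synthetic dataset and write it to disk
#'
#' Generates a population from `spec`, writes the tabular NN dialect
#' (`population.tsv`), the spec as YAML (`population_spec.yaml`) and a
#' run manifest (`manifest.json`) recording all seeds, the package
#' version and the percentile convention, so a manifest re-run
#' reproduces all outputs byte-identically.
#'
#' @param spec A [population_spec()].
#' @param out_dir Output directory (created if missing).
#'
#' @return Invisibly, the population list.
#' @export
run_simulate <- function(spec = population_spec(), out_dir) {
  if (!inherits(spec, "population_spec")) {
    spec <- do.call(population_spec, as.list(spec))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pop <- generate_population(spec)
  data_path <- file.path(out_dir, "population.tsv")
  write_nn_tsv(pop, data_path)
  population_spec_to_yaml(spec, file.path(out_dir, "population_spec.yaml"))
  write_manifest(out_dir, list(
    step = "simulate",
    spec = unclass(spec),
    n_subjects = length(pop),
    data_file = "population.tsv",
    data_sha1 = file_digest(data_path)
  ))
  invisible(pop)
}

#' Analyse a dataset on disk and write report tables
#'
#' Reads the tabular NN dialect, runs [analyze_population()], and
#' writes: `subject_hrv.tsv`, `descriptives.tsv`, `agreement.tsv`,
#' `icc.tsv`, `bland_altman_data.tsv`, `segments.tsv`, `qc.tsv`,
#' `exclusions.tsv` and a manifest. Identical input and seeds give
#' identical reports.
#'
#' @param data_path Path to a `population.tsv` written by
#'   [run_simulate()] (or a population list).
#' @param out_dir Output directory.
#' @param segment_seed,boot_seed,n_boot Passed to
#'   [analyze_population()].
#'
#' @return Invisibly, the `hrv_analysis` object.
#' @export
run_analyze <- function(data_path, out_dir, segment_seed = 1,
                        boot_seed = 1, n_boot = 2000) {
  pop <- if (is.character(data_path)) read_nn_tsv(data_path) else data_path
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- analyze_population(pop, segment_seed = segment_seed,
                            boot_seed = boot_seed, n_boot = n_boot)
  wt <- function(d, f) utils::write.table(
    d, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(res$subject_hrv, "subject_hrv.tsv")
  wt(res$descriptives, "descriptives.tsv")
  wt(res$agreement$agreement, "agreement.tsv")
  wt(res$agreement$icc, "icc.tsv")
  wt(res$agreement$ba_data, "bland_altman_data.tsv")
  wt(res$segments, "segments.tsv")
  if (!is.null(res$qc)) wt(res$qc, "qc.tsv")
  wt(res$exclusions, "exclusions.tsv")
  write_manifest(out_dir, list(
    step = "analyze",
    segment_seed = segment_seed, boot_seed = boot_seed, n_boot = n_boot,
    n_analysed = length(unique(res$subject_hrv$subject_id)),
    n_excluded = nrow(res$exclusions),
    five_percent_rule = "interpolated fraction counted over intervals",
    avg10s = "raw-scale mean of the three 10 s measures, log of the mean",
    percentile_definition = "inclusive linear interpolation (R type 7)"
  ))
  invisible(res)
}

#' Run the bootstrap null simulation and write its table
#'
#' @param analysis An `hrv_analysis` from [run_analyze()] /
#'   [analyze_population()], or a stacked subject HRV table.
#' @param out_dir Output directory.
#' @param n_reps Bootstrap repetitions.
#' @param seed Base seed.
#'
#' @return Invisibly, the null-simulation table.
#' @export
run_nullsim <- function(analysis, out_dir, n_reps = 1000, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (inherits(analysis, "hrv_analysis")) {
    tab <- nullsim_table(analysis$subject_hrv, n_reps = n_reps, seed = seed,
                         agreement = analysis$agreement)
  } else {
    tab <- nullsim_table(analysis, n_reps = n_reps, seed = seed)
  }
  utils::write.table(tab, file.path(out_dir, "nullsim.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_manifest(out_dir, list(
    step = "nullsim", n_reps = n_reps, seed = seed,
    percentile_definition = "inclusive linear interpolation (R type 7)",
    drop_policy = "negative-radicand pairs dropped, not clamped"
  ))
  invisible(tab)
}

write_manifest <- function(out_dir, fields) {
  fields$package <- "ushrv"
  fields$package_version <- as.character(utils::packageVersion("ushrv"))
  path <- file.path(out_dir, paste0("manifest_", fields$step, ".json"))
  jsonlite::write_json(fields, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

file_digest <- function(path) {
  # cheap content fingerprint (sum + size) to tie manifests to data
  # files without a digest dependency
  bytes <- readBin(path, "raw", file.info(path)$size)
  sprintf("sum%08x-size%d", sum(as.integer(bytes)) %% .Machine$integer.max,
          length(bytes))
}
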