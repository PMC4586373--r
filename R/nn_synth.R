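#' Single-subject NN-interval generator parameters
#'
#' The generator writes each NN interval as a mean level plus two
#' sinusoidal oscillations (a high-frequency, respiratory-band
#' component and a low-frequency, baroreflex-band component), a
#' Gaussian random-walk drift, and white beat-to-beat noise:
#' \deqn{NN_i = \mu + A_{lf}\sin(2\pi f_{lf} t_i + \phi_{lf})
#'            + A_{hf}\sin(2\pi f_{hf} t_i + \phi_{hf}) + d_i + \epsilon_i,}
#' where \eqn{t_i} is the cumulative beat time at which interval
#' \eqn{i} starts, \eqn{d_i} is a random walk with per-step standard
#' deviation `drift_sd`, and \eqn{\epsilon_i} is white noise with
#' standard deviation `noise_sd`. Phases are drawn uniformly per
#' subject. Oscillations are sampled at beat times (point-process
#' sampling), matching how HRV arises in beat-indexed data. Intervals
#' are clamped at a physiologic floor of 200 ms.
#'
#' The random walk and the low-frequency oscillation give SDNN its
#' dependence on recording length, while RMSSD, driven by the fast
#' components, is nearly length-invariant.
#'
#' @param mean_nn Mean NN interval in milliseconds (> 0).
#' @param hf_amp,lf_amp Amplitudes of the high-/low-frequency
#'   oscillations, ms (>= 0).
#' @param hf_freq,lf_freq Oscillation frequencies in Hz; must satisfy
#'   `hf_freq > lf_freq > 0` and both must lie below half the beat rate
#'   implied by `mean_nn`.
#' @param drift_sd Per-step standard deviation of the random-walk
#'   drift, ms (>= 0).
#' @param noise_sd Standard deviation of white beat-to-beat noise, ms
#'   (>= 0).
#' @param duration Target recording duration in seconds (> 0).
#' @param artifact_rate Per-beat probability of an injected artifact,
#'   in [0, 1).
#'
#' @return A `generator_params` list.
#' @export
#' @examples
#' p <- generator_params(mean_nn = 800, duration = 10)
#' generate_subject(p, seed = 1)
generator_params <- function(mean_nn = 882, hf_amp = 16.5, hf_freq = 0.25,
                             lf_amp = 22, lf_freq = 0.08, drift_sd = 2.45,
                             noise_sd = 8.3, duration = 290,
                             artifact_rate = 0) {
  p <- list(mean_nn = mean_nn, hf_amp = hf_amp, hf_freq = hf_freq,
            lf_amp = lf_amp, lf_freq = lf_freq, drift_sd = drift_sd,
            noise_sd = noise_sd, duration = duration,
            artifact_rate = artifact_rate)
  for (f in names(p)) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop_field(f, "must be a single finite number")
    }
  }
  if (p$mean_nn <= 0) stop_field("mean_nn", "must be positive")
  for (f in c("hf_amp", "lf_amp", "drift_sd", "noise_sd")) {
    if (p[[f]] < 0) stop_field(f, "must be non-negative")
  }
  if (p$duration <= 0) stop_field("duration", "must be positive")
  if (p$artifact_rate < 0 || p$artifact_rate >= 1) {
    stop_field("artifact_rate", "must lie in [0, 1)")
  }
  if (p$lf_freq <= 0) stop_field("lf_freq", "must be positive")
  if (p$hf_freq <= p$lf_freq) {
    stop_field("hf_freq", "must exceed lf_freq")
  }
  nyquist <- 0.5 * 1000 / p$mean_nn
  if (p$hf_freq >= nyquist) {
    stop_field("hf_freq", sprintf(
      "must be below half the beat rate (%.3f Hz) implied by mean_nn", nyquist))
  }
  structure(p, class = "generator_params")
}

#' Generate one synthetic NN-interval recording
#'
#' Produces a seeded `nn_series` from the beat-indexed oscillation +
#' drift + noise model described in [generator_params()]. Generation
#' proceeds beat by beat until the cumulative beat time spans
#' `params$duration` seconds. With `artifact_rate > 0`, artifacts are
#' injected afterwards via [inject_artifacts()] with a seed drawn from
#' the same stream.
#'
#' @param params A `generator_params` object.
#' @param seed Integer seed; identical `(params, seed)` give
#'   bitwise-identical output.
#' @param subject_id Identifier for the generated subject.
#'
#' @return An `nn_series`.
#' @export
generate_subject <- function(params, seed, subject_id = "S1") {
  if (!inherits(params, "generator_params")) {
    params <- do.call(generator_params, as.list(params))
  }
  with_rng_seed(seed, {
    phi_lf <- stats::runif(1, 0, 2 * pi)
    phi_hf <- stats::runif(1, 0, 2 * pi)
    n_guess <- ceiling(params$duration * 1000 / params$mean_nn * 1.6) + 30L
    intervals <- numeric(n_guess)
    t <- 0
    drift <- 0
    i <- 0L
    while (t < params$duration - 1e-9) {
      i <- i + 1L
      if (i > length(intervals)) intervals <- c(intervals, numeric(n_guess))
      drift <- drift + stats::rnorm(1, 0, params$drift_sd)
      iv <- params$mean_nn +
        params$lf_amp * sin(2 * pi * params$lf_freq * t + phi_lf) +
        params$hf_amp * sin(2 * pi * params$hf_freq * t + phi_hf) +
        drift + stats::rnorm(1, 0, params$noise_sd)
      iv <- max(iv, 200)
      intervals[i] <- iv
      t <- t + iv / 1000
    }
    out <- nn_series(intervals[seq_len(i)], subject_id = subject_id)
    if (params$artifact_rate > 0) {
      art_seed <- sample.int(2147483646L, 1)
      out <- inject_artifacts(out, params$artifact_rate, art_seed)
    }
    out
  })
}

#' Inject artifacts into an NN-interval series
#'
#' Flags a seeded random subset of intervals as `"artifact"` and
#' perturbs their values, alternating (in draw order) between halving
#' and doubling, as produced by false or missed beat detections. Beat
#' times are rebuilt from the perturbed cumulative intervals. The input
#' series is not modified.
#'
#' @param series An `nn_series`.
#' @param rate Per-interval artifact probability in [0, 1).
#' @param seed Integer seed.
#'
#' @return A new `nn_series` with artifact flags.
#' @export
inject_artifacts <- function(series, rate, seed) {
  validate_nn_series(series)
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) ||
      rate < 0 || rate >= 1) {
    stop_field("rate", "must lie in [0, 1)")
  }
  if (rate == 0) return(series)
  with_rng_seed(seed, {
    hit <- stats::runif(n_intervals(series)) < rate
    if (any(hit)) {
      idx <- which(hit)
      factor <- ifelse(seq_along(idx) %% 2 == 1, 0.5, 2)
      series$intervals[idx] <- series$intervals[idx] * factor
      series$flags[idx] <- "artifact"
      series <- rebuild_beat_times(series)
    }
    series
  })
}

#' Population specification for the synthetic cohort
#'
#' Describes the across-subject distribution of [generator_params()]
#' fields for a cohort of resting recordings. The mean NN interval is
#' Gaussian across subjects; oscillation amplitudes, the drift step SD
#' and the white-noise SD are log-normal (producing the right-skewed
#' HRV distributions that motivate log-scale analysis); oscillation
#' frequencies and recording duration are uniform over physiologic
#' bands.
#'
#' Defaults are calibrated to a general adult population at rest: mean
#' heart rate near 68 bpm, population median SDNN near 32 ms and median
#' RMSSD near 24.5 ms for the full 240-300 s recording, with SDNN
#' growing markedly with recording length while RMSSD stays nearly
#' flat.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param seed Integer seed for the whole population draw.
#' @param mean_nn_mean,mean_nn_sd Gaussian mean/SD of the per-subject
#'   mean NN interval, ms.
#' @param hf_amp_meanlog,hf_amp_sdlog Log-scale location/scale of the
#'   high-frequency amplitude, ms.
#' @param lf_amp_meanlog,lf_amp_sdlog Log-scale location/scale of the
#'   low-frequency amplitude, ms.
#' @param noise_sd_meanlog,noise_sd_sdlog Log-scale location/scale of
#'   the white-noise SD, ms.
#' @param drift_sd_meanlog,drift_sd_sdlog Log-scale location/scale of
#'   the random-walk step SD, ms.
#' @param hf_freq_range,lf_freq_range Uniform frequency bands, Hz.
#' @param duration_range Uniform recording-duration band, seconds.
#' @param artifact_rate Per-beat artifact probability applied to every
#'   subject.
#'
#' @return A `population_spec` list.
#' @export
population_spec <- function(n_subjects = 500, seed = 20150928,
                            mean_nn_mean = 882, mean_nn_sd = 120,
                            hf_amp_meanlog = log(16.5), hf_amp_sdlog = 0.55,
                            lf_amp_meanlog = log(22), lf_amp_sdlog = 0.55,
                            noise_sd_meanlog = log(8.3), noise_sd_sdlog = 0.5,
                            drift_sd_meanlog = log(2.45), drift_sd_sdlog = 0.55,
                            hf_freq_range = c(0.18, 0.40),
                            lf_freq_range = c(0.05, 0.12),
                            duration_range = c(280, 300),
                            artifact_rate = 0) {
  s <- list(n_subjects = n_subjects, seed = seed,
            mean_nn_mean = mean_nn_mean, mean_nn_sd = mean_nn_sd,
            hf_amp_meanlog = hf_amp_meanlog, hf_amp_sdlog = hf_amp_sdlog,
            lf_amp_meanlog = lf_amp_meanlog, lf_amp_sdlog = lf_amp_sdlog,
            noise_sd_meanlog = noise_sd_meanlog,
            noise_sd_sdlog = noise_sd_sdlog,
            drift_sd_meanlog = drift_sd_meanlog,
            drift_sd_sdlog = drift_sd_sdlog,
            hf_freq_range = hf_freq_range, lf_freq_range = lf_freq_range,
            duration_range = duration_range, artifact_rate = artifact_rate)
  if (!is.numeric(s$n_subjects) || s$n_subjects < 1) {
    stop_field("n_subjects", "must be at least 1")
  }
  for (f in c("mean_nn_sd", "hf_amp_sdlog", "lf_amp_sdlog",
              "noise_sd_sdlog", "drift_sd_sdlog")) {
    if (!is.numeric(s[[f]]) || s[[f]] < 0) {
      stop_field(f, "must be a non-negative scale")
    }
  }
  for (f in c("hf_freq_range", "lf_freq_range", "duration_range")) {
    v <- s[[f]]
    if (!is.numeric(v) || length(v) != 2L || any(!is.finite(v)) ||
        v[1] > v[2] || v[1] <= 0) {
      stop_field(f, "must be an increasing positive pair")
    }
  }
  if (s$artifact_rate < 0 || s$artifact_rate >= 1) {
    stop_field("artifact_rate", "must lie in [0, 1)")
  }
  structure(s, class = "population_spec")
}

#' Generate a synthetic NN-interval population
#'
#' Draws per-subject generator parameters from `spec` and generates one
#' recording per subject, all from a single seeded stream: identical
#' specs give identical populations. Subject identifiers are
#' `S0001 ... Sn`.
#'
#' @param spec A [population_spec()].
#'
#' @return Named list of `nn_series`, one per subject.
#' @export
generate_population <- function(spec = population_spec()) {
  if (!inherits(spec, "population_spec")) {
    spec <- do.call(population_spec, as.list(spec))
  }
  n <- as.integer(spec$n_subjects)
  with_rng_seed(spec$seed, {
    out <- vector("list", n)
    ids <- sprintf("S%04d", seq_len(n))
    for (k in seq_len(n)) {
      mean_nn <- min(max(stats::rnorm(1, spec$mean_nn_mean, spec$mean_nn_sd),
                         500), 1500)
      p <- generator_params(
        mean_nn = mean_nn,
        hf_amp = stats::rlnorm(1, spec$hf_amp_meanlog, spec$hf_amp_sdlog),
        hf_freq = stats::runif(1, spec$hf_freq_range[1],
                               min(spec$hf_freq_range[2], 0.45 * 1000 / mean_nn)),
        lf_amp = stats::rlnorm(1, spec$lf_amp_meanlog, spec$lf_amp_sdlog),
        lf_freq = stats::runif(1, spec$lf_freq_range[1], spec$lf_freq_range[2]),
        drift_sd = stats::rlnorm(1, spec$drift_sd_meanlog, spec$drift_sd_sdlog),
        noise_sd = stats::rlnorm(1, spec$noise_sd_meanlog, spec$noise_sd_sdlog),
        duration = stats::runif(1, spec$duration_range[1],
                                spec$duration_range[2]),
        artifact_rate = spec$artifact_rate
      )
      subj_seed <- sample.int(2147483646L, 1)
      out[[k]] <- generate_subject(p, seed = subj_seed, subject_id = ids[k])
    }
    names(out) <- ids
    out
  })
}

#' Read or write a population spec as YAML
#'
#' The YAML keys mirror the [population_spec()] argument names.
#'
#' @param path YAML file path.
#' @param spec A `population_spec`.
#' @return `population_spec_from_yaml` returns a `population_spec`;
#'   the writer returns `path` invisibly.
#' @export
population_spec_from_yaml <- function(path) {
  do.call(population_spec, yaml::read_yaml(path))
}

#' @rdname population_spec_from_yaml
#' @export
population_spec_to_yaml <- function(spec, path) {
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}
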