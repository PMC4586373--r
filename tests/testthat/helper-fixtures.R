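# Deterministic series builders used across the suite.

constant_series <- function(value = 1000, n = 300, subject_id = "S1",
                            flags = NULL) {
  nn_series(rep(value, n), subject_id = subject_id, flags = flags)
}

# Alternating value +/- delta series: RMSSD is exactly 2*delta on any
# sub-window with >= 2 intervals; SDNN lies in [delta, delta*sqrt(N/(N-1))].
alternating_series <- function(value = 800, delta = 10, duration_s = 300,
                               subject_id = "S1") {
  n <- ceiling(duration_s * 1000 / value) + 2
  iv <- rep(c(value + delta, value - delta), length.out = n)
  nn_series(iv, subject_id = subject_id)
}

# Stacked per-subject HRV table built directly from given raw values;
# ln fields derived, one label per row.
make_hrv_rows <- function(subject_id, labels, sdnn, rmssd, n_intervals) {
  data.frame(
    subject_id = subject_id, label = labels, n_intervals = n_intervals,
    sdnn = sdnn, rmssd = rmssd,
    ln_sdnn = log(sdnn), ln_rmssd = log(rmssd),
    stringsAsFactors = FALSE
  )
}

# A small cached default-spec synthetic population and its analysis,
# shared by tests that only need "a realistic population".
small_population <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_population(population_spec(n_subjects = 80,
                                                    seed = 424242))
    }
    cache
  }
})

small_analysis <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- analyze_population(small_population(), segment_seed = 11,
                                   boot_seed = 12, n_boot = 200)
    }
    cache
  }
})
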