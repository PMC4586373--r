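test_that("variance decomposition reproduces the hand example", {
  # total: 6 intervals, SDNN^2 = 120; short: 2 intervals, SDNN^2 = 200
  # remainder^2 = (120*5 - 200*1) / 3 = 400/3
  dec <- decompose_remainder(sqrt(120), 6, sqrt(200), 2)
  expect_equal(dec$value, sqrt(400 / 3), tolerance = 1e-12)
  expect_equal(dec$value, 11.547005, tolerance = 1e-6)
  expect_equal(dec$n, 4)
})

test_that("homogeneous variance passes through decomposition almost unchanged", {
  # with equal HRV c on both sides the N-weighted divisors do not cancel
  # exactly: the remainder is c * sqrt((Nt-Ns)/(Nt-Ns-1))
  dec <- decompose_remainder(25, 300, 25, 12)
  expect_equal(dec$value, 25 * sqrt(288 / 287), tolerance = 1e-12)
  expect_equal(dec$value, 25, tolerance = 2e-3)
})

test_that("negative radicands yield NA, never a clamped zero", {
  dec <- decompose_remainder(10, 10, 40, 8)
  expect_true(is.na(dec$value))
  expect_error(decompose_remainder(10, 10, 10, 9), "n_total")
  expect_error(decompose_remainder(-1, 10, 5, 3), "non-negative")
})

test_that("recombination inverts decomposition and matches its example", {
  comb <- recombine_hrv(sqrt(200), 2, sqrt(400 / 3), 4)
  expect_equal(comb$value, sqrt(120), tolerance = 1e-12)
  expect_equal(comb$n, 6)
  # equal values recombine to the same value up to the divisor mismatch
  expect_equal(recombine_hrv(17, 40, 17, 200)$value,
               17 * sqrt(238 / 239), tolerance = 1e-12)
  expect_equal(recombine_hrv(17, 40, 17, 200)$value, 17, tolerance = 3e-3)
  set.seed(4)
  for (k in 1:100) {
    tot <- runif(1, 5, 60); n_t <- sample(100:400, 1)
    sh <- runif(1, 1, tot); n_s <- sample(5:50, 1)
    dec <- decompose_remainder(tot, n_t, sh, n_s)
    if (is.na(dec$value)) next
    back <- recombine_hrv(sh, n_s, dec$value, dec$n)
    expect_equal(back$value, tot, tolerance = 1e-9)
    expect_equal(back$n, n_t)
  }
  expect_error(recombine_hrv(10, 1, 10, 5), "at least 2")
})

test_that("for SDNN with equal segment means, Eq-style decomposition is exact", {
  set.seed(11)
  for (k in 1:20) {
    n1 <- sample(5:20, 1); n2 <- sample(10:40, 1)
    x1 <- rnorm(n1, 800, 30)
    x2 <- rnorm(n2, 800, 45)
    x2 <- x2 - mean(x2) + mean(x1)  # equal segment means
    total <- c(x1, x2)
    dec <- decompose_remainder(sd(total), n1 + n2, sd(x1), n1)
    expect_equal(dec$value, sd(x2), tolerance = 1e-9)
  }
})

test_that("a single bootstrap repetition is reproducible by hand", {
  tabs <- rbind(
    make_hrv_rows("A", c("10s_1", "total"), c(20, 30), c(18, 19), c(11, 330)),
    make_hrv_rows("B", c("10s_1", "total"), c(35, 40), c(25, 26), c(12, 340)),
    make_hrv_rows("C", c("10s_1", "total"), c(15, 28), c(30, 28), c(10, 320))
  )
  res <- bootstrap_null(tabs, metric = "lnSDNN", label = "10s_1",
                        n_reps = 1, seed = 77)
  # replay the seeded stream and the recombination by hand
  sv <- c(20, 35, 15); ns <- c(11, 12, 10)
  tv <- c(30, 40, 28); nt <- c(330, 340, 320)
  rem <- sqrt((tv^2 * (nt - 1) - sv^2 * (ns - 1)) / (nt - ns - 1))
  set.seed(77L)
  i <- sample.int(3, 3, replace = TRUE)
  j <- sample.int(3, 3, replace = TRUE)
  s <- sv[i]
  comb <- sqrt((s^2 * (ns[i] - 1) + rem[j]^2 * (nt[j] - ns[j] - 1)) /
                 (ns[i] + nt[j] - ns[j] - 1))
  ls <- log(s); lc <- log(comb)
  d_i <- lc - ls
  expect_equal(unname(res$sims[1, "r"]), cor(ls, lc), tolerance = 1e-12)
  expect_equal(unname(res$sims[1, "bias"]), mean(d_i), tolerance = 1e-12)
  expect_equal(unname(res$sims[1, "loa_high"]),
               mean(d_i) + 1.96 * sd(d_i), tolerance = 1e-12)
  expect_equal(unname(res$sims[1, "d"]), mean(d_i) / sd(lc),
               tolerance = 1e-12)
  expect_equal(res$n_used, 3)
})

test_that("the null simulation is deterministic in the seed", {
  tabs <- small_analysis()$subject_hrv
  a <- bootstrap_null(tabs, "lnRMSSD", "30s", n_reps = 30, seed = 5)
  b <- bootstrap_null(tabs, "lnRMSSD", "30s", n_reps = 30, seed = 5)
  expect_identical(a$sims, b$sims)
  expect_identical(a$ranges, b$ranges)
})

test_that("null range for r covers the analytic part-whole correlation", {
  # independent chi-square construction: short^2 ~ s2*chi2(Ns-1)/(Ns-1),
  # total recombined from an independent remainder; expected part-whole
  # r ~ sqrt((Ns-1)/(Nt-1))
  set.seed(21)
  n <- 400
  n_s <- 11; n_t <- 331
  s_val <- sqrt(900 * rchisq(n, n_s - 1) / (n_s - 1))
  r_val <- sqrt(900 * rchisq(n, n_t - n_s - 1) / (n_t - n_s - 1))
  tot <- recombine_hrv(s_val, n_s, r_val, n_t - n_s)$value
  tabs <- rbind(
    make_hrv_rows(sprintf("P%03d", 1:n), "10s_1", s_val, s_val, n_s),
    make_hrv_rows(sprintf("P%03d", 1:n), "total", tot, tot, n_t)
  )
  res <- bootstrap_null(tabs, "lnSDNN", "10s_1", n_reps = 400, seed = 13)
  expected <- sqrt((n_s - 1) / (n_t - 1))
  lo <- res$ranges$lo[res$ranges$statistic == "r"]
  hi <- res$ranges$hi[res$ranges$statistic == "r"]
  expect_gt(expected, lo)
  expect_lt(expected, hi)
})

test_that("reference-range jitter shrinks roughly as 1/sqrt(n_reps)", {
  tabs <- small_analysis()$subject_hrv
  ends <- function(n_reps, seeds) {
    vapply(seeds, function(s) {
      res <- bootstrap_null(tabs[tabs$subject_id %in%
                                   unique(tabs$subject_id)[1:50], ],
                            "lnSDNN", "10s_1", n_reps = n_reps, seed = s)
      res$ranges$hi[res$ranges$statistic == "r"]
    }, numeric(1))
  }
  sd_small <- sd(ends(250, 1:10))
  sd_big <- sd(ends(4000, 101:110))
  ratio <- sd_small / sd_big
  expect_gt(ratio, 2)
  expect_lt(ratio, 8)
})

test_that("nullsim_table covers every metric and label with verdicts", {
  ana <- small_analysis()
  tab <- nullsim_table(ana$subject_hrv, n_reps = 60, seed = 3,
                       agreement = ana$agreement)
  expect_equal(nrow(tab), 2 * 6 * 5)
  expect_true(all(tab$null_lo <= tab$null_hi))
  expect_true(all(tab$verdict %in% c("below", "inside", "above")))
  # genuine within-subject stability: observed r above its null range
  rsub <- tab[tab$statistic == "r", ]
  expect_true(all(rsub$verdict == "above"))
})
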