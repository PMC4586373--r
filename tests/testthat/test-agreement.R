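# Brute-force Pearson r from the definitional sum formula.
pearson_oracle <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

test_that("Pearson r matches examples and a brute-force oracle", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_with_ci(x, x)$r, 1)
  expect_equal(pearson_with_ci(x, -x)$r, -1)
  r <- pearson_with_ci(x, c(1, 2, 3, 5))$r
  expect_equal(round(r, 4), 0.9827)
  for (s in 1:5) {
    set.seed(s)
    a <- rnorm(20); b <- 0.6 * a + rnorm(20)
    res <- pearson_with_ci(a, b)
    expect_equal(res$r, pearson_oracle(a, b), tolerance = 1e-12)
    expect_true(res$ci[1] <= res$r && res$r <= res$ci[2])
    expect_true(all(res$ci >= -1 & res$ci <= 1))
  }
  expect_error(pearson_with_ci(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson_with_ci(c(1, 2), c(1, 2)), "at least 3")
})

test_that("Bland-Altman bias and limits match closed forms", {
  g <- c(3.1, 3.5, 2.9, 3.3)
  res <- bland_altman(g, g)
  expect_equal(res$bias, 0)
  expect_equal(res$loa_low, 0)
  expect_equal(res$loa_high, 0)

  res <- bland_altman(g + 0.1, g)
  expect_equal(res$bias, 0.1)
  expect_equal(res$loa_high - res$loa_low, 0)

  d <- rep(c(1, -1), 50)
  res <- bland_altman(d, rep(0, 100))
  expect_equal(res$bias, 0)
  sd_d <- sd(d)
  expect_equal(res$loa_high, 1.96 * sd_d, tolerance = 1e-12)
  expect_equal(res$loa_low, -1.96 * sd_d, tolerance = 1e-12)
  expect_equal(res$bias_ci[2], 1.96 * sd_d / 10, tolerance = 1e-12)
  # brute force on random pairs
  set.seed(2)
  gold <- rnorm(20, 3, 0.5); short <- gold - rnorm(20, 0.2, 0.3)
  res <- bland_altman(gold, short)
  dd <- gold - short
  expect_equal(res$bias, mean(dd), tolerance = 1e-12)
  expect_equal(res$loa_high, mean(dd) + 1.96 * sd(dd), tolerance = 1e-12)
  expect_equal(res$plot_data$gold, gold)
})

test_that("Cohen's d divides bias by total-recording SD with bands", {
  expect_equal(cohens_d(0, 0.5)$d, 0)
  expect_equal(cohens_d(0.5, 0.5)$d, 1)
  expect_equal(cohens_d(0.5, 0.5)$band, "large")
  expect_equal(cohens_d(0.0135, 0.5)$band, "very small")  # d = 0.027
  expect_equal(cohens_d(0.15, 0.5)$band, "small")
  expect_equal(cohens_d(0.3, 0.5)$band, "moderate")
  expect_error(cohens_d(0.1, 0), "positive")
})

test_that("bootstrap CI for Cohen's d covers the truth at ~95%", {
  # gold ~ N(0,1), short = gold - delta + e: true d = delta / 1
  delta <- 0.4
  n <- 50
  hits <- 0L
  n_sim <- 150
  set.seed(99)
  for (s in seq_len(n_sim)) {
    gold <- rnorm(n)
    short <- gold - delta + rnorm(n, 0, 0.4)
    ci <- ushrv:::cohens_d_boot_ci(gold, short, n_boot = 400, seed = s)
    if (ci[1] <= delta && delta <= ci[2]) hits <- hits + 1L
  }
  expect_gt(hits / n_sim, 0.88)
  expect_lte(hits / n_sim, 1)
})

test_that("ICC(A,1) matches an aov mean-squares oracle to 1e-10", {
  for (s in 1:5) {
    set.seed(s)
    n <- 20
    subj <- rnorm(n, 3, 0.6)
    a <- subj + rnorm(n, 0, 0.3)
    b <- subj + 0.1 + rnorm(n, 0, 0.3)
    res <- icc_absolute(a, b)
    df <- data.frame(
      y = c(a, b),
      subject = factor(rep(seq_len(n), 2)),
      rater = factor(rep(1:2, each = n))
    )
    ms <- summary(stats::aov(y ~ subject + rater, data = df))[[1]][["Mean Sq"]]
    msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
    icc_oracle <- (msr - mse) / (msr + mse + 2 * (msc - mse) / n)
    expect_equal(res$icc, icc_oracle, tolerance = 1e-10)
    expect_equal(res$msr, msr, tolerance = 1e-10)
    expect_equal(res$msc, msc, tolerance = 1e-10)
    expect_equal(res$mse, mse, tolerance = 1e-10)
    expect_true(res$ci[1] <= res$icc && res$icc <= res$ci[2])
  }
})

test_that("ICC is 1 on identity and near 0 under a dominant offset", {
  a <- c(3.0, 3.2, 3.4, 3.6, 3.8)
  res <- icc_absolute(a, a)
  expect_equal(res$icc, 1)
  res <- icc_absolute(a, a + 50)
  expect_lt(res$icc, 0.01)
  expect_error(icc_absolute(rep(1, 5), rep(1, 5)), "zero between-subject")
})

test_that("agreement_table produces coherent statistics per metric x label", {
  ana <- small_analysis()
  agr <- ana$agreement$agreement
  expect_equal(nrow(agr), 12)
  expect_setequal(unique(agr$label),
                  c("10s_1", "10s_2", "10s_3", "Avg10s", "30s", "120s"))
  expect_true(all(agr$r >= -1 & agr$r <= 1))
  expect_true(all(agr$loa_low <= agr$bias & agr$bias <= agr$loa_high))
  # cohens_d == bias / sd(gold) recomputed from the BA data
  for (k in seq_len(nrow(agr))) {
    ba <- ana$agreement$ba_data
    ba <- ba[ba$metric == agr$metric[k] & ba$label == agr$label[k], ]
    expect_equal(agr$cohens_d[k], mean(ba$diff) / sd(ba$gold),
                 tolerance = 1e-9)
  }
  expect_equal(nrow(ana$agreement$icc), 6)
  expect_true(all(ana$agreement$icc$icc <= 1))
})

test_that("Cohen's d is invariant to shifting gold and short together", {
  tabs <- small_analysis()$subject_hrv
  shifted <- tabs
  shifted$ln_sdnn <- shifted$ln_sdnn + 1.7
  shifted$ln_rmssd <- shifted$ln_rmssd + 1.7
  a0 <- agreement_table(tabs, boot_seed = 5, n_boot = 50)$agreement
  a1 <- agreement_table(shifted, boot_seed = 5, n_boot = 50)$agreement
  expect_equal(a1$cohens_d, a0$cohens_d, tolerance = 1e-9)
  expect_equal(a1$bias, a0$bias, tolerance = 1e-9)
})
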