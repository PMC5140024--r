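test_that("periodogram recovers a pure 24 h square wave", {
  bin_s <- 600
  day <- c(rep(0, 72), rep(80, 72))        # 12 h rest, 12 h active
  x <- rep(day, 10)
  pg <- chisq_periodogram(x, bin_s)
  expect_equal(pg$peak_period_s, 86400)
  expect_equal(pg$df, (pg$period_s / bin_s) - 1)
  expect_true(all(pg$qp >= 0))
})

test_that("Qp matches an independent brute-force fold-and-variance oracle", {
  set.seed(7001)
  bin_s <- 600
  day <- 40 + 40 * sin(2 * pi * (0:143) / 144)
  x <- rep(day, 3) + rnorm(432, 0, 10)     # 3 days, rhythmic + noise
  pg <- chisq_periodogram(x, bin_s, period_range_s = c(20, 26) * 3600)
  for (P in c(120, 131, 144, 150, 156)) {
    i <- match(P * bin_s, pg$period_s)
    expect_equal(pg$qp[i], oracle_qp(x, P), tolerance = 1e-9)
  }
})

test_that("Qp is invariant to affine rescaling of activity", {
  set.seed(7002)
  x <- rep(c(rep(0, 72), rep(50, 72)), 4) + runif(576, 0, 5)
  a <- chisq_periodogram(x, 600)
  b <- chisq_periodogram(3.7 * x + 11, 600)
  expect_equal(a$qp, b$qp, tolerance = 1e-12)
  expect_equal(a$peak_period_s, b$peak_period_s)
})

test_that("white noise rarely crosses the alpha = 0.001 significance line", {
  set.seed(7003)
  n_sig <- 0L
  n_seeds <- 200L
  for (i in seq_len(n_seeds)) {
    x <- rnorm(1440)                        # 10 days of 10-min bins
    pg <- chisq_periodogram(x, 600)
    if (!is.na(pg$peak_period_s)) n_sig <- n_sig + 1L
  }
  expect_lt(n_sig / n_seeds, 0.05)
})

test_that("degenerate periodogram inputs raise explicit errors", {
  expect_error(chisq_periodogram(rep(5, 1440), 600), "no rhythm detectable")
  expect_error(chisq_periodogram(rnorm(100), 600), "2 complete cycles")
  expect_error(chisq_periodogram(c(rnorm(1439), NA), 600), "gap-free")
})

test_that("actogram folding has the documented shape and conserves totals", {
  x <- seq_len(288)                         # 2 days of 10-min bins
  m1 <- actogram_matrix(x, 600, double_plot = FALSE)
  expect_equal(dim(m1), c(2L, 144L))
  expect_equal(unname(rowSums(m1)), c(sum(1:144), sum(145:288)))

  m2 <- actogram_matrix(x, 600, double_plot = TRUE)
  expect_equal(dim(m2), c(2L, 288L))
  expect_equal(unname(m2[1, 145:288]), unname(m1[2, ]))
  expect_true(all(is.na(m2[2, 145:288])))

  # incomplete trailing day padded with NA
  m3 <- actogram_matrix(seq_len(150), 600, double_plot = FALSE)
  expect_equal(dim(m3), c(2L, 144L))
  expect_true(all(is.na(m3[2, 7:144])))
})

test_that("folding a free-running trace at its own period aligns onsets", {
  # Onsets measured on the mean profiles of the two halves of the record
  # stay put when the fold matches tau, and drift when it does not.
  tau_s <- 23.7 * 3600
  half_drift <- function(x, p_bins) {
    nd <- length(x) %/% p_bins
    m <- matrix(x[seq_len(nd * p_bins)], ncol = p_bins, byrow = TRUE)
    h1 <- colMeans(m[1:(nd %/% 2), , drop = FALSE])
    h2 <- colMeans(m[(nd %/% 2 + 1):nd, , drop = FALSE])
    activity_onset(h2, 600, floor_frac = 0.25) -
      activity_onset(h1, 600, floor_frac = 0.25)
  }
  d_tau <- d_24 <- numeric(0)
  for (seed in 1:8) {
    sim <- simulate_mouse(sim_config(duration_days = 10, regime = "DD",
                                     tau_s = tau_s, seed = 7200 + seed))
    x <- resample_activity(sim$trace, 600, "mean")$activity[, 1]
    d_tau <- c(d_tau, half_drift(x, round(tau_s / 600)))
    d_24 <- c(d_24, half_drift(x, 144))
  }
  expect_lte(stats::median(abs(d_tau)), 2 * 600)
  expect_lt(stats::median(abs(d_tau)), stats::median(abs(d_24)))
})

test_that("light schedules are inferred from the LDR channel", {
  set.seed(7004)
  epoch_s <- 10
  n_day <- 8640
  lit <- rep(rep(c(TRUE, FALSE), each = n_day / 2), 3)
  light <- ifelse(lit, 500 + rnorm(3 * n_day, 0, 20),
                  pmax(0, rnorm(3 * n_day, 3, 1)))
  sch <- infer_light_schedule(light, epoch_s)
  expect_equal(sch$regime, "LD")
  expect_equal(sch$period_s, 86400)
  # transitions at the true switch times (+- 1 epoch)
  trans <- as.numeric(sch$intervals$start[-1])
  expect_true(all(abs(trans - seq(43200, by = 43200,
                                  length.out = length(trans))) <= epoch_s))

  expect_equal(infer_light_schedule(rep(0, 1000), epoch_s,
                                    threshold = 10)$regime, "DD")
  expect_equal(infer_light_schedule(rep(500, 1000), epoch_s,
                                    threshold = 10)$regime, "LL")
})

test_that("a one-epoch light spike inside the dark is debounced away", {
  set.seed(7005)
  n_day <- 8640
  lit <- rep(c(TRUE, FALSE), each = n_day / 2)
  light <- ifelse(lit, 500, 2)
  spiked <- light
  spiked[6000] <- 500                       # glitch in the dark phase
  a <- infer_light_schedule(light, 10)
  b <- infer_light_schedule(spiked, 10)
  expect_equal(b$intervals$phase, a$intervals$phase)
  expect_equal(as.numeric(b$intervals$start), as.numeric(a$intervals$start))
})

test_that("an unseparable light histogram is refused with auto threshold", {
  set.seed(7006)
  expect_error(infer_light_schedule(rnorm(5000, 100, 10), 10),
               "cannot infer")
})

test_that("activity onsets are found at steps and missing on flat profiles", {
  prof <- c(rep(0, 72), rep(60, 72))
  expect_equal(activity_onset(prof, 600), 72 * 600)
  expect_true(is.na(activity_onset(rep(5, 144), 600)))
})

test_that("simulated LD mice start activity near lights-off", {
  onsets <- numeric(0)
  for (s in 1:8) {
    sim <- simulate_mouse(sim_config(duration_days = 4, seed = 7100 + s))
    b <- resample_activity(sim$trace, 600, "mean")
    m <- actogram_matrix(b$activity[, 1], 600, double_plot = FALSE)
    onsets <- c(onsets, activity_onset(m, 600, floor_frac = 0.25))
  }
  onsets <- onsets[!is.na(onsets)]
  # lights-off at 12 h into each day; median onset within 20 min
  expect_lte(abs(stats::median(onsets) - 43200), 1200)
})

test_that("interdaily stability is 1 for identical days and drops when days are shuffled within", {
  day <- c(rep(0, 24), rep(50, 24))
  x <- rep(day, 5)
  expect_equal(interdaily_stability(x, 1800), 1)

  set.seed(7008)
  xn <- rep(day, 5) + rnorm(240, 0, 5)
  is0 <- interdaily_stability(xn, 1800)
  # permuting whole days leaves IS unchanged
  m <- matrix(xn, nrow = 5, byrow = TRUE)
  xp <- as.vector(t(m[sample(5), ]))
  expect_equal(interdaily_stability(xp, 1800), is0, tolerance = 1e-12)
  # shuffling within days destroys the daily pattern
  xs <- as.vector(apply(m, 1, sample))
  xs <- as.vector(t(matrix(xs, ncol = 5)))
  expect_lt(interdaily_stability(sample(xn), 1800), is0 / 2)
  expect_error(interdaily_stability(rep(1, 96), 1800), "zero-variance")
})

test_that("intradaily variability is ~2 for white noise and small for a sinusoid", {
  set.seed(7009)
  ivs <- replicate(50, intradaily_variability(rnorm(480)))
  expect_equal(mean(ivs), 2, tolerance = 0.05)
  smooth <- sin(2 * pi * (0:479) / 48)
  expect_lt(intradaily_variability(smooth), 0.1)
})
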