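test_that("run and window modes score immobile periods per their definitions", {
  # 60 s of immobility: all 6 epochs in run mode, 3 windows in window mode
  z6 <- rep(0, 6)
  expect_equal(score_sleep(z6)$flags, rep(1, 6))
  expect_equal(score_sleep(z6, mode = "window")$flags,
               c(0, 0, 0, 1, 1, 1))
  # 30 s of immobility is below the 40 s criterion in both modes
  z3 <- rep(0, 3)
  expect_warning(f3 <- score_sleep(z3)$flags, "shorter")
  expect_equal(f3, rep(0, 3))
  # two qualifying runs separated by one movement epoch
  x <- c(0, 0, 0, 0, 5, 0, 0, 0, 0)
  expect_equal(score_sleep(x)$flags, c(1, 1, 1, 1, 0, 1, 1, 1, 1))
  expect_equal(score_sleep(x, mode = "window")$flags,
               c(0, 0, 0, 1, 0, 0, 0, 0, 1))
})

test_that("degenerate scoring inputs are handled explicitly", {
  expect_error(score_sleep(c(0, -1, 0)), "negative")
  expect_error(score_sleep(rep(0, 10), threshold_bins = 0), "positive integer")
  # any nonzero activity breaks immobility, even 1%
  x <- c(0, 0, 1, 0, 0, 0, 0, 0)
  expect_equal(score_sleep(x)$flags, c(0, 0, 0, 1, 1, 1, 1, 1))
  # configurable noise floor admits sub-threshold twitches
  expect_equal(score_sleep(x, floor = 1)$flags, rep(1, 8))
})

test_that("missing epochs break immobility runs and flag as NA", {
  x <- c(0, 0, NA, 0, 0, 0, 0, 0)
  f <- score_sleep(x)$flags
  expect_true(is.na(f[3]))
  expect_equal(f[-3], c(0, 0, 1, 1, 1, 1, 1))
  # na_breaks = FALSE treats the gap as immobile
  f2 <- score_sleep(x, na_breaks = FALSE)$flags
  expect_equal(f2[-3], rep(1, 7))
})

test_that("scoring matches the brute-force run-enumeration oracle", {
  set.seed(4021)
  for (rep_i in 1:60) {
    n <- sample(20:400, 1)
    x <- sample(c(0, 0, 0, 5, 40), n, replace = TRUE)
    th <- sample(2:6, 1)
    for (mode in c("run", "window")) {
      got <- score_sleep(x, threshold_bins = th, mode = mode)$flags
      expect_equal(got, oracle_sleep_flags(x, th, mode))
    }
  }
})

test_that("run mode exceeds window mode by threshold-1 epochs per qualifying run", {
  set.seed(4022)
  for (rep_i in 1:40) {
    x <- sample(c(0, 0, 10), sample(50:500, 1), replace = TRUE)
    th <- 4
    r <- sum(score_sleep(x, th, "run")$flags)
    w <- sum(score_sleep(x, th, "window")$flags)
    expect_equal(r - w, (th - 1) * oracle_n_long_runs(x, th))
  }
})

test_that("total sleep is monotone in the threshold and bounded by immobility", {
  set.seed(4023)
  for (rep_i in 1:20) {
    x <- sample(c(0, 0, 0, 25), 300, replace = TRUE)
    totals <- vapply(1:8, function(th)
      sum(score_sleep(x, threshold_bins = th)$flags), numeric(1))
    expect_true(all(diff(totals) <= 0))
    # sleep is a subset of immobility: >0 s immobility alone overestimates
    expect_true(all(totals <= sum(x == 0)))
    expect_equal(totals[1], sum(x == 0))
  }
})

test_that("sleep bouts are maximal, ordered, and sized in seconds", {
  s <- score_sleep(c(0, 0, 0, 0, 5, 0, 0, 0, 0))
  b <- sleep_bouts(s)
  expect_equal(nrow(b), 2L)
  expect_equal(b$duration_s, c(40, 40))
  expect_equal(b$onset, c(1, 6))

  expect_warning(s0 <- score_sleep(rep(10, 3)))
  expect_equal(nrow(sleep_bouts(s0)), 0L)

  s1 <- score_sleep(rep(0, 360))
  b1 <- sleep_bouts(s1)
  expect_equal(nrow(b1), 1L)
  expect_equal(b1$duration_s, 3600)
})

test_that("sleep minutes per bin scale and saturate correctly", {
  # a fully flagged 30 min bin scores 30 min
  s <- score_sleep(rep(0, 180))
  expect_equal(sleep_minutes_per_bin(s)$values, 30)
  # 12 flagged 10 s epochs = 2 min
  x <- c(rep(0, 12), rep(50, 168))
  s2 <- score_sleep(x)
  expect_equal(sleep_minutes_per_bin(s2)$values, 2)
  # an empty bin scores 0
  expect_warning(s3 <- score_sleep(rep(9, 2)))
  expect_equal(sleep_minutes_per_bin(s3, 60)$values, 0)
})

test_that("scoring an activity trace keeps its clock and cages", {
  tr <- make_trace(c(rep(0, 6), rep(80, 6)))
  s <- score_sleep(tr)
  expect_s3_class(s, "sleep_series")
  expect_equal(s$time[1], tr$time[1])
  mins <- sleep_minutes_per_bin(s, 60)
  expect_equal(mins$values, c(1, 0))
  expect_equal(as.numeric(diff(mins$time), units = "secs"), 60)
})
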