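test_that("invalid configs are rejected listing the offending fields", {
  expect_error(sim_config(duration_days = -1), "duration_days")
  expect_error(sim_config(p_quiet_light = 1.5), "p_quiet_light")
  err <- tryCatch(sim_config(active_dwell_s = 0, artifact_prob = 2),
                  error = conditionMessage)
  expect_match(err, "active_dwell_s")
  expect_match(err, "artifact_prob")
})

test_that("the same seed reproduces the simulation bit for bit", {
  cfg <- sim_config(duration_days = 2, seed = 99)
  a <- simulate_mouse(cfg)
  b <- simulate_mouse(cfg)
  expect_identical(a$trace$activity, b$trace$activity)
  expect_identical(a$trace$light, b$trace$light)
  expect_identical(a$states, b$states)
  expect_identical(as.character(a$hypnogram$states),
                   as.character(b$hypnogram$states))
  c_ <- simulate_mouse(cfg, seed = 100)
  expect_false(identical(a$trace$activity, c_$trace$activity))
})

test_that("output components are consistent with each other", {
  sim <- simulate_mouse(sim_config(duration_days = 2, seed = 12))
  n <- length(sim$states)
  expect_equal(nrow(sim$trace$activity), n)
  expect_equal(length(sim$hypnogram$states), n)
  expect_equal(length(sim$trace$light), n)
  # hypnogram is SLEEP -> NREM, wake states -> WAKE
  expect_equal(as.character(sim$hypnogram$states) == "NREM",
               as.character(sim$states) == "SLEEP")
  # light channel consistent with the declared schedule
  ph <- schedule_phase(sim$schedule, sim$trace$time)
  expect_true(all(sim$trace$light[ph == "LIGHT"] > 100))
  expect_true(all(sim$trace$light[ph == "DARK"] < 100))
  # emissions bounded
  expect_true(all(sim$trace$activity >= 0 & sim$trace$activity <= 100))
})

test_that("suppressing sleep dwell removes scoreable sleep entirely", {
  # sleep bouts collapse to single epochs (< 40 s); with no quiet wake and
  # no artifacts, no immobile run can reach the criterion
  cfg <- sim_config(duration_days = 1, sleep_dwell_s = 1e-9,
                    p_quiet_light = 0, p_quiet_dark = 0,
                    artifact_prob = 0, seed = 5)
  sim <- simulate_mouse(cfg)
  expect_lt(mean(sim$hypnogram$states == "NREM"), 0.5)
  expect_equal(sum(sleep_minutes_per_bin(score_sleep(sim$trace),
                                         1800)$values), 0)
})

test_that("simulated mice are nocturnal under LD", {
  n_dark_dominant <- 0L
  n_seeds <- 100L
  for (s in seq_len(n_seeds)) {
    sim <- simulate_mouse(sim_config(duration_days = 2, seed = 9000 + s))
    lit <- schedule_phase(sim$schedule, sim$trace$time) == "LIGHT"
    active <- sim$states == "ACTIVE"
    if (mean(active[!lit]) > mean(active[lit]))
      n_dark_dominant <- n_dark_dominant + 1L
  }
  expect_equal(n_dark_dominant, n_seeds)
})

test_that("free-running period is recovered from DD and LL simulations", {
  dd <- simulate_mouse(sim_config(duration_days = 10, regime = "DD",
                                  seed = 77))
  expect_equal(dd$config$tau_s, 23.7 * 3600)
  x <- resample_activity(dd$trace, 600, "mean")$activity[, 1]
  expect_equal(chisq_periodogram(x, 600)$peak_period_s / 3600, 23.7,
               tolerance = 0.01)
  ll <- simulate_mouse(sim_config(duration_days = 10, regime = "LL",
                                  seed = 78))
  expect_equal(ll$config$tau_s, 24.6 * 3600)
})

test_that("cohorts derive per-animal seeds deterministically and honour jitter", {
  cfg <- sim_config(duration_days = 1)
  a <- simulate_cohort(3, cfg, seed = 1234)
  b <- simulate_cohort(3, cfg, seed = 1234)
  expect_identical(lapply(a, function(s) s$trace$activity),
                   lapply(b, function(s) s$trace$activity))
  # zero jitter: animals differ only through their seeds
  expect_false(identical(a$m01$trace$activity, a$m02$trace$activity))
  expect_equal(a$m01$config$active_dwell_s, a$m02$config$active_dwell_s)
  # jitter perturbs the dwell parameter per animal
  j <- simulate_cohort(3, cfg, jitter = list(active_dwell_s = 30),
                       seed = 1234)
  dwells <- vapply(j, function(s) s$config$active_dwell_s, numeric(1))
  expect_gt(stats::sd(dwells), 0)
  expect_error(simulate_cohort(2, cfg, overrides = list(list())),
               "one element per animal")
})

test_that("a perfect sensor makes PIR sleep equal EEG sleep exactly", {
  cfg <- sim_config(duration_days = 4, p_quiet_light = 0, p_quiet_dark = 0,
                    artifact_prob = 0, min_sleep_bout_s = 40, seed = 314)
  sim <- simulate_mouse(cfg)
  pir <- sleep_minutes_per_bin(score_sleep(sim$trace), 1800)
  eeg <- hypnogram_sleep_minutes(sim$hypnogram, 1800)
  expect_identical(pir$values, eeg$values)
})
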