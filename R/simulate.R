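#' Configure a home-cage behaviour simulation
#'
#' Defines a semi-Markov behavioural-state model of a singly housed mouse
#' under a known light regime, together with the PIR emission model that
#' turns states into percent-activation epochs. The simulator alternates
#' wake and sleep bouts with exponentially distributed dwell times whose
#' means are modulated by circadian phase: in the (subjective) night the
#' mean ACTIVE dwell is multiplied by \code{active_dark_mult} (nocturnality)
#' and in the (subjective) day the mean SLEEP dwell by
#' \code{sleep_light_mult}. Each wake bout is quiet wakefulness — awake but
#' essentially motionless, the known confound of immobility-based sleep
#' scoring — with phase-dependent probability \code{p_quiet_light} /
#' \code{p_quiet_dark}, otherwise ACTIVE.
#'
#' Emissions per 10-s epoch: ACTIVE draws a percent activation from a
#' Normal(\code{mu_active}, \code{sd_active}) rounded and clamped to
#' [1, 100] (a locomoting mouse always trips at least one of the 100 sensor
#' polls); QUIET_WAKE moves with per-epoch probability
#' \code{quiet_move_prob} (drawing from Normal(\code{mu_quiet},
#' \code{sd_quiet}), clamped to [1, 100]) and is otherwise 0; SLEEP is 0
#' except for sensor artifacts with per-epoch probability
#' \code{artifact_prob}.
#'
#' Circadian phase comes from the light cycle in LD and free-runs at
#' \code{tau_s} in DD/LL (defaults 23.7 h in DD, 24.6 h in LL — the
#' canonical shortening in constant dark and lengthening in constant light
#' for C57BL/6J). \code{phase_offset_s} shifts the animal's subjective
#' clock without moving the light channel, which lets cohorts carry
#' early/late chronotype phenotypes.
#'
#' @param duration_days length of the recording.
#' @param epoch_s acquisition epoch (10 s).
#' @param regime \code{"LD"}, \code{"DD"} or \code{"LL"}.
#' @param light_period_s,light_fraction light cycle (default 12 h : 12 h;
#'   lights on at recording start).
#' @param tau_s intrinsic free-running period; \code{NULL} picks the regime
#'   default (entrained = light period in LD, 23.7 h DD, 24.6 h LL).
#' @param phase_offset_s subjective-clock offset in seconds.
#' @param active_dwell_s mean ACTIVE bout length (s) in the subjective day.
#' @param active_dark_mult multiplier on the ACTIVE dwell in the subjective
#'   night (> 1 makes the animal nocturnal).
#' @param quiet_dwell_s mean quiet-wakefulness bout length (s).
#' @param sleep_dwell_s mean sleep bout length (s) in the subjective night.
#' @param sleep_light_mult multiplier on the sleep dwell in the subjective
#'   day.
#' @param p_quiet_light,p_quiet_dark probability that a wake bout is quiet
#'   wakefulness, in the light and dark phase respectively.
#' @param quiet_move_prob per-epoch probability of detectable movement
#'   during quiet wakefulness.
#' @param artifact_prob per-epoch probability of a spurious activation
#'   during sleep.
#' @param mu_active,sd_active,mu_quiet,sd_quiet emission parameters (percent
#'   activation).
#' @param min_sleep_bout_s floor on sleep-bout length (0 = none; set to 40
#'   to guarantee every bout is scoreable by the 40-s criterion).
#' @param light_on_level,light_off_level mean raw LDR reading when lights
#'   are on / off.
#' @param start_time POSIXct (UTC) start of the recording.
#' @param seed optional RNG seed stored in the config; identical seeds give
#'   bit-identical simulations.
#' @return validated object of class \code{"sim_config"}.
#' @export
sim_config <- function(duration_days = 14, epoch_s = 10,
                       regime = c("LD", "DD", "LL"),
                       light_period_s = 86400, light_fraction = 0.5,
                       tau_s = NULL, phase_offset_s = 0,
                       active_dwell_s = 240, active_dark_mult = 4,
                       quiet_dwell_s = 240,
                       sleep_dwell_s = 420, sleep_light_mult = 2.5,
                       p_quiet_light = 0.30, p_quiet_dark = 0.08,
                       quiet_move_prob = 0.1, artifact_prob = 0.001,
                       mu_active = 40, sd_active = 20,
                       mu_quiet = 3, sd_quiet = 2,
                       min_sleep_bout_s = 0,
                       light_on_level = 500, light_off_level = 3,
                       start_time = as.POSIXct("2024-01-01 00:00:00",
                                               tz = "UTC"),
                       seed = NULL) {
  regime <- match.arg(regime)
  if (is.null(tau_s))
    tau_s <- switch(regime, LD = light_period_s, DD = 23.7 * 3600,
                    LL = 24.6 * 3600)
  cfg <- list(duration_days = duration_days, epoch_s = epoch_s,
              regime = regime, light_period_s = light_period_s,
              light_fraction = light_fraction, tau_s = tau_s,
              phase_offset_s = phase_offset_s,
              active_dwell_s = active_dwell_s,
              active_dark_mult = active_dark_mult,
              quiet_dwell_s = quiet_dwell_s, sleep_dwell_s = sleep_dwell_s,
              sleep_light_mult = sleep_light_mult,
              p_quiet_light = p_quiet_light, p_quiet_dark = p_quiet_dark,
              quiet_move_prob = quiet_move_prob,
              artifact_prob = artifact_prob,
              mu_active = mu_active, sd_active = sd_active,
              mu_quiet = mu_quiet, sd_quiet = sd_quiet,
              min_sleep_bout_s = min_sleep_bout_s,
              light_on_level = light_on_level,
              light_off_level = light_off_level,
              start_time = start_time, seed = seed)
  bad <- character(0)
  pos <- c("duration_days", "epoch_s", "light_period_s", "tau_s",
           "active_dwell_s", "active_dark_mult", "quiet_dwell_s",
           "sleep_dwell_s", "sleep_light_mult")
  for (f in pos)
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] <= 0)
      bad <- c(bad, f)
  prob <- c("light_fraction", "p_quiet_light", "p_quiet_dark",
            "quiet_move_prob", "artifact_prob")
  for (f in prob)
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L ||
        cfg[[f]] < 0 || cfg[[f]] > 1)
      bad <- c(bad, f)
  if (!is.numeric(cfg$min_sleep_bout_s) || cfg$min_sleep_bout_s < 0)
    bad <- c(bad, "min_sleep_bout_s")
  if (length(bad) > 0L)
    stop("invalid sim_config field(s): ", paste(bad, collapse = ", "))
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("simulation config: %g days, %s regime, tau = %.2f h\n",
              x$duration_days, x$regime, x$tau_s / 3600))
  invisible(x)
}

# Subjective circadian day indicator at time t (seconds from start).
subjective_day <- function(cfg, t_s) {
  ((t_s - cfg$phase_offset_s) %% cfg$tau_s) / cfg$tau_s < cfg$light_fraction
}

# Actual light at time t (seconds from start): lights on at t = 0 in LD.
lights_on_at <- function(cfg, t_s) {
  switch(cfg$regime,
         LD = (t_s %% cfg$light_period_s) / cfg$light_period_s <
           cfg$light_fraction,
         DD = rep(FALSE, length(t_s)),
         LL = rep(TRUE, length(t_s)))
}

#' Simulate one mouse
#'
#' Samples the semi-Markov behavioural-state sequence defined by a
#' \code{\link{sim_config}}, emits a PIR activity trace with a matched light
#' channel, and derives the ground-truth hypnogram (SLEEP epochs scored
#' NREM, everything else WAKE) and light schedule. Identical seeds give
#' bit-identical output.
#'
#' @param config a \code{\link{sim_config}}.
#' @param seed RNG seed (defaults to \code{config$seed}; \code{NULL} leaves
#'   the RNG state untouched).
#' @return object of class \code{"sim_output"}: \code{trace}
#'   (\code{\link{activity_trace}} with one cage), \code{states} (factor
#'   ACTIVE/QUIET_WAKE/SLEEP per epoch), \code{hypnogram},
#'   \code{schedule}, \code{config}.
#' @export
simulate_mouse <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  cfg <- config
  ep <- cfg$epoch_s
  n <- as.integer(round(cfg$duration_days * 86400 / ep))
  min_sleep_ep <- as.integer(ceiling(cfg$min_sleep_bout_s / ep))

  # --- state sequence: alternate wake and sleep bouts ---------------------
  vals <- integer(0)    # 1 ACTIVE, 2 QUIET_WAKE, 3 SLEEP
  lens <- integer(0)
  pos <- 0L
  asleep <- subjective_day(cfg, 0)  # animals mostly asleep in the day
  while (pos < n) {
    t_s <- pos * ep
    day <- subjective_day(cfg, t_s)
    if (asleep) {
      st <- 3L
      mean_s <- cfg$sleep_dwell_s * if (day) cfg$sleep_light_mult else 1
      d <- max(stats::rexp(1L, 1 / mean_s), cfg$min_sleep_bout_s)
      ne <- max(1L, as.integer(round(d / ep)), min_sleep_ep)
    } else {
      p_quiet <- if (day) cfg$p_quiet_light else cfg$p_quiet_dark
      if (stats::runif(1L) < p_quiet) {
        st <- 2L
        mean_s <- cfg$quiet_dwell_s
      } else {
        st <- 1L
        mean_s <- cfg$active_dwell_s * if (day) 1 else cfg$active_dark_mult
      }
      ne <- max(1L, as.integer(round(stats::rexp(1L, 1 / mean_s) / ep)))
    }
    vals <- c(vals, st)
    lens <- c(lens, ne)
    pos <- pos + ne
    asleep <- !asleep
  }
  states <- rep.int(vals, lens)[seq_len(n)]

  # --- emissions ----------------------------------------------------------
  act <- numeric(n)
  ia <- which(states == 1L)
  if (length(ia) > 0L)
    act[ia] <- pmin(100, pmax(1, round(stats::rnorm(length(ia),
                                                    cfg$mu_active,
                                                    cfg$sd_active))))
  iq <- which(states == 2L)
  if (length(iq) > 0L) {
    mv <- stats::runif(length(iq)) < cfg$quiet_move_prob
    if (any(mv))
      act[iq[mv]] <- pmin(100, pmax(1, round(stats::rnorm(sum(mv),
                                                          cfg$mu_quiet,
                                                          cfg$sd_quiet))))
  }
  is_ <- which(states == 3L)
  if (length(is_) > 0L) {
    ar <- stats::runif(length(is_)) < cfg$artifact_prob
    if (any(ar))
      act[is_[ar]] <- pmin(100, pmax(1, round(stats::rnorm(sum(ar),
                                                           cfg$mu_quiet,
                                                           cfg$sd_quiet))))
  }

  # --- light channel + ground-truth schedule ------------------------------
  t_s <- (seq_len(n) - 1L) * ep
  lit <- lights_on_at(cfg, t_s)
  light <- numeric(n)
  light[lit] <- round(pmax(0, stats::rnorm(sum(lit), cfg$light_on_level,
                                           0.05 * cfg$light_on_level)))
  light[!lit] <- round(pmax(0, stats::rnorm(sum(!lit), cfg$light_off_level,
                                            1)))
  r <- rle(lit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  intervals <- data.frame(
    start = cfg$start_time + (starts - 1L) * ep,
    end = cfg$start_time + ends * ep,
    phase = ifelse(r$values, "LIGHT", "DARK"),
    stringsAsFactors = FALSE)
  schedule <- light_schedule(
    intervals, regime = cfg$regime,
    period_s = if (cfg$regime == "LD") cfg$light_period_s else NA_real_)

  time <- cfg$start_time + t_s
  trace <- activity_trace(time, matrix(act, ncol = 1L), light = light,
                          epoch_s = ep, cages = "sim")
  hyp <- hypnogram(ifelse(states == 3L, "NREM", "WAKE"),
                   start_time = cfg$start_time, epoch_s = ep)
  structure(list(trace = trace,
                 states = factor(c("ACTIVE", "QUIET_WAKE", "SLEEP")[states],
                                 levels = c("ACTIVE", "QUIET_WAKE", "SLEEP")),
                 hypnogram = hyp, schedule = schedule, config = cfg),
            class = "sim_output")
}

#' @export
print.sim_output <- function(x, ...) {
  n <- length(x$states)
  cat(sprintf("simulated mouse: %.1f days, %s regime, tau %.2f h\n",
              n * x$config$epoch_s / 86400, x$config$regime,
              x$config$tau_s / 3600))
  print(round(table(x$states) / n, 3))
  invisible(x)
}

#' Simulate a cohort
#'
#' Runs \code{\link{simulate_mouse}} for \code{n_animals} copies of a
#' template config. Per-animal RNG seeds are derived deterministically from
#' the master seed; optional Gaussian jitter perturbs named numeric config
#' fields per animal, and \code{overrides} (a list of per-animal named
#' lists) imposes systematic differences such as phase phenotypes.
#'
#' @param n_animals number of animals.
#' @param config template \code{\link{sim_config}}.
#' @param jitter named list of standard deviations, e.g.
#'   \code{list(active_dwell_s = 30)}; jittered positive fields are floored
#'   at 10\% of the template value.
#' @param overrides optional list of length \code{n_animals}; element i is a
#'   named list of config fields replaced for animal i.
#' @param seed master seed.
#' @return named list of \code{"sim_output"} objects (\code{m01}, ...).
#' @export
simulate_cohort <- function(n_animals, config, jitter = list(),
                            overrides = NULL, seed = NULL) {
  stopifnot(inherits(config, "sim_config"), n_animals >= 1L)
  if (!is.null(overrides) && length(overrides) != n_animals)
    stop("overrides must have one element per animal")
  if (!is.null(seed)) set.seed(seed)
  animal_seeds <- sample.int(2147483646L, n_animals)
  jit <- lapply(jitter, function(sd_)
    stats::rnorm(n_animals, 0, sd_))
  out <- vector("list", n_animals)
  for (i in seq_len(n_animals)) {
    ci <- unclass(config)
    for (f in names(jitter)) {
      v <- ci[[f]] + jit[[f]][i]
      if (ci[[f]] > 0) v <- max(v, 0.1 * ci[[f]])
      ci[[f]] <- v
    }
    if (!is.null(overrides))
      for (f in names(overrides[[i]])) ci[[f]] <- overrides[[i]][[f]]
    ci$seed <- NULL
    cfg_i <- do.call(sim_config, ci)
    out[[i]] <- simulate_mouse(cfg_i, seed = animal_seeds[i])
  }
  names(out) <- sprintf("m%02d", seq_len(n_animals))
  out
}
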