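#' Sokolove-Bushell chi-squared periodogram
#'
#' For each candidate period P (in bins) the series is folded into K
#' complete cycles of P columns and the rhythm statistic computed as
#' \deqn{Q_P = K N \sum_h (M_h - \bar M)^2 / \sum_i (x_i - \bar M)^2}
#' where N = K P is the number of bins used, M_h are the column (phase)
#' means and \eqn{\bar M} the grand mean over those N bins. Under the null
#' of no rhythm Q_P is approximately chi-square with P - 1 degrees of
#' freedom, giving a per-period significance line at the (1 - alpha)
#' quantile. The peak period is the candidate with the largest excess of
#' Q_P over its significance line.
#'
#' Q_P is invariant to affine rescaling of the activity values. The input
#' is normally mean activity in 10-min bins.
#'
#' @param x numeric vector of binned activity (gap-free).
#' @param bin_s bin width in seconds.
#' @param period_range_s candidate period range in seconds (default
#'   20-28 h); candidates are every integer number of bins inside it.
#' @param alpha significance level for the threshold line.
#' @return an object of class \code{"chisq_periodogram"}: data.frame-like
#'   list with \code{period_s}, \code{qp}, \code{df}, \code{sig},
#'   plus \code{peak_period_s}, \code{alpha}, \code{bin_s}.
#' @export
chisq_periodogram <- function(x, bin_s, period_range_s = c(20, 28) * 3600,
                              alpha = 0.001) {
  x <- as.numeric(x)
  if (anyNA(x))
    stop("periodogram input must be gap-free; fill or trim missing bins first")
  if (stats::var(x) == 0)
    stop("no rhythm detectable: input has zero variance")
  pmin_b <- max(2L, as.integer(ceiling(period_range_s[1L] / bin_s)))
  pmax_b <- as.integer(floor(period_range_s[2L] / bin_s))
  if (pmax_b < pmin_b) stop("empty candidate period range")
  n <- length(x)
  if (n < 2L * pmax_b)
    stop("fewer than 2 complete cycles of the longest candidate period (",
         pmax_b * bin_s, " s); need >= ", 2L * pmax_b, " bins, have ", n)
  periods <- pmin_b:pmax_b
  qp <- vapply(periods, function(P) {
    K <- n %/% P
    N <- K * P
    xs <- x[seq_len(N)]
    M <- colMeans(matrix(xs, nrow = K, byrow = TRUE))
    Mbar <- mean(xs)
    denom <- sum((xs - Mbar)^2)
    K * N * sum((M - Mbar)^2) / denom
  }, numeric(1))
  df <- periods - 1L
  sig <- stats::qchisq(1 - alpha, df)
  excess <- qp - sig
  peak <- if (any(excess > 0)) periods[which.max(excess)] * bin_s else NA_real_
  structure(list(period_s = periods * bin_s, qp = qp, df = df, sig = sig,
                 peak_period_s = peak, alpha = alpha, bin_s = bin_s),
            class = "chisq_periodogram")
}

#' @export
print.chisq_periodogram <- function(x, ...) {
  cat(sprintf("chi-squared periodogram: %d candidate periods, %.1f-%.1f h\n",
              length(x$period_s), min(x$period_s) / 3600,
              max(x$period_s) / 3600))
  if (is.na(x$peak_period_s)) {
    cat(sprintf("  no period significant at alpha = %g\n", x$alpha))
  } else {
    i <- match(x$peak_period_s, x$period_s)
    cat(sprintf("  peak period %.2f h (Qp = %.1f, threshold %.1f, alpha = %g)\n",
                x$peak_period_s / 3600, x$qp[i], x$sig[i], x$alpha))
  }
  invisible(x)
}

#' @export
plot.chisq_periodogram <- function(x, ...) {
  h <- x$period_s / 3600
  graphics::plot(h, x$qp, type = "l", xlab = "period (h)",
                 ylab = expression(Q[p]), ...)
  graphics::lines(h, x$sig, lty = 2, col = "red")
  if (!is.na(x$peak_period_s))
    graphics::abline(v = x$peak_period_s / 3600, col = "grey", lty = 3)
  invisible(x)
}

#' Fold binned activity into an actogram matrix
#'
#' Row d, column b holds the activity of day d at time-of-period b. With
#' \code{double_plot = TRUE} each row shows day d followed by day d + 1
#' (the standard double-plotted actogram); the right half of the last row is
#' missing. Incomplete trailing days are padded with \code{NA}.
#'
#' @param x numeric vector of binned activity.
#' @param bin_s bin width in seconds.
#' @param period_s folding period in seconds (default 24 h); must be an
#'   integer multiple of \code{bin_s}.
#' @param double_plot plot two consecutive periods per row?
#' @return a matrix of class \code{"actogram"} [days x bins] (or
#'   [days x 2 bins] when double-plotted).
#' @export
actogram_matrix <- function(x, bin_s, period_s = 86400, double_plot = TRUE) {
  x <- as.numeric(x)
  p <- period_s / bin_s
  if (p != round(p) || p < 1)
    stop("period_s must be a positive integer multiple of bin_s")
  p <- as.integer(round(p))
  nd <- ceiling(length(x) / p)
  xp <- c(x, rep(NA_real_, nd * p - length(x)))
  m <- matrix(xp, nrow = nd, ncol = p, byrow = TRUE)
  if (double_plot)
    m <- cbind(m, rbind(m[-1L, , drop = FALSE], rep(NA_real_, p)))
  dimnames(m) <- list(paste0("day", seq_len(nd)),
                      paste0("b", seq_len(ncol(m))))
  structure(m, bin_s = bin_s, period_s = period_s, double_plot = double_plot,
            class = c("actogram", class(m)))
}

#' @export
plot.actogram <- function(x, col = grDevices::grey.colors(64, 0.95, 0),
                          ...) {
  m <- unclass(x)
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  graphics::image(x = seq_len(ncol(m)) * attr(x, "bin_s") / 3600,
                  y = seq_len(nrow(m)), z = t(m), col = col,
                  xlab = "time (h)", ylab = "day", yaxt = "n", ...)
  graphics::axis(2, at = seq_len(nrow(m)), labels = rev(seq_len(nrow(m))))
  invisible(x)
}

light_schedule <- function(intervals, regime, period_s = NA_real_,
                           threshold = NA_real_) {
  structure(list(intervals = intervals, regime = regime,
                 period_s = period_s, threshold = threshold),
            class = "light_schedule")
}

#' @export
print.light_schedule <- function(x, ...) {
  cat(sprintf("light schedule: regime %s", x$regime))
  if (!is.na(x$period_s)) cat(sprintf(", period %.2f h", x$period_s / 3600))
  cat(sprintf(", %d interval(s)\n", nrow(x$intervals)))
  invisible(x)
}

#' Infer the light schedule from the LDR channel
#'
#' Thresholds the raw light readings (automatic threshold = midpoint of a
#' 2-means split of the values), debounces phase runs shorter than
#' \code{debounce_s}, and classifies the regime: \code{LD} when light and
#' dark alternate with a stable period, \code{DD} when always dark,
#' \code{LL} when always light, \code{irregular} otherwise. With the
#' automatic threshold, values that do not separate into two modes
#' (separation below twice the within-cluster spread) are refused.
#'
#' @param light numeric vector of raw light readings, one per epoch.
#' @param epoch_s epoch width in seconds.
#' @param threshold \code{"auto"} or an explicit numeric cut; readings >=
#'   the cut are LIGHT.
#' @param debounce_s minimum accepted phase duration (default 600 s);
#'   shorter runs are absorbed into their neighbours.
#' @param start_time optional POSIXct start; interval times are POSIXct when
#'   given, else seconds from trace start.
#' @return a \code{"light_schedule"}: intervals (start, end, phase), regime,
#'   period_s, threshold.
#' @export
infer_light_schedule <- function(light, epoch_s, threshold = "auto",
                                 debounce_s = 600, start_time = NULL) {
  light <- as.numeric(light)
  ok <- !is.na(light)
  if (!any(ok)) stop("no light readings")
  if (identical(threshold, "auto")) {
    v <- light[ok]
    if (length(unique(v)) < 2L)
      stop("cannot infer light threshold: light channel is unimodal; ",
           "supply an explicit threshold")
    km <- stats::kmeans(v, centers = range(v))
    cs <- sort(km$centers[, 1L])
    wsd <- vapply(1:2, function(g) {
      vg <- v[km$cluster == g]
      if (length(vg) > 1L) stats::sd(vg) else 0
    }, numeric(1))
    if (diff(cs) <= 2 * sum(wsd))
      stop("cannot infer light threshold: light histogram looks unimodal ",
           "(mode separation ", signif(diff(cs), 3), " <= 2x spread ",
           signif(sum(wsd), 3), "); supply an explicit threshold")
    threshold <- mean(cs)
  }
  lit <- light >= threshold
  lit[!ok] <- FALSE
  deb <- max(1L, as.integer(round(debounce_s / epoch_s)))
  r <- rle(lit)
  while (length(r$lengths) > 1L && any(r$lengths < deb)) {
    i <- which.min(r$lengths)
    if (r$lengths[i] >= deb) break
    r$values[i] <- !r$values[i]
    r <- rle(inverse.rle(r))
  }
  lit <- inverse.rle(r)
  r <- rle(lit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  t_of <- function(i) {
    s <- (i - 1L) * epoch_s
    if (is.null(start_time)) s else start_time + s
  }
  intervals <- data.frame(start = t_of(starts), end = t_of(ends + 1L),
                          phase = ifelse(r$values, "LIGHT", "DARK"),
                          stringsAsFactors = FALSE)
  period_s <- NA_real_
  if (all(!lit)) {
    regime <- "DD"
  } else if (all(lit)) {
    regime <- "LL"
  } else {
    # full light/dark cycles: drop the (possibly partial) first and last run
    nr <- length(r$lengths)
    full <- if (nr > 2L) r$lengths[2:(nr - 1L)] else integer(0)
    fullv <- if (nr > 2L) r$values[2:(nr - 1L)] else logical(0)
    stable <- function(d) length(d) == 0L ||
      (max(d) - min(d)) <= 0.1 * stats::median(d)
    if (nr >= 3L && stable(full[fullv]) && stable(full[!fullv])) {
      regime <- "LD"
      ml <- mean(full[fullv]) * epoch_s
      md <- mean(full[!fullv]) * epoch_s
      if (length(full[fullv]) == 0L || length(full[!fullv]) == 0L) {
        # fewer than one full run of each phase: fall back to onset spacing
        period_s <- NA_real_
      } else period_s <- ml + md
    } else regime <- "irregular"
  }
  light_schedule(intervals, regime, period_s, threshold)
}

#' Light phase at given times
#'
#' @param schedule a \code{"light_schedule"}.
#' @param times POSIXct or numeric times (same representation as the
#'   schedule's intervals).
#' @return character vector \code{"LIGHT"}/\code{"DARK"} (\code{NA} outside
#'   the schedule).
#' @export
schedule_phase <- function(schedule, times) {
  stopifnot(inherits(schedule, "light_schedule"))
  iv <- schedule$intervals
  i <- findInterval(as.numeric(times), as.numeric(iv$start))
  out <- rep(NA_character_, length(times))
  ok <- i >= 1L & as.numeric(times) < as.numeric(iv$end[pmax(i, 1L)])
  out[ok] <- iv$phase[i[ok]]
  out
}

#' Detect daily activity onset
#'
#' Scans one folded day of binned activity for the first bin whose value
#' exceeds mean + k * sd of the preceding quiescent baseline window and
#' whose following \code{sustain_s} of activity stays above that threshold
#' on average (the window-mean form is robust to single-bin dips from brief
#' sleep bouts after onset). Days with no qualifying bin yield \code{NA}
#' (a missing onset, not an error).
#'
#' @param x numeric vector of one period of binned activity, or an actogram
#'   matrix (single-plotted; one onset per row).
#' @param bin_s bin width in seconds.
#' @param baseline_window_s length of the preceding baseline window
#'   (default 6 h).
#' @param k threshold in baseline standard deviations (default 2).
#' @param sustain_s length of the post-onset window whose mean activity
#'   must stay above threshold (default 30 min).
#' @param floor_frac optional scale-aware floor: the threshold is never
#'   lower than \code{floor_frac} times the profile maximum. The default of
#'   0 keeps the plain baseline rule; ~0.25 makes detection robust to small
#'   ultradian bouts rising out of an otherwise dead-quiet rest phase.
#' @return onset time(s) in seconds from the start of the period, \code{NA}
#'   where none qualifies.
#' @export
activity_onset <- function(x, bin_s, baseline_window_s = 21600, k = 2,
                           sustain_s = 1800, floor_frac = 0) {
  if (is.matrix(x))
    return(apply(unclass(x), 1L, activity_onset, bin_s = bin_s,
                 baseline_window_s = baseline_window_s, k = k,
                 sustain_s = sustain_s, floor_frac = floor_frac))
  x <- as.numeric(x)
  w <- max(1L, as.integer(round(baseline_window_s / bin_s)))
  s <- max(1L, as.integer(round(sustain_s / bin_s)))
  n <- length(x)
  if (n < w + s) return(NA_real_)
  floor_thr <- floor_frac * max(x, na.rm = TRUE)
  for (i in (w + 1L):(n - s + 1L)) {
    base <- x[(i - w):(i - 1L)]
    if (anyNA(base) || anyNA(x[i:(i + s - 1L)])) next
    thr <- max(mean(base) + k * stats::sd(base), floor_thr)
    if (x[i] > thr && mean(x[i:(i + s - 1L)]) > thr)
      return((i - 1L) * bin_s)
  }
  NA_real_
}

#' Interdaily stability
#'
#' Nonparametric measure of how reproducible the 24-h activity profile is
#' from day to day: the variance of the mean daily profile relative to the
#' total variance,
#' \deqn{IS = n \sum_h (\bar x_h - \bar x)^2 / (p \sum_i (x_i - \bar x)^2)}
#' over p period-bins and n total bins. 1 for a perfectly repeated daily
#' pattern, near 0 for noise.
#'
#' @param x numeric vector of binned activity (>= 2 complete periods).
#' @param bin_s bin width in seconds.
#' @param period_s folding period (default 24 h); must be a multiple of
#'   \code{bin_s}.
#' @return IS in [0, 1].
#' @export
interdaily_stability <- function(x, bin_s, period_s = 86400) {
  x <- as.numeric(x)
  if (anyNA(x)) stop("IS requires gap-free input")
  p <- period_s / bin_s
  if (p != round(p) || p < 1)
    stop("period_s must be a positive integer multiple of bin_s")
  p <- as.integer(round(p))
  n <- length(x)
  if (n < 2L * p) stop("need at least 2 complete periods")
  tot <- sum((x - mean(x))^2)
  if (tot == 0) stop("zero-variance input")
  h <- ((seq_len(n) - 1L) %% p) + 1L
  xh <- as.numeric(tapply(x, h, mean))
  n * sum((xh - mean(x))^2) / (p * tot)
}

#' Intradaily variability
#'
#' Nonparametric fragmentation measure: the mean squared first difference of
#' the series relative to its variance,
#' \deqn{IV = n \sum_i (x_i - x_{i-1})^2 / ((n - 1) \sum_i (x_i - \bar x)^2).}
#' About 2 for white noise, near 0 for a smooth sinusoid; higher values mean
#' a more fragmented rhythm.
#'
#' @param x numeric vector of binned activity.
#' @param bin_s bin width in seconds (kept for interface symmetry).
#' @return IV >= 0.
#' @export
intradaily_variability <- function(x, bin_s = NULL) {
  x <- as.numeric(x)
  if (anyNA(x)) stop("IV requires gap-free input")
  n <- length(x)
  if (n < 2L) stop("need at least 2 bins")
  tot <- sum((x - mean(x))^2)
  if (tot == 0) stop("zero-variance input")
  n * sum(diff(x)^2) / ((n - 1L) * tot)
}
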