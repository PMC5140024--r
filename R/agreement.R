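#' Align two binned sleep series on their common time range
#'
#' Restricts a PIR-scored and an EEG-scored minutes-per-bin series to the
#' bins present in both (matched on bin start time); the counts of bins
#' dropped from each side are reported.
#'
#' @param x,y binned series with the same \code{bin_s} (e.g. from
#'   \code{\link{sleep_minutes_per_bin}} and
#'   \code{\link{hypnogram_sleep_minutes}}). When both carry bin times the
#'   match is on time; clockless series are matched by index.
#' @return list with \code{time}, \code{x}, \code{y}, \code{dropped_x},
#'   \code{dropped_y}.
#' @export
align_sleep_pairs <- function(x, y) {
  stopifnot(inherits(x, "binned_series"), inherits(y, "binned_series"))
  if (x$bin_s != y$bin_s)
    stop("bin widths differ (", x$bin_s, " vs ", y$bin_s,
         " s); resample first")
  if (!is.null(x$time) && !is.null(y$time)) {
    tx <- as.numeric(x$time)
    ty <- as.numeric(y$time)
    common <- intersect(tx, ty)
    if (length(common) == 0L) stop("no overlapping bins between the series")
    common <- sort(common)
    ix <- match(common, tx)
    iy <- match(common, ty)
    time <- x$time[ix]
  } else {
    n <- min(length(x$values), length(y$values))
    if (n == 0L) stop("no overlapping bins between the series")
    ix <- seq_len(n)
    iy <- seq_len(n)
    time <- if (!is.null(x$time)) x$time[ix] else NULL
  }
  list(time = time, x = x$values[ix], y = y$values[iy],
       dropped_x = length(x$values) - length(ix),
       dropped_y = length(y$values) - length(iy))
}

#' Pearson product-moment correlation
#'
#' Thin wrapper around \code{stats::cor} that refuses degenerate input:
#' fewer than 3 pairs or a constant vector (where r is undefined) raise an
#' error rather than returning \code{NA}.
#'
#' @param x,y numeric vectors of equal length.
#' @return r in [-1, 1].
#' @export
pearson_r <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) stop("lengths differ")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant vector")
  stats::cor(x, y)
}

#' Bland-Altman agreement analysis
#'
#' Computes the per-bin differences d = x - y (method 1 minus method 2),
#' their mean (the bias) and the limits of agreement bias +/- 1.96 sd(d)
#' (sample sd, n - 1 denominator). When per-bin phase labels are supplied
#' the analysis is repeated on each phase subset, so agreement in the light
#' and dark halves of the day can be compared.
#'
#' @param x,y paired numeric vectors (minutes of sleep per bin by the two
#'   methods).
#' @param phase optional character vector of per-bin labels (e.g.
#'   \code{"LIGHT"}/\code{"DARK"}).
#' @param conf_mult multiplier for the limits (1.96 for 95\% limits of
#'   agreement).
#' @return object of class \code{"bland_altman"}: data.frame \code{stats}
#'   with one row per subset (subset, n, bias, sd_diff, loa_low, loa_high).
#' @export
bland_altman <- function(x, y, phase = NULL, conf_mult = 1.96) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) stop("lengths differ")
  if (length(x) < 2L) stop("need at least 2 pairs")
  d <- x - y
  one <- function(dd, label) {
    if (length(dd) < 2L)
      return(data.frame(subset = label, n = length(dd), bias = mean(dd),
                        sd_diff = NA_real_, loa_low = NA_real_,
                        loa_high = NA_real_, stringsAsFactors = FALSE))
    s <- stats::sd(dd)
    m <- mean(dd)
    data.frame(subset = label, n = length(dd), bias = m, sd_diff = s,
               loa_low = m - conf_mult * s, loa_high = m + conf_mult * s,
               stringsAsFactors = FALSE)
  }
  out <- one(d, "overall")
  if (!is.null(phase)) {
    if (length(phase) != length(d)) stop("phase labels must match pairs")
    for (ph in unique(phase[!is.na(phase)]))
      out <- rbind(out, one(d[!is.na(phase) & phase == ph], ph))
  }
  structure(list(stats = out, conf_mult = conf_mult),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, digits = 3, ...) {
  cat("Bland-Altman agreement (method 1 - method 2)\n")
  s <- x$stats
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-8s n=%4d  bias %+0.*f  limits of agreement [%0.*f, %0.*f]\n",
                s$subset[i], s$n[i], digits, s$bias[i], digits,
                s$loa_low[i], digits, s$loa_high[i]))
  invisible(x)
}

#' Validate PIR-scored sleep against an EEG hypnogram
#'
#' End-to-end convenience wrapper: scores the PIR trace for sleep, bins both
#' the PIR and EEG sleep into minutes per \code{bin_s}, aligns them on their
#' common time range, and reports the Pearson correlation and Bland-Altman
#' agreement, split by light phase when a schedule is supplied (bins
#' straddling a light transition are assigned by their start time).
#'
#' @param trace an \code{\link{activity_trace}} with a single cage (or a
#'   pre-scored \code{sleep_series}).
#' @param hyp a \code{\link{hypnogram}} covering an overlapping time range.
#' @param bin_s comparison bin width in seconds (default 1800 = 30 min).
#' @param schedule optional \code{"light_schedule"} for the phase split.
#' @param mode sleep-scoring mode passed to \code{\link{score_sleep}}.
#' @param threshold_bins immobility threshold passed to
#'   \code{\link{score_sleep}}.
#' @return object of class \code{"sleep_agreement"}: \code{pearson_r},
#'   \code{bland_altman}, \code{n_bins}, \code{bin_s}, \code{pairs}.
#' @export
sleep_agreement <- function(trace, hyp, bin_s = 1800, schedule = NULL,
                            mode = "run", threshold_bins = 4) {
  series <- if (inherits(trace, "sleep_series")) trace
  else score_sleep(trace, threshold_bins = threshold_bins, mode = mode)
  if (!inherits(series, "sleep_series"))
    stop("trace must hold exactly one cage")
  pir <- sleep_minutes_per_bin(series, bin_s)
  eeg <- hypnogram_sleep_minutes(hyp, bin_s)
  pr <- align_sleep_pairs(pir, eeg)
  phase <- if (!is.null(schedule) && !is.null(pr$time))
    schedule_phase(schedule, pr$time) else NULL
  structure(list(pearson_r = pearson_r(pr$x, pr$y),
                 bland_altman = bland_altman(pr$x, pr$y, phase = phase),
                 n_bins = length(pr$x), bin_s = bin_s, pairs = pr),
            class = "sleep_agreement")
}

#' @export
print.sleep_agreement <- function(x, ...) {
  cat(sprintf("PIR vs EEG sleep agreement over %d bins of %g min\n",
              x$n_bins, x$bin_s / 60))
  cat(sprintf("  Pearson r = %.3f\n", x$pearson_r))
  print(x$bland_altman)
  invisible(x)
}
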