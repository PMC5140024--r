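#' Score behavioural sleep from immobility
#'
#' Flags epochs as asleep when the animal has been immobile (zero PIR
#' activation) for at least \code{threshold_bins} consecutive epochs — with
#' 10 s epochs and the default of 4 bins this is the classic ">= 40 s of
#' immobility" criterion.
#'
#' Two conventions are provided. In \code{"run"} mode (default) every epoch
#' inside a maximal zero-activity run of length >= \code{threshold_bins} is
#' flagged, so a 60 s immobile period scores 60 s of sleep. In
#' \code{"window"} mode epoch i is flagged iff the window of
#' \code{threshold_bins} epochs ending at i is all zero — the literal
#' rolling-sum spreadsheet rule (\code{IF(SUM(last 4 bins)=0,1,0)}) — which
#' scores the same period as 30 s because the first three epochs of each run
#' cannot complete a window. The two totals differ by exactly
#' \code{threshold_bins - 1} epochs per qualifying run.
#'
#' Missing epochs break immobility runs by default and their flags are
#' \code{NA}.
#'
#' @param x numeric vector of percent activation per epoch, or an
#'   \code{\link{activity_trace}} (scored per cage; returns a named list).
#' @param threshold_bins immobility threshold in epochs (>= 1).
#' @param mode \code{"run"} or \code{"window"}.
#' @param epoch_s epoch width in seconds (taken from the trace if given one).
#' @param floor activity at or below this value counts as immobile
#'   (default 0: any nonzero activation breaks immobility).
#' @param na_breaks should missing epochs break immobility runs?
#' @param start_time optional POSIXct start of the first epoch.
#' @return an object of class \code{"sleep_series"}: list with \code{flags}
#'   (0/1/NA per epoch), \code{epoch_s}, \code{threshold_bins}, \code{mode},
#'   \code{time}.
#' @export
score_sleep <- function(x, threshold_bins = 4, mode = c("run", "window"),
                        epoch_s = 10, floor = 0, na_breaks = TRUE,
                        start_time = NULL) {
  mode <- match.arg(mode)
  if (inherits(x, "activity_trace")) {
    out <- lapply(seq_along(x$cages), function(j)
      score_sleep(x$activity[, j], threshold_bins = threshold_bins,
                  mode = mode, epoch_s = x$epoch_s, floor = floor,
                  na_breaks = na_breaks, start_time = x$time[1L]))
    names(out) <- x$cages
    if (length(out) == 1L) return(out[[1L]])
    return(out)
  }
  x <- as.numeric(x)
  if (threshold_bins < 1 || threshold_bins != round(threshold_bins))
    stop("threshold_bins must be a positive integer")
  threshold_bins <- as.integer(threshold_bins)
  if (any(!is.na(x) & x < 0)) stop("negative activity values")
  n <- length(x)
  if (n < threshold_bins) {
    warning("trace shorter than the immobility threshold; no sleep flagged")
    flags <- rep(0, n)
    flags[is.na(x)] <- NA
    return(new_sleep_series(flags, epoch_s, threshold_bins, mode, start_time))
  }
  zero <- !is.na(x) & x <= floor
  if (!na_breaks) zero[is.na(x)] <- TRUE
  th <- threshold_bins
  # window flag at i: all of zero[(i-th+1)..i]; via cumulative sums
  cz <- cumsum(as.numeric(zero))
  roll <- cz[th:n] - c(0, cz)[seq.int(1L, n - th + 1L)]
  w <- numeric(n)
  w[th:n] <- as.numeric(roll == th)
  if (mode == "window") {
    flags <- w
  } else {
    # run flag at i: some all-zero window covers i, i.e. a window flag in
    # [i, i + th - 1]
    wp <- c(w, rep(0, th - 1L))
    cw <- cumsum(wp)
    flags <- as.numeric((cw[seq.int(th, n + th - 1L)] -
                           c(0, cw)[seq_len(n)]) > 0)
  }
  flags[is.na(x)] <- NA
  new_sleep_series(flags, epoch_s, threshold_bins, mode, start_time)
}

new_sleep_series <- function(flags, epoch_s, threshold_bins, mode,
                             start_time) {
  time <- if (is.null(start_time)) NULL else
    start_time + (seq_along(flags) - 1L) * epoch_s
  structure(list(flags = flags, epoch_s = epoch_s,
                 threshold_bins = threshold_bins, mode = mode, time = time),
            class = "sleep_series")
}

#' @export
print.sleep_series <- function(x, ...) {
  n <- length(x$flags)
  tot <- sum(x$flags, na.rm = TRUE) * x$epoch_s / 3600
  cat(sprintf(
    "sleep series (%s mode, >=%d x %g s immobility): %d epochs, %.2f h asleep\n",
    x$mode, x$threshold_bins, x$epoch_s, n, tot))
  invisible(x)
}

#' @export
summary.sleep_series <- function(object, ...) {
  b <- sleep_bouts(object)
  n <- length(object$flags)
  structure(list(n_epochs = n, epoch_s = object$epoch_s, mode = object$mode,
                 total_sleep_h = sum(object$flags, na.rm = TRUE) *
                   object$epoch_s / 3600,
                 fraction_asleep = mean(object$flags, na.rm = TRUE),
                 n_bouts = nrow(b),
                 mean_bout_s = if (nrow(b)) mean(b$duration_s) else NA_real_),
            class = "summary.sleep_series")
}

#' @export
print.summary.sleep_series <- function(x, ...) {
  cat(sprintf("%d epochs (%s mode): %.2f h asleep (%.1f%%), %d bouts, mean bout %.0f s\n",
              x$n_epochs, x$mode, x$total_sleep_h, 100 * x$fraction_asleep,
              x$n_bouts, x$mean_bout_s))
  invisible(x)
}

#' Extract sleep bouts
#'
#' One bout per maximal run of flagged epochs; bouts are non-overlapping and
#' ordered, with \code{duration_s = n_epochs * epoch_s}.
#'
#' @param series a \code{\link{score_sleep}} result.
#' @return data.frame with columns \code{onset} (time, or epoch index when
#'   the series carries no clock), \code{n_epochs}, \code{duration_s}.
#' @export
sleep_bouts <- function(series) {
  stopifnot(inherits(series, "sleep_series"))
  f <- series$flags
  f[is.na(f)] <- 0
  r <- rle(f == 1)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  starts <- starts[keep]
  ne <- r$lengths[keep]
  onset <- if (is.null(series$time)) starts else series$time[starts]
  data.frame(onset = onset, n_epochs = as.integer(ne),
             duration_s = ne * series$epoch_s)
}

#' Minutes of immobility-defined sleep per analysis bin
#'
#' Sums sleep flags into half-open bins of \code{bin_s} seconds (bin label =
#' bin start) and converts to minutes; a fully flagged 30-min bin scores 30.
#' Missing epochs contribute no sleep.
#'
#' @param series a \code{\link{score_sleep}} result.
#' @param bin_s bin width in seconds (default 1800); must be a multiple of
#'   the epoch.
#' @return a binned series of minutes asleep per bin.
#' @export
sleep_minutes_per_bin <- function(series, bin_s = 1800) {
  stopifnot(inherits(series, "sleep_series"))
  k <- bin_s / series$epoch_s
  if (k != round(k) || k < 1)
    stop("bin_s must be a positive integer multiple of the epoch (",
         series$epoch_s, " s)")
  k <- as.integer(round(k))
  f <- series$flags
  f[is.na(f)] <- 0
  n <- length(f)
  nb <- ceiling(n / k)
  idx <- rep(seq_len(nb), each = k)[seq_len(n)]
  mins <- rowsum(f, idx)[, 1L] * series$epoch_s / 60
  time <- if (is.null(series$time)) NULL else
    series$time[1L] + (seq_len(nb) - 1L) * bin_s
  binned_series(time, bin_s, mins, complete = tabulate(idx, nb) == k)
}
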