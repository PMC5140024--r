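#' Describe a PIR CSV dialect
#'
#' The canonical on-disk format is comma-separated with one header row:
#' column \code{timestamp} (ISO8601 UTC with a \code{Z} suffix), one
#' \code{cage_<id>} column per cage holding percent activation in [0, 100],
#' and a final \code{light} column with the raw light-sensor reading.
#' Loggers differ, so every piece is configurable.
#'
#' @param sep field separator.
#' @param timestamp_col name of the timestamp column.
#' @param time_format \code{strptime} format used to parse timestamps (UTC).
#' @param cage_pattern regular expression identifying activity columns; the
#'   matched prefix is stripped to form the cage identifier.
#' @param cage_cols explicit activity column names (overrides
#'   \code{cage_pattern}).
#' @param light_col name of the light column, or \code{NULL} if absent.
#' @param clamp if \code{TRUE}, activity values outside [0, 100] are clamped
#'   instead of raising an integrity error.
#' @param gap_tol_s tolerance (seconds) when matching timestamps to the
#'   regular epoch grid; larger deviations from a multiple of the epoch are
#'   an integrity error, exact multiples > 1 are recorded as gaps.
#' @return an object of class \code{"pir_dialect"}.
#' @export
pir_dialect <- function(sep = ",", timestamp_col = "timestamp",
                        time_format = "%Y-%m-%dT%H:%M:%OSZ",
                        cage_pattern = "^cage_", cage_cols = NULL,
                        light_col = "light", clamp = FALSE, gap_tol_s = 1) {
  structure(list(sep = sep, timestamp_col = timestamp_col,
                 time_format = time_format, cage_pattern = cage_pattern,
                 cage_cols = cage_cols, light_col = light_col,
                 clamp = clamp, gap_tol_s = gap_tol_s),
            class = "pir_dialect")
}

#' Construct an activity trace
#'
#' An activity trace is a regular grid of fixed-width epochs holding percent
#' PIR activation per cage plus an optional environmental-light channel.
#' Epochs missing from the input are kept as explicit gaps (\code{NA} rows,
#' \code{observed = FALSE}), never silently dropped; timestamps must be
#' strictly increasing and sit on the epoch grid.
#'
#' @param time POSIXct (UTC) epoch start times of the observed rows.
#' @param activity numeric vector or matrix [n x cages] of percent
#'   activation in [0, 100].
#' @param light optional numeric vector of raw light readings (>= 0).
#' @param epoch_s epoch width in seconds; inferred from the smallest
#'   timestamp difference when \code{NULL}.
#' @param cages cage identifiers (defaults to activity column names).
#' @param gap_tol_s grid-matching tolerance in seconds.
#' @return an object of class \code{"activity_trace"}: a list with elements
#'   \code{time} (full grid), \code{epoch_s}, \code{cages}, \code{activity}
#'   (matrix, \code{NA} at gaps), \code{light}, \code{observed}.
#' @export
activity_trace <- function(time, activity, light = NULL, epoch_s = NULL,
                           cages = NULL, gap_tol_s = 1) {
  if (is.null(dim(activity))) activity <- matrix(as.numeric(activity), ncol = 1)
  activity <- as.matrix(activity)
  storage.mode(activity) <- "double"
  if (ncol(activity) < 1L) stop("activity trace must contain at least one cage")
  if (inherits(time, "POSIXct")) {
    tnum <- as.numeric(time)
  } else {
    tnum <- as.numeric(time)
    time <- as.POSIXct(tnum, origin = "1970-01-01", tz = "UTC")
  }
  n_obs <- length(tnum)
  if (n_obs == 0L) stop("format error: no epochs")
  if (nrow(activity) != n_obs)
    stop("activity must have one row per timestamp")
  d <- diff(tnum)
  if (any(d <= 0)) {
    bad <- which(d <= 0) + 1L
    stop("integrity error: timestamps not strictly increasing at rows ",
         paste(bad, collapse = ", "))
  }
  if (is.null(epoch_s)) epoch_s <- if (n_obs > 1L) min(d) else 10
  k <- round((tnum - tnum[1L]) / epoch_s)
  off <- abs(tnum - (tnum[1L] + k * epoch_s))
  if (any(off > gap_tol_s)) {
    bad <- which(off > gap_tol_s)
    stop("integrity error: timestamps off the ", epoch_s,
         " s epoch grid at rows ", paste(bad, collapse = ", "))
  }
  bad_act <- which(!is.na(activity) & (activity < 0 | activity > 100),
                   arr.ind = TRUE)
  if (nrow(bad_act) > 0L)
    stop("integrity error: activity outside [0, 100] at rows ",
         paste(unique(bad_act[, 1L]), collapse = ", "))
  if (!is.null(light)) {
    light <- as.numeric(light)
    if (length(light) != n_obs)
      stop("light vector must have the same length as activity rows")
    if (any(!is.na(light) & light < 0))
      stop("integrity error: negative light readings")
  }
  n <- k[n_obs] + 1L
  grid_time <- time[1L] + (seq_len(n) - 1L) * epoch_s
  if (is.null(cages)) cages <- colnames(activity)
  if (is.null(cages)) cages <- as.character(seq_len(ncol(activity)))
  act <- matrix(NA_real_, nrow = n, ncol = ncol(activity),
                dimnames = list(NULL, cages))
  act[k + 1L, ] <- activity
  lt <- rep(NA_real_, n)
  if (!is.null(light)) lt[k + 1L] <- light
  observed <- rep(FALSE, n)
  observed[k + 1L] <- TRUE
  structure(list(time = grid_time, epoch_s = epoch_s, cages = cages,
                 activity = act, light = if (is.null(light)) NULL else lt,
                 observed = observed),
            class = "activity_trace")
}

#' @export
print.activity_trace <- function(x, ...) {
  n <- length(x$time)
  cat("PIR activity trace\n")
  cat(sprintf("  %d epochs of %g s (%.2f days), %d cage(s): %s\n",
              n, x$epoch_s, n * x$epoch_s / 86400, length(x$cages),
              paste(x$cages, collapse = ", ")))
  cat(sprintf("  start %s UTC, %d missing epoch(s)%s\n",
              format(x$time[1L], "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
              sum(!x$observed),
              if (is.null(x$light)) ", no light channel" else ""))
  invisible(x)
}

#' Read a PIR activity CSV
#'
#' Parses a delimited text file of per-epoch percent PIR activation into an
#' \code{\link{activity_trace}}. Timestamps are parsed as UTC; rows whose
#' timestamp does not parse are an error naming their line numbers, as are
#' non-monotone timestamps and (unless the dialect clamps) activity outside
#' [0, 100]. Consecutive timestamps further apart than one epoch are kept as
#' explicit gaps.
#'
#' @param file path or connection.
#' @param dialect a \code{\link{pir_dialect}}.
#' @param epoch_s expected epoch width in seconds.
#' @return an \code{\link{activity_trace}}.
#' @export
read_pir_csv <- function(file, dialect = pir_dialect(), epoch_s = 10) {
  stopifnot(inherits(dialect, "pir_dialect"))
  df <- utils::read.table(file, header = TRUE, sep = dialect$sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0L) stop("format error: empty PIR file")
  if (!dialect$timestamp_col %in% names(df))
    stop("format error: no timestamp column '", dialect$timestamp_col, "'")
  raw_t <- as.character(df[[dialect$timestamp_col]])
  time <- as.POSIXct(strptime(raw_t, dialect$time_format, tz = "UTC"))
  if (anyNA(time)) {
    bad <- which(is.na(time)) + 1L   # +1 for the header line
    stop("integrity error: unparseable timestamps at line(s) ",
         paste(bad, collapse = ", "))
  }
  d <- diff(as.numeric(time))
  if (any(d <= 0)) {
    bad <- which(d <= 0) + 2L        # offending row, 1-based file lines
    stop("integrity error: non-monotone timestamps at line(s) ",
         paste(bad, collapse = ", "))
  }
  cage_cols <- dialect$cage_cols
  if (is.null(cage_cols))
    cage_cols <- grep(dialect$cage_pattern, names(df), value = TRUE)
  if (length(cage_cols) == 0L)
    stop("format error: no activity columns match '", dialect$cage_pattern, "'")
  act <- as.matrix(df[cage_cols])
  storage.mode(act) <- "double"
  out_of_range <- !is.na(act) & (act < 0 | act > 100)
  if (any(out_of_range)) {
    if (dialect$clamp) {
      act <- pmin(pmax(act, 0), 100)
    } else {
      bad <- sort(unique(which(out_of_range, arr.ind = TRUE)[, 1L])) + 1L
      stop("integrity error: activity outside [0, 100] at line(s) ",
           paste(bad, collapse = ", "))
    }
  }
  cages <- if (is.null(dialect$cage_cols))
    sub(dialect$cage_pattern, "", cage_cols) else cage_cols
  light <- NULL
  if (!is.null(dialect$light_col) && dialect$light_col %in% names(df))
    light <- as.numeric(df[[dialect$light_col]])
  activity_trace(time, act, light = light, epoch_s = epoch_s, cages = cages,
                 gap_tol_s = dialect$gap_tol_s)
}

#' Write a PIR activity CSV
#'
#' Inverse of \code{\link{read_pir_csv}} for the canonical dialect: observed
#' epochs are written one per row (gap epochs are omitted, so a subsequent
#' read reconstructs the same gaps), timestamps as ISO8601 UTC.
#'
#' @param trace an \code{\link{activity_trace}}.
#' @param file path or connection.
#' @export
write_pir_csv <- function(trace, file) {
  stopifnot(inherits(trace, "activity_trace"))
  if (length(trace$cages) == 0L || ncol(trace$activity) == 0L)
    stop("refusing to write a trace with no cages")
  obs <- trace$observed
  df <- data.frame(timestamp = format(trace$time[obs], "%Y-%m-%dT%H:%M:%SZ",
                                      tz = "UTC"),
                   check.names = FALSE, stringsAsFactors = FALSE)
  act <- trace$activity[obs, , drop = FALSE]
  for (j in seq_along(trace$cages))
    df[[paste0("cage_", trace$cages[j])]] <- fmt_num(act[, j])
  if (!is.null(trace$light)) df[["light"]] <- fmt_num(trace$light[obs])
  utils::write.table(df, file, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(NULL)
}

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("")
    format(v, digits = 15, scientific = FALSE, trim = TRUE)
  }, character(1))
  out
}

#' Resample an activity trace into coarser bins
#'
#' Aggregates the per-epoch activity (and light) into half-open bins
#' [start, start + bin_s) labelled by bin start. Gap epochs are ignored in
#' the aggregation; bins with no observed epochs are \code{NA}. A trailing
#' bin covering fewer than \code{bin_s / epoch_s} epochs is flagged
#' incomplete.
#'
#' @param trace an \code{\link{activity_trace}}.
#' @param bin_s bin width in seconds; must be an integer multiple of the
#'   trace epoch.
#' @param statistic \code{"mean"} or \code{"sum"}.
#' @return an object of class \code{"binned_trace"}: list with \code{time}
#'   (bin starts), \code{bin_s}, \code{statistic}, \code{activity} (matrix
#'   [bins x cages]), \code{light}, \code{n_obs}, \code{complete}.
#' @export
resample_activity <- function(trace, bin_s, statistic = c("mean", "sum")) {
  stopifnot(inherits(trace, "activity_trace"))
  statistic <- match.arg(statistic)
  k <- bin_s / trace$epoch_s
  if (k != round(k) || k < 1)
    stop("bin_s must be a positive integer multiple of the epoch (",
         trace$epoch_s, " s)")
  k <- as.integer(round(k))
  n <- length(trace$time)
  nb <- ceiling(n / k)
  idx <- rep(seq_len(nb), each = k)[seq_len(n)]
  agg <- function(v) {
    obs <- !is.na(v)
    s <- rowsum(ifelse(obs, v, 0), idx, reorder = TRUE)[, 1L]
    cnt <- rowsum(as.numeric(obs), idx, reorder = TRUE)[, 1L]
    if (statistic == "mean") ifelse(cnt > 0, s / cnt, NA_real_)
    else ifelse(cnt > 0, s, NA_real_)
  }
  act <- apply(trace$activity, 2L, agg)
  if (is.null(dim(act))) act <- matrix(act, nrow = nb)
  colnames(act) <- trace$cages
  light <- if (is.null(trace$light)) NULL else {
    obs <- !is.na(trace$light)
    s <- rowsum(ifelse(obs, trace$light, 0), idx)[, 1L]
    cnt <- rowsum(as.numeric(obs), idx)[, 1L]
    ifelse(cnt > 0, s / cnt, NA_real_)
  }
  structure(list(time = trace$time[1L] + (seq_len(nb) - 1L) * bin_s,
                 bin_s = bin_s, statistic = statistic, activity = act,
                 light = light,
                 n_obs = as.integer(tabulate(idx, nb)),
                 complete = tabulate(idx, nb) == k),
            class = "binned_trace")
}

# One-dimensional binned series (sleep minutes per bin etc.); `time` may be
# NULL when the source series carried no clock.
binned_series <- function(time, bin_s, values, complete = NULL) {
  structure(list(time = time, bin_s = bin_s, values = as.numeric(values),
                 complete = complete),
            class = "binned_series")
}

#' @export
print.binned_series <- function(x, ...) {
  cat(sprintf("binned series: %d bins of %g s\n", length(x$values), x$bin_s))
  print(utils::head(x$values, 10))
  invisible(x)
}
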