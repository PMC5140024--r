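#' Construct a hypnogram
#'
#' A hypnogram is the per-epoch sequence of vigilance states (WAKE, NREM,
#' REM) scored from EEG/EMG — the reference standard against which
#' immobility-defined sleep is validated.
#'
#' @param states character vector of canonical states.
#' @param start_time POSIXct (UTC) start of the first epoch, or \code{NULL}.
#' @param epoch_s epoch width in seconds (10 for standard scoring).
#' @return an object of class \code{"hypnogram"}.
#' @export
hypnogram <- function(states, start_time = NULL, epoch_s = 10) {
  states <- as.character(states)
  bad <- setdiff(unique(states), c("WAKE", "NREM", "REM"))
  if (length(bad) > 0L)
    stop("unknown vigilance state(s): ", paste(bad, collapse = ", "))
  structure(list(states = factor(states, levels = c("WAKE", "NREM", "REM")),
                 start_time = start_time, epoch_s = epoch_s),
            class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  n <- length(x$states)
  cat(sprintf("hypnogram: %d epochs of %g s (%.2f h)\n",
              n, x$epoch_s, n * x$epoch_s / 3600))
  print(table(x$states))
  invisible(x)
}

#' Read an EEG/EMG hypnogram CSV
#'
#' One vigilance-state token per epoch row. Every raw token must map to
#' exactly one canonical state through \code{label_map}; an unmapped token is
#' an error naming the token and its line — never silently scored as WAKE.
#'
#' @param file path or connection.
#' @param label_map named character vector mapping raw tokens to
#'   \code{"WAKE"}, \code{"NREM"} or \code{"REM"}, e.g.
#'   \code{c(W = "WAKE", NR = "NREM", R = "REM")}.
#' @param epoch_s epoch width in seconds; must match the PIR trace the
#'   hypnogram will be compared against (or be resampled explicitly).
#' @param state_col name or index of the state column.
#' @param timestamp_col optional name of a timestamp column (ISO8601 UTC);
#'   when present it sets \code{start_time}.
#' @param start_time explicit start time, used when the file has no
#'   timestamp column.
#' @param sep field separator.
#' @param header does the file have a header row?
#' @return a \code{\link{hypnogram}}.
#' @export
read_hypnogram_csv <- function(file, label_map, epoch_s = 10,
                               state_col = "state", timestamp_col = NULL,
                               start_time = NULL, sep = ",", header = TRUE) {
  df <- utils::read.table(file, header = header, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0L) stop("format error: empty hypnogram file")
  tokens <- as.character(df[[state_col]])
  unknown <- !(tokens %in% names(label_map))
  if (any(unknown)) {
    i <- which(unknown)[1L]
    stop("unknown vigilance token '", tokens[i], "' at line ",
         i + as.integer(header))
  }
  if (!is.null(timestamp_col) && timestamp_col %in% names(df)) {
    t0 <- as.POSIXct(strptime(as.character(df[[timestamp_col]][1L]),
                              "%Y-%m-%dT%H:%M:%OSZ", tz = "UTC"))
    if (!is.na(t0)) start_time <- t0
  }
  hypnogram(unname(label_map[tokens]), start_time = start_time,
            epoch_s = epoch_s)
}

#' Minutes of EEG-scored sleep per analysis bin
#'
#' Sleep is NREM + REM. Epochs are aggregated into half-open bins of
#' \code{bin_s} seconds labelled by bin start; the result is in minutes so a
#' fully asleep 30-min bin scores 30.
#'
#' @param h a \code{\link{hypnogram}}.
#' @param bin_s bin width in seconds (default 1800 = 30 min); must be a
#'   multiple of the hypnogram epoch.
#' @return a binned series of minutes asleep per bin.
#' @export
hypnogram_sleep_minutes <- function(h, bin_s = 1800) {
  stopifnot(inherits(h, "hypnogram"))
  k <- bin_s / h$epoch_s
  if (k != round(k) || k < 1)
    stop("bin_s must be a positive integer multiple of the epoch (",
         h$epoch_s, " s)")
  k <- as.integer(round(k))
  asleep <- as.numeric(h$states %in% c("NREM", "REM"))
  n <- length(asleep)
  nb <- ceiling(n / k)
  idx <- rep(seq_len(nb), each = k)[seq_len(n)]
  mins <- rowsum(asleep, idx)[, 1L] * h$epoch_s / 60
  time <- if (is.null(h$start_time)) NULL else
    h$start_time + (seq_len(nb) - 1L) * bin_s
  binned_series(time, bin_s, mins, complete = tabulate(idx, nb) == k)
}
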