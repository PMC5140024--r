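#' Mean daily profile with SEM
#'
#' Folds a binned series into complete days (incomplete trailing day
#' excluded) and returns the per-bin mean and standard error of the mean
#' over days.
#'
#' @param x numeric vector of binned activity or sleep.
#' @param bin_s bin width in seconds.
#' @param period_s folding period (default 24 h); must be a multiple of
#'   \code{bin_s}.
#' @return object of class \code{"daily_profile"}: \code{mean}, \code{sem}
#'   (vectors of length period/bin), \code{n_days}, \code{bin_s}.
#' @export
daily_profile <- function(x, bin_s, period_s = 86400) {
  x <- as.numeric(x)
  p <- period_s / bin_s
  if (p != round(p) || p < 1)
    stop("period_s must be a positive integer multiple of bin_s")
  p <- as.integer(round(p))
  nd <- length(x) %/% p
  if (nd < 1L) stop("need at least 1 complete period")
  m <- matrix(x[seq_len(nd * p)], nrow = nd, ncol = p, byrow = TRUE)
  mu <- colMeans(m, na.rm = TRUE)
  if (nd == 1L) {
    warning("single day: SEM undefined, reported as 0")
    sem <- rep(0, p)
  } else {
    sem <- apply(m, 2L, stats::sd, na.rm = TRUE) / sqrt(nd)
  }
  structure(list(mean = mu, sem = sem, n_days = nd, bin_s = bin_s,
                 period_s = period_s),
            class = "daily_profile")
}

#' @export
print.daily_profile <- function(x, ...) {
  cat(sprintf("daily profile: %d bins of %g min, averaged over %d day(s)\n",
              length(x$mean), x$bin_s / 60, x$n_days))
  invisible(x)
}

#' @export
plot.daily_profile <- function(x, shade = "grey80", ...) {
  h <- (seq_along(x$mean) - 1L) * x$bin_s / 3600
  lo <- x$mean - x$sem
  hi <- x$mean + x$sem
  graphics::plot(h, x$mean, type = "n", ylim = range(lo, hi),
                 xlab = "time of day (h)", ylab = "mean activity", ...)
  graphics::polygon(c(h, rev(h)), c(hi, rev(lo)), col = shade, border = NA)
  graphics::lines(h, x$mean)
  invisible(x)
}

#' Hierarchical clustering of per-animal daily profiles
#'
#' Clusters a cohort's daily activity (or sleep) profiles with agglomerative
#' hierarchical clustering. Rows are z-scored per animal by default so that
#' the clustering reflects the shape and phase of the daily pattern rather
#' than its amplitude. Rows are sorted by label before clustering so the
#' leaf order is deterministic and invariant to the input row order.
#'
#' @param x numeric matrix [animals x bins]; row names identify animals.
#' @param metric distance passed to \code{stats::dist}.
#' @param linkage agglomeration method passed to \code{stats::hclust}.
#' @param normalise z-score each row first?
#' @param k optional number of clusters to cut the tree into.
#' @return object of class \code{"profile_clustering"}: \code{hclust} tree,
#'   \code{order} (leaf labels left to right), \code{matrix} (normalised,
#'   reordered), \code{assignments} (named cluster ids when \code{k} is
#'   given), plus the parameters used.
#' @export
cluster_profiles <- function(x, metric = "euclidean", linkage = "average",
                             normalise = TRUE, k = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 animals")
  if (is.null(rownames(x)))
    rownames(x) <- sprintf("animal%02d", seq_len(nrow(x)))
  x <- x[order(rownames(x)), , drop = FALSE]
  z <- x
  if (normalise) {
    s <- apply(x, 1L, stats::sd)
    if (any(s == 0))
      stop("constant profile cannot be z-scored: ",
           paste(rownames(x)[s == 0], collapse = ", "))
    z <- (x - rowMeans(x)) / s
  }
  hc <- stats::hclust(stats::dist(z, method = metric), method = linkage)
  assignments <- if (!is.null(k)) stats::cutree(hc, k = k) else NULL
  structure(list(hclust = hc, order = rownames(z)[hc$order],
                 matrix = z[hc$order, , drop = FALSE],
                 assignments = assignments, metric = metric,
                 linkage = linkage, normalise = normalise, k = k),
            class = "profile_clustering")
}

#' @export
print.profile_clustering <- function(x, ...) {
  cat(sprintf("hierarchical clustering of %d profiles (%s distance, %s linkage%s)\n",
              nrow(x$matrix), x$metric, x$linkage,
              if (x$normalise) ", z-scored" else ""))
  cat("  leaf order:", paste(x$order, collapse = " "), "\n")
  if (!is.null(x$assignments)) {
    cat(sprintf("  %d-cluster cut:\n", x$k))
    print(x$assignments)
  }
  invisible(x)
}

#' @export
plot.profile_clustering <- function(x, ...) {
  graphics::plot(x$hclust, xlab = "", sub = "", main = "profile clustering",
                 ...)
  invisible(x)
}
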