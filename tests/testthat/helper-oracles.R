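# Independent brute-force oracles used to validate the vectorised
# implementations. Deliberately written as plain scans, sharing no code with
# the package internals.

# Maximal-zero-run enumeration: walk the vector, find each maximal run of
# zeros, and flag it according to the scoring convention.
oracle_sleep_flags <- function(x, th, mode = c("run", "window")) {
  mode <- match.arg(mode)
  n <- length(x)
  flags <- numeric(n)
  i <- 1L
  while (i <= n) {
    if (x[i] == 0) {
      j <- i
      while (j < n && x[j + 1L] == 0) j <- j + 1L
      len <- j - i + 1L
      if (len >= th) {
        if (mode == "run") flags[i:j] <- 1
        else flags[(i + th - 1L):j] <- 1
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  flags
}

# Number of maximal zero runs with length >= th.
oracle_n_long_runs <- function(x, th) {
  r <- rle(x == 0)
  sum(r$values & r$lengths >= th)
}

# Fold-and-variance chi-squared periodogram statistic at one period,
# computed with explicit loops over phase columns.
oracle_qp <- function(x, P) {
  K <- length(x) %/% P
  N <- K * P
  xs <- x[1:N]
  Mbar <- mean(xs)
  col_means <- numeric(P)
  for (h in 1:P) {
    idx <- h + P * (0:(K - 1))
    col_means[h] <- mean(xs[idx])
  }
  num <- 0
  for (h in 1:P) num <- num + (col_means[h] - Mbar)^2
  den <- 0
  for (i in 1:N) den <- den + (xs[i] - Mbar)^2
  K * N * num / den
}

# Build a small single-cage trace from a value vector (10 s epochs).
make_trace <- function(values, light = NULL, epoch_s = 10,
                       start = as.POSIXct("2024-01-01 00:00:00", tz = "UTC")) {
  time <- start + (seq_along(values) - 1L) * epoch_s
  activity_trace(time, matrix(values, ncol = 1), light = light,
                 epoch_s = epoch_s, cages = "A")
}

# Fraction of animals assigned to the right phenotype by a 2-cluster cut,
# maximised over the two label permutations.
recovery_accuracy <- function(assignments, truth) {
  a <- as.integer(assignments)
  acc1 <- mean(a == truth)
  acc2 <- mean(a == (3L - truth))
  max(acc1, acc2)
}
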