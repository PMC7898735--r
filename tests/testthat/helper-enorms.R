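# Independent oracles used across the test files. These deliberately avoid
# the package's own code paths: smoothing, run enumeration and slice
# statistics are recomputed from first principles.

# edge-truncated centered moving median, written as a direct loop
oracle_smooth <- function(d, window) {
  if (window == 1) return(d)
  h <- (window - 1) / 2
  n <- length(d)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - h)
    hi <- min(n, i + h)
    out[i] <- median(d[lo:hi])
  }
  out
}

# exhaustive enumeration of every contiguous interval of difference indices
# whose smoothed differences all sit at or below tau; returns the chosen
# value-index bounds under the longest / smallest-sum / leftmost rule, or
# NULL when no interval of at least min_run points qualifies
oracle_plateau <- function(values, window = 9, k = 6,
                           min_run = max(10, ceiling(0.05 * length(values)))) {
  s <- sort(values)
  d <- diff(s)
  sm <- oracle_smooth(d, window)
  tau <- k * median(d)
  nd <- length(d)
  best <- NULL
  for (i in seq_len(nd)) {
    for (j in i:nd) {
      if (all(sm[i:j] <= tau)) {
        len <- j - i + 1
        cand <- list(i = i, j = j, len = len, sum = sum(sm[i:j]))
        if (is.null(best) ||
            cand$len > best$len ||
            (cand$len == best$len && cand$sum < best$sum)) {
          best <- cand
        }
      } else {
        break  # extending a failing interval cannot succeed
      }
    }
  }
  if (is.null(best) || best$j - best$i + 2 < min_run) return(NULL)
  c(a = best$i, b = best$j + 1)
}

# plain slice statistics for oracle-equivalence checks
oracle_slice_stats <- function(values, a, b) {
  s <- sort(values)[a:b]
  list(n = length(s), mean = mean(s), sd = sd(s), min = min(s), max = max(s))
}

# assorted series generators for property sweeps
random_test_series <- function(seed) {
  set.seed(seed)
  kind <- seed %% 4
  n <- sample(30:200, 1)
  switch(
    as.character(kind),
    "0" = rnorm(n, 50, 5),
    "1" = c(rnorm(round(0.7 * n), 10, 1), rlnorm(n - round(0.7 * n), 3, 0.5)),
    "2" = round(rnorm(n, 25, 3), 1),           # discretized, many ties
    "3" = rexp(n, rate = 0.2)
  )
}
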