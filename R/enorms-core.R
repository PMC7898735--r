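# ---- input validation ------------------------------------------------------

validate_series <- function(values, min_n = 1L, what = "values") {
  if (!is.numeric(values)) {
    stop("`", what, "` must be a numeric vector", call. = FALSE)
  }
  if (length(values) < min_n) {
    stop("`", what, "` must contain at least ", min_n,
         " observation(s), got ", length(values), call. = FALSE)
  }
  bad <- which(!is.finite(values))
  if (length(bad) > 0L) {
    stop("non-finite value at index ", bad[1L],
         " (", length(bad), " non-finite in total); ",
         "remove or impute before analysis", call. = FALSE)
  }
  invisible(values)
}

# run a block with a temporary RNG seed, restoring the caller's stream
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# ---- rank plot -------------------------------------------------------------

#' Sort a measurement series and compute its rank plot
#'
#' Sorts the observations in ascending order, assigns 1-based ranks and
#' computes the first-order differences between successive sorted values.
#' Plotting the sorted values against rank gives the characteristic
#' "inverted S" cumulative curve whose flat middle (the plateau) contains
#' the values from non-pathological subjects.
#'
#' @param values Numeric vector of measurements (at least two, all finite).
#' @return An object of class `rank_plot`: a list with `sorted_values`,
#'   `ranks` (integers `1..n`), `diffs` (length `n - 1`,
#'   `diffs[i] = sorted_values[i + 1] - sorted_values[i]`), and
#'   `smoothed_diffs` (populated once a smoothing window has been applied;
#'   initialized to the raw differences).
#' @seealso [detect_plateau()], [run_enorms()]
#' @examples
#' sort_and_rank(c(3, 1, 2))
#' @export
sort_and_rank <- function(values) {
  validate_series(values, min_n = 2L)
  sorted <- sort(values, method = "radix")  # stable
  d <- diff(sorted)
  structure(
    list(
      sorted_values  = sorted,
      ranks          = seq_along(sorted),
      diffs          = d,
      smoothed_diffs = d,
      window         = 1L
    ),
    class = "rank_plot"
  )
}

#' @export
print.rank_plot <- function(x, ...) {
  n <- length(x$sorted_values)
  cat("e-norms rank plot: ", n, " observations, range [",
      format(x$sorted_values[1L]), ", ", format(x$sorted_values[n]),
      "]\n", sep = "")
  cat("  first-order differences: median ", format(stats::median(x$diffs)),
      ", max ", format(max(x$diffs)),
      " (smoothing window ", x$window, ")\n", sep = "")
  invisible(x)
}

#' Smooth first-order differences with a centered moving median
#'
#' A centered moving median of odd span, truncated at the edges (the window
#' shrinks near the ends rather than padding). Medians, unlike means, are not
#' dragged upward by a single large gap, so an isolated outlying difference
#' inside an otherwise dense region does not break the plateau.
#'
#' @param diffs Numeric vector of non-negative first-order differences.
#' @param window Odd positive integer smoothing span, in rank units;
#'   `window = 1` returns the input unchanged.
#' @return Numeric vector of the same length as `diffs`.
#' @examples
#' smooth_differences(c(0, 0, 9, 0, 0), window = 3)  # the spike is removed
#' @export
smooth_differences <- function(diffs, window) {
  if (!is.numeric(window) || length(window) != 1L || is.na(window) ||
      window < 1 || window != as.integer(window) || window %% 2 == 0) {
    stop("`window` must be a positive odd integer, got ",
         deparse(window), call. = FALSE)
  }
  if (!is.numeric(diffs) || length(diffs) < 1L) {
    stop("`diffs` must be a non-empty numeric vector", call. = FALSE)
  }
  window <- as.integer(window)
  if (window > length(diffs)) {
    stop("`window` (", window, ") exceeds the number of differences (",
         length(diffs), ")", call. = FALSE)
  }
  if (window == 1L) return(diffs)
  n <- length(diffs)
  h <- (window - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    stats::median(diffs[max(1L, i - h):min(n, i + h)])
  }, numeric(1))
}

# ---- plateau detection -----------------------------------------------------

#' Plateau-detection parameters
#'
#' The plateau of the rank plot is identified as the longest contiguous run
#' of smoothed first-order differences not exceeding `k` times the median
#' raw difference. The original procedure locates the inflection points A
#' and B by eye; these parameters operationalize that judgement so the
#' method is reproducible and scriptable.
#'
#' @param window Odd positive integer, span of the moving-median smoother
#'   applied to the differences before thresholding. Default 9.
#' @param k Positive multiplier on the median difference defining the
#'   plateau threshold `tau = k * median(diffs)`. The default 6 is
#'   calibrated so that on a pure Gaussian sample the plateau covers
#'   approximately the central 95% (mean +/- 2 SD).
#' @param min_run Minimum plateau length in points. `NULL` (default)
#'   resolves to `max(10, ceiling(0.05 * n))` at detection time.
#' @return An object of class `plateau_params`.
#' @export
plateau_params <- function(window = 9L, k = 6, min_run = NULL) {
  if (!is.numeric(window) || length(window) != 1L || window < 1 ||
      window != as.integer(window) || window %% 2 == 0) {
    stop("`window` must be a positive odd integer", call. = FALSE)
  }
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k <= 0) {
    stop("`k` must be a positive real number", call. = FALSE)
  }
  if (!is.null(min_run)) {
    if (!is.numeric(min_run) || length(min_run) != 1L || min_run < 2 ||
        min_run != as.integer(min_run)) {
      stop("`min_run` must be an integer >= 2 (or NULL for the default)",
           call. = FALSE)
    }
    min_run <- as.integer(min_run)
  }
  structure(
    list(window = as.integer(window), k = as.numeric(k), min_run = min_run),
    class = "plateau_params"
  )
}

#' @export
print.plateau_params <- function(x, ...) {
  cat("plateau parameters: window =", x$window, ", k =", x$k,
      ", min_run =",
      if (is.null(x$min_run)) "max(10, 5% of n)" else x$min_run, "\n")
  invisible(x)
}

resolve_min_run <- function(params, n) {
  if (is.null(params$min_run)) max(10L, as.integer(ceiling(0.05 * n)))
  else params$min_run
}

#' Detect the plateau of an e-norms rank plot
#'
#' Finds the inflection points A and B delimiting the flat central region of
#' the sorted-value-versus-rank curve. The differences are smoothed with a
#' centered moving median (see [smooth_differences()]); the plateau is the
#' longest contiguous run of smoothed differences at or below
#' `tau = k * median(diffs)`. Equal-length runs are broken in favour of the
#' run with the smaller sum of member differences, then the leftmost run.
#'
#' A run over difference indices `i..j` maps to value indices `a = i`,
#' `b = j + 1` (1-based, both inclusive): a difference sits between the two
#' values it separates, so both endpoints belong to the plateau.
#'
#' Zero differences (exact ties in the data) always satisfy the threshold,
#' so heavily discretized measurements are biased toward plateau membership;
#' this is inherent to the difference-based rule and is reported, not
#' corrected.
#'
#' @param plot A `rank_plot`, from [sort_and_rank()].
#' @param params A `plateau_params` object.
#' @return An object of class `plateau_bounds`: list with 1-based value
#'   indices `a` and `b` (`1 <= a < b <= n`), the threshold `tau`, the
#'   resolved `min_run`, and the smoothed differences used.
#' @examples
#' x <- c(seq(0, 9), seq(9.01, 9.50, by = 0.01), seq(10.5, 19.5))
#' detect_plateau(sort_and_rank(x), plateau_params(window = 3))
#' @export
detect_plateau <- function(plot, params = plateau_params()) {
  stopifnot(inherits(plot, "rank_plot"))
  if (!inherits(params, "plateau_params")) {
    stop("`params` must be created with plateau_params()", call. = FALSE)
  }
  n <- length(plot$sorted_values)
  min_run <- resolve_min_run(params, n)
  if (n < max(20L, min_run + 2L)) {
    stop("series too small for plateau detection: n = ", n,
         " but at least ", max(20L, min_run + 2L), " points are required",
         call. = FALSE)
  }
  if (n < 100L) {
    warning("n = ", n, " (< 100): plateau estimates may be unstable",
            call. = FALSE)
  }
  d <- plot$diffs
  sm <- smooth_differences(d, params$window)
  tau <- params$k * stats::median(d)
  ok <- sm <= tau

  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values)
  if (length(keep) == 0L) {
    stop("no plateau detected: no run of smoothed differences below the ",
         "threshold tau = ", format(tau), call. = FALSE)
  }
  lens <- runs$lengths[keep]
  best_len <- max(lens)
  cand <- keep[lens == best_len]
  if (length(cand) > 1L) {
    sums <- vapply(cand, function(j) sum(sm[starts[j]:ends[j]]), numeric(1))
    cand <- cand[sums == min(sums)]
  }
  best <- cand[1L]  # leftmost among remaining ties
  a <- starts[best]
  b <- ends[best] + 1L
  if (b - a + 1L < min_run) {
    stop("no plateau detected: longest qualifying run spans ", b - a + 1L,
         " points, fewer than min_run = ", min_run, call. = FALSE)
  }
  structure(
    list(a = a, b = b, tau = tau, min_run = min_run,
         window = params$window, k = params$k, smoothed_diffs = sm),
    class = "plateau_bounds"
  )
}

#' @export
print.plateau_bounds <- function(x, ...) {
  cat("plateau bounds: A = rank ", x$a, ", B = rank ", x$b,
      " (", x$b - x$a + 1L, " points; threshold tau = ", format(x$tau),
      ")\n", sep = "")
  invisible(x)
}

# ---- normative range -------------------------------------------------------

#' Summarize the plateau into a normative range
#'
#' Descriptive statistics of the sorted values lying between the inflection
#' points A and B. The headline healthy range is the minimum-to-maximum of
#' the plateau values; `mean +/- 2 SD` limits are also reported as a
#' secondary summary.
#'
#' @param plot A `rank_plot`.
#' @param bounds A `plateau_bounds` object (or a list with 1-based inclusive
#'   value indices `a` and `b`, for manually chosen inflection points).
#' @return An object of class `normative_range`: `n_plateau`, `mean`, `sd`
#'   (sample SD, `n - 1` denominator), `min`, `max`, `lower_2sd`,
#'   `upper_2sd`, all in measurement units.
#' @export
normative_range <- function(plot, bounds) {
  stopifnot(inherits(plot, "rank_plot"))
  n <- length(plot$sorted_values)
  a <- bounds$a
  b <- bounds$b
  if (!is.numeric(a) || !is.numeric(b) || length(a) != 1L || length(b) != 1L ||
      a < 1L || b > n || a >= b) {
    stop("invalid plateau bounds: need 1 <= a < b <= ", n,
         ", got a = ", a, ", b = ", b, call. = FALSE)
  }
  slice <- plot$sorted_values[a:b]
  m <- mean(slice)
  s <- stats::sd(slice)
  structure(
    list(
      n_plateau = length(slice),
      mean = m,
      sd = s,
      min = slice[1L],
      max = slice[length(slice)],
      lower_2sd = m - 2 * s,
      upper_2sd = m + 2 * s
    ),
    class = "normative_range"
  )
}

#' @export
print.normative_range <- function(x, ...) {
  cat("normative range (plateau of ", x$n_plateau, " points)\n", sep = "")
  cat("  min-max : ", format(x$min), " to ", format(x$max), "\n", sep = "")
  cat("  mean (SD): ", format(x$mean), " (", format(x$sd), ")\n", sep = "")
  cat("  mean +/- 2 SD: ", format(x$lower_2sd), " to ",
      format(x$upper_2sd), "\n", sep = "")
  invisible(x)
}

# ---- diagnostics -----------------------------------------------------------

#' Distribution diagnostics for a set of values
#'
#' Moment-based skewness and excess kurtosis, the Kolmogorov-Smirnov d
#' statistic against a Gaussian with the sample's mean and SD, and a
#' Lilliefors p-value for the same composite hypothesis. Because the
#' Gaussian parameters are estimated from the sample, the ordinary KS null
#' distribution does not apply; the Lilliefors p-value is obtained by
#' Monte-Carlo simulation (the replicate count and seed are recorded in the
#' returned report so results are exactly reproducible).
#'
#' @param values Numeric vector, at least 8 observations.
#' @param lilliefors_nsim Number of Monte-Carlo replicates (default 10000).
#' @param lilliefors_seed RNG seed for the Monte-Carlo (default 20210222).
#' @return An object of class `diagnostics_report`: `skewness` (third
#'   standardized moment), `excess_kurtosis` (fourth standardized moment
#'   minus 3), `ks_d`, `lilliefors_p`, `lilliefors_nsim`, `lilliefors_seed`,
#'   `n`.
#' @export
distribution_diagnostics <- function(values,
                                     lilliefors_nsim = 10000L,
                                     lilliefors_seed = 20210222L) {
  validate_series(values)
  n <- length(values)
  if (n < 8L) {
    stop("distribution diagnostics require at least 8 values, got ", n,
         call. = FALSE)
  }
  m <- mean(values)
  c2 <- mean((values - m)^2)
  c3 <- mean((values - m)^3)
  c4 <- mean((values - m)^4)
  skew <- if (c2 > 0) c3 / c2^1.5 else 0
  exkurt <- if (c2 > 0) c4 / c2^2 - 3 else -3

  d_obs <- ks_stat_gaussian(values)
  p <- lilliefors_mc_p(d_obs, n, lilliefors_nsim, lilliefors_seed)

  structure(
    list(
      skewness = skew,
      excess_kurtosis = exkurt,
      ks_d = d_obs,
      lilliefors_p = p,
      lilliefors_nsim = as.integer(lilliefors_nsim),
      lilliefors_seed = as.integer(lilliefors_seed),
      n = n
    ),
    class = "diagnostics_report"
  )
}

# KS statistic against N(mean(x), sd(x)); sample SD (n-1 denominator)
ks_stat_gaussian <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / stats::sd(x))
  p <- stats::pnorm(z)
  i <- seq_len(n)
  max(pmax(i / n - p, p - (i - 1) / n))
}

# Monte-Carlo null distribution of the Lilliefors statistic, chunked to
# bound memory on large samples
lilliefors_mc_p <- function(d_obs, n, nsim, seed) {
  nsim <- as.integer(nsim)
  if (nsim < 1L) stop("`lilliefors_nsim` must be >= 1", call. = FALSE)
  exceed <- 0L
  with_seed(seed, {
    chunk <- max(1L, min(nsim, as.integer(2e6 / n)))
    done <- 0L
    i <- seq_len(n)
    upper <- i / n
    lower <- (i - 1) / n
    while (done < nsim) {
      b <- min(chunk, nsim - done)
      m <- matrix(stats::rnorm(n * b), nrow = n, ncol = b)
      cm <- colMeans(m)
      csd <- sqrt((colSums(m * m) - n * cm^2) / (n - 1))
      z <- apply((m - rep(cm, each = n)) / rep(csd, each = n), 2L, sort)
      pr <- stats::pnorm(z)
      d_sim <- apply(pmax(upper - pr, pr - lower), 2L, max)
      exceed <- exceed + sum(d_sim >= d_obs)
      done <- done + b
    }
  })
  (exceed + 1) / (nsim + 1)
}

#' @export
print.diagnostics_report <- function(x, ...) {
  cat("distribution diagnostics (n = ", x$n, ")\n", sep = "")
  cat("  skewness ", format(round(x$skewness, 3)),
      ", excess kurtosis ", format(round(x$excess_kurtosis, 3)), "\n",
      sep = "")
  cat("  KS d = ", format(round(x$ks_d, 4)),
      ", Lilliefors p = ", format(round(x$lilliefors_p, 4)),
      " (Monte-Carlo, ", x$lilliefors_nsim, " replicates, seed ",
      x$lilliefors_seed, ")\n", sep = "")
  invisible(x)
}

# ---- simple helpers --------------------------------------------------------

#' Minimum-to-maximum difference of a series
#'
#' The spread `max(values) - min(values)`. Values from healthy subjects
#' cluster in a narrow min-to-max band (e.g. fasting glucose 70-99 mg/dl, a
#' difference of 29), while pathological values span a band orders of
#' magnitude wider; this contrast is what makes the plateau detectable.
#'
#' @param values Non-empty numeric vector of finite values.
#' @return A single number, `max - min`.
#' @examples
#' min_max_difference(c(70, 99))
#' @export
min_max_difference <- function(values) {
  validate_series(values, min_n = 1L)
  max(values) - min(values)
}

# ---- pipeline --------------------------------------------------------------

#' Run the full e-norms pipeline on a measurement series
#'
#' Sorts the series, computes and smooths first-order differences, detects
#' the plateau, and summarizes it into a normative range with distribution
#' diagnostics. The result is deterministic given the data and parameters,
#' invariant to the input order, and affine-equivariant: running on
#' `a * x + b` (a > 0) yields the same plateau ranks with the range
#' transformed accordingly.
#'
#' @param values Numeric vector of measurements.
#' @param params A `plateau_params` object.
#' @param diagnostics Which values the diagnostics are computed on:
#'   `"plateau"` (default; the plateau subset, i.e. the derived healthy
#'   values), `"full"` (the whole series), or `"none"` (skip diagnostics,
#'   useful in large simulation sweeps where the Monte-Carlo Lilliefors
#'   replicate loop dominates the cost).
#' @param lilliefors_nsim,lilliefors_seed Passed to
#'   [distribution_diagnostics()].
#' @return An object of class `enorms_fit`: list with `plot` (the
#'   `rank_plot`, `smoothed_diffs` filled in), `bounds`, `range`,
#'   `diagnostics` (`NULL` when skipped), `diagnostics_scope`, and the
#'   resolved `params`.
#' @examples
#' x <- simulate_gaussian(1000, mean = 20, sd = 1.5, seed = 1)
#' fit <- run_enorms(x, diagnostics = "none")
#' fit$range
#' @export
run_enorms <- function(values,
                       params = plateau_params(),
                       diagnostics = c("plateau", "full", "none"),
                       lilliefors_nsim = 10000L,
                       lilliefors_seed = 20210222L) {
  diagnostics <- match.arg(diagnostics)
  plot <- sort_and_rank(values)
  bounds <- detect_plateau(plot, params)
  plot$smoothed_diffs <- bounds$smoothed_diffs
  plot$window <- bounds$window
  rng <- normative_range(plot, bounds)
  diag <- switch(
    diagnostics,
    plateau = distribution_diagnostics(
      plot$sorted_values[bounds$a:bounds$b],
      lilliefors_nsim = lilliefors_nsim, lilliefors_seed = lilliefors_seed),
    full = distribution_diagnostics(
      plot$sorted_values,
      lilliefors_nsim = lilliefors_nsim, lilliefors_seed = lilliefors_seed),
    none = NULL
  )
  structure(
    list(
      plot = plot,
      bounds = bounds,
      range = rng,
      diagnostics = diag,
      diagnostics_scope = diagnostics,
      params = list(window = bounds$window, k = bounds$k,
                    min_run = bounds$min_run)
    ),
    class = "enorms_fit"
  )
}

#' @export
print.enorms_fit <- function(x, ...) {
  n <- length(x$plot$sorted_values)
  cat("e-norms fit on ", n, " observations\n", sep = "")
  cat("  plateau: ranks ", x$bounds$a, " to ", x$bounds$b, "\n", sep = "")
  print(x$range)
  if (!is.null(x$diagnostics)) print(x$diagnostics)
  invisible(x)
}

#' Tabulate an e-norms fit for plotting
#'
#' One row per rank: the sorted value, its raw and smoothed first-order
#' difference (`NA` in the last row, where no successor exists) and a flag
#' marking plateau membership. The table is sufficient to redraw the
#' classic e-norms figure -- cumulative curve, difference dots and
#' inflection points A/B -- in any plotting tool.
#'
#' @param fit An `enorms_fit` object.
#' @return A data frame with columns `rank`, `value`, `diff`,
#'   `smoothed_diff`, `in_plateau`.
#' @export
enorms_plot_data <- function(fit) {
  stopifnot(inherits(fit, "enorms_fit"))
  n <- length(fit$plot$sorted_values)
  data.frame(
    rank = fit$plot$ranks,
    value = fit$plot$sorted_values,
    diff = c(fit$plot$diffs, NA_real_),
    smoothed_diff = c(fit$plot$smoothed_diffs, NA_real_),
    in_plateau = fit$plot$ranks >= fit$bounds$a & fit$plot$ranks <= fit$bounds$b
  )
}

#' Plot an e-norms fit
#'
#' Draws the cumulative rank plot with the first-order differences overlaid
#' (rescaled to the value axis) and vertical lines at the inflection points
#' A and B.
#'
#' @param x An `enorms_fit` object.
#' @param ... Further arguments passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.enorms_fit <- function(x, ...) {
  pd <- enorms_plot_data(x)
  graphics::plot(pd$rank, pd$value, type = "l",
                 xlab = "rank", ylab = "sorted value",
                 main = "e-norms plot", ...)
  dmax <- max(pd$smoothed_diff, na.rm = TRUE)
  if (dmax > 0) {
    scale <- 0.25 * diff(range(pd$value)) / dmax
    graphics::points(pd$rank, min(pd$value) + pd$smoothed_diff * scale,
                     pch = 16, cex = 0.3, col = "grey40")
  }
  graphics::abline(v = c(x$bounds$a, x$bounds$b), lty = 2, col = "red")
  graphics::mtext(sprintf("plateau: %.4g to %.4g", x$range$min, x$range$max),
                  side = 3, line = 0.2, cex = 0.8)
  invisible(x)
}
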