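# Per-(sex x age-bin) application of the e-norms method, demographics
# tabulation and between-stratum comparisons.

#' Age bins for stratified analysis
#'
#' An ordered set of inclusive integer-year intervals. The default bins --
#' 17-49, 50-69, 70-79 and 80-98 -- are those used when comparing indirect
#' BMI reference ranges against large actuarial mortality studies. Ages
#' below the lowest bin or above the highest are excluded from analysis
#' (e.g. subjects under 17).
#'
#' @param edges A list of length-2 integer vectors `c(low, high)`,
#'   non-overlapping and strictly increasing.
#' @return An object of class `age_bins` with a `labels` attribute
#'   (`"low-high"`).
#' @export
age_bins <- function(edges = list(c(17L, 49L), c(50L, 69L),
                                  c(70L, 79L), c(80L, 98L))) {
  if (!is.list(edges) || length(edges) == 0L) {
    stop("`edges` must be a non-empty list of c(low, high) pairs",
         call. = FALSE)
  }
  m <- t(vapply(edges, function(e) {
    if (length(e) != 2L || !is.numeric(e) || any(!is.finite(e)) ||
        any(e != as.integer(e)) || e[1] > e[2]) {
      stop("each bin must be c(low, high) with integer low <= high",
           call. = FALSE)
    }
    as.integer(e)
  }, integer(2)))
  if (nrow(m) > 1L) {
    for (i in 2:nrow(m)) {
      if (m[i, 1] <= m[i - 1, 2]) {
        stop("age bins must be non-overlapping and strictly increasing: [",
             m[i - 1, 1], "-", m[i - 1, 2], "] then [",
             m[i, 1], "-", m[i, 2], "]", call. = FALSE)
      }
    }
  }
  structure(
    list(low = m[, 1], high = m[, 2],
         labels = paste0(m[, 1], "-", m[, 2])),
    class = "age_bins"
  )
}

#' @export
print.age_bins <- function(x, ...) {
  cat("age bins:", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

# bin index for each age; NA when outside all bins
assign_bins <- function(age, bins) {
  idx <- rep(NA_integer_, length(age))
  for (j in seq_along(bins$low)) {
    idx[age >= bins$low[j] & age <= bins$high[j]] <- j
  }
  idx
}

check_cohort <- function(cohort) {
  need <- c("age", "sex", "value")
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols) > 0L) {
    stop("cohort is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad_sex <- which(!(cohort$sex %in% c("male", "female")))
  if (length(bad_sex) > 0L) {
    stop("unknown sex code '", cohort$sex[bad_sex[1L]],
         "' in record ", bad_sex[1L],
         " (expected 'male' or 'female'; ", length(bad_sex),
         " offending records)", call. = FALSE)
  }
  invisible(cohort)
}

#' Split a cohort into (sex, age-bin) strata
#'
#' Every record whose age falls inside a bin is assigned to exactly one
#' stratum; records outside all bins are excluded and counted. Bin
#' membership is inclusive on both edges (age 49 belongs to 17-49, age 50
#' to 50-69).
#'
#' @param cohort Data frame with columns `age`, `sex` (`"male"`/`"female"`)
#'   and `value`.
#' @param bins An `age_bins` object.
#' @return An object of class `stratified_cohort`: a named list (names
#'   `"<sex>_<low>-<high>"`) of entries `list(sex, age_bin, values)`, with
#'   attribute `excluded_n` giving the number of age-excluded records.
#'   Empty strata are omitted.
#' @export
stratify_cohort <- function(cohort, bins = age_bins()) {
  check_cohort(cohort)
  if (nrow(cohort) == 0L) stop("cohort is empty", call. = FALSE)
  if (!inherits(bins, "age_bins")) {
    stop("`bins` must be created with age_bins()", call. = FALSE)
  }
  idx <- assign_bins(cohort$age, bins)
  excluded <- sum(is.na(idx))
  if (excluded > 0L) {
    message(excluded, " record(s) outside the age bins were excluded")
  }
  out <- list()
  for (sex in c("male", "female")) {
    for (j in seq_along(bins$labels)) {
      sel <- !is.na(idx) & idx == j & cohort$sex == sex
      if (any(sel)) {
        key <- paste0(sex, "_", bins$labels[j])
        out[[key]] <- list(sex = sex, age_bin = bins$labels[j],
                           values = cohort$value[sel])
      }
    }
  }
  structure(out, excluded_n = excluded, class = "stratified_cohort")
}

#' Demographics table of a cohort
#'
#' Record counts by age bin and sex, with marginal totals; only records
#' inside the bins are counted. Row and column sums are internally
#' consistent with the grand total.
#'
#' @inheritParams stratify_cohort
#' @return A data frame with one row per age bin plus a `TOTAL` row, and
#'   columns `age_group`, `male`, `female`, `total`.
#' @export
summarize_demographics <- function(cohort, bins = age_bins()) {
  check_cohort(cohort)
  idx <- assign_bins(cohort$age, bins)
  keep <- !is.na(idx)
  counts <- matrix(0L, nrow = length(bins$labels), ncol = 2L,
                   dimnames = list(bins$labels, c("male", "female")))
  if (any(keep)) {
    tab <- table(factor(idx[keep], levels = seq_along(bins$labels)),
                 factor(cohort$sex[keep], levels = c("male", "female")))
    counts[] <- as.integer(tab)
  }
  df <- data.frame(
    age_group = c(bins$labels, "TOTAL"),
    male = c(counts[, "male"], sum(counts[, "male"])),
    female = c(counts[, "female"], sum(counts[, "female"])),
    stringsAsFactors = FALSE
  )
  df$total <- df$male + df$female
  df
}

#' Compare two measurement series with a t-test
#'
#' `method = "welch"` performs Welch's unequal-variance two-sample t-test;
#' `method = "paired"` performs a paired t-test and requires equal lengths
#' (reduce unequal strata to a common quantile grid first, as
#' [run_stratified_enorms()] does in its paired mode). A paired comparison
#' whose differences have zero variance is degenerate: the statistic is
#' reported as 0 with p = 1 when the mean difference is also zero, or as
#' signed infinity with p = 0 otherwise, and the result is flagged.
#'
#' @param a,b Numeric vectors (each `n >= 2`).
#' @param method `"welch"` or `"paired"`.
#' @return An object of class `stratum_comparison`: `method`, `statistic`,
#'   `df`, `p_value`, `mean_difference`, `degenerate` (logical).
#' @export
compare_strata <- function(a, b, method = c("welch", "paired")) {
  method <- match.arg(method)
  validate_series(a, min_n = 2L, what = "a")
  validate_series(b, min_n = 2L, what = "b")
  if (method == "paired") {
    if (length(a) != length(b)) {
      stop("paired comparison requires equal lengths (", length(a), " vs ",
           length(b), "); reduce to a common quantile grid first",
           call. = FALSE)
    }
    d <- a - b
    if (stats::sd(d) == 0) {
      md <- mean(d)
      return(structure(
        list(method = "paired",
             statistic = if (md == 0) 0 else sign(md) * Inf,
             df = length(d) - 1,
             p_value = if (md == 0) 1 else 0,
             mean_difference = md,
             degenerate = TRUE),
        class = "stratum_comparison"
      ))
    }
    tt <- stats::t.test(a, b, paired = TRUE)
  } else {
    tt <- stats::t.test(a, b, var.equal = FALSE)
  }
  structure(
    list(method = method,
         statistic = unname(tt$statistic),
         df = unname(tt$parameter),
         p_value = tt$p.value,
         mean_difference = if (method == "paired") mean(a - b)
                           else mean(a) - mean(b),
         degenerate = FALSE),
    class = "stratum_comparison"
  )
}

#' @export
print.stratum_comparison <- function(x, ...) {
  cat(x$method, " t-test: t = ", format(round(x$statistic, 4)),
      ", df = ", format(round(x$df, 2)),
      ", p = ", format.pval(x$p_value, digits = 4),
      if (x$degenerate) " [degenerate: zero-variance differences]" else "",
      "\n", sep = "")
  invisible(x)
}

# reduce two series to a common grid of k = min(n_a, n_b) quantiles so a
# paired test is well-defined on unequal strata
quantile_pair <- function(a, b) {
  k <- min(length(a), length(b))
  probs <- (seq_len(k) - 0.5) / k
  list(a = unname(stats::quantile(a, probs, type = 7)),
       b = unname(stats::quantile(b, probs, type = 7)))
}

#' Stratified e-norms analysis with male-female comparisons
#'
#' Applies the e-norms pipeline to every (sex, age-bin) stratum of a cohort
#' and compares the derived male and female plateau values within each age
#' bin. Strata that are empty or too small for plateau detection are
#' reported as skipped (with the reason) rather than aborting the run.
#'
#' With `t_test = "welch"` (default) the plateau values of the two sexes are
#' compared directly by Welch's test. With `t_test = "paired"` both plateau
#' series are first reduced to a common grid of `min(n_male, n_female)`
#' quantiles and compared pairwise, which approximates comparisons of
#' matched summary values on strata of unequal size.
#'
#' @inheritParams stratify_cohort
#' @param params A `plateau_params` object.
#' @param t_test `"welch"` or `"paired"`.
#' @param diagnostics Diagnostics scope passed to [run_enorms()]
#'   (`"plateau"`, `"full"` or `"none"`).
#' @param lilliefors_nsim,lilliefors_seed Passed to [run_enorms()].
#' @return An object of class `stratified_enorms`: `results` (list of
#'   per-stratum entries: `key`, `sex`, `age_bin`, `n`, `fit`), `skipped`
#'   (list of `key`, `reason`), `comparisons` (one `stratum_comparison` per
#'   age bin with both sexes present), `excluded_n`, `params`.
#' @export
run_stratified_enorms <- function(cohort, bins = age_bins(),
                                  params = plateau_params(),
                                  t_test = c("welch", "paired"),
                                  diagnostics = c("plateau", "full", "none"),
                                  lilliefors_nsim = 10000L,
                                  lilliefors_seed = 20210222L) {
  t_test <- match.arg(t_test)
  diagnostics <- match.arg(diagnostics)
  strata <- stratify_cohort(cohort, bins)
  results <- list()
  skipped <- list()
  for (key in names(strata)) {
    st <- strata[[key]]
    fit <- tryCatch(
      run_enorms(st$values, params = params, diagnostics = diagnostics,
                 lilliefors_nsim = lilliefors_nsim,
                 lilliefors_seed = lilliefors_seed),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      skipped[[length(skipped) + 1L]] <-
        list(key = key, reason = conditionMessage(fit))
    } else {
      results[[key]] <- list(key = key, sex = st$sex, age_bin = st$age_bin,
                             n = length(st$values), fit = fit)
    }
  }
  comparisons <- list()
  for (lab in unique(vapply(results, `[[`, "", "age_bin"))) {
    km <- paste0("male_", lab)
    kf <- paste0("female_", lab)
    if (!is.null(results[[km]]) && !is.null(results[[kf]])) {
      pm <- plateau_values(results[[km]]$fit)
      pf <- plateau_values(results[[kf]]$fit)
      cmp <- if (t_test == "paired") {
        qp <- quantile_pair(pm, pf)
        compare_strata(qp$a, qp$b, method = "paired")
      } else {
        compare_strata(pm, pf, method = "welch")
      }
      cmp$key_a <- km
      cmp$key_b <- kf
      comparisons[[lab]] <- cmp
    }
  }
  structure(
    list(results = results, skipped = skipped, comparisons = comparisons,
         excluded_n = attr(strata, "excluded_n"),
         params = params, t_test = t_test),
    class = "stratified_enorms"
  )
}

#' Extract the plateau values from an e-norms fit
#'
#' @param fit An `enorms_fit` object.
#' @return The sorted values between the inflection points A and B.
#' @export
plateau_values <- function(fit) {
  stopifnot(inherits(fit, "enorms_fit"))
  fit$plot$sorted_values[fit$bounds$a:fit$bounds$b]
}

#' @export
print.stratified_enorms <- function(x, ...) {
  cat("stratified e-norms analysis:", length(x$results), "strata analysed,",
      length(x$skipped), "skipped,", x$excluded_n, "records age-excluded\n")
  for (r in x$results) {
    cat(sprintf("  %-15s n=%6d  plateau %7.3f to %7.3f  mean %.3f (SD %.3f)\n",
                r$key, r$n, r$fit$range$min, r$fit$range$max,
                r$fit$range$mean, r$fit$range$sd))
  }
  for (s in x$skipped) cat("  skipped ", s$key, ": ", s$reason, "\n", sep = "")
  if (length(x$comparisons) > 0L) {
    cat("male vs female (", x$t_test, " t-test on plateau values):\n",
        sep = "")
    for (lab in names(x$comparisons)) {
      cmp <- x$comparisons[[lab]]
      cat(sprintf("  %-7s t = %8.3f, df = %8.1f, p = %s\n", lab,
                  cmp$statistic, cmp$df, format.pval(cmp$p_value, digits = 3)))
    }
  }
  invisible(x)
}

#' Tabulate stratified e-norms results
#'
#' @param x A `stratified_enorms` object.
#' @return A data frame with one row per analysed stratum: `key`, `sex`,
#'   `age_bin`, `n`, `n_plateau`, `mean`, `sd`, `min`, `max`.
#' @export
stratum_table <- function(x) {
  stopifnot(inherits(x, "stratified_enorms"))
  do.call(rbind, lapply(x$results, function(r) {
    data.frame(key = r$key, sex = r$sex, age_bin = r$age_bin, n = r$n,
               n_plateau = r$fit$range$n_plateau, mean = r$fit$range$mean,
               sd = r$fit$range$sd, min = r$fit$range$min,
               max = r$fit$range$max, stringsAsFactors = FALSE,
               row.names = NULL)
  }))
}
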