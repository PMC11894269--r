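#' The theoretical four-inch sphere radius
#'
#' Monson's classical proposal: an occlusal sphere of four-inch radius.
#' With the inch fixed at exactly 25.4 mm this is 101.6 mm, the reference
#' value for the one-sample t-test in [compare_cohort()].
#'
#' @return 101.6 (mm).
#' @export
four_inch_radius <- function() 4 * 25.4

#' Descriptive summary of a radius sample
#'
#' Mean, standard deviation (n-1 denominator), median (average of the two
#' central order statistics for even n) and the t-based 95% confidence
#' interval of the mean, \eqn{\bar{x} \pm t_{0.975, n-1}\, s/\sqrt{n}}.
#'
#' @param values Numeric vector of radii (mm), n >= 2.
#' @param conf Confidence level (default 0.95).
#' @return A `group_summary`: list with `n`, `mean`, `sd`, `median`,
#'   `ci_low`, `ci_high` (all mm except `n`).
#' @examples
#' summarize_radii(c(71.4, 77.8, 72.5, 75.7))
#' @export
summarize_radii <- function(values, conf = 0.95) {
  values <- as.numeric(values)
  if (length(values) < 2 || any(!is.finite(values))) {
    ms_computation_error("summary requires at least 2 finite values")
  }
  ci <- mean_ci_summary(mean(values), stats::sd(values), length(values), conf)
  structure(
    list(n = length(values), mean = mean(values), sd = stats::sd(values),
         median = stats::median(values),
         ci_low = ci[1], ci_high = ci[2], conf = conf),
    class = "group_summary"
  )
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("n = %d: %.2f +/- %.2f mm (median %.2f, %d%% CI %.2f-%.2f)\n",
              x$n, x$mean, x$sd, x$median, round(100 * x$conf),
              x$ci_low, x$ci_high))
  invisible(x)
}

#' t-based confidence interval of a mean from summary statistics
#'
#' \eqn{\bar{x} \pm t_{1-\alpha/2, n-1}\, s/\sqrt{n}}; lets printed
#' mean/SD/n triples (e.g. from a published summary table) be turned back
#' into the interval they imply.
#'
#' @param mean,sd Sample mean and standard deviation (mm).
#' @param n Sample size (>= 2).
#' @param conf Confidence level (default 0.95).
#' @return Length-2 vector `c(low, high)` in mm.
#' @export
mean_ci_summary <- function(mean, sd, n, conf = 0.95) {
  if (n < 2) ms_computation_error("confidence interval requires n >= 2")
  half <- stats::qt(1 - (1 - conf) / 2, df = n - 1) * sd / sqrt(n)
  c(mean - half, mean + half)
}

#' One-sample t-test against a reference radius
#'
#' Tests whether the mean fitted radius differs from a reference value
#' `mu0` (typically the four-inch 101.6 mm):
#' \eqn{t = (\bar{x} - \mu_0) / (s/\sqrt{n})} on n-1 degrees of freedom,
#' two-sided.
#'
#' @param values Numeric vector of radii (mm), n >= 2 with positive SD.
#' @param mu0 Reference radius (mm); defaults to [four_inch_radius()].
#' @return A list with `t`, `df`, `p_value`, `mean`, `mu0`.
#' @export
one_sample_t <- function(values, mu0 = four_inch_radius()) {
  values <- as.numeric(values)
  if (length(values) < 2) {
    ms_computation_error("one-sample t-test requires at least 2 values")
  }
  if (stats::sd(values) == 0) {
    ms_computation_error("degenerate data: zero standard deviation")
  }
  ht <- stats::t.test(values, mu = mu0, alternative = "two.sided")
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, mean = mean(values), mu0 = mu0)
}

#' One-sample t-test from summary statistics
#'
#' Same test as [one_sample_t()] driven by a printed mean/SD/n triple
#' rather than raw data.
#'
#' @param mean,sd Sample mean and standard deviation (mm), `sd > 0`.
#' @param n Sample size (>= 2).
#' @param mu0 Reference radius (mm).
#' @return A list with `t`, `df`, `p_value`, `mean`, `mu0`.
#' @export
one_sample_t_summary <- function(mean, sd, n, mu0 = four_inch_radius()) {
  if (n < 2) ms_computation_error("one-sample t-test requires n >= 2")
  if (sd <= 0) ms_computation_error("degenerate data: zero standard deviation")
  t <- (mean - mu0) / (sd / sqrt(n))
  list(t = t, df = n - 1,
       p_value = 2 * stats::pt(abs(t), df = n - 1, lower.tail = FALSE),
       mean = mean, mu0 = mu0)
}

#' Mann-Whitney U test between two radius samples
#'
#' U is computed from rank sums with midranks for ties:
#' \eqn{U_a = \sum \mathrm{rank}(a) - n_a(n_a+1)/2}. The two-sided
#' p-value uses exact enumeration when \eqn{n_a + n_b \le 20} and there
#' are no ties, and otherwise the normal approximation with tie and
#' continuity corrections.
#'
#' @param a,b Numeric vectors (mm), both non-empty.
#' @return A list with `U` (for sample `a`), `p_value`, `n_a`, `n_b` and
#'   `method` (`"exact"` or `"normal approximation"`).
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
#' @export
mann_whitney_u <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) {
    ms_computation_error("both groups must be non-empty")
  }
  n_a <- length(a); n_b <- length(b)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- (n_a + n_b <= 20) && !ties
  if (stats::var(r) == 0) {
    # every observation tied: no evidence either way
    return(list(U = U, p_value = 1, n_a = n_a, n_b = n_b,
                method = "normal approximation"))
  }
  ht <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided",
                       exact = exact, correct = TRUE)
  )
  stopifnot(isTRUE(all.equal(unname(ht$statistic), U)))
  list(U = U, p_value = ht$p.value, n_a = n_a, n_b = n_b,
       method = if (exact) "exact" else "normal approximation")
}

#' Read a cohort CSV file
#'
#' Header `subject_id,sex,radius_mm`, `sex` coded `M`/`F`; `#` comment
#' lines are ignored.
#'
#' @param path Path to the CSV file.
#' @return A data frame with columns `subject_id`, `sex` (`"M"`/`"F"`),
#'   `radius_mm`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) ms_io_error(paste0("file not found: ", path))
  df <- tryCatch(
    utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) ms_io_error(paste0("cannot parse ", path, ": ",
                                           conditionMessage(e))))
  if (!all(c("subject_id", "sex", "radius_mm") %in% names(df))) {
    ms_io_error(paste0("expected header 'subject_id,sex,radius_mm' in ", path))
  }
  df$sex <- toupper(trimws(df$sex))
  if (!all(df$sex %in% c("M", "F"))) {
    ms_validation_error("sex must be coded M or F")
  }
  if (!is.numeric(df$radius_mm) || any(!is.finite(df$radius_mm)) ||
      any(df$radius_mm <= 0)) {
    ms_validation_error("all radii must be positive finite numbers")
  }
  df[, c("subject_id", "sex", "radius_mm")]
}

#' Write a cohort table to CSV
#'
#' @param cohort Data frame with columns `subject_id`, `sex`, `radius_mm`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  lines <- c("subject_id,sex,radius_mm",
             sprintf("%s,%s,%.17g", cohort$subject_id, cohort$sex,
                     cohort$radius_mm))
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) ms_io_error(paste0("cannot write ", path))
  invisible(path)
}

#' Sex-difference and four-inch comparison report for a cohort
#'
#' Produces the cohort analysis: per-sex and pooled descriptive summaries,
#' the male-minus-female mean difference, a two-sided Mann-Whitney U test
#' between the sexes, and a one-sample t-test of the pooled radii against
#' the theoretical four-inch radius.
#'
#' @param records Data frame with columns `subject_id`, `sex`
#'   (`"M"`/`"F"`), `radius_mm`; at least 2 records per sex.
#' @param theoretical Reference radius in mm (default
#'   [four_inch_radius()], 101.6 mm).
#' @param alpha Significance level recorded in the report (default 0.05).
#' @return A `cohort_report`: list with `male`, `female`, `total`
#'   ([summarize_radii()] summaries), `mean_difference` (male - female,
#'   mm), `mann_whitney`, `one_sample_t` (vs `theoretical`),
#'   `theoretical_radius_mm` and `alpha`.
#' @export
compare_cohort <- function(records, theoretical = four_inch_radius(),
                           alpha = 0.05) {
  if (!all(c("sex", "radius_mm") %in% names(records))) {
    ms_validation_error("records must have columns sex and radius_mm")
  }
  males <- records$radius_mm[records$sex == "M"]
  females <- records$radius_mm[records$sex == "F"]
  if (length(males) < 2 || length(females) < 2) {
    ms_computation_error(sprintf(
      "at least 2 records per sex required (got %d male, %d female)",
      length(males), length(females)))
  }
  pooled_t <- if (stats::sd(records$radius_mm) > 0) {
    one_sample_t(records$radius_mm, mu0 = theoretical)
  } else {
    # all radii identical: the t statistic is undefined
    list(t = NA_real_, df = length(records$radius_mm) - 1,
         p_value = NA_real_, mean = mean(records$radius_mm),
         mu0 = theoretical)
  }
  structure(
    list(
      male = summarize_radii(males),
      female = summarize_radii(females),
      total = summarize_radii(records$radius_mm),
      mean_difference = mean(males) - mean(females),
      mann_whitney = mann_whitney_u(males, females),
      one_sample_t = pooled_t,
      theoretical_radius_mm = theoretical,
      alpha = alpha
    ),
    class = "cohort_report"
  )
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("Monson-sphere cohort report (radii in mm)\n")
  cat(sprintf("  males   n=%2d  %.2f +/- %.2f (median %.2f, CI %.2f-%.2f)\n",
              x$male$n, x$male$mean, x$male$sd, x$male$median,
              x$male$ci_low, x$male$ci_high))
  cat(sprintf("  females n=%2d  %.2f +/- %.2f (median %.2f, CI %.2f-%.2f)\n",
              x$female$n, x$female$mean, x$female$sd, x$female$median,
              x$female$ci_low, x$female$ci_high))
  cat(sprintf("  total   n=%2d  %.2f +/- %.2f (median %.2f, CI %.2f-%.2f)\n",
              x$total$n, x$total$mean, x$total$sd, x$total$median,
              x$total$ci_low, x$total$ci_high))
  cat(sprintf("  male - female mean difference: %.2f mm\n", x$mean_difference))
  cat(sprintf("  Mann-Whitney U = %.1f, p %s\n", x$mann_whitney$U,
              format.pval(x$mann_whitney$p_value, digits = 3)))
  cat(sprintf("  one-sample t vs %.1f mm: t = %.2f (df %d), p %s\n",
              x$theoretical_radius_mm, x$one_sample_t$t, x$one_sample_t$df,
              format.pval(x$one_sample_t$p_value, digits = 3)))
  invisible(x)
}

#' Serialise a cohort report to JSON
#'
#' @param x A `cohort_report`.
#' @param path Optional output file; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
cohort_report_json <- function(x, path = NULL) {
  if (!inherits(x, "cohort_report")) {
    ms_validation_error("x must be a cohort_report")
  }
  unsum <- function(s) s[c("n", "mean", "sd", "median", "ci_low", "ci_high")]
  doc <- list(
    schema_version = "1.0",
    male = unsum(x$male), female = unsum(x$female), total = unsum(x$total),
    mean_difference_mm = x$mean_difference,
    mann_whitney = x$mann_whitney,
    one_sample_t = x$one_sample_t,
    theoretical_radius_mm = x$theoretical_radius_mm,
    alpha = x$alpha
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
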