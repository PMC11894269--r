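#' Two-way single-measures intraclass correlation coefficient
#'
#' Intrarater reliability of repeated Monson-sphere radius measurements:
#' the data are decomposed by a two-way ANOVA (subjects x sessions) and
#' the Shrout-Fleiss single-measures ICC of the requested form is
#' computed with its exact F-based 95% confidence interval and a one-sided
#' p-value against ICC = 0.
#'
#' Forms: `"consistency"` is ICC(3,1), the two-way mixed model in which a
#' constant session offset does not count against reliability —
#' appropriate when the same operator measured twice, and the package
#' default. `"agreement"` is ICC(2,1), two-way random absolute agreement,
#' in which a session shift lowers the coefficient.
#'
#' With between-subject mean square \eqn{MS_B}, between-session mean
#' square \eqn{MS_J} and error mean square \eqn{MS_E} over n subjects and
#' k sessions:
#' \deqn{ICC(3,1) = \frac{MS_B - MS_E}{MS_B + (k-1) MS_E}}
#' \deqn{ICC(2,1) = \frac{MS_B - MS_E}{MS_B + (k-1) MS_E + k (MS_J - MS_E)/n}}
#'
#' @param data A `repeated_radii` object from [read_repeated_radii()], a
#'   data frame with columns `model_id`, `r1_mm`, `r2_mm` (or any set of
#'   measurement columns after the id), or an n x k numeric matrix with
#'   one row per subject and one column per session.
#' @param form `"consistency"` (ICC(3,1), default) or `"agreement"`
#'   (ICC(2,1)).
#' @param conf Confidence level for the interval (default 0.95).
#' @return An `icc_result`: list with `icc`, `ci_low`, `ci_high`,
#'   `f_value`, `df1`, `df2`, `p_value`, `form`, `n`, `k` and
#'   `anova_table` (mean squares and degrees of freedom for subjects,
#'   sessions and error).
#' @references Shrout, P. E. and Fleiss, J. L. (1979). Intraclass
#'   correlations: uses in assessing rater reliability. Psychological
#'   Bulletin, 86, 420-428.
#' @examples
#' tab1 <- read_repeated_radii(system.file("extdata",
#'   "table1_repeated_radii.csv", package = "monson"))
#' icc_single_measures(tab1)
#' @export
icc_single_measures <- function(data, form = c("consistency", "agreement"),
                                conf = 0.95) {
  form <- match.arg(form)
  m <- as_radii_matrix(data)
  n <- nrow(m)
  k <- ncol(m)
  if (n < 3) {
    ms_computation_error(sprintf(
      "ICC requires at least 3 subjects, got %d", n))
  }
  if (any(!is.finite(m))) ms_validation_error("all measurements must be finite")

  grand <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  ssb <- k * sum((row_m - grand)^2)           # between subjects
  ssj <- n * sum((col_m - grand)^2)           # between sessions
  sst <- sum((m - grand)^2)
  sse <- sst - ssb - ssj
  msb <- ssb / (n - 1)
  msj <- ssj / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (sst <= 0) ms_computation_error("zero total variance: ICC undefined")

  icc <- if (form == "consistency") {
    (msb - mse) / (msb + (k - 1) * mse)
  } else {
    (msb - mse) / (msb + (k - 1) * mse + k * (msj - mse) / n)
  }

  alpha <- 1 - conf
  fo <- msb / mse
  df1 <- n - 1
  df2 <- (n - 1) * (k - 1)
  p <- stats::pf(fo, df1, df2, lower.tail = FALSE)

  if (form == "consistency") {
    fl <- fo / stats::qf(1 - alpha / 2, df1, df2)
    fu <- fo * stats::qf(1 - alpha / 2, df2, df1)
    ci_low <- (fl - 1) / (fl + k - 1)
    ci_high <- (fu - 1) / (fu + k - 1)
  } else {
    # Satterthwaite degrees of freedom for the ICC(2,1) interval
    fj <- msj / mse
    a <- k * icc / (n * (1 - icc))
    b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
    v <- (a * msj + b * mse)^2 /
      ((a * msj)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_star_l <- stats::qf(1 - alpha / 2, df1, v)
    f_star_u <- stats::qf(1 - alpha / 2, v, df1)
    ci_low <- n * (msb - f_star_l * mse) /
      (f_star_l * (k * msj + (k * n - k - n) * mse) + n * msb)
    ci_high <- n * (f_star_u * msb - mse) /
      (k * msj + (k * n - k - n) * mse + n * f_star_u * msb)
  }

  structure(
    list(icc = icc, ci_low = min(ci_low, icc), ci_high = max(ci_high, icc),
         conf = conf, f_value = fo, df1 = df1, df2 = df2, p_value = p,
         form = form, n = n, k = k,
         anova_table = data.frame(
           source = c("subjects", "sessions", "error"),
           df = c(df1, k - 1, df2),
           mean_sq = c(msb, msj, mse))),
    class = "icc_result"
  )
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC (%s, single measures): %.3f, %d%% CI (%.3f, %.3f)\n",
              x$form, x$icc, round(100 * x$conf), x$ci_low, x$ci_high))
  cat(sprintf("  F(%d, %d) = %.2f, one-sided p %s\n", x$df1, x$df2, x$f_value,
              format.pval(x$p_value, digits = 3)))
  invisible(x)
}

as_radii_matrix <- function(data) {
  if (inherits(data, "repeated_radii")) data <- data$rows
  if (is.data.frame(data)) {
    meas <- data[, setdiff(names(data), c("model_id", "subject_id")),
                 drop = FALSE]
    m <- as.matrix(meas)
  } else {
    m <- as.matrix(data)
  }
  if (nrow(m) == 0) {
    # empty table: let the n >= 3 check raise insufficient-data
    return(matrix(numeric(), ncol = max(2, ncol(m))))
  }
  if (!is.numeric(m) || ncol(m) < 2) {
    ms_validation_error("repeated measurements must form an n x k numeric matrix, k >= 2")
  }
  m
}

#' Read a repeated-radii CSV file
#'
#' Reads paired repeat radius measurements with header
#' `model_id,r1_mm,r2_mm`; `#` comment lines are ignored. The 15 pairs of
#' repeat measurements used for the intrarater reliability analysis ship
#' with the package:
#' `system.file("extdata", "table1_repeated_radii.csv", package = "monson")`.
#'
#' @param path Path to the CSV file.
#' @return A `repeated_radii` object: list with `rows` (data frame
#'   `model_id`, `r1_mm`, `r2_mm`), `n_models` and `n_sessions`.
#' @export
read_repeated_radii <- function(path) {
  if (!file.exists(path)) ms_io_error(paste0("file not found: ", path))
  df <- tryCatch(
    utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) ms_io_error(paste0("cannot parse ", path, ": ",
                                           conditionMessage(e))))
  if (!all(c("model_id", "r1_mm", "r2_mm") %in% names(df))) {
    ms_io_error(paste0("expected header 'model_id,r1_mm,r2_mm' in ", path))
  }
  r <- as.matrix(df[, c("r1_mm", "r2_mm")])
  if (nrow(df) > 0) {
    if (!is.numeric(r) || any(!is.finite(r))) {
      ms_io_error(paste0("non-numeric radius value in ", path))
    }
    if (any(r <= 0)) ms_validation_error("all radii must be positive")
  }
  structure(
    list(rows = df[, c("model_id", "r1_mm", "r2_mm")],
         n_models = nrow(df), n_sessions = 2L),
    class = "repeated_radii"
  )
}

#' Write repeated radii to CSV
#'
#' @param data A `repeated_radii` object or compatible data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_repeated_radii <- function(data, path) {
  if (inherits(data, "repeated_radii")) data <- data$rows
  lines <- c("model_id,r1_mm,r2_mm",
             sprintf("%s,%.17g,%.17g", data$model_id, data$r1_mm, data$r2_mm))
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) ms_io_error(paste0("cannot write ", path))
  invisible(path)
}

#' Serialise an ICC result to JSON
#'
#' @param x An `icc_result`.
#' @param path Optional output file; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
icc_json <- function(x, path = NULL) {
  if (!inherits(x, "icc_result")) ms_validation_error("x must be an icc_result")
  doc <- list(
    schema_version = "1.0",
    icc = x$icc, ci_low = x$ci_low, ci_high = x$ci_high, conf = x$conf,
    f_value = x$f_value, df1 = x$df1, df2 = x$df2, p_value = x$p_value,
    form = x$form, n = x$n, k = x$k,
    anova_table = x$anova_table
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
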