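#' Precision and accuracy of replicate determinations
#'
#' Summarises replicate found concentrations against the nominal (added)
#' value: the coefficient of variation `CV% = 100 * SD / mean` (precision)
#' and the relative error `100 * (mean - nominal) / nominal` (accuracy).
#' The sample SD uses the n - 1 denominator. Both statistics are invariant
#' under rescaling of found and nominal by a common factor.
#'
#' @param found Replicate found concentrations (ug/mL), length >= 2.
#' @param nominal Nominal concentration (ug/mL), > 0.
#' @param scope `"within_day"` or `"between_day"`; between-day statistics
#'   are computed on the grand mean of all replicates.
#' @return An object of class `"precision_result"`.
#' @examples
#' precision_accuracy(c(5.00, 5.08, 5.16), 5.00)  # CV 1.57%, error 1.60%
#' @export
precision_accuracy <- function(found,
                               nominal,
                               scope = c("within_day", "between_day")) {
  scope <- match.arg(scope)
  if (length(found) < 2L)
    stop("at least two replicates are required", call. = FALSE)
  if (!is.finite(nominal) || nominal <= 0)
    stop("nominal concentration must be positive", call. = FALSE)
  m <- mean(found)
  s <- stats::sd(found)
  structure(
    list(nominal = nominal, found_mean = m, found_sd = s,
         cv_percent = 100 * s / m,
         error_percent = 100 * (m - nominal) / nominal,
         n = length(found), scope = scope),
    class = "precision_result"
  )
}

#' @export
print.precision_result <- function(x, ...) {
  cat(sprintf(
    "<precision_result> %s (n = %d): %.2f +/- %.2f ug/mL, CV %.2f%%, error %.2f%%\n",
    x$scope, x$n, x$found_mean, x$found_sd, x$cv_percent, x$error_percent))
  invisible(x)
}

#' Precision table in the conventional report layout
#'
#' @param results List of [precision_accuracy()] results.
#' @return Data frame with one row per nominal level.
#' @export
precision_report <- function(results) {
  do.call(rbind, lapply(results, function(r) data.frame(
    scope = r$scope, n = r$n, added_ug_ml = r$nominal,
    found_ug_ml = round(r$found_mean, 2), sd = round(r$found_sd, 2),
    cv_percent = round(r$cv_percent, 2),
    error_percent = round(r$error_percent, 2))))
}

#' Standard-addition relative recovery
#'
#' Percent of a known spike recovered on top of the sample's own content,
#' `100 * (found_spiked - found_base) / added`; probes interference from
#' the tablet matrix and excipients.
#'
#' @param found_spiked Concentration found in the spiked sample (ug/mL).
#' @param found_base Concentration found in the unspiked sample (ug/mL).
#' @param added Spiked amount (ug/mL), > 0. Vectors recycle elementwise.
#' @return Recovery in percent.
#' @export
recovery_standard_addition <- function(found_spiked, found_base, added) {
  if (any(!is.finite(added)) || any(added <= 0))
    stop("added amount must be positive", call. = FALSE)
  100 * (found_spiked - found_base) / added
}

new_comparison_result <- function(t_stat = NA_real_, t_crit = NA_real_,
                                  df_t = NA_integer_, f_stat = NA_real_,
                                  f_crit = NA_real_, df_f_num = NA_integer_,
                                  df_f_den = NA_integer_, alpha = 0.05,
                                  degenerate = FALSE) {
  pass_t <- if (is.na(t_stat)) TRUE else abs(t_stat) < t_crit
  pass_f <- if (is.na(f_stat)) TRUE else f_stat < f_crit
  structure(
    list(t_stat = t_stat, t_crit = t_crit, df_t = df_t,
         f_stat = f_stat, f_crit = f_crit,
         df_f_num = df_f_num, df_f_den = df_f_den, alpha = alpha,
         degenerate = degenerate,
         conclusion = if (pass_t && pass_f) "no_significant_difference"
                      else "significant_difference"),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("<comparison_result>\n")
  if (!is.na(x$t_stat))
    cat(sprintf("  paired t = %.3f (critical %.3f, df %d)\n",
                x$t_stat, x$t_crit, x$df_t))
  if (!is.na(x$f_stat))
    cat(sprintf("  F = %.3f (critical %.2f, df %d,%d)\n",
                x$f_stat, x$f_crit, x$df_f_num, x$df_f_den))
  cat(sprintf("  conclusion: %s (alpha %g)%s\n", x$conclusion, x$alpha,
              if (x$degenerate) " [degenerate: zero-variance differences]"
              else ""))
  invisible(x)
}

#' Paired Student t test between two methods
#'
#' `t = mean(d) / (sd(d) / sqrt(n))` on the paired differences
#' `d = method_a - method_b`, with `n - 1` degrees of freedom and a
#' two-sided critical value. Used to compare a proposed assay against a
#' reference method on the same samples.
#'
#' @param method_a,method_b Paired measurements, equal length >= 2.
#' @param alpha Two-sided significance level (default 0.05).
#' @return A `"comparison_result"` with the t fields filled in. If the
#'   differences have zero variance but non-zero mean, `t_stat` is
#'   infinite and the result is flagged `degenerate`.
#' @export
paired_t_test <- function(method_a, method_b, alpha = 0.05) {
  n <- length(method_a)
  if (length(method_b) != n || n < 2L)
    stop("method_a and method_b must be paired vectors of length >= 2",
         call. = FALSE)
  d <- method_a - method_b
  sdd <- stats::sd(d)
  t_stat <- if (sdd == 0) {
    if (mean(d) == 0) 0 else Inf * sign(mean(d))
  } else {
    mean(d) / (sdd / sqrt(n))
  }
  new_comparison_result(
    t_stat = t_stat, t_crit = stats::qt(1 - alpha / 2, df = n - 1),
    df_t = n - 1L, alpha = alpha, degenerate = sdd == 0 && mean(d) != 0)
}

#' Variance-ratio F test between two methods
#'
#' `F = var(method_a) / var(method_b)` with the fixed a-over-b convention
#' (the reference method goes in the denominator; the ratio may be below
#' 1), compared against the upper critical value at
#' `(n_a - 1, n_b - 1)` degrees of freedom.
#'
#' @param method_a Measurements of the method under evaluation, length >= 2.
#' @param method_b Measurements of the reference method, length >= 2; must
#'   not have zero variance.
#' @param alpha Upper-tail significance level (default 0.05).
#' @return A `"comparison_result"` with the F fields filled in.
#' @export
variance_ratio_f_test <- function(method_a, method_b, alpha = 0.05) {
  if (length(method_a) < 2L || length(method_b) < 2L)
    stop("both samples need at least two values", call. = FALSE)
  vb <- stats::var(method_b)
  if (vb == 0)
    stop("reference method has zero variance; F is undefined", call. = FALSE)
  df1 <- length(method_a) - 1L
  df2 <- length(method_b) - 1L
  new_comparison_result(
    f_stat = stats::var(method_a) / vb,
    f_crit = stats::qf(1 - alpha, df1, df2),
    df_f_num = df1, df_f_den = df2, alpha = alpha)
}

#' Combined paired-t / F method comparison
#'
#' Runs [paired_t_test()] and [variance_ratio_f_test()] on the same paired
#' data; the methods are declared not significantly different only if both
#' the mean difference and the variance ratio are within their critical
#' values.
#'
#' @inheritParams paired_t_test
#' @return A `"comparison_result"` with both parts filled in.
#' @export
compare_methods <- function(method_a, method_b, alpha = 0.05) {
  tt <- paired_t_test(method_a, method_b, alpha)
  ff <- variance_ratio_f_test(method_a, method_b, alpha)
  new_comparison_result(
    t_stat = tt$t_stat, t_crit = tt$t_crit, df_t = tt$df_t,
    f_stat = ff$f_stat, f_crit = ff$f_crit,
    df_f_num = ff$df_f_num, df_f_den = ff$df_f_den,
    alpha = alpha, degenerate = tt$degenerate)
}
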