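#' Fit a single-wavelength calibration line
#'
#' Ordinary least squares of derivative amplitude on analyte concentration,
#' `Y = slope * X + intercept`, with the regression standard errors of both
#' coefficients and the correlation coefficient r. One fitted line
#' corresponds to one calibration series measured at one working wavelength.
#'
#' @param concentrations Analyte concentrations, ug/mL; >= 3 points,
#'   non-negative and not all equal.
#' @param responses Derivative amplitudes (AU nm^-order), same length.
#' @param analyte_id,wavelength,order Optional provenance recorded in the
#'   result.
#' @return An object of class `"calibration_curve"` with fields
#'   `slope`, `intercept`, `r`, `sd_slope`, `sd_intercept`, the input data
#'   and the concentration range.
#' @seealso [summarize_curves()], [predict_concentration()]
#' @export
fit_calibration <- function(concentrations, responses, analyte_id = NA,
                            wavelength = NA, order = NA) {
  if (length(concentrations) != length(responses))
    stop("concentrations and responses differ in length", call. = FALSE)
  if (length(concentrations) < 3L)
    stop("at least three calibration points are required", call. = FALSE)
  if (any(concentrations < 0))
    stop("concentrations must be non-negative", call. = FALSE)
  if (stats::var(concentrations) == 0)
    stop("concentrations are all equal; cannot fit a line", call. = FALSE)
  fit <- stats::lm(responses ~ concentrations)
  # collinear synthetic data triggers lm's "essentially perfect fit"
  # warning; zero standard errors are a legitimate outcome here
  co <- suppressWarnings(summary(fit))$coefficients
  r <- suppressWarnings(stats::cor(concentrations, responses))
  structure(
    list(analyte_id = analyte_id, wavelength = wavelength, order = order,
         concentrations = as.numeric(concentrations),
         responses = as.numeric(responses),
         slope = unname(co["concentrations", "Estimate"]),
         intercept = unname(co["(Intercept)", "Estimate"]),
         r = r,
         sd_slope = unname(co["concentrations", "Std. Error"]),
         sd_intercept = unname(co["(Intercept)", "Std. Error"]),
         conc_range = range(concentrations)),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> %s: Y = %.5g X %+.5g, r = %.4f (n = %d)\n",
              x$analyte_id, x$slope, x$intercept, x$r,
              length(x$concentrations)))
  invisible(x)
}

#' Detection and quantification limits
#'
#' `LOD = 3.3 * sigma / s` and `LOQ = 10 * sigma / s`, where `sigma` is the
#' standard deviation of the calibration intercept and `s` the slope.
#' Values are returned unrounded; round to two decimals only for reporting.
#'
#' @param sd_intercept Standard deviation of the intercept (response
#'   units), non-negative.
#' @param slope Calibration slope (response per ug/mL), strictly positive.
#' @return List with elements `lod` and `loq` in ug/mL.
#' @examples
#' lod_loq(0.00047, 0.00295)  # lod 0.526, loq 1.593
#' @export
lod_loq <- function(sd_intercept, slope) {
  if (!is.finite(slope) || slope <= 0)
    stop("slope must be positive", call. = FALSE)
  if (!is.finite(sd_intercept) || sd_intercept < 0)
    stop("sd_intercept must be non-negative", call. = FALSE)
  list(lod = 3.3 * sd_intercept / slope,
       loq = 10 * sd_intercept / slope)
}

#' Aggregate replicate calibration curves
#'
#' Pools several independently measured calibration curves of one analyte
#' at one working wavelength into across-curve statistics: mean, SD, RSD%
#' and confidence half-interval of the slope; mean, SD and confidence
#' half-interval of the intercept; the pooled regression equation; and
#' LOD/LOQ computed from the across-curve SD of the intercept and the
#' magnitude of the mean slope via [lod_loq()] (derivative responses may
#' legitimately have negative slope; the detection limit depends only on
#' the sensitivity's magnitude).
#'
#' The confidence half-interval is `z * SD / sqrt(n)` with
#' `z = 1.96` (two-sided, P = 0.05); set `ci = "t"` to use the Student t
#' quantile with `n - 1` degrees of freedom instead.
#'
#' @param curves List of [fit_calibration()] results for one analyte and
#'   wavelength; at least two.
#' @param ci `"normal"` (z = 1.96, default) or `"t"`.
#' @param alpha Two-sided confidence level complement (default 0.05).
#' @return An object of class `"calibration_summary"`.
#' @export
summarize_curves <- function(curves, ci = c("normal", "t"), alpha = 0.05) {
  ci <- match.arg(ci)
  if (length(curves) < 2L)
    stop("at least two curves are required", call. = FALSE)
  for (cv in curves) stopifnot(inherits(cv, "calibration_curve"))
  ids <- vapply(curves, function(cv) as.character(cv$analyte_id),
                character(1))
  wls <- vapply(curves, function(cv) as.numeric(cv$wavelength), numeric(1))
  if (length(unique(ids)) > 1L ||
      (any(!is.na(wls)) && diff(range(wls, na.rm = TRUE)) > 1e-9))
    stop("curves mix analytes or wavelengths; cannot aggregate",
         call. = FALSE)
  n <- length(curves)
  slopes <- vapply(curves, `[[`, numeric(1), "slope")
  intercepts <- vapply(curves, `[[`, numeric(1), "intercept")
  crit <- if (ci == "normal") 1.96 else stats::qt(1 - alpha / 2, df = n - 1)
  mean_slope <- mean(slopes)
  sd_slope <- stats::sd(slopes)
  sd_intercept <- stats::sd(intercepts)
  ll <- lod_loq(sd_intercept, abs(mean_slope))
  structure(
    list(analyte_id = ids[1L], wavelength = wls[1L],
         order = curves[[1L]]$order, n_curves = n,
         mean_slope = mean_slope, sd_slope = sd_slope,
         rsd_slope_percent = 100 * sd_slope / mean_slope,
         ci_slope = crit * sd_slope / sqrt(n),
         mean_intercept = mean(intercepts), sd_intercept = sd_intercept,
         ci_intercept = crit * sd_intercept / sqrt(n),
         r = mean(vapply(curves, `[[`, numeric(1), "r")),
         linear_range = range(vapply(curves, `[[`, numeric(2),
                                     "conc_range")),
         lod = ll$lod, loq = ll$loq,
         slope = mean_slope, intercept = mean(intercepts),
         conc_range = range(vapply(curves, `[[`, numeric(2), "conc_range"))),
    class = "calibration_summary"
  )
}

#' @export
print.calibration_summary <- function(x, ...) {
  cat(sprintf("<calibration_summary> %s at %.1f nm (%d curves)\n",
              x$analyte_id, x$wavelength, x$n_curves))
  cat(sprintf("  linearity range     %g-%g ug/mL\n",
              x$linear_range[1L], x$linear_range[2L]))
  cat(sprintf("  regression equation Y = %.5g X %+.5g\n",
              x$mean_slope, x$mean_intercept))
  cat(sprintf("  SD of slope %.3g | RSD of slope %.2f%% | CI of slope %.3g\n",
              x$sd_slope, x$rsd_slope_percent, x$ci_slope))
  cat(sprintf("  SD of intercept %.3g | CI of intercept %.3g\n",
              x$sd_intercept, x$ci_intercept))
  cat(sprintf("  r %.4f | LOQ %.2f | LOD %.2f ug/mL\n",
              x$r, x$loq, x$lod))
  invisible(x)
}

#' Summary table in the conventional calibration-report layout
#'
#' @param summaries List of [summarize_curves()] results (one column each).
#' @return Data frame with one row per reported statistic.
#' @export
calibration_report <- function(summaries) {
  col <- function(s) c(
    sprintf("%dD at %.1f nm", s$order, s$wavelength),
    sprintf("%g-%g", s$linear_range[1L], s$linear_range[2L]),
    sprintf("Y=%.5gX%+.5g", s$mean_slope, s$mean_intercept),
    signif(s$sd_slope, 3), round(s$rsd_slope_percent, 2),
    signif(s$ci_slope, 3), signif(s$sd_intercept, 3),
    signif(s$ci_intercept, 3), round(s$r, 3),
    round(s$loq, 2), round(s$lod, 2))
  out <- data.frame(
    parameter = c("Channel", "Linearity range (ug/mL)",
                  "Regression equation", "SD of slope", "RSD of slope (%)",
                  "CI of slope", "SD of intercept", "CI of intercept",
                  "Correlation coefficient", "LOQ", "LOD"),
    stringsAsFactors = FALSE)
  for (s in summaries) out[[as.character(s$analyte_id)]] <- col(s)
  out
}

#' Predict concentration from a calibration
#'
#' Inverse regression `(response - intercept) / slope`. Responses mapping
#' outside the calibration's concentration range are still converted but
#' flagged (attribute `out_of_range`) with a warning.
#'
#' @param object A `calibration_curve` or `calibration_summary`.
#' @param response Derivative amplitude(s) to convert.
#' @return Concentration(s) in ug/mL with logical attribute `out_of_range`.
#' @export
predict_concentration <- function(object, response) {
  if (!inherits(object, c("calibration_curve", "calibration_summary")))
    stop("object must be a calibration curve or summary", call. = FALSE)
  if (object$slope == 0)
    stop("slope is zero; concentration is undefined", call. = FALSE)
  conc <- (response - object$intercept) / object$slope
  oor <- conc < object$conc_range[1L] - 1e-9 |
    conc > object$conc_range[2L] + 1e-9
  if (any(oor))
    warning(sprintf("%d prediction(s) outside the calibrated range %g-%g ug/mL",
                    sum(oor), object$conc_range[1L], object$conc_range[2L]),
            call. = FALSE)
  attr(conc, "out_of_range") <- oor
  conc
}

#' Read a calibration table from CSV
#'
#' Expected columns `analyte`, `conc_ug_per_ml`, `response`; one
#' [fit_calibration()] is performed per analyte (and per `curve` column if
#' present, giving replicate curves).
#'
#' @param path CSV file path.
#' @param wavelength,order Optional provenance stored on each curve.
#' @return Named list (by analyte) of lists of `calibration_curve`s.
#' @export
read_calibration_csv <- function(path, wavelength = NA, order = NA) {
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("analyte", "conc_ug_per_ml", "response")
  if (!all(need %in% names(df)))
    stop("calibration CSV needs columns analyte, conc_ug_per_ml, response",
         call. = FALSE)
  if (!"curve" %in% names(df)) df$curve <- 1L
  out <- list()
  for (id in unique(df$analyte)) {
    sub <- df[df$analyte == id, ]
    out[[id]] <- lapply(split(sub, sub$curve), function(g)
      fit_calibration(g$conc_ug_per_ml, g$response, analyte_id = id,
                      wavelength = wavelength, order = order))
  }
  out
}
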