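#' Locate zero crossings of a derivative spectrum
#'
#' The zero-crossing technique quantifies an analyte at a wavelength where
#' the interfering compounds' derivative spectra pass through zero, so the
#' mixture's derivative there depends only on the analyte. This function
#' finds all zero crossings of one derivative trace:
#'
#' * every sign change between adjacent grid points yields one crossing,
#'   located by linear interpolation;
#' * runs of exact zeros collapse to the midpoint of the run;
#' * crossings whose flanking (nearest non-zero) amplitudes are both below
#'   `amplitude_floor` are discarded - a guard against crossings
#'   manufactured by baseline noise.
#'
#' @param dspec A [derivative()] spectrum.
#' @param amplitude_floor Noise guard in the derivative's units
#'   (AU nm^-order); `0` disables it. A sensible choice is 3x the
#'   [propagated_noise_sd()] of the instrument noise.
#' @param compound_id Label carried into the result.
#' @return An object of class `"crossing_set"`: list with `compound_id`,
#'   `crossings` (data frame: `wavelength`, `slope_sign`) and `config`.
#'   The set may be empty.
#' @export
find_zero_crossings <- function(dspec, amplitude_floor = 0,
                                compound_id = NULL) {
  stopifnot(inherits(dspec, "derivative_spectrum"))
  if (is.null(compound_id))
    compound_id <- dspec$source_meta$compound %||% NA_character_
  v <- dspec$values
  wl <- dspec$wavelengths
  nz <- which(v != 0)
  cross_wl <- numeric(0)
  cross_sign <- integer(0)
  if (length(nz) >= 1L) {
    # zero runs bounded by non-zero values on both sides
    zero_idx <- which(v == 0)
    if (length(zero_idx)) {
      runs <- split(zero_idx, cumsum(c(1L, diff(zero_idx) != 1L)))
      for (run in runs) {
        lo <- min(run); hi <- max(run)
        if (lo == 1L || hi == length(v)) next     # edge runs: no crossing
        if (abs(v[lo - 1L]) < amplitude_floor &&
            abs(v[hi + 1L]) < amplitude_floor) next
        cross_wl <- c(cross_wl, (wl[lo] + wl[hi]) / 2)
        cross_sign <- c(cross_sign, sign(v[hi + 1L] - v[lo - 1L]))
      }
    }
    # sign changes between consecutive non-zero points
    for (k in seq_len(length(nz) - 1L)) {
      i <- nz[k]; j <- nz[k + 1L]
      if (j != i + 1L) next                       # separated by a zero run
      if (sign(v[i]) == sign(v[j])) next
      if (abs(v[i]) < amplitude_floor && abs(v[j]) < amplitude_floor) next
      lam <- wl[i] + (wl[j] - wl[i]) * v[i] / (v[i] - v[j])
      cross_wl <- c(cross_wl, lam)
      cross_sign <- c(cross_sign, sign(v[j] - v[i]))
    }
  }
  o <- order(cross_wl)
  structure(
    list(compound_id = compound_id,
         crossings = data.frame(wavelength = cross_wl[o],
                                slope_sign = cross_sign[o]),
         config = dspec$config),
    class = "crossing_set"
  )
}

#' @export
print.crossing_set <- function(x, ...) {
  cat(sprintf("<crossing_set> %s: %d crossing(s)\n",
              x$compound_id, nrow(x$crossings)))
  if (nrow(x$crossings)) print(x$crossings, row.names = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

same_config <- function(a, b) {
  isTRUE(a$order == b$order) && identical(a$method, b$method) &&
    isTRUE(abs((a$delta_lambda_effective %||% a$delta_lambda) -
               (b$delta_lambda_effective %||% b$delta_lambda)) < 1e-9)
}

#' Common zero crossings of two compounds
#'
#' Wavelengths where both compounds' derivative traces cross zero, i.e.
#' candidate working wavelengths for the third component of a ternary
#' mixture. Crossing pairs closer than `wavelength_tol` are reported at
#' their midpoint, deduplicated.
#'
#' @param a,b [find_zero_crossings()] results sharing one
#'   [derivative_config()].
#' @param wavelength_tol Pairing tolerance in nm.
#' @return Sorted numeric vector of wavelengths (possibly empty).
#' @export
common_zero_crossings <- function(a, b, wavelength_tol) {
  stopifnot(inherits(a, "crossing_set"), inherits(b, "crossing_set"))
  if (!same_config(a$config, b$config))
    stop("crossing sets come from different derivative configurations",
         call. = FALSE)
  wa <- a$crossings$wavelength
  wb <- b$crossings$wavelength
  out <- numeric(0)
  for (x in wa) {
    hits <- wb[abs(wb - x) <= wavelength_tol]
    if (length(hits)) out <- c(out, (x + hits) / 2)
  }
  out <- sort(out)
  if (length(out) > 1L)
    out <- out[c(TRUE, diff(out) > 1e-6)]
  out
}

#' Select the working wavelength for one analyte
#'
#' Operationalises the "best linear response, unaffected by the other
#' components" criterion: among all grid wavelengths where every
#' interferent's derivative amplitude is at most `residual_tol`, pick the
#' one maximising
#' `score = |analyte derivative| * r^2`,
#' where `r` is the Pearson correlation between the mixture derivative at
#' that wavelength and the analyte concentration across `calibration_stack`.
#' Ties go to the larger analyte amplitude, then the lower wavelength.
#'
#' @param analyte Derivative spectrum of the pure analyte at a
#'   representative concentration.
#' @param interferents List of derivative spectra of the pure interfering
#'   compounds at their working concentrations.
#' @param calibration_stack List of mixture derivative spectra at varied
#'   analyte concentration (interferents fixed), all on the analyte's grid.
#' @param concentrations Analyte concentrations of `calibration_stack`
#'   (ug/mL). If `NULL`, read from each spectrum's
#'   `source_meta$concentrations[[analyte_id]]`.
#' @param residual_tol Admissible interferent amplitude
#'   (AU nm^-order), scalar or one per interferent. By default the gate is
#'   relative: a wavelength is a candidate when every interferent's
#'   amplitude is at most 0.5% of the analyte's own amplitude *there*
#'   (`relative_tol`), which bounds the relative quantification bias an
#'   interferent can cause. An absolute `residual_tol` overrides this.
#' @param relative_tol Fraction of the analyte amplitude used by the
#'   default relative gate (0.005).
#' @param analyte_id Label for the result (default: analyte's meta).
#' @return An object of class `"working_wavelength"`: `analyte_id`,
#'   `wavelength`, `order`, `delta_lambda` (effective), `method`,
#'   `interferent_residual` (largest interferent |D| at the selection),
#'   `analyte_signal`, `score` and the `config` used.
#' @export
select_working_wavelength <- function(analyte, interferents,
                                      calibration_stack,
                                      concentrations = NULL,
                                      residual_tol = NULL,
                                      relative_tol = 0.005,
                                      analyte_id = NULL) {
  stopifnot(inherits(analyte, "derivative_spectrum"))
  if (is.null(analyte_id))
    analyte_id <- analyte$source_meta$compound %||% NA_character_
  specs <- c(list(analyte), interferents, calibration_stack)
  for (s in specs) {
    stopifnot(inherits(s, "derivative_spectrum"))
    if (!same_config(s$config, analyte$config) ||
        length(s$wavelengths) != length(analyte$wavelengths) ||
        max(abs(s$wavelengths - analyte$wavelengths)) > 1e-9)
      stop("all spectra must share one grid and derivative configuration",
           call. = FALSE)
  }
  if (is.null(concentrations))
    concentrations <- vapply(
      calibration_stack,
      function(s) as.numeric(s$source_meta$concentrations[[analyte_id]]),
      numeric(1))
  if (length(concentrations) != length(calibration_stack))
    stop("one analyte concentration per calibration spectrum is required",
         call. = FALSE)

  if (max(abs(analyte$values)) == 0)
    stop("analyte derivative is identically zero; no selection possible",
         call. = FALSE)

  imat <- vapply(interferents, function(s) abs(s$values),
                 numeric(length(analyte$values)))
  imat <- matrix(imat, ncol = length(interferents))
  worst <- apply(imat, 1L, max)
  if (is.null(residual_tol)) {
    # relative gate: residual small against the analyte signal *here*
    tolvec <- relative_tol * abs(analyte$values)
    ok <- worst <= tolvec
    if (!any(ok)) {
      best <- which.min(worst / pmax(abs(analyte$values), .Machine$double.xmin))
      stop(sprintf(paste0(
        "no wavelength has all interferent residuals below %.2g of the ",
        "analyte amplitude; best candidate %.1f nm reaches %.3g"),
        relative_tol, analyte$wavelengths[best],
        worst[best] / abs(analyte$values[best])), call. = FALSE)
    }
  } else {
    if (length(residual_tol) == 1L)
      residual_tol <- rep(residual_tol, length(interferents))
    ok <- rep(TRUE, length(analyte$values))
    for (j in seq_along(interferents))
      ok <- ok & imat[, j] <= residual_tol[j]
    if (!any(ok)) {
      rel <- sweep(imat, 2L, residual_tol, "/")
      best <- which.min(apply(rel, 1L, max))
      stop(sprintf(paste0(
        "no wavelength satisfies the interferent residual tolerance; ",
        "best candidate %.1f nm has residuals %s (tolerances %s)"),
        analyte$wavelengths[best],
        paste(signif(imat[best, ], 3), collapse = ", "),
        paste(signif(residual_tol, 3), collapse = ", ")), call. = FALSE)
    }
  }

  stackmat <- vapply(calibration_stack, function(s) s$values,
                     numeric(length(analyte$values)))
  cand <- which(ok)
  r2 <- vapply(cand, function(i) {
    y <- stackmat[i, ]
    if (stats::sd(y) == 0) return(0)
    stats::cor(y, concentrations)^2
  }, numeric(1))
  asig <- abs(analyte$values[cand])
  score <- asig * r2
  # max score; ties to larger |analyte D|, then lower wavelength
  o <- order(-score, -asig, analyte$wavelengths[cand])
  pick <- cand[o[1L]]

  structure(
    list(analyte_id = analyte_id,
         wavelength = analyte$wavelengths[pick],
         order = analyte$config$order,
         delta_lambda = analyte$config$delta_lambda_effective %||%
           analyte$config$delta_lambda,
         method = analyte$config$method,
         interferent_residual = max(imat[pick, ]),
         analyte_signal = analyte$values[pick],
         score = score[o[1L]],
         config = analyte$config),
    class = "working_wavelength"
  )
}

#' @export
print.working_wavelength <- function(x, ...) {
  cat(sprintf(
    "<working_wavelength> %s: %.1f nm (order %d, delta_lambda %g nm, %s)\n",
    x$analyte_id, x$wavelength, x$order, x$delta_lambda, x$method))
  cat(sprintf("  analyte signal %.4g, worst interferent residual %.4g\n",
              x$analyte_signal, x$interferent_residual))
  invisible(x)
}

#' Crossing table for a set of compounds
#'
#' Convenience wrapper producing the CSV-ready table of zero crossings of
#' several pure-compound spectra under one derivative configuration.
#'
#' @param spectra Named list of zero-order `spectrum` objects.
#' @param config A [derivative_config()].
#' @param amplitude_floor Passed to [find_zero_crossings()].
#' @return Data frame with columns `compound`, `wavelength_nm`,
#'   `flank_sign`.
#' @export
crossing_table <- function(spectra, config, amplitude_floor = 0) {
  rows <- lapply(names(spectra), function(id) {
    cs <- find_zero_crossings(derivative(spectra[[id]], config),
                              amplitude_floor, compound_id = id)
    if (!nrow(cs$crossings))
      return(NULL)
    data.frame(compound = id,
               wavelength_nm = round(cs$crossings$wavelength, 1),
               flank_sign = cs$crossings$slope_sign)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows))
    return(data.frame(compound = character(0), wavelength_nm = numeric(0),
                      flank_sign = integer(0)))
  do.call(rbind, rows)
}
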