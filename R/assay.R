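#' Tablet dilution scheme
#'
#' Describes how the assayed solution relates to tablet content: a powder
#' aliquot equivalent to `sample_mass_fraction` tablets is dissolved in
#' `primary_volume` mL, and `aliquot` mL of the filtrate is diluted to
#' `final_volume` mL for measurement.
#'
#' @param sample_mass_fraction Tablets' worth of powder taken (e.g. 0.25).
#' @param primary_volume First volumetric flask volume, mL.
#' @param aliquot Volume of filtrate transferred, mL; `<= primary_volume`.
#' @param final_volume Second flask volume, mL.
#' @return An object of class `"dilution_scheme"`.
#' @export
dilution_scheme <- function(sample_mass_fraction = 0.25,
                            primary_volume = 100,
                            aliquot = 3,
                            final_volume = 100) {
  if (any(c(sample_mass_fraction, primary_volume, aliquot,
            final_volume) <= 0))
    stop("all dilution quantities must be positive", call. = FALSE)
  if (aliquot > primary_volume)
    stop("aliquot cannot exceed the primary volume", call. = FALSE)
  structure(list(sample_mass_fraction = sample_mass_fraction,
                 primary_volume = primary_volume, aliquot = aliquot,
                 final_volume = final_volume),
            class = "dilution_scheme")
}

#' Back-calculate tablet content from a measured concentration
#'
#' `content (mg) = conc * final_volume / aliquot * primary_volume /
#'  sample_mass_fraction / 1000` with `conc` in ug/mL.
#'
#' @param conc Measured concentration(s) in the final solution, ug/mL.
#' @param scheme A [dilution_scheme()].
#' @return Content per tablet in mg.
#' @seealso [content_to_concentration()] for the exact inverse.
#' @export
content_per_tablet <- function(conc, scheme) {
  stopifnot(inherits(scheme, "dilution_scheme"))
  conc * scheme$final_volume / scheme$aliquot * scheme$primary_volume /
    scheme$sample_mass_fraction / 1000
}

#' Final-solution concentration implied by a tablet content
#'
#' Exact inverse of [content_per_tablet()]; useful to locate the expected
#' measurement concentration implied by a label claim.
#'
#' @param content_mg Content per tablet, mg.
#' @param scheme A [dilution_scheme()].
#' @return Concentration in the measured solution, ug/mL.
#' @export
content_to_concentration <- function(content_mg, scheme) {
  stopifnot(inherits(scheme, "dilution_scheme"))
  content_mg * 1000 * scheme$sample_mass_fraction /
    scheme$primary_volume * scheme$aliquot / scheme$final_volume
}

#' Default per-analyte derivative configurations
#'
#' The derivative order and delta-lambda of each quantification channel:
#' first order (28.0 nm) for the major analyte, second order (31.5 nm) and
#' fourth order (27.0 nm) for the two minor ones. The channels use the
#' Savitzky-Golay variant with delta-lambda as the total filter window:
#' over a 100 nm recorded range an iterated peak-to-peak difference of
#' these widths would leave little or no usable wavelength range (an
#' order-4 comb of 27 nm spans 108 nm), whereas the local
#' smoothing-differentiation keeps the derivative's tail behaviour - and
#' with it the existence of zero-crossing regions - intact.
#'
#' @param sg_polyorder Polynomial degree used by every channel (default 5).
#' @return Named list of [derivative_config()] objects.
#' @export
default_channel_configs <- function(sg_polyorder = 5) {
  list(
    acetaminophen   = derivative_config(1, 28.0, "savitzky_golay",
                                        sg_polyorder),
    diphenhydramine = derivative_config(2, 31.5, "savitzky_golay",
                                        sg_polyorder),
    pseudoephedrine = derivative_config(4, 27.0, "savitzky_golay",
                                        sg_polyorder)
  )
}

#' Read a derivative amplitude at a working wavelength
#'
#' @param spectrum Zero-order `spectrum` of the sample.
#' @param ww A `working_wavelength` (or any list with `config` and
#'   `wavelength`).
#' @return The derivative amplitude at the working wavelength.
#' @export
measure_response <- function(spectrum, ww) {
  derivative_at(derivative(spectrum, ww$config), ww$wavelength)
}

#' Develop working wavelengths for every analyte
#'
#' Method-development step: from noiseless pure-compound and calibration
#' spectra, pick each analyte's interference-free working wavelength with
#' [select_working_wavelength()]. Interferents are simulated at the fixed
#' levels of the analyte's calibration design (their working
#' concentrations); the analyte reference spectrum uses its top design
#' level (the selection score is invariant to that choice).
#'
#' The calibration stack handed to the selector pools the mixtures of
#' *all* designs, so the interferent concentrations vary across it (each
#' analyte is an interferent in the other two designs). At a wavelength
#' with interferent leakage the mixture derivative then decorrelates from
#' the analyte concentration, and the r^2 term of the selection score
#' penalises it - this is what makes "unaffected by the other components"
#' operational even for noiseless spectra.
#'
#' @param models Named list of [compound_model()] objects.
#' @param designs Calibration designs as in
#'   [default_calibration_designs()].
#' @param configs Per-analyte [derivative_config()]s as in
#'   [default_channel_configs()].
#' @param residual_tol Passed to [select_working_wavelength()].
#' @param grid Wavelength grid.
#' @return Named list of `working_wavelength` objects.
#' @export
develop_method <- function(models,
                           designs = default_calibration_designs(),
                           configs = default_channel_configs(),
                           residual_tol = NULL,
                           grid = default_grid()) {
  stack <- unlist(lapply(names(designs), function(id)
    generate_calibration_dataset(models, id, designs[[id]]$levels,
                                 designs[[id]]$fixed, noise_sd = 0,
                                 grid = grid)),
    recursive = FALSE)
  out <- list()
  for (id in names(designs)) {
    des <- designs[[id]]
    cfg <- configs[[id]]
    analyte_d <- derivative(
      compound_spectrum(models[[id]], max(des$levels), grid), cfg)
    interf_d <- lapply(names(des$fixed), function(j)
      derivative(compound_spectrum(models[[j]], des$fixed[[j]], grid), cfg))
    stack_d <- lapply(stack, derivative, config = cfg)
    out[[id]] <- select_working_wavelength(
      analyte_d, interf_d, stack_d,
      residual_tol = residual_tol, analyte_id = id)
  }
  out
}

#' Fit one calibration curve from measured spectra
#'
#' @param spectra List of calibration `spectrum` objects (one series).
#' @param ww The analyte's `working_wavelength`.
#' @param concentrations Analyte concentrations; default read from each
#'   spectrum's metadata.
#' @param analyte_id Label; default from `ww`.
#' @return A [fit_calibration()] curve.
#' @export
fit_calibration_from_spectra <- function(spectra, ww,
                                         concentrations = NULL,
                                         analyte_id = ww$analyte_id) {
  if (is.null(concentrations))
    concentrations <- vapply(
      spectra,
      function(s) as.numeric(s$meta$concentrations[[analyte_id]]),
      numeric(1))
  responses <- vapply(spectra, measure_response, numeric(1), ww = ww)
  fit_calibration(concentrations, responses, analyte_id = analyte_id,
                  wavelength = ww$wavelength, order = ww$order)
}

#' Run the full assay on unknown sample spectra
#'
#' For every analyte: take the derivative of each unknown spectrum under
#' the analyte's channel configuration, read the amplitude at its working
#' wavelength, convert to concentration by inverse regression, and
#' back-calculate the content per tablet through the dilution scheme.
#' Concentrations outside the calibrated range are flagged but still
#' reported.
#'
#' @param calibrations Named list (by analyte) of `calibration_curve` or
#'   `calibration_summary` objects.
#' @param unknowns List of zero-order `spectrum` replicates of the assay
#'   solution (a single `spectrum` is accepted).
#' @param working_wavelengths Named list of `working_wavelength` objects.
#' @param scheme A [dilution_scheme()].
#' @param label_claims Optional named vector of label claims, mg/tablet.
#' @param reference Optional named list of reference-method content
#'   vectors (mg/tablet) for a [compare_methods()] per analyte.
#' @param alpha Significance level for the optional comparison.
#' @return An object of class `"assay_result"`: `table` (per-compound
#'   summary data frame), `found` (per-compound content vectors, mg),
#'   `concentrations` (per-compound measured ug/mL), and optional
#'   `comparison` per compound.
#' @export
run_assay <- function(calibrations, unknowns, working_wavelengths, scheme,
                      label_claims = NULL, reference = NULL, alpha = 0.05) {
  stopifnot(inherits(scheme, "dilution_scheme"))
  if (inherits(unknowns, "spectrum")) unknowns <- list(unknowns)
  ids <- names(working_wavelengths)
  if (!all(ids %in% names(calibrations)))
    stop("a calibration is required for every working wavelength",
         call. = FALSE)
  found <- list(); concs <- list(); comparison <- list()
  rows <- list()
  for (id in ids) {
    ww <- working_wavelengths[[id]]
    responses <- vapply(unknowns, measure_response, numeric(1), ww = ww)
    conc <- suppressWarnings(
      predict_concentration(calibrations[[id]], responses))
    oor <- attr(conc, "out_of_range")
    content <- content_per_tablet(as.numeric(conc), scheme)
    found[[id]] <- content
    concs[[id]] <- as.numeric(conc)
    claim <- if (!is.null(label_claims)) label_claims[[id]] else NA_real_
    cmp <- NULL
    if (!is.null(reference) && !is.null(reference[[id]])) {
      cmp <- compare_methods(content, reference[[id]], alpha)
      comparison[[id]] <- cmp
    }
    rows[[id]] <- data.frame(
      compound = id,
      wavelength_nm = ww$wavelength,
      order = ww$order,
      measured_conc_ug_ml = mean(as.numeric(conc)),
      content_mg = mean(content),
      content_sd_mg = if (length(content) > 1L) stats::sd(content)
                      else NA_real_,
      label_claim_mg = claim,
      percent_of_label = if (is.na(claim)) NA_real_
                         else 100 * mean(content) / claim,
      out_of_range = any(oor),
      t_stat = if (is.null(cmp)) NA_real_ else cmp$t_stat,
      f_stat = if (is.null(cmp)) NA_real_ else cmp$f_stat)
  }
  structure(
    list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
         found = found, concentrations = concs,
         comparison = if (length(comparison)) comparison else NULL,
         scheme = scheme),
    class = "assay_result"
  )
}

#' @export
print.assay_result <- function(x, ...) {
  cat("<assay_result>\n")
  print(x$table, row.names = FALSE, digits = 6)
  invisible(x)
}
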