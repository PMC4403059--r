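#' Gaussian-band spectral model of a compound
#'
#' The simulator represents each compound's absorptivity as a sum of
#' Gaussian bands,
#' `eps(lambda) = sum(eps_peak * exp(-(lambda - center)^2 / (2 sigma^2)))`,
#' in AU mL ug^-1 cm^-1, so a Beer-Lambert absorbance is
#' `A(lambda) = eps(lambda) * conc * path_length`.
#'
#' @param compound_id Compound label.
#' @param bands Data frame with columns `center_nm`, `sigma_nm`,
#'   `epsilon_peak`; at least one band, `sigma_nm > 0`,
#'   `epsilon_peak >= 0`.
#' @param path_length Cuvette path length in cm (default 1).
#' @return An object of class `"compound_model"`.
#' @seealso [default_compound_models()], [compound_spectrum()]
#' @export
compound_model <- function(compound_id, bands, path_length = 1) {
  need <- c("center_nm", "sigma_nm", "epsilon_peak")
  if (!is.data.frame(bands) || !all(need %in% names(bands)) ||
      nrow(bands) < 1L)
    stop("bands must be a data frame with >= 1 row and columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (any(bands$sigma_nm <= 0) || any(bands$epsilon_peak < 0))
    stop("band widths must be positive and peak absorptivities non-negative",
         call. = FALSE)
  if (path_length <= 0)
    stop("path_length must be positive", call. = FALSE)
  structure(list(compound_id = compound_id, bands = bands,
                 path_length = path_length),
            class = "compound_model")
}

#' @export
print.compound_model <- function(x, ...) {
  cat(sprintf("<compound_model> %s: %d Gaussian band(s), path %g cm\n",
              x$compound_id, nrow(x$bands), x$path_length))
  print(x$bands, row.names = FALSE)
  invisible(x)
}

#' Absorptivity of a compound model
#'
#' @param model A [compound_model()].
#' @param wavelengths Wavelengths in nm.
#' @return `eps(lambda)` in AU mL ug^-1 cm^-1.
#' @export
epsilon <- function(model, wavelengths) {
  stopifnot(inherits(model, "compound_model"))
  out <- numeric(length(wavelengths))
  for (i in seq_len(nrow(model$bands))) {
    b <- model$bands[i, ]
    out <- out + b$epsilon_peak *
      exp(-(wavelengths - b$center_nm)^2 / (2 * b$sigma_nm^2))
  }
  out
}

#' Default uniform simulation grid
#'
#' 200-300 nm at a 0.1 nm step, the recorded range of the emulated
#' instrument.
#'
#' @return Numeric wavelength vector.
#' @export
default_grid <- function() seq(200, 300, by = 0.1)

#' Synthetic band models of the three-compound system
#'
#' Loads the synthetic Gaussian-band parameters shipped in
#' `extdata/synthetic_band_models.csv`. They emulate a ternary common-cold
#' formulation measured in dilute acid: a dominant mid-UV absorber
#' (`acetaminophen`, strong band near 243 nm plus end absorption), a minor
#' component with strong short-wavelength absorption and very weak
#' benzenoid fine structure (`diphenhydramine`), and a minor component with
#' strong end absorption and weak benzenoid bands (`pseudoephedrine`).
#' The parameters are synthetic: chosen to reproduce the qualitative band
#' positions, relative intensities and overlap of the real system, not
#' fitted to measured spectra.
#'
#' @return Named list of three [compound_model()] objects.
#' @export
default_compound_models <- function() {
  path <- system.file("extdata", "synthetic_band_models.csv",
                      package = "derivspec", mustWork = TRUE)
  df <- utils::read.csv(path, comment.char = "#")
  lapply(split(df, df$compound_id)[unique(df$compound_id)], function(g)
    compound_model(g$compound_id[1L],
                   g[, c("center_nm", "sigma_nm", "epsilon_peak")]))
}

#' Noiseless Beer-Lambert spectrum of one compound
#'
#' @param model A [compound_model()].
#' @param conc Concentration in ug/mL, >= 0.
#' @param grid Wavelength grid (nm), default [default_grid()].
#' @return A `spectrum`; `meta$compound` and `meta$conc` record the truth.
#' @export
compound_spectrum <- function(model, conc, grid = default_grid()) {
  stopifnot(inherits(model, "compound_model"))
  if (!is.finite(conc) || conc < 0)
    stop("concentration must be non-negative", call. = FALSE)
  new_spectrum(grid, epsilon(model, grid) * conc * model$path_length,
               meta = list(compound = model$compound_id, conc = conc))
}

#' Simulated mixture spectrum with instrument noise
#'
#' Additive Beer-Lambert mixing of the named components plus i.i.d.
#' Gaussian absorbance noise. The true concentrations are stored in the
#' result's metadata.
#'
#' @param models Named list of [compound_model()] objects.
#' @param concentrations Named numeric vector/list, compound id -> ug/mL;
#'   every name must have a model.
#' @param noise_sd Absorbance noise SD in AU (default 0, noiseless).
#' @param seed Optional integer seed; when given, the draw is reproducible.
#' @param grid Wavelength grid (nm).
#' @return A `spectrum` with `meta$concentrations`, `meta$noise_sd` and
#'   `meta$seed`.
#' @export
mixture_spectrum <- function(models, concentrations, noise_sd = 0,
                             seed = NULL, grid = default_grid()) {
  concentrations <- unlist(concentrations)
  missing_ids <- setdiff(names(concentrations), names(models))
  if (length(missing_ids))
    stop("no spectral model for compound(s): ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  if (any(concentrations < 0) || noise_sd < 0)
    stop("concentrations and noise_sd must be non-negative", call. = FALSE)
  a <- numeric(length(grid))
  for (id in names(concentrations))
    a <- a + epsilon(models[[id]], grid) * concentrations[[id]] *
      models[[id]]$path_length
  if (!is.null(seed)) set.seed(seed)
  if (noise_sd > 0)
    a <- a + stats::rnorm(length(grid), sd = noise_sd)
  new_spectrum(grid, a,
               meta = list(concentrations = as.list(concentrations),
                           noise_sd = noise_sd, seed = seed))
}

#' Calibration designs of the emulated study
#'
#' The standard-solution pattern of the emulated assay: each analyte is
#' varied over its series with the other two compounds held at fixed
#' levels - acetaminophen 5-40 ug/mL against 1.5 + 1.5 ug/mL of the minor
#' compounds; diphenhydramine 0.25-4 ug/mL and pseudoephedrine 0.5-5 ug/mL
#' each against 25 ug/mL acetaminophen and 1.5 ug/mL of the other minor
#' compound. The design is data, not code; edit the returned object for
#' other designs.
#'
#' @return Named list with, per analyte, `levels` (ug/mL series) and
#'   `fixed` (named vector of the other compounds' concentrations).
#' @export
default_calibration_designs <- function() {
  list(
    acetaminophen = list(
      levels = c(5, 10, 15, 20, 25, 30, 35, 40),
      fixed = c(diphenhydramine = 1.5, pseudoephedrine = 1.5)),
    diphenhydramine = list(
      levels = c(0.25, 0.5, 1, 1.5, 2, 2.5, 3, 3.5, 4),
      fixed = c(acetaminophen = 25, pseudoephedrine = 1.5)),
    pseudoephedrine = list(
      levels = c(0.5, 1, 1.5, 2, 2.5, 3, 3.5, 4, 4.5, 5),
      fixed = c(acetaminophen = 25, diphenhydramine = 1.5))
  )
}

#' Simulate one calibration series
#'
#' One mixture spectrum per design level: the analyte at each level with
#' the interferents fixed, plus noise. True concentrations live in each
#' spectrum's metadata, so the collection is self-describing.
#'
#' @param models Named list of [compound_model()] objects.
#' @param analyte_id Compound varied over the series.
#' @param levels Analyte concentrations (ug/mL); may be empty.
#' @param fixed Named vector of the other compounds' fixed concentrations.
#' @param noise_sd Absorbance noise SD (AU).
#' @param seed Optional integer seed for the whole collection.
#' @param grid Wavelength grid.
#' @return List of `spectrum` objects, one per level.
#' @export
generate_calibration_dataset <- function(models, analyte_id, levels, fixed,
                                         noise_sd = 0, seed = NULL,
                                         grid = default_grid()) {
  if (!is.null(seed)) set.seed(seed)
  lapply(levels, function(conc) {
    cc <- c(stats::setNames(conc, analyte_id), fixed)
    mixture_spectrum(models, cc, noise_sd = noise_sd, seed = NULL,
                     grid = grid)
  })
}
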