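#' Derivative configuration
#'
#' Describes how a derivative spectrum of order 1-4 is formed from a
#' zero-order spectrum. Two algorithms are offered:
#'
#' * `finite_difference` (default): the classic peak-to-peak derivative.
#'   One application computes the centred difference
#'   `D(lambda) = (A(lambda + dl/2) - A(lambda - dl/2)) / dl`
#'   where `dl` is `delta_lambda` rounded to the nearest even number of grid
#'   steps; higher orders apply the operator iteratively. Each application
#'   narrows the usable wavelength range by `dl/2` on each side.
#' * `savitzky_golay`: local polynomial smoothing-differentiation. The
#'   filter window is the odd number of points closest to
#'   `delta_lambda / step`, a polynomial of degree `sg_polyorder` is fitted
#'   in the window and its `order`-th derivative evaluated at the centre,
#'   scaled by `step^-order` so the units are AU nm^-order. The usable range
#'   shrinks by half a window on each side.
#'
#' `delta_lambda` controls the trade-off between smoothing (noise rejection)
#' and band resolution; large values also shift apparent zero-crossings, so
#' calibration and measurement must always share one configuration.
#'
#' @param order Derivative order, integer 1-4.
#' @param delta_lambda Differencing width / filter window in nm; must span
#'   at least two grid steps of the spectra it is applied to.
#' @param method `"finite_difference"` or `"savitzky_golay"`.
#' @param sg_polyorder Polynomial degree for `savitzky_golay`; must exceed
#'   `order`. Default `order + 1`.
#' @return An object of class `"derivative_config"`.
#' @seealso [derivative()]
#' @export
derivative_config <- function(order, delta_lambda,
                              method = c("finite_difference", "savitzky_golay"),
                              sg_polyorder = NULL) {
  method <- match.arg(method)
  order <- as.integer(order)
  if (is.na(order) || order < 1L || order > 4L)
    stop("order must be an integer between 1 and 4", call. = FALSE)
  if (!is.numeric(delta_lambda) || length(delta_lambda) != 1L ||
      !is.finite(delta_lambda) || delta_lambda <= 0)
    stop("delta_lambda must be a positive number (nm)", call. = FALSE)
  if (method == "savitzky_golay") {
    if (is.null(sg_polyorder)) sg_polyorder <- order + 1L
    sg_polyorder <- as.integer(sg_polyorder)
    if (sg_polyorder <= order)
      stop("sg_polyorder must exceed the derivative order", call. = FALSE)
  } else {
    sg_polyorder <- NULL
  }
  structure(
    list(order = order, delta_lambda = delta_lambda, method = method,
         sg_polyorder = sg_polyorder),
    class = "derivative_config"
  )
}

#' @export
print.derivative_config <- function(x, ...) {
  cat(sprintf("<derivative_config> order %d, delta_lambda %g nm, %s%s%s\n",
              x$order, x$delta_lambda, x$method,
              if (!is.null(x$sg_polyorder))
                sprintf(", polyorder %d", x$sg_polyorder) else "",
              if (!is.null(x$delta_lambda_effective))
                sprintf(" (effective %g nm)", x$delta_lambda_effective) else ""))
  invisible(x)
}

# effective half-width of one centred-difference pass, in grid steps
fd_half_steps <- function(delta_lambda, step) {
  max(1L, as.integer(round(delta_lambda / (2 * step))))
}

# odd Savitzky-Golay window length in points closest to delta_lambda/step
sg_window_points <- function(delta_lambda, step) {
  2L * as.integer(round((delta_lambda / step - 1) / 2)) + 1L
}

# central-row Savitzky-Golay kernels are expensive to derive for wide
# windows, and one session reuses a handful of configurations heavily
.sg_cache <- new.env(parent = emptyenv())

sg_center_coefs <- function(p, n, m, ts) {
  key <- paste(p, n, m, signif(ts, 12), sep = "|")
  hit <- .sg_cache[[key]]
  if (!is.null(hit)) return(hit)
  coefs <- signal::sgolay(p = p, n = n, m = m, ts = ts)[(n + 1L) %/% 2L, ]
  .sg_cache[[key]] <- coefs
  coefs
}

#' Compute a derivative spectrum
#'
#' Applies the configured derivative operator to a zero-order spectrum.
#' Wavelengths where the operator window does not fit inside the grid are
#' dropped, never zero-padded (padding manufactures spurious
#' zero-crossings). The configuration actually used - including the
#' effective `delta_lambda` after rounding onto the grid - is stored in the
#' result so any later measurement can be made under identical conditions.
#'
#' @param spectrum A [new_spectrum()] object.
#' @param config A [derivative_config()].
#' @return An object of class `"derivative_spectrum"`: list with
#'   `wavelengths`, `values` (AU nm^-order), `config` (with
#'   `delta_lambda_effective` filled in) and `source_meta`.
#' @examples
#' s <- new_spectrum(seq(200, 300, 0.5), 0.01 * seq(200, 300, 0.5))
#' d <- derivative(s, derivative_config(1, 2))
#' range(d$values)  # 0.01 0.01
#' @export
derivative <- function(spectrum, config) {
  stopifnot(inherits(spectrum, "spectrum"),
            inherits(config, "derivative_config"))
  h <- wl_step(spectrum)
  if (config$delta_lambda < 2 * h - 1e-9)
    stop("delta_lambda must span at least two grid steps", call. = FALSE)
  wl <- spectrum$wavelengths
  v <- spectrum$absorbance

  if (config$method == "finite_difference") {
    half <- fd_half_steps(config$delta_lambda, h)
    eff <- 2 * half * h
    for (pass in seq_len(config$order)) {
      n <- length(v)
      if (n <= 2L * half)
        stop(sprintf(
          "differencing window (%g nm x %d passes) wider than spectrum",
          eff, config$order), call. = FALSE)
      idx <- (half + 1L):(n - half)
      v <- (v[idx + half] - v[idx - half]) / eff
      wl <- wl[idx]
    }
  } else {
    w <- sg_window_points(config$delta_lambda, h)
    if (w <= config$sg_polyorder)
      stop("Savitzky-Golay window too narrow for the polynomial order",
           call. = FALSE)
    if (w > length(v))
      stop("Savitzky-Golay window wider than spectrum", call. = FALSE)
    eff <- (w - 1L) * h
    coefs <- sg_center_coefs(config$sg_polyorder, w, config$order, h)
    halfw <- (w - 1L) %/% 2L
    keep <- (halfw + 1L):(length(v) - halfw)
    v <- as.numeric(stats::filter(v, rev(coefs), method = "convolution",
                                  sides = 2))[keep]
    wl <- wl[keep]
  }

  config$delta_lambda_effective <- eff
  structure(
    list(wavelengths = wl, values = as.numeric(v), config = config,
         source_meta = spectrum$meta),
    class = "derivative_spectrum"
  )
}

#' @export
print.derivative_spectrum <- function(x, ...) {
  cat(sprintf("<derivative_spectrum> order %d (%s), %d points, %.4g-%.4g nm\n",
              x$config$order, x$config$method, length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' @export
as.data.frame.derivative_spectrum <- function(x, ...) {
  data.frame(wavelength_nm = x$wavelengths, value = x$values)
}

#' Derivative value at given wavelengths
#'
#' Linear interpolation of a derivative trace; used to read the analytical
#' signal at a working wavelength that may fall between grid points.
#'
#' @param dspec A `derivative_spectrum`.
#' @param wavelength Wavelength(s) in nm, inside the derivative's domain.
#' @return Numeric vector of derivative amplitudes.
#' @export
derivative_at <- function(dspec, wavelength) {
  stopifnot(inherits(dspec, "derivative_spectrum"))
  rng <- range(dspec$wavelengths)
  if (any(wavelength < rng[1L] - 1e-9 | wavelength > rng[2L] + 1e-9))
    stop("wavelength outside the derivative's domain", call. = FALSE)
  stats::approx(dspec$wavelengths, dspec$values, xout = wavelength,
                rule = 2)$y
}

#' Noise standard deviation propagated through a derivative operator
#'
#' For i.i.d. Gaussian absorbance noise of standard deviation `noise_sd`,
#' returns the standard deviation of the derivative trace values. For the
#' iterated centred difference the binomial weights give a factor
#' `sqrt(choose(2n, n)) / dl^n`; for Savitzky-Golay it is the Euclidean norm
#' of the (derivative-scaled) convolution coefficients. Useful to set the
#' amplitude floor of [find_zero_crossings()].
#'
#' @param config A [derivative_config()].
#' @param step Grid step (nm) of the spectra the config will be applied to.
#' @param noise_sd Absorbance noise standard deviation (AU).
#' @return Standard deviation of the derivative values (AU nm^-order).
#' @export
propagated_noise_sd <- function(config, step, noise_sd) {
  stopifnot(inherits(config, "derivative_config"))
  if (config$method == "finite_difference") {
    half <- fd_half_steps(config$delta_lambda, step)
    eff <- 2 * half * step
    n <- config$order
    noise_sd * sqrt(choose(2 * n, n)) / eff^n
  } else {
    w <- sg_window_points(config$delta_lambda, step)
    coefs <- signal::sgolay(p = config$sg_polyorder, n = w,
                            m = config$order, ts = step)[(w + 1L) %/% 2L, ]
    noise_sd * sqrt(sum(coefs^2))
  }
}
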