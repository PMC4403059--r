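#' Construct an absorbance spectrum
#'
#' A `spectrum` holds an absorbance trace sampled on a strictly increasing,
#' uniform wavelength grid, the raw measurement of a UV-Vis
#' spectrophotometer. All downstream operations (derivatives, zero-crossing
#' location, quantification) assume this uniform grid.
#'
#' @param wavelengths Numeric vector of wavelengths in nm; strictly
#'   increasing and uniform (constant step to within `1e-9` nm), length >= 2.
#' @param absorbance Numeric vector of absorbance values (AU), same length
#'   as `wavelengths`; every value must be finite.
#' @param meta Named list of free-form provenance (sample id, dilution
#'   factor, true concentrations for simulated spectra, ...).
#'
#' @return An object of class `"spectrum"`: a list with elements
#'   `wavelengths`, `absorbance` and `meta`.
#' @seealso [resample()], [derivative()], [read_spectrum_csv()]
#' @examples
#' s <- new_spectrum(seq(200, 300, by = 0.5), rep(0.1, 201))
#' wl_step(s)
#' @export
new_spectrum <- function(wavelengths, absorbance, meta = list()) {
  if (!is.numeric(wavelengths) || !is.numeric(absorbance))
    stop("wavelengths and absorbance must be numeric vectors", call. = FALSE)
  n <- length(wavelengths)
  if (n < 2L)
    stop("a spectrum needs at least two grid points", call. = FALSE)
  if (length(absorbance) != n)
    stop("wavelengths and absorbance differ in length", call. = FALSE)
  d <- diff(wavelengths)
  if (any(d <= 0))
    stop("wavelengths must be strictly increasing", call. = FALSE)
  if (n > 2L && max(d) - min(d) > 1e-9)
    stop("wavelength grid is not uniform (tolerance 1e-9 nm)", call. = FALSE)
  if (!all(is.finite(absorbance)))
    stop("absorbance contains non-finite values", call. = FALSE)
  if (!is.list(meta))
    stop("meta must be a list", call. = FALSE)
  structure(
    list(wavelengths = as.numeric(wavelengths),
         absorbance  = as.numeric(absorbance),
         meta        = meta),
    class = "spectrum"
  )
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %d points, %.4g-%.4g nm, step %.4g nm\n",
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
              wl_step(x)))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.spectrum <- function(x, ...) {
  data.frame(wavelength_nm = x$wavelengths, absorbance = x$absorbance)
}

#' Grid step of a spectrum
#'
#' @param x A [new_spectrum()] object (or a derivative spectrum).
#' @return Wavelength increment of the uniform grid, in nm.
#' @export
wl_step <- function(x) {
  (x$wavelengths[length(x$wavelengths)] - x$wavelengths[1L]) /
    (length(x$wavelengths) - 1L)
}

#' Resample a spectrum onto a new uniform grid
#'
#' Linear interpolation onto `seq(grid_start, grid_stop, by = step)`. The
#' requested range must lie within the source range; metadata is carried
#' over unchanged.
#'
#' @param spectrum A [new_spectrum()] object.
#' @param grid_start,grid_stop Range of the new grid (nm).
#' @param step New grid step (nm).
#' @return A `spectrum` on the requested grid.
#' @examples
#' s <- new_spectrum(c(200, 300), c(0, 1))
#' resample(s, 200, 300, 50)$absorbance  # 0.0 0.5 1.0
#' @export
resample <- function(spectrum, grid_start, grid_stop, step) {
  stopifnot(inherits(spectrum, "spectrum"))
  if (grid_stop <= grid_start || step <= 0)
    stop("invalid target grid", call. = FALSE)
  rng <- range(spectrum$wavelengths)
  if (grid_start < rng[1L] - 1e-9 || grid_stop > rng[2L] + 1e-9)
    stop(sprintf("requested range [%g, %g] outside source range [%g, %g]",
                 grid_start, grid_stop, rng[1L], rng[2L]), call. = FALSE)
  grid <- seq(grid_start, grid_stop, by = step)
  vals <- stats::approx(spectrum$wavelengths, spectrum$absorbance,
                        xout = grid, rule = 1)$y
  new_spectrum(grid, vals, meta = spectrum$meta)
}

#' Read a spectrum from a two-column CSV file
#'
#' Expected header `wavelength_nm,absorbance`; lines starting with `#` are
#' treated as comments.
#'
#' @param path Path to the CSV file.
#' @param meta Optional metadata list; the file path is recorded under
#'   `$source_file`.
#' @return A `spectrum`.
#' @export
read_spectrum_csv <- function(path, meta = list()) {
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("wavelength_nm", "absorbance")
  if (!all(need %in% names(df)))
    stop("spectrum CSV must have columns 'wavelength_nm' and 'absorbance'",
         call. = FALSE)
  meta$source_file <- path
  new_spectrum(df$wavelength_nm, df$absorbance, meta = meta)
}

#' Write a spectrum to CSV
#'
#' @param spectrum A `spectrum`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "spectrum"))
  utils::write.csv(as.data.frame(spectrum), path, row.names = FALSE)
  invisible(path)
}

#' Read a spectrum from a JCAMP-DX file (XYDATA, AFFN form)
#'
#' Minimal import for instrument exports using an uncompressed
#' `##XYDATA=(X++(Y..Y))` block with `##FIRSTX`, `##DELTAX` (or per-line X
#' values) and optional `##XFACTOR`/`##YFACTOR` scaling. Compressed (SQZ/DIF)
#' ordinate forms are not supported.
#'
#' @param path Path to the JCAMP-DX file.
#' @return A `spectrum`; the JCAMP `##TITLE` is stored in `meta$title`.
#' @export
read_jcamp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  get_field <- function(key) {
    hit <- grep(paste0("^##", key, "="), lines, value = TRUE)
    if (!length(hit)) return(NA_character_)
    trimws(sub(paste0("^##", key, "="), "", hit[1L]))
  }
  xfac <- get_field("XFACTOR"); xfac <- if (is.na(xfac)) 1 else as.numeric(xfac)
  yfac <- get_field("YFACTOR"); yfac <- if (is.na(yfac)) 1 else as.numeric(yfac)
  start <- grep("^##XYDATA=", lines)
  if (!length(start))
    stop("no ##XYDATA block found", call. = FALSE)
  end <- grep("^##", lines)
  end <- end[end > start[1L]]
  end <- if (length(end)) min(end) - 1L else length(lines)
  block <- lines[(start[1L] + 1L):end]
  block <- block[nzchar(trimws(block))]
  dx <- as.numeric(get_field("DELTAX"))   # step in actual x units
  if (is.na(dx)) {
    npts  <- as.numeric(get_field("NPOINTS"))
    lastx <- as.numeric(get_field("LASTX"))
    firstx <- as.numeric(get_field("FIRSTX"))
    dx <- (lastx - firstx) / (npts - 1)
  }
  wl <- numeric(0); ab <- numeric(0)
  for (ln in block) {
    vals <- as.numeric(strsplit(trimws(ln), "[[:space:],]+")[[1L]])
    if (any(is.na(vals)))
      stop("non-numeric ordinate data; compressed JCAMP forms unsupported",
           call. = FALSE)
    ys <- vals[-1L]
    wl <- c(wl, vals[1L] * xfac + dx * (seq_along(ys) - 1L))
    ab <- c(ab, ys * yfac)
  }
  o <- order(wl)
  new_spectrum(wl[o], ab[o], meta = list(title = get_field("TITLE"),
                                         source_file = path))
}
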