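test_that("a sign change between adjacent points interpolates linearly", {
  d <- dspec_from_values(c(220, 221), c(1, -1))
  cs <- find_zero_crossings(d)
  expect_equal(cs$crossings$wavelength, 220.5)
  expect_equal(cs$crossings$slope_sign, -1)
})

test_that("a strictly positive trace has no crossings", {
  d <- dspec_from_values(seq(220, 230, 1), rep(0.2, 11))
  expect_equal(nrow(find_zero_crossings(d)$crossings), 0)
})

test_that("runs of exact zeros collapse to their midpoint", {
  d <- dspec_from_values(seq(220, 226, 1), c(2, 1, 0, 0, 0, -1, -2))
  cs <- find_zero_crossings(d)
  expect_equal(cs$crossings$wavelength, 223)
  expect_equal(cs$crossings$slope_sign, -1)
  # edge runs of zeros are not crossings
  d2 <- dspec_from_values(seq(220, 224, 1), c(0, 0, 1, 2, 3))
  expect_equal(nrow(find_zero_crossings(d2)$crossings), 0)
})

test_that("amplitude floor discards noise-level crossings only", {
  d <- dspec_from_values(seq(220, 225, 1),
                         c(0.001, -0.001, 0.001, -1, 1, 0.5))
  cs <- find_zero_crossings(d, amplitude_floor = 0.01)
  # tiny wiggles dropped; the -1 / +1 crossing kept, and the 0.001 -> -1
  # flank pair kept because one flank is large
  expect_equal(nrow(cs$crossings), 2)
  expect_true(all(cs$crossings$wavelength > 222))
})

test_that("first derivative of a Gaussian band crosses zero at its center", {
  for (method in c("finite_difference", "savitzky_golay")) {
    s <- gaussian_spectrum(center = 250, sigma = 8)
    d <- derivative(s, derivative_config(1, 4, method))
    cs <- find_zero_crossings(d)
    # analytic root of the first derivative: the band center
    expect_equal(nrow(cs$crossings), 1)
    expect_equal(cs$crossings$wavelength, 250, tolerance = 0.5)
  }
})

test_that("common_zero_crossings agrees with a brute-force all-pairs search", {
  set.seed(11)
  cfg <- derivative_config(1, 2)
  for (rep in 1:20) {
    a <- sort(runif(sample(1:8, 1), 210, 290))
    b <- sort(runif(sample(1:8, 1), 210, 290))
    tol <- runif(1, 0.1, 5)
    sa <- structure(list(compound_id = "a",
                         crossings = data.frame(wavelength = a,
                                                slope_sign = 1),
                         config = cfg), class = "crossing_set")
    sb <- structure(list(compound_id = "b",
                         crossings = data.frame(wavelength = b,
                                                slope_sign = 1),
                         config = cfg), class = "crossing_set")
    got <- common_zero_crossings(sa, sb, tol)
    brute <- numeric(0)
    for (x in a) for (y in b)
      if (abs(x - y) <= tol) brute <- c(brute, (x + y) / 2)
    brute <- sort(unique(brute))
    brute <- if (length(brute) > 1)
      brute[c(TRUE, diff(brute) > 1e-6)] else brute
    expect_equal(got, brute)
  }
})

test_that("common crossings of identical sets are the sets' own wavelengths", {
  cfg <- derivative_config(2, 4)
  cs <- structure(list(compound_id = "a",
                       crossings = data.frame(wavelength = c(250, 270),
                                              slope_sign = c(1, -1)),
                       config = cfg), class = "crossing_set")
  expect_equal(common_zero_crossings(cs, cs, 1), c(250, 270))
})

test_that("disjoint crossing sets give no common crossings, mismatched configs error", {
  mk <- function(wl, cfg) structure(
    list(compound_id = "x",
         crossings = data.frame(wavelength = wl, slope_sign = 1),
         config = cfg), class = "crossing_set")
  cfg1 <- derivative_config(1, 2)
  expect_equal(length(common_zero_crossings(mk(250, cfg1), mk(270, cfg1), 1)),
               0)
  expect_error(
    common_zero_crossings(mk(250, cfg1), mk(250, derivative_config(2, 2)), 1),
    "configuration")
})

test_that("selection returns the only interference-free candidate", {
  grid <- seq(200, 300, 0.5)
  cfg <- derivative_config(1, 4)
  analyte <- derivative(gaussian_spectrum(240, 12, 1, grid), cfg)
  interf <- derivative(gaussian_spectrum(270, 5, 1, grid), cfg)
  stack <- lapply(c(1, 2, 3), function(k)
    derivative(new_spectrum(grid, k * gaussian_spectrum(240, 12, 1, grid)$absorbance +
                                  gaussian_spectrum(270, 5, 0.5, grid)$absorbance), cfg))
  ww <- select_working_wavelength(analyte, list(interf), stack,
                                  concentrations = c(1, 2, 3),
                                  analyte_id = "a")
  # the interferent's own crossing at its band center is the natural pick
  # only where the analyte still has signal; selection must satisfy the gate
  imax <- abs(derivative_at(interf, ww$wavelength))
  expect_lte(imax, 0.005 * abs(ww$analyte_signal) + 1e-12)
  expect_gt(abs(ww$analyte_signal), 0)
})

test_that("selection reproduces an exhaustive grid search of the same score", {
  st <- study()
  grid <- default_grid()
  id <- "diphenhydramine"
  des <- st$designs[[id]]
  cfg <- st$configs[[id]]
  wws <- develop_method(st$models, st$designs, st$configs)
  # independent brute force: plain loops over every grid wavelength
  ad <- derivative(compound_spectrum(st$models[[id]], max(des$levels), grid),
                   cfg)
  ints <- lapply(names(des$fixed), function(j)
    derivative(compound_spectrum(st$models[[j]], des$fixed[[j]], grid), cfg))
  stack <- unlist(lapply(names(st$designs), function(k)
    generate_calibration_dataset(st$models, k, st$designs[[k]]$levels,
                                 st$designs[[k]]$fixed)), recursive = FALSE)
  stack_d <- lapply(stack, derivative, config = cfg)
  conc <- vapply(stack, function(s)
    as.numeric(s$meta$concentrations[[id]]), numeric(1))
  best <- NULL
  for (i in seq_along(ad$wavelengths)) {
    resid <- max(vapply(ints, function(s) abs(s$values[i]), numeric(1)))
    if (resid > 0.005 * abs(ad$values[i])) next
    y <- vapply(stack_d, function(s) s$values[i], numeric(1))
    r2 <- if (sd(y) == 0) 0 else cor(y, conc)^2
    sc <- abs(ad$values[i]) * r2
    if (is.null(best) || sc > best$sc) best <- list(sc = sc, wl = ad$wavelengths[i])
  }
  expect_equal(wws[[id]]$wavelength, best$wl)
})

test_that("an identically zero analyte is never confidently selected", {
  grid <- seq(200, 300, 0.5)
  cfg <- derivative_config(1, 4)
  analyte <- derivative(new_spectrum(grid, rep(0, length(grid))), cfg)
  interf <- derivative(gaussian_spectrum(270, 5, 1, grid), cfg)
  stack <- list(derivative(gaussian_spectrum(270, 5, 1, grid), cfg),
                derivative(gaussian_spectrum(270, 5, 1, grid), cfg))
  expect_error(
    select_working_wavelength(analyte, list(interf), stack,
                              concentrations = c(1, 2), analyte_id = "a"),
    "zero")
})

test_that("crossing_table reports rounded wavelengths per compound", {
  st <- study()
  spectra <- list(
    acetaminophen = compound_spectrum(st$models$acetaminophen, 20),
    pseudoephedrine = compound_spectrum(st$models$pseudoephedrine, 7))
  tab <- crossing_table(spectra, derivative_config(1, 28, "savitzky_golay", 5))
  expect_true(all(c("compound", "wavelength_nm", "flank_sign") %in%
                  names(tab)))
  expect_true(all(tab$wavelength_nm >= 200 & tab$wavelength_nm <= 300))
  expect_true("acetaminophen" %in% tab$compound)
})
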