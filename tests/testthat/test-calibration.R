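test_that("points on an exact line are fitted exactly", {
  conc <- c(5, 10, 15, 20, 25, 30, 35, 40)
  resp <- 0.00295 * conc - 0.0024
  cv <- fit_calibration(conc, resp, analyte_id = "major", wavelength = 281.5,
                        order = 1)
  expect_equal(cv$slope, 0.00295)
  expect_equal(cv$intercept, -0.0024)
  expect_equal(cv$r, 1)
  expect_equal(cv$sd_slope, 0, tolerance = 1e-12)
  expect_equal(cv$sd_intercept, 0, tolerance = 1e-12)
})

test_that("constant responses give slope zero", {
  cv <- fit_calibration(c(1, 2, 3), c(0.5, 0.5, 0.5))
  expect_equal(cv$slope, 0)
  expect_equal(cv$intercept, 0.5)
})

test_that("OLS matches a brute-force normal-equations solver to 1e-10", {
  set.seed(21)
  for (rep in 1:10) {
    x <- runif(8, 1, 40)
    y <- 0.003 * x + rnorm(8, sd = 0.01)
    cv <- fit_calibration(x, y)
    # independent normal-equations oracle with textbook SE formulas
    n <- 8
    sxx <- sum((x - mean(x))^2)
    b <- sum((x - mean(x)) * (y - mean(y))) / sxx
    a <- mean(y) - b * mean(x)
    s2 <- sum((y - a - b * x)^2) / (n - 2)
    expect_equal(cv$slope, b, tolerance = 1e-10)
    expect_equal(cv$intercept, a, tolerance = 1e-10)
    expect_equal(cv$sd_slope, sqrt(s2 / sxx), tolerance = 1e-10)
    expect_equal(cv$sd_intercept, sqrt(s2 * (1 / n + mean(x)^2 / sxx)),
                 tolerance = 1e-10)
    expect_equal(cv$r^2, cor(x, y)^2, tolerance = 1e-12)
  }
})

test_that("degenerate designs are rejected", {
  expect_error(fit_calibration(c(1, 1, 1), c(1, 2, 3)), "equal")
  expect_error(fit_calibration(c(1, 2), c(1, 2)), "three")
  expect_error(fit_calibration(c(-1, 2, 3), c(1, 2, 3)), "non-negative")
})

test_that("identical curves summarize with zero spread", {
  curves <- replicate(6, fit_calibration(c(5, 10, 20, 40),
                                         0.003 * c(5, 10, 20, 40) + 0.01,
                                         analyte_id = "a", wavelength = 250),
                      simplify = FALSE)
  s <- summarize_curves(curves)
  expect_equal(s$sd_slope, 0)
  expect_equal(s$ci_slope, 0)
  expect_equal(s$rsd_slope_percent, 0)
  expect_equal(s$lod, 0)
  expect_equal(s$loq, 0)
})

test_that("across-curve statistics follow the z-based confidence formula", {
  set.seed(22)
  curves <- lapply(1:6, function(k) {
    x <- c(5, 10, 15, 20, 25, 30, 35, 40)
    fit_calibration(x, (0.0028 + 0.0001 * k) * x + 0.01 * k,
                    analyte_id = "a", wavelength = 250)
  })
  s <- summarize_curves(curves)
  sl <- vapply(curves, `[[`, numeric(1), "slope")
  ic <- vapply(curves, `[[`, numeric(1), "intercept")
  expect_equal(s$mean_slope, mean(sl))
  expect_equal(s$sd_slope, sd(sl))
  expect_equal(s$rsd_slope_percent, 100 * sd(sl) / mean(sl))
  expect_equal(s$ci_slope, 1.96 * sd(sl) / sqrt(6))
  expect_equal(s$ci_intercept, 1.96 * sd(ic) / sqrt(6))
  expect_equal(s$loq, 10 * sd(ic) / mean(sl))
  # Student-t option widens the interval
  st <- summarize_curves(curves, ci = "t")
  expect_gt(st$ci_slope, s$ci_slope)
})

test_that("published-style SD/CI pairs reproduce under the z formula", {
  # CI = 1.96 * SD / sqrt(6): 0.00081 -> 0.00065 at 5 decimals
  expect_equal(round(1.96 * 0.00081 / sqrt(6), 5), 0.00065)
  curves <- lapply(1:6, function(k)
    fit_calibration(c(1, 2, 3), 0.03598 * c(1, 2, 3) + 0.06,
                    analyte_id = "p", wavelength = 218))
  s <- summarize_curves(curves)
  expect_equal(s$n_curves, 6)
})

test_that("mixed analytes cannot be aggregated", {
  c1 <- fit_calibration(c(1, 2, 3), c(1, 2, 3), analyte_id = "a")
  c2 <- fit_calibration(c(1, 2, 3), c(1, 2, 3), analyte_id = "b")
  expect_error(summarize_curves(list(c1, c2)), "mix")
  expect_error(summarize_curves(list(c1)), "two curves")
})

test_that("LOD and LOQ follow the 3.3/10 sigma-over-slope rule", {
  ll <- lod_loq(0.00047, 0.00295)
  expect_equal(round(ll$loq, 2), 1.59)
  expect_equal(round(ll$lod, 2), 0.53)
  # direct evaluation for a second compound's sigma/slope pair
  ll2 <- lod_loq(0.0031, 0.03598)
  expect_equal(round(ll2$loq, 2), 0.86)
  expect_equal(round(ll2$lod, 2), 0.28)
  expect_equal(lod_loq(0, 1), list(lod = 0, loq = 0))
  expect_error(lod_loq(0.001, 0), "positive")
  expect_error(lod_loq(0.001, -2), "positive")
  # the ratio is 10/3.3 for every input
  set.seed(23)
  for (rep in 1:20) {
    s <- runif(1, 1e-4, 1); sig <- runif(1, 0, 0.1)
    ll <- lod_loq(sig, s)
    if (sig > 0) expect_equal(ll$loq / ll$lod, 10 / 3.3, tolerance = 1e-12)
  }
})

test_that("inverse regression recovers concentrations exactly", {
  conc <- c(5, 10, 20, 25, 40)
  resp <- 0.00295 * conc - 0.0024
  cv <- fit_calibration(conc, resp)
  expect_equal(as.numeric(predict_concentration(cv, resp)), conc,
               tolerance = 1e-10)
  expect_equal(as.numeric(predict_concentration(cv, 0.00295 * 25 - 0.0024)),
               25)
  expect_equal(as.numeric(suppressWarnings(
    predict_concentration(cv, cv$intercept))), 0, tolerance = 1e-12)
  # random-curve inversion against the algebraic oracle
  set.seed(24)
  for (rep in 1:10) {
    x <- runif(5, 1, 40); y <- runif(1, -1, 1) * x + rnorm(5)
    cvr <- fit_calibration(x, y)
    if (cvr$slope == 0) next
    r0 <- runif(1, min(y), max(y))
    expect_equal(as.numeric(suppressWarnings(
      predict_concentration(cvr, r0))),
      (r0 - cvr$intercept) / cvr$slope, tolerance = 1e-12)
  }
})

test_that("out-of-range predictions are flagged but reported", {
  cv <- fit_calibration(c(5, 10, 20), 0.003 * c(5, 10, 20))
  expect_warning(p <- predict_concentration(cv, 0.003 * 50), "outside")
  expect_equal(as.numeric(p), 50, tolerance = 1e-10)
  expect_true(attr(p, "out_of_range"))
})

test_that("calibration CSV reader builds replicate curves per analyte", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(analyte = rep("a", 6), curve = rep(1:2, each = 3),
                   conc_ug_per_ml = rep(c(1, 2, 3), 2),
                   response = rep(c(0.1, 0.2, 0.3), 2))
  write.csv(df, path, row.names = FALSE)
  out <- read_calibration_csv(path, wavelength = 250, order = 1)
  expect_equal(length(out$a), 2)
  expect_equal(out$a[[1]]$slope, 0.1)
})
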