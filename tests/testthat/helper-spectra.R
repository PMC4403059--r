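# shared builders for synthetic test spectra

default_test_grid <- function(step = 0.5) seq(200, 300, by = step)

gaussian_spectrum <- function(center = 250, sigma = 8, amp = 1,
                              grid = default_test_grid()) {
  new_spectrum(grid, amp * exp(-(grid - center)^2 / (2 * sigma^2)))
}

ramp_spectrum <- function(slope = 0.01, grid = default_test_grid()) {
  new_spectrum(grid, slope * grid)
}

random_spectrum <- function(grid = default_test_grid()) {
  new_spectrum(grid, as.numeric(stats::filter(rnorm(length(grid)),
                                              rep(1 / 5, 5),
                                              circular = TRUE)))
}

# derivative spectrum built directly from values (for crossing tests)
dspec_from_values <- function(wavelengths, values,
                              config = derivative_config(1, 2)) {
  config$delta_lambda_effective <- config$delta_lambda
  structure(list(wavelengths = wavelengths, values = values,
                 config = config, source_meta = list()),
            class = c("derivative_spectrum"))
}

# three-compound study conditions used across pipeline tests
study <- function() {
  list(models = default_compound_models(),
       designs = default_calibration_designs(),
       configs = default_channel_configs(),
       scheme = dilution_scheme(),
       truth = c(acetaminophen = 37.5, diphenhydramine = 1.875,
                 pseudoephedrine = 2.25),
       truth_mg = c(acetaminophen = 500, diphenhydramine = 25,
                    pseudoephedrine = 30))
}
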