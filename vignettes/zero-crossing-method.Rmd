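---
title: "Zero-crossing derivative spectrophotometry with derivspec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Zero-crossing derivative spectrophotometry with derivspec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(derivspec)
```

## The analytical problem

Fixed-dose common-cold tablets combine a dominant analgesic (acetaminophen,
hundreds of mg) with two minor components (an antihistamine and a
decongestant, tens of mg). All three absorb in the same 200-300 nm window,
so classical single-wavelength spectrophotometry cannot resolve them: at
assay dilutions the major component contributes most of the absorbance at
every usable wavelength.

Derivative spectrophotometry sharpens overlapped bands: differentiating an
absorbance spectrum $A(\lambda)$ $n$ times suppresses broad features
(amplitude scales as $\sigma^{-n}$ for a band of width $\sigma$) and turns
band maxima into zero crossings. The *zero-crossing technique* exploits
this: for each analyte one finds a wavelength where the derivative spectra
of **both** other components pass through zero. Because the Beer-Lambert
absorbances of non-interacting solutes add, and differentiation is linear,
the mixture's derivative at such a wavelength equals the analyte's own
derivative contribution:

$$
D_n^{mix}(\lambda^*) \;=\; \sum_i c_i\, D_n^{(i)}(\lambda^*)
\;=\; c_a\, D_n^{(a)}(\lambda^*) \quad\text{when } D_n^{(j)}(\lambda^*)=0
\ \forall j\neq a .
$$

A straight calibration of $D_n^{mix}(\lambda^*)$ against $c_a$ then
quantifies the analyte as if it were alone. `derivspec` implements this
workflow end to end: derivative computation, crossing location, working
wavelength selection, calibration and validation statistics, and
tablet-content back-calculation, plus a fully synthetic simulator so the
whole chain is testable without instrument data.

## Derivative operators and the meaning of delta-lambda

Instrument firmware rarely documents its derivative algorithm beyond a
"delta-lambda" setting. `derivative()` therefore offers two explicit
operators:

* **`finite_difference`** (the default of `derivative()`): the classic
  peak-to-peak difference
  $D_1(\lambda) = [A(\lambda + \Delta\lambda/2) - A(\lambda -
  \Delta\lambda/2)]/\Delta\lambda$, with $\Delta\lambda$ rounded to the
  nearest even number of grid steps (the effective value is recorded in
  the result's config); higher orders iterate the operator. This keeps
  zero crossings directly interpretable, but each pass consumes
  $\Delta\lambda/2$ of wavelength range on each side and, for
  $\Delta\lambda$ much wider than a band, the iterated "comb" reads
  absorbance tens of nm away from $\lambda$.
* **`savitzky_golay`**: local least-squares polynomial
  smoothing-differentiation. $\Delta\lambda$ is the **total filter
  window**; the window is the odd number of points closest to
  $\Delta\lambda/\text{step}$, a polynomial of degree `sg_polyorder` is
  fitted and its $n$-th derivative taken at the centre, scaled by
  $\text{step}^{-n}$.

The package's default assay channels use the orders and widths
(order 1, 28.0 nm), (order 2, 31.5 nm) and (order 4, 27.0 nm) with the
Savitzky-Golay operator (degree 5). The choice of operator here is forced
by arithmetic as much as by physics: over a 100 nm recorded range an
iterated peak-to-peak difference of 27 nm at order 4 would span 108 nm and
leave no usable wavelengths at all, and at order 2 the 63 nm comb couples
each measurement point to absorbance far outside the local band structure,
destroying the tail decay on which interference-free regions rely. A wide
*smoothing* window with local differentiation reproduces the qualitative
behaviour of scanning instruments (heavy smoothing at large delta-lambda,
preserved zero-crossing topology) while keeping the derivative local.

Edge handling is strict: wavelengths where the operator window leaves the
grid are dropped, never zero-padded - padding manufactures sign changes
and hence false zero crossings.

Both operators are linear in the spectrum to floating precision; the test
suite asserts this directly, because the zero-crossing method's
correctness *is* this linearity.

## Locating crossings and selecting working wavelengths

`find_zero_crossings()` reports every sign change between adjacent grid
points, locating the crossing by linear interpolation; runs of exact zeros
collapse to their midpoint. An `amplitude_floor` (a sensible value is 3x
the [propagated_noise_sd()] of the instrument noise) discards crossings
whose flanking amplitudes are both at noise level.

`select_working_wavelength()` makes the informal criterion "best linear
response, unaffected by the other components" operational:

1. **Candidate gate.** A wavelength qualifies when every interferent's
   derivative amplitude is at most 0.5% of the analyte's own amplitude
   *at that wavelength*. The gate is deliberately relative to the analyte
   signal: a bound relative to the interferent's maximum looks natural but
   admits wavelengths where a dominant co-formulated compound leaks tens
   of percent of a minor analyte's signal, which no practitioner would
   accept. An absolute tolerance can still be supplied.
2. **Score.** Among candidates the selector maximises
   $|D_n^{(a)}(\lambda)| \cdot r^2(\lambda)$, where $r$ is the Pearson
   correlation between the mixture derivative and the analyte
   concentration across a calibration stack. Ties break toward larger
   analyte amplitude, then lower wavelength.

`develop_method()` feeds the selector a stack that pools **all three**
calibration designs. Because each analyte appears as a varying interferent
in the other designs, any interference leakage decorrelates the response
from the analyte concentration and the $r^2$ term penalises it - even for
noiseless spectra, where a stack with fixed interferents would give
$r^2 = 1$ everywhere and the score would degenerate to amplitude greed.

## Calibration statistics

`fit_calibration()` is ordinary least squares (via `stats::lm`) of
derivative amplitude on concentration, reporting slope, intercept, their
standard errors and $r$. `summarize_curves()` aggregates replicate curves
(six in the default study design) into across-curve mean, SD, RSD% and a
confidence half-interval $z_{0.975}\,\mathrm{SD}/\sqrt{n}$ with
$z_{0.975} = 1.96$ (P = 0.05); Student's $t$ quantile is available via
`ci = "t"` for small-$n$ purists. Detection limits follow the ICH-style
intercept-dispersion convention,

$$\mathrm{LOD} = 3.3\,\sigma/s, \qquad \mathrm{LOQ} = 10\,\sigma/s,$$

with $\sigma$ the across-curve SD of the intercept and $s$ the mean
slope. Derivative responses can legitimately have negative slope
(amplitudes are signed); the summary uses $|s|$, while `lod_loq()` itself
enforces the positive-slope domain so that a sign error in user code
surfaces as an error rather than a negative detection limit.

## Validation statistics

* Precision/accuracy: CV% $= 100\,s/\bar{x}$ and relative error
  $= 100(\bar{x} - c_{nom})/c_{nom}$, sample SD with $n-1$ throughout;
  between-day statistics use the grand mean of all replicates.
* Standard-addition recovery: $100(\hat{c}_{spiked} -
  \hat{c}_{base})/c_{added}$, probing matrix/excipient interference.
* Method comparison: paired Student $t$ on content differences
  ($df = n-1$, two-sided) and the variance-ratio $F = s^2_{prop} /
  s^2_{ref}$ with the **fixed a-over-b convention** - the reference method
  is always the denominator, so $F$ may fall below 1; the critical value
  is the upper $\alpha$ quantile at $(n_a - 1, n_b - 1)$ df. The two
  methods are declared equivalent only if both statistics are inside
  their critical values.

## The simulator: what it emulates and what it does not

`default_compound_models()` loads synthetic Gaussian-band absorptivity
models (`extdata/synthetic_band_models.csv`) for a ternary system in
dilute acid:

* a dominant mid-UV absorber: strong band near 243 nm plus short-
  wavelength end absorption (peak absorptivity 0.066 AU mL ug^-1 cm^-1,
  so 20 ug/mL gives a ~1.3 AU band maximum);
* a minor compound with intense absorption near 221 nm and very weak
  benzenoid fine structure near 253/258 nm;
* a second minor compound with intense end absorption near 205 nm and
  weak benzenoid bands at 251/257/263 nm.

Band centres, widths and relative intensities were chosen once to
reproduce the qualitative features that make the real chemical system
amenable to zero-crossing work - in particular, the existence for every
analyte of a wavelength where both interferents' derivative amplitudes
are negligible against the analyte's. The exact band parameters are
synthetic; they are not fitted absorptivities, and the working
wavelengths they produce (printed by `develop_method()`) are properties
of the synthetic system, not of any real instrument's spectra.

Mixtures obey additive Beer-Lambert absorbance with i.i.d. Gaussian
absorbance noise, default SD 0.002 AU, homoscedastic across wavelength -
a reasonable desk model of a well-maintained double-beam instrument at
moderate absorbance. The simulator does **not** model stray light,
finite spectral bandwidth, heteroscedastic (absorbance-dependent) noise,
baseline drift, wavelength-registration error, or solute-solute
interactions. Consequently, passing simulation tests demonstrates the
correctness of the *algorithms* (derivative operators, selection logic,
calibration arithmetic, dilution back-calculation) under the stated noise
model; it does not certify performance on real instrument data, where
bandwidth and drift typically dominate the error budget.

The default calibration designs mirror the usual practice for this
formulation: each analyte's series (5-40, 0.25-4 and 0.5-5 ug/mL) with
the other two compounds fixed (25 and 1.5 ug/mL patterns). The abstract
linearity claim of up to 50 ug/mL for the major compound is noted, but
the package defaults to the 5-40 ug/mL series actually prepared; the
design object is data and can be edited freely.

## Numerical choices

* Simulation grid: 200-300 nm at 0.1 nm (1001 points); wavelengths are
  reported to 0.1 nm.
* Delta-lambda rounding: to the nearest even number of grid steps
  (finite difference) or nearest odd window (Savitzky-Golay); the
  effective width is recorded in the output config rather than silently
  interpolated.
* Crossing location: linear interpolation between the flanking points;
  exact-zero runs collapse to midpoints; edge runs are not crossings.
* Selection ties: larger analyte amplitude, then lower wavelength.
* Degenerate inputs fail loudly: an identically zero analyte derivative,
  zero concentration variance, non-positive slope in `lod_loq()`, and
  zero reference variance in the F test are all errors, not NA results.
* Zero-variance paired differences with a non-zero mean yield an
  infinite $t$ flagged `degenerate` instead of an error, since real
  rounded data can produce them.

## Problem sizes used by the test suite

The simulation-based checks run at desk scale, chosen to keep the full
suite fast while leaving the statistics well resolved: single noiseless
pipeline runs for exactness checks; 100 seeded replicates of the full
noisy study (six calibration curves per analyte, one unknown) for the
recovery envelope (mean absolute content error below 2% at 0.002 AU
noise; below 0.5% noiseless); 2000 replicates for the empirical type-I
error of the paired-t and F tests (each within binomial sampling error of
the nominal 5%); and 1000 replicates for the noise-SD calibration of the
mixture simulator.

## A worked example

```{r example, eval = FALSE}
models <- default_compound_models()
designs <- default_calibration_designs()
configs <- default_channel_configs()

# method development: one interference-free wavelength per analyte
wws <- develop_method(models, designs, configs)

# six-curve calibration with instrument noise
set.seed(1)
cals <- lapply(names(designs), function(id) {
  curves <- lapply(1:6, function(k)
    fit_calibration_from_spectra(
      generate_calibration_dataset(models, id, designs[[id]]$levels,
                                   designs[[id]]$fixed, noise_sd = 0.002),
      wws[[id]]))
  summarize_curves(curves)
})
names(cals) <- names(designs)

# assay a simulated tablet solution through the 1/4-tablet dilution train
scheme <- dilution_scheme(0.25, 100, 3, 100)
truth <- c(acetaminophen = 37.5, diphenhydramine = 1.875,
           pseudoephedrine = 2.25)
unk <- lapply(1:5, function(i)
  mixture_spectrum(models, truth, noise_sd = 0.002))
run_assay(cals, unk, wws, scheme,
          label_claims = c(acetaminophen = 500, diphenhydramine = 25,
                           pseudoephedrine = 30))
```

## Known limitations

* Single-wavelength resolution only: the deliberately excluded
  alternatives (multi-wavelength least squares, ratio-spectra derivative
  methods, PLS/PCR chemometrics) are better choices when no clean
  zero-crossing exists.
* The selection gate is evaluated on the simulation/measurement grid; a
  crossing falling between grid points is seen at the flanking points'
  amplitudes. At 0.1 nm this is harmless for bands wider than ~2 nm.
* The JCAMP-DX reader covers uncompressed AFFN `(X++(Y..Y))` tables
  only - enough for typical UV-Vis exports, not the compressed
  SQZ/DIF/DUP forms.
* Savitzky-Golay attenuation of very narrow bands grows with the
  window-to-bandwidth ratio; with the default 27-31.5 nm windows,
  features narrower than ~2 nm are strongly damped and should not carry
  the analytical signal.
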