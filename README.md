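# phbdeg

Quantifying the biodegradation of poly(3-hydroxybutyrate)/plasticizer
blends from well-plate image time series and ¹H NMR spectra.

## The problem

PHB (poly(3-hydroxybutyrate)) is a bacterial polyester whose brittleness
is tamed by blending it with BDF, a ferulic-acid-derived plasticizer
(0–40 w%). How fast fungi or alkali break the blend down depends on the
BDF fraction, and two cheap read-outs track it:

* **Image route.** Blend powder on agar shows up as bright grains that a
  fungus consumes while its whitish mycelium overgrows the well. Every
  frame of a well series is binarized with **one shared closed threshold
  interval** so white-pixel counts are comparable over time, and the
  remaining percentage is

  ```
  value(t) = 100 · WPt / WPt0
  ```

  with `WPt` the white-pixel count at time `t`. The half-degradation
  time **t50** — the first time the fitted curve crosses 50% — is
  estimated by significance-screened polynomial regression: degrees
  1..6 are fitted by OLS, a permutation-calibrated F-screen keeps the
  family type-I error at α, and among significant degrees the fit
  maximizing the *adjusted* R² wins (ties to the lowest degree). Fits
  are never extrapolated: a curve that never reaches 50% in the
  observation window is censored (`"> 336"`), not forced to a number.
  Replicate t50 values are compared across blends by one-way ANOVA and
  Tukey HSD (α = 0.05) with a compact letter display.

* **NMR route.** During alkaline degradation the polymer chain peak
  (5.20 ppm) shrinks while the free monomer peak (4.20 ppm) grows. Both
  are integrated by the trapezoidal rule over `center ± 0.15 ppm` after
  subtracting the endpoint chord, and the chemical degradation degree is
  `100 · monomer / (monomer + polymer)`.

A synthetic-data generator renders ground-truth-annotated well images
(shrinking grains, random-walk mycelium, illumination field, noise) and
two-Lorentzian spectra, so the whole chain is testable without
laboratory data.

## Worked example

Fit a single noisy replicate curve (true t50 = 120 h):

```r
library(phbdeg)
tr  <- logistic_trajectory(seq(0, 336, by = 24), t50 = 120)
cv  <- simulate_kinetic_curve(tr, noise_sd = 0.05, seed = 7)
fit <- t50_fit(cv)
fit
#> Polynomial degradation-kinetics fit: S1 (blend)
#>   degree 6 (of 6 candidates), R2 = 0.9988, adj R2 = 0.9979, F p = 3.06e-11
#>   t50 = 111.2 h (window 0..336 h)
```

The selected degree-6 polynomial explains 99.9% of the variance and
crosses 50% at 111.2 h — within 8% of the 120 h truth at 5% noise.
Quantify a spectrum simulated at degradation fraction 0.737:

```r
s <- simulate_spectrum(spectrum_params(degradation_fraction = 0.737))
degradation_degree(integrate_peak(s, default_regions()$monomer),
                   integrate_peak(s, default_regions()$polymer))
#> [1] 73.7  (percent)
```

Run the full synthetic study — four blends in triplicate, 15 frames per
well over 14 days — and compare blends:

```r
res <- run_pipeline("all", pipeline_config(out_dir = "study"))
res$comparison
#> t50 comparison across blends
#>   one-way ANOVA: F(3, 8) = 267.2, p = 2.34e-08
#>  blend mean_t50_h n letters
#>  BDF40     101.67 3       a
#>  BDF20     111.37 3       a
#>  BDF10     183.94 3       b
#>   BDF5     245.41 3       c
#>   blends sharing no letter differ at alpha = 0.05 (Tukey HSD)
```

Mean t50 falls monotonically as the plasticizer fraction rises; the two
high-BDF blends (~100–110 h) share a letter while 10 w% and 5 w% each
form their own group. All artifacts (manifest, kinetics CSV, threshold
and fit JSON with embedded configuration, ANOVA/Tukey/letters CSV, run
log) land in the output directory.

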