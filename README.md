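# burstfit

Tools for inferring how a promoter transcribes — in rare, large bursts or
in frequent, small steps — from nothing more than clonal flow-cytometry
fluorescence distributions. The package was built around the biology of
semi-randomly integrating reporters (an HIV-promoter/GFP cassette in
T cells is the motivating system): each integration clone has its own
fluorescence distribution, and the *shape* of that distribution encodes
the underlying transcriptional dynamics at that genomic position.

## The model

A two-state (telegraph) gene switches between a repressed and an active
configuration at rates κ<sub>a</sub> and κ<sub>r</sub>; the active state
transcribes at rate κ<sub>t</sub><sup>+</sup>, transcripts decay at
κ<sub>t</sub><sup>−</sup> (≡ 1, the unit of all rates), are translated at
κ<sub>p</sub><sup>+</sup>, and protein decays/dilutes at
κ<sub>p</sub><sup>−</sup>. The fitted quantities are the burst
coordinates:

- burst size **b** = κ<sub>t</sub><sup>+</sup>/κ<sub>r</sub> (transcripts
  per activation event),
- burst frequency **κ<sub>a</sub>** (activations per transcript lifetime),
- active duration **τ** = 1/κ<sub>r</sub>, of which the data resolve only
  an upper bound **τ<sub>Max</sub>**,
- active fraction **f** = κ<sub>a</sub>τ/(1 + κ<sub>a</sub>τ).

The pipeline: solve the chemical master equation of this model at steady
state on a graded coarse-grained grid; push the protein distribution
through the fluorescence calibration (γ = 2.5 RFU per mean transcript)
and an autofluorescence convolution; compare with gated, log-binned,
Fourier-smoothed event data via a masked squared-deviation statistic
Dev; calibrate Dev against a bootstrap bound Dev<sub>data</sub> from
resampled events; and profile Dev<sub>r</sub> = Dev/Dev<sub>data</sub>
over τ to get best-fit (b, κ<sub>a</sub>) with confidence ellipses and
τ<sub>Max</sub>. Cross-clone analyses regress distribution variance and
fitted burst parameters against the clone means to determine whether
burst size or burst frequency is the modulated quantity. A fully seeded
synthetic-data module generates clonal event tables (cell-size coupling,
scatter channels, autofluorescence) with known ground truth, so every
stage is testable without external data.

## Worked example

Simulate one integration clone with known truth (b = 15, κ<sub>a</sub> =
0.8, τ = 0.02), process it as a cytometry measurement, and fit it back:

```r
library(burstfit)

calib <- calibration()                      # gamma = 2.5, kappa_p_minus = 0.25
rates <- from_burst_coordinates(b = 15, kappa_a = 0.8, tau = 0.02)
clone <- simulate_clone(rates, calib, n_events = 10000, seed = 3)
af    <- autofluorescence_profile(generate_autofluorescence(seed = 11))

h <- process_events(clone$events)           # gate 60%, log-bin, smooth
h
#> RFU histogram: 256 log bins [0.1, 1e+03], mean 34.7 RFU, CV 0.47, smoothed (cutoff 16)

mm <- moment_match(hist_mean(h) - af$mean, hist_var(h) - af$var, calib)
c(b = mm$b, kappa_a = mm$kappa_a)           # analytic first guess
#>          b    kappa_a
#> 13.9765050  0.8502063

dev_data <- bootstrap_dev_bound(clone$events, n_boot = 200, seed = 4)
fit <- fit_at_tau(h, tau = 0.02, calib = calib, autofluor = af)
c(b = fit$b, kappa_a = fit$kappa_a)
#>          b    kappa_a
#> 14.5623597  0.8382901

ci <- confidence_intervals(h, fit$b, fit$kappa_a, 0.02, dev_data,
                           calib = calib, autofluor = af)
rbind(b = ci$b, kappa_a = ci$kappa_a)
#>               [,1]      [,2]
#> b       13.2803774 15.968094
#> kappa_a  0.7672615  0.915894
```

The moment-based first guess lands within ~7% of the generating values;
the systematic fit tightens burst size to ~3%, and the 95% interval
(maximum simultaneous parameter variation that raises Dev<sub>r</sub> by
1) covers the truth on both axes.
`profile_tau()` adds the Dev<sub>r</sub>(τ) profile and τ<sub>Max</sub>;
`trend_report()` aggregates many clones into the variance-mean power law,
burst-parameter regressions, and burst-size/frequency correlation; and
`mode_prediction()` turns fits into testable active-fraction patterns for
the two candidate modes of burst-size control.

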