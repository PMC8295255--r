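# neurotimescales

Estimating how long neural representations of dynamic visual stimuli
persist, and how that persistence changes along a visual cortical
hierarchy.

When a movie is shown repeatedly while spiking activity is recorded across
visual areas (e.g., rat V1 → LM → LI → LL, or mouse LGN → V1 → higher
areas), three characteristic timescales can be extracted from the data, all
with the same estimator — the average Pearson correlation `C(Δ)` between
paired observations separated by a temporal lag `Δ`, fitted with a decaying
exponential `a·e^(−t/τ)` or a damped oscillation `a·e^(−t/τ)·cos(ωt+φ)+b`
selected by an extra sum-of-squares F-test; the envelope decay constant `τ`
is the timescale:

* the **stimulus timescale** (correlation over pixels between movie
  frames),
* the **response timescale** (correlation over units between trial-averaged
  population vectors at 33-ms bins),
* the **intrinsic timescale** (correlation over trials of single-unit spike
  counts, averaged over units) — stimulus-independent, within-trial firing
  persistence.

A cross-temporal decoding analysis complements them: a linear SVM trained to
discriminate population activity at two times is tested at lagged times on
held-out trials (decoding timescale) and on the training trials themselves;
the gain `Δp = p_train − p_test` at a one-bin lag isolates the contribution
of intrinsic correlations to representation stability. A regression layer
(common-slope OLS with area intercepts, robust Theil–Sen with stratified
percentile bootstrap, hierarchy-score regressions) and a locomotion-state
(rest/run) partition analysis complete the pipeline. A synthetic-data
generator (AR(1) movies, Fourier phase-scrambled and white-noise stimuli,
doubly stochastic Poisson spike populations, wheel-velocity traces) provides
ground truth for every stage, so the whole pipeline is testable without any
data download.

## Worked example

```r
library(neurotimescales)

# a synthetic movie that decorrelates with tau = 0.3 s
mov <- gen_ar_movie(600, 30, 60, 60, target_timescale_s = 0.3, seed = 1)
estimate_timescale(pixel_correlation(mov, max_lag_s = 2), family = "stimulus")
#> <timescale_fit: dosc> tau = 0.3633 s, rmse = 0.004318 (n = 60)
#>       a     tau       w     phi
#> 2.00000 0.36329 0.29058 1.05404

# a synthetic area with a planted 120-ms intrinsic timescale
spec <- population_spec("LM", n_units = 100, n_trials = 30, mean_rate = 15,
                        intrinsic_timescale_s = 0.12,
                        intrinsic_amplitude = 1.5, seed = 2)
bc <- gen_population(spec, n_bins = 600, bin_width_s = 0.033)
estimate_timescale(intrinsic_correlation(bc, 2), family = "intrinsic")
#> <timescale_fit: exp> tau = 0.1127 s, rmse = 0.0009055 (n = 61)
#>       a     tau
#> 0.33838 0.11267
```

The first fit reads: the pixel-correlation function of this particular 20-s
movie was best described (by the F-test) by a slowly modulated envelope with
`τ ≈ 0.36` s — a single 600-frame movie estimates its generating `τ = 0.3` s
with roughly this much sampling scatter, which is why the recovery analyses
below report medians over seeds. The second fit recovers the planted
intrinsic timescale (120 ms) from across-trial spike-count correlations to
within a few percent (estimates are slightly biased low by rate
rectification and Poisson noise).

`run_synthetic_benchmark(seed = 1)` chains the stages end to end on a
planted four-area hierarchy and reports recovered versus true values.

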