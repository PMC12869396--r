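# noisyplume

Bayesian localization of a turbulent odor source from one instantaneous
snapshot of binary detections by a multisensor agent — and the
counterintuitive role of noise in it.

An agent carries `N` threshold chemosensors scattered uniformly in a disc
of radius `R` inside a plume. Each sensor reports `m = 1` when the local
concentration exceeds its sensitivity `c0`. Armed with a statistical model
of the plume — the detection probability `ℓ(φ)` at position `φ` relative
to the source — the agent computes the maximum-a-posteriori (MAP) estimate
of its own position by maximizing

    Σᵢ [ mᵢ log ℓ(ξ + δᵢ) + (1 − mᵢ) log(1 − ℓ(ξ + δᵢ)) ]

over a uniform prior rectangle, where `δᵢ` are the *perceived* sensor
offsets. For an anisotropic (conical) plume,

    ℓ(φ) = min(1, (φx/λ)^(−δ) · exp(−φy²/β²φx²)),
    λ = 96.86 Δx, δ = 1.54, β = 0.08,

blurring the perceived offsets with noise of magnitude `η` does **not**
necessarily degrade the estimate: the noise inflates the perceived agent
size to `σ ≈ R + η`, and a group of sensors asymptotically behaves like a
*pair of detections* at `(x, ±σ)` whose estimate is `x̂ = σ·sqrt(2/δ)/β`.
An optimal perceived size exists, bounded by the optimal pair distance
`a*(x) = x·β·sqrt(δ/2)`, and hence an optimal noise `η* ≈ a* − R` that
grows with distance from the source. The package implements this whole
story: plume models and their fitting, a Gaussian-copula generator of
independent or spatiotemporally correlated binary snapshots (the
turbulence surrogate), grid MAP inference under four noise mechanisms
(proprioceptive, positional, binary flip, raw-signal) with error-corrected
variants, the detection-pair and infinite-sensor theory, empirical noise
tuning from the observed detection fraction, and a seeded scenario runner
with MSE/bias metrics, regional aggregation and condition comparison.

## Worked example

Scan the proprioceptive noise level at two distances inside a correlated
surrogate plume (N = 500 sensors, R = 25, 40 realizations per level,
common random numbers across levels):

```r
library(noisyplume)

p <- plume_params()                  # lambda = 96.86, delta = 1.54, beta = 0.08
f <- parametric_field(p, x_hi = 12 * p$lambda, y_half = 300, dx = 10, dy = 12)
truth <- data.frame(loc_id = 1:2, x = c(400, 900), y = 0)
cfg <- scenario_config(f, truth, N = 500, R = 25, Nr = 40, master_seed = 1)
scan <- optimal_noise_scan(cfg, c(0, 25, 50, 100, 150, 200))
scan$optimum[, c("x", "eta_star", "sigma_star", "mse_star", "mse_zero", "a_star")]
#>     x eta_star sigma_star mse_star  mse_zero   a_star
#> 1 400       25         50 37404.59  41284.16 28.07989
#> 2 900      100        125 20971.27 382898.24 63.17974
```

Close to the source (x = 400) noise barely matters; at x = 900 tuning the
noise to `η* = 100` cuts the mean squared error in x by a factor of ~18
relative to perfect proprioception (`mse_zero`), and the optimal
perceived size `σ* = R + η*` tracks the optimal detection-pair distance
`a*`. The practical rule that needs no knowledge of the true distance —
invert the centerline likelihood at the observed detection fraction,
then set `η̂ = max(0, a*(x_guess) − R)`:

```r
empirical_noise(0.05, p, R = 25)
#> [1] 22.56686
```

The methods vignette (`vignettes/noise-tuned-plume-inference.Rmd`)
documents the plume model, the copula surrogate and its correlation
defaults, the four noise mechanisms and corrections, the asymptotic
theory, and every numerical choice.

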