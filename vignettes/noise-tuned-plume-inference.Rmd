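---
title: "Noise-tuned Bayesian source localization in turbulent odor plumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Noise-tuned Bayesian source localization in turbulent odor plumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noisyplume)
```

## The problem

An agent carrying $N$ chemical sensors scattered uniformly in a disc of
radius $R$ sits inside a turbulent odor plume and must infer, from one
instantaneous snapshot of binary detections, where the odor source is.
Each sensor thresholds the local concentration at a sensitivity $c_0$
(`binarize()`), and the agent owns a statistical model of the plume: the
time-averaged probability $\ell(\phi)$ of detecting odor at position
$\phi$ relative to the source.  The maximum-a-posteriori (MAP) estimate
maximizes

$$\sum_{i=1}^N \big[ m_i \ln \ell(\xi + \delta_i)
  + (1 - m_i)\ln(1 - \ell(\xi + \delta_i)) \big]$$

over candidate source-relative center positions $\xi$ inside a uniform
prior rectangle, where $m_i$ are the detections and $\delta_i$ the
*perceived* sensor offsets.  The scientific question the package is built
around: does blurring the perceived offsets (proprioceptive noise of
magnitude $\eta$) degrade the estimate?  In an anisotropic (conical)
plume the answer is no — an optimal $\eta^*(x) > 0$ exists far from the
source — while in an isotropic plume noise never helps.

## The plume model

The anisotropic detection-probability field is the canonical power-law
cone (`conical_likelihood()`):

$$\ell(\phi) = \min\!\Big(1,\;
  (\phi_x/\lambda)^{-\delta} e^{-\phi_y^2 / \beta^2 \phi_x^2}\Big),$$

with defaults $\lambda = 96.86$, $\delta = 1.54$, $\beta = 0.08$ (all
lengths in grid spacings $\Delta x$), the values obtained by fitting this
form to a turbulent channel-flow simulation.  Positions upwind of the
source have probability zero; the value is clamped to $[0,1]$ and the
default prior starts at $x = \lambda$, where the centerline saturates.
The isotropic control (`isotropic_likelihood()`) keeps the same
centerline decay, $\min(1, (r/\lambda)^{-\delta})$, so geometry is the
*only* difference between the two models.

Two pieces of closed-form geometry drive the theory:

* the iso-probability contour at level $L$ has half-width
  $c(\phi_x) = \beta\phi_x\sqrt{-\delta\ln(\phi_x/\lambda) - \ln L}$
  with a single peak at $\phi_x = \lambda L^{-1/\delta} e^{-1/2}$
  (`contour_at_level()`);
* a pair of detections perceived at $(x, \pm a)$ pins the MAP at
  $\hat x_a = a \sqrt{2/\delta}/\beta$, so the perceived half-distance
  $a$ is a knob for the estimate, exact when
  $a^*(x) = x\beta\sqrt{\delta/2}$ (`pair_estimate()`,
  `optimal_pair_distance()`).

## The synthetic-data generator

In the reference setting this surrogate stands in for, odor snapshots
come from direct numerical simulations of turbulence.  The package
instead generates binary snapshots from a
thresholded latent Gaussian field (`sample_correlated()`): a zero-mean,
unit-variance field $g(\phi, t)$ with squared-exponential spatial
covariance (correlation length $l$) and AR(1) temporal correlation
(correlation time $\tau_c$, in snapshot intervals) is compared with the
local standard-normal quantile $z(\phi) = \Phi^{-1}(1 - \ell(\phi))$.
This Gaussian-copula construction has two properties that make it the
right surrogate here: every node's long-run detection frequency equals
$\ell(\phi)$ *exactly*, for any correlation settings, and the
correlation structure is a single tunable knob.  `corr_length = 0`
recovers independent Bernoulli sampling (`sample_bernoulli()`).  On full
grids the separability of the squared-exponential kernel lets us sample
via the two one-dimensional Cholesky factors; at arbitrary sensor
positions the full pairwise kernel is factored.

A positive raw-concentration proxy (`raw_from_latent()`) is defined as
$c = c_0 e^{s(g - z(\phi))}$, so $c \ge c_0$ exactly when the binary
value is 1.  The log-scale $s$ sets the dynamic range near the
threshold; the experiment default $s = 0.1$ keeps an appreciable
fraction of readings hovering near $c_0$, as in intermittent odor
signals where a fixed additive noise of order $10^{-2} c_0$ visibly
perturbs threshold crossings.  With $s = 1$ the proxy spans orders of
magnitude and the fixed raw-noise condition would be inert by
construction, leaving that mechanism nothing to act through.

**Correlation defaults.**  The surrogate's correlation length is set to
$R/2$ (12.5 $\Delta x$ for the standard $R = 25$ agent) and the
correlation time to 5 snapshot intervals.  A correlation length *equal*
to the agent radius was considered and rejected: it makes the whole
sensor disc read a single coherent patch, so the detection count jumps
between $\approx 0$ and $\approx N$.  Two features turbulent
detection data are expected to show rule that out — accuracy improves as $R$ grows from 10 to
40 (possible only if the odor correlation length is below the agent
scale), and the detection-count histograms are fat-tailed but graded,
not bimodal.  At $l = R/2$ the surrogate reproduces both (the count
distribution over snapshots has positive excess kurtosis relative to the
matching binomial), which is what the "correlations corrupt the
detection fraction" mechanism requires.  What the surrogate does *not*
emulate: turbulent spectra, sweeping of coherent structures by a mean
flow, concentration statistics beyond the marginal detection
probability, and any Reynolds-number dependence.  Passing tests
therefore support the inference machinery and the noise-benefit
mechanism, not fluid-dynamical fidelity.

## Inference and the four noise mechanisms

`map_estimate()` maximizes the log-posterior over the field lattice
restricted to the prior.  Numerical choices:

* probabilities are clamped to $[p_{\text{floor}}, 1-p_{\text{floor}}]$
  with $p_{\text{floor}} = 10^{-6}$ before logs (the model does not say
  how cells with $\ell \in \{0, 1\}$ should be handled);
* each sensor reads the lattice node nearest to
  $\xi + \delta_i$ — binary fields cannot be meaningfully
  interpolated — and positions beyond the grid edge clamp to it;
* ties break deterministically toward the smallest $\hat x$, then the
  smallest $\hat y$, so runs are bit-reproducible;
* the hot loop (candidates × sensors) is compiled (Rcpp); because
  candidates sit on the lattice, the nearest-node lookup reduces to one
  integer shift per sensor.

One consequence of the clamped cone worth knowing: in the off-cone
"dead zone" (large $|\phi_y|$ at small $\phi_x$) all clamped
probabilities tie at the floor, so an all-zero observation over a full
2-D prior resolves, via the deterministic tie-break, to the smallest
$(x, y)$ corner.  On a centerline prior, where the likelihood decays
monotonically, the all-zero estimate collapses to the far edge, the
far-field behavior the asymptotic theory assumes.

The four noise mechanisms (`noise_spec()`, `apply_noise()`):

1. **proprioceptive** — detections read at the true positions, perceived
   offsets blurred by truncated-Gaussian noise
   $\gamma \sim N_T(0, \eta^2)$, truncated at $\pm(\eta + 1)$: noise in
   processing only, which inflates the perceived agent size to
   $\sigma(\eta) \approx R + \eta$ (`perceived_size()`);
2. **positional** — sensors *sample* at blurred positions while the
   estimator keeps the nominal offsets;
3. **flip** — each binary detection flipped with probability $\eta$;
4. **raw** — Gaussian noise of SD $\eta$ added to the raw concentration
   before thresholding.

Error-corrected variants (`corrected_log_tables()`) fold a known noise
level $\eta_0$ into the per-sensor model: the flip correction
$\ell' = \eta_0 + (1 - 2\eta_0)\ell$ is exact; the positional/
proprioceptive correction replaces $\ell$ by its truncated-Gaussian
blur (separable discrete convolution); the raw correction uses a
two-point proxy (background 0, burst $2c_0$) and is flagged as an
approximation — the binary marginal simply does not carry the raw
distribution.

## Asymptotic theory and noise tuning

For infinitely many independent sensors the detection fraction $\theta$
approaches $\ell(x, 0)$ and the estimate is governed by two numbers:
$\theta$ and the perceived size $\sigma$.  `asymptotic_map()` maximizes
the *lateral* Gaussian-smeared expected log-likelihood

$$F(\xi_x) = \mathbb{E}_{v\sim N(0,1)}\big[\theta \ln\ell(\xi_x, \sigma v)
 + (1-\theta)\ln(1 - \ell(\xi_x, \sigma v))\big]$$

on a centerline candidate grid, with Gauss–Hermite quadrature (order 32).
The smear is applied to the lateral coordinate only: this is the
one-dimensional centerline reduction in which the perceived spread
interacts with the cone geometry.  A longitudinal smear component would
merely relabel the candidate coordinate — and, near the source, lets the
narrow-cone dead zone spuriously absorb zero-detection estimates.  The
reduction has the two limits that matter exactly: at $\sigma = 0$ the
estimate inverts the centerline decay,
$\hat x = \lambda\theta^{-1/\delta}$ (`invert_centerline()`), and at
large $\sigma$ it collapses onto $\hat x = \sigma\sqrt{2/\delta}/\beta$
independent of $\theta$ — the detection-pair geometry with
$a = \sigma$.  $\theta = 0$ is prior-dominated and returns the far edge.

With finite $N$, $\hat\theta$ is a binomial perturbation of
$\ell(x, 0)$ and `finite_n_optimal_sigma()` bootstraps it to find the
perceived size $\sigma^*$ minimizing the mean squared error.  Two
regimes emerge, and both are tested:

* $\sigma^* \in (0, a^*(x)]$ at $N = 10$, growing with distance — the
  perceived size acts as the detection-pair distance, bounded by the
  optimum $a^*$;
* as $N$ grows the *absolute* advantage of noise vanishes ($\propto
  1/N$) and in the information-rich near field ($\ell \gtrsim 0.3$) the
  argmin itself hits zero.  Far from the source a *relative* variance
  benefit persists at any finite $N$: near the $\sigma$ where the
  $\theta$-independent collapse branch crosses the truth, the
  sensitivity $d\hat x/d\hat\theta$ shrinks, clipping the
  over-detection fluctuations.  This is a property of the estimator
  geometry itself (any estimator behaving like
  $\max(\text{inversion}, \text{collapse})$ shows it), so we treat
  "noise provides no advantage as $N \to \infty$" as a statement about
  the limit, not about the argmin at any finite $N$.

`empirical_noise()` implements the practical tuning rule that needs no
knowledge of the true distance: invert the centerline likelihood at the
observed detection fraction to get a distance guess, then set
$\hat\eta = \max(0, a^*(x_{\hat\theta}) - R)$.

## Experiment design

`run_scenario()` drives the full pipeline.  Reproducibility and fair
comparisons rest on a documented seed scheme: a sub-seed per (location,
realization) is derived from the master seed by a small modular hash
that deliberately ignores the noise level and mechanism, and every base
random draw (sensor placement, latent field, flip uniforms, raw-noise
normals, truncated-normal uniforms) happens once per realization in a
fixed order.  Noise levels are then applied through inverse-CDF
transforms of those shared draws, so an $\eta$ scan
(`optimal_noise_scan()`) and a mechanism comparison use common random
numbers.  Identical configuration and master seed give bit-identical
record tables.

The realization-exclusion rule (fewer than 2 detections) is applied in
the anisotropic tuning experiments, where it belongs to the tuning
protocol; it is *not* applied in the isotropic controls, where it is not
part of the protocol and where conditioning on rare over-detection
bursts would itself fabricate a spurious noise benefit (the kept
realizations all under-estimate, and any large perceived size partially
corrects them).

**Problem sizes.**  The packaged experiment defaults are desk-scale
choices: a $9\times3$ grid of test locations spanning $x/L \in
[0.1, 0.95]$, $N_r$ = 50–100 realizations, an $\eta$ grid of 8 values
from 0 to $10R$, and a lattice of $10 \times 12\,\Delta x$ cells.  The
regional-contrast experiments run on a domain of length $L = 12\lambda$:
the close/mid/far thirds then span detection probabilities from
$\approx 0.75$ down to $\approx 0.02$, the information gradient the
regional story is about.  On a $30\lambda$ domain (the field
constructor's default extent) even the closest test column sits at
$\ell \le 0.19$ and the far third at $\ell < 0.01$, where nearly every
snapshot fails the 2-detection rule — all regions are then far-field and
the close-region contrast cannot be probed.  One further caveat follows
from the thin near-field cone: at the closest columns the plume
half-width ($\beta x \approx 9$–$29$) is below the off-centerline test
rows ($|y| = 50$), so those locations are dilute despite being close,
and noise helps there just as it does far away.  The near-field
no-benefit property is therefore a statement about *information-rich*
locations (detection probability at the agent of order 0.15 or more),
which is how the package's checks evaluate it.

**Isotropic controls** restrict the prior to a lateral band
($|y| \le 150$): a radially symmetric likelihood cannot identify
direction, and on an analytic field the resulting exact posterior ties
along circles of constant radius would otherwise be resolved by the
deterministic tie-break into a systematic negative $x$-bias at
$\eta = 0$ that masquerades as a noise benefit.  The band isolates the
question the control is for — geometry, not correlations.  Even so, a
small residual improvement (a few percent of the error at the largest
levels) survives in the controls: the radial decay's curvature and the
prior clamp act weakly like the geometric mechanism, and paired
common-random-number comparisons are powerful enough to resolve it.  The
control claim is therefore quantitative — the isotropic benefit fraction
stays below one tenth of the noiseless error, versus more than one half
(often a factor 10–100) in the anisotropic far field.

## Parameter recovery

`fit_conical()` recovers $(\lambda, \delta, \beta)$ from an empirical
frequency field in two stages: the pilot stage is the transparent
protocol (log-log regression of the centerline decay; pooled
per-column regression of $\ln\ell$ against $y^2/x^2$ for the width),
and a refinement stage minimizes the binomial-variance-weighted squared
error on the probability scale, with both the fit region
($\ell \in (0.01, 0.99)$) and the weights taken from the *pilot model*
rather than the noisy frequencies.  The exogenous region and weights
matter: weighting or truncating on the observed frequencies correlates
weights with residuals and flattens the decay by several percent at 200
snapshots, while the refined estimator recovers all three parameters to
within about 2%.

```{r fit-example}
params <- plume_params()
x <- seq(1.2 * params$lambda, 6 * params$lambda, length.out = 60)
y <- seq(-90, 90, length.out = 40)
pts <- cbind(rep(x, times = length(y)), rep(y, each = length(x)))
gen <- likelihood_field(x, y,
                        matrix(conical_likelihood(params, pts), nrow = length(x)),
                        params = params)
emp <- empirical_likelihood(sample_bernoulli(gen, 200, seed = 1))
fit_conical(emp)
```

## Known limitations

* The surrogate's correlations are stationary and isotropic in space;
  real plume correlations are swept by the mean flow and scale with the
  local plume width.
* The raw-concentration proxy is a one-parameter caricature of
  intermittent concentration statistics; the raw-noise mechanism and its
  correction inherit that.
* The error corrections for positional and raw noise are pragmatic
  constructions; their qualitative behavior, not their exact form, is
  the tested surface.
* MAP estimates live on the field lattice, so every error quantile is
  resolved only to one grid cell.
* The asymptotic module is strictly one-dimensional along the
  centerline; no 2-D asymptotics are attempted.
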