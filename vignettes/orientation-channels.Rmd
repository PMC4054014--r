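---
title: "Simulating orientation summation: noise-in-noise detection, ideal observers, and power-spectrum classification images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating orientation summation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(oriband)
```

## The scientific question

How does the visual system combine information across orientation when
detecting a broadband pattern? The classic multiple-channels model of early
vision assumes mechanisms with *fixed* orientation bandwidths; an alternative
holds that the detecting mechanism *adjusts* its bandwidth to match the
stimulus. The two hypotheses are hard to separate with thresholds alone,
because an ideal observer predicts the same threshold-versus-bandwidth law in
both cases. `oriband` implements the full simulation-and-analysis pipeline
used to separate them with noise targets detected in noise masks:

1. **Stimuli.** Targets are samples of two-dimensional Gaussian noise passed
   through an ideal (hard-edged) spatial-frequency and orientation filter —
   center frequency 5 cy/deg, 1- or 2-octave frequency bandwidth, two-sided
   orientation bandwidths from 2 to 180 degrees about horizontal — embedded in
   a fresh white Gaussian noise mask of contrast variance 0.32 on every
   interval of every trial. The signal is windowed by a circular Gaussian
   contrast envelope (SD 1.08 deg).
2. **Task.** Two-interval forced choice: one interval contains mask alone,
   the other mask plus signal. Contrast is driven by four interleaved
   transformed up-down staircases (two 2-down/1-up, two 4-down/1-up; 75
   trials each), and the 75%-correct RMS-contrast threshold is read from a
   maximum-likelihood cumulative-normal fit on log contrast.
3. **Threshold analysis.** Log threshold is regressed on the log number of
   independent Fourier components in the stimulus. The ideal observer obeys
   the quarter-root law (exponent 1/4); absolute efficiency is the squared
   ratio of ideal to observer thresholds for identical stimuli.
4. **Channel estimation.** At a fixed near-threshold contrast, the power
   spectra of the two intervals' masks are differenced trial by trial, binned
   by signal interval and correctness, and combined into a power-spectrum
   classification image — an estimate of the linear template the observer
   applies to stimulus power. Collapsed over spatial frequency into a
   1-degree-resolution orientation profile, the template is summarized by a
   constrained difference-of-Gaussians (DoG) fit whose bandwidth parameters
   can be compared across stimulus bandwidths.

Because no human data ship with the package, *synthetic observers* stand in
for participants: the ideal observer (uniform weights on the stimulus band)
and DoG-template proxies whose tuning either scales with the stimulus
(adjustable channels) or stays fixed. The pipeline's job is to recover, from
simulated trials alone, whatever channel structure the generating observer
actually had.

## The observer model

Every simulated observer is a linear template on the power spectrum. For
interval $j$ with power spectrum $P_j$, the decision variable is

$$ v_j = \sum_k w_k \, P_j(k) + \varepsilon_j, \qquad
   \varepsilon_j \sim \mathcal N(0, \sigma_{\mathrm{int}}^2), $$

with the sum counting each conjugate pair once, and the observer chooses the
interval with the larger $v$ (ties to interval 1, so the zero-noise rule is
deterministic). The ideal observer for detecting Gaussian noise with a flat
in-band spectrum in white Gaussian noise is monotone in in-band energy, so
its template is the band indicator. DoG proxies use

$$ w(\theta) = 2A_i e^{-d(\theta)^2/2\sigma_e^2} - A_i e^{-d(\theta)^2/2\sigma_i^2}, $$

with $d(\theta)$ the 180-degree-wrapped distance to the channel center,
extruded over the stimulus spatial-frequency annulus. The 2:1 amplitude
ratio and the ordering $\sigma_e < \sigma_i$ are the standard constraints on
orientation-channel models and are built into `dog_params()`.

Two closed forms anchor the Monte-Carlo machinery. Writing $m$ for the mask
contrast variance, $N$ for the number of in-band components, and
$s = n^2 c^2 / 2N$ for the per-component signal power at contrast $c$ on an
$n \times n$ grid, each half-plane component's power is exponential with mean
$m$ ($m + s$ in the signal band of the signal interval), so

$$ P_c = \Phi\!\left( \frac{s \sum_{b} w}
   {\sqrt{\sum_k w_k^2\left[(m+s_k)^2 + m^2\right] + 2\sigma_{\mathrm{int}}^2}} \right). $$

`analytic_proportion_correct()` and `analytic_threshold()` implement this
(exact for unenveloped stimuli under expected-value rescaling; a close
approximation otherwise — the Monte-Carlo check in the test suite agrees to
within binomial error). Because the decision variable is linear in *power*,
sensitivity grows as $c^2$, and absolute efficiency reduces in the
small-signal limit to a cosine similarity between template and band:

$$ \eta = \frac{\sum_{b} w}{\sqrt{N \sum_k w_k^2}}. $$

Note the absence of a square: squaring this expression would give the
matched-filter efficiency of an *amplitude*-domain template, which does not
apply here. `template_efficiency()` implements the cosine form, and the
Monte-Carlo measurement in the acceptance suite confirms it (measured 0.67
vs predicted 0.67 for a $\sigma_e=25,\ \sigma_i=75$ proxy in the 48-degree
condition; the squared form would predict 0.45).

## Numerical and design choices

**Grids.** The frequency plane uses the DFT layout with orientation defined
as the grating orientation (0 deg = horizontal grating = frequency vector
along the vertical axis; a 90-degree rotation relative to the geometric
angle, applied once in `fourier_grid()`). Band edges are closed (a bin
exactly on an edge is included); DC and the Nyquist row/column are excluded
from all masks — DC has no orientation and Nyquist bins have no conjugate
partner. Component counts are conjugate pairs counted once.

**Patch geometry.** Package defaults are the full-scale stimulus (512 px at
94.8 px/deg). Simulations in the tests and the acceptance script run at
128 px with the same physical band, choosing px/deg per analysis: 20 px/deg
for threshold-versus-bandwidth sweeps, which puts more than 200 components in
the narrowest fitted band so that the quarter-root law's small-signal
asymptotic regime applies (at threshold the per-component signal-to-mask
ratio adds a constant term to $c^2 \propto \sqrt N$, flattening the fitted
exponent when $N$ is small); and 32 px/deg for classification imaging, so the
64-bin crop retains DC-8 cy/deg and covers the whole 3.5-7.1 cy/deg signal
annulus. Even so, two small biases remain and are visible in the recovered
exponent (typically 0.235-0.245 rather than 0.250): the contrast envelope
blurs the hard band edges and leaks a few percent of signal energy outside
the band — proportionally more for narrow orientation bands — and the
finite-signal correction above. Both are properties of the simulated
stimuli, not estimator bugs.

**Contrast convention.** Threshold contrast is the RMS contrast of the
filtered noise *before* the envelope is applied; the envelope then modulates
contrast on the "screen". The mask is not enveloped. Both choices are
configurable in `noise_condition()`.

**Mask synthesis.** Sessions synthesize mask spectra directly in the
frequency domain (independent Hermitian complex-Gaussian coefficients),
which is distributionally identical to transforming a pixel-domain white
field — the test suite verifies Hermitian symmetry, realness of the inverse
transform, and per-bin statistics — and lets classification-image replay
skip the transforms entirely. Per-trial seeds for both masks and the signal
are stored in the trial log, so any session replays bit-identically.

**Staircases.** The 71% track is 2-down/1-up and the 84% track 4-down/1-up
(asymptotes 70.7% and 84.1%). Steps are 0.1 log10 units until the second
reversal, 0.05 after; the 71% staircases start at four times the closed-form
threshold estimate (clearly visible), the 84% staircases 0.3 log units
lower. The psychometric fit pools all staircases, anchors the lower
asymptote at 0.5, and fixes the lapse rate at 0 (both configurable); with
that anchoring the 75% point is $10^\mu$. Trials are aggregated into
binomial counts per contrast level before fitting, which keeps the
999-replicate bootstrap of the power-law exponent inexpensive.

**Power-law weights.** The "weighted maximum-likelihood" fit is realized as weighted
least squares on log thresholds with inverse-variance weights from the
psychometric fits' delta-method SEs. The narrowest bandwidth is excluded by
default (critical-band flattening is out of scope). The white-noise control
condition can be simulated (`noise_condition(grid, NULL)`) and is excluded
from fits; for a fixed band-limited template its threshold sits above the
band-condition power-law prediction, reproducing the breakdown of the
quarter-root law for unfiltered noise. A DoG proxy with the 2:1 ratio
cannot detect white noise at all — its total weight $\propto 2\sigma_e -
\sigma_i$ is negative, so added broadband power drives the decision the
wrong way — which is why the breakdown demonstration uses the band-energy
fixed template.

**Classification images.** The difference spectrum is signal-interval minus
non-signal-interval, computed from mask-alone spectra by default (the
alternative including the signal is available via `spectra = "stimulus"`).
Bin averages use bin-specific trial counts; the correct-bin and
incorrect-bin averages are each averaged before differencing; the image is
normalized to peak magnitude 1 with the sign fixed positive over the signal
band. Power spectra of real images are exactly conjugate-symmetric, so the
two half-planes agree by construction and the orientation collapse uses one
half-plane. Smoothing is a separable 5x5 triangular kernel ((1,2,3,2,1)/9
per axis) with reflected edges so crop borders are not darkened. In the
channel analysis (`channel_experiment()`) the kernel is applied to each
trial's cropped difference spectrum before accumulation — every later step
is linear, so this equals smoothing the finished image while keeping the
stored per-trial profiles, and hence all bootstraps, exactly consistent.
At the signal annulus radius the kernel blurs orientation by 2-3 degrees,
inflating fitted channel SDs by under 1%, while without it the
per-component estimates at 2,500 trials are noise-dominated; raw-image
analysis remains available via `smooth = FALSE`.

**Estimator noise and template recovery.** At 2,500 trials the raw
classification image has per-component SNR of roughly
$1.6\,m/\sqrt N \big/ (m\sqrt 2 / \sqrt{n_{\mathrm{trials}}/4})$, which caps
its pixelwise correlation with the generating template near 0.65 for these
conditions — narrow bands because the in-band region is a tiny fraction of
the crop, broad bands because per-component SNR falls as $1/\sqrt N$. The
smoothed image correlates at 0.85-0.97. The orientation profile, which
aggregates across the frequency band before fitting, is what carries the
channel analysis; wedges that contain no Fourier components at a given grid
resolution are reported as 0 with a warning and excluded from DoG fitting.

**DoG fitting.** Least squares over (center, $\sigma_e$, $\delta$,
$A_i$) with $\sigma_i = \sigma_e + \delta$, $\delta > 0$ — a smooth
parameterization of the ordering constraint needing no penalty tuning —
multi-started over a coarse bandwidth grid. Surround-free data drive the
fit to the $\delta$ boundary, which is reported with a warning. The fitted
amplitude count deserves a note: the unconstrained DoG has four shape
parameters; with the amplitude ratio fixed and the centers shared, the
constrained fit here has four free numbers (center, two bandwidths, one
amplitude). Confidence intervals are trial-level percentile bootstraps
(resampling trials, not profile points, so classification-image estimation
noise propagates). The trend of fitted bandwidths across stimulus
bandwidth is weighted least squares with the percent increase read off the
fitted line at the narrowest and widest conditions. `bandwidth_trend()`
accepts arbitrary weights (e.g. inverse squared CI half-widths), but
`channel_experiment()` uses equal weights: every condition carries the
same number of trials, and weights estimated from a few hundred bootstrap
replicates are heavy-tailed enough that their own noise visibly distorts
the weighted trend.

## What the synthetic data do and do not show

The generator reproduces the trial structure, stimulus statistics, adaptive
procedure, and trial counts of the study design (300 staircase trials per
condition per session; 2,500 fixed-contrast trials per classification
image). Synthetic observers are *linear in power* with optional Gaussian
internal noise; they have no nonlinear transduction, gain control,
uncertainty, or learning. Passing tests therefore show that the analysis
pipeline is unbiased and well-calibrated for the observer class it assumes
— the same proportionality assumption under which power-spectrum
classification images are interpretable at all — not that human observers
satisfy that assumption. Efficiencies of the shipped DoG proxies
(~0.45-0.65) are higher than typical human values (0.2-0.4) because the
proxies have no internal noise; the efficiency bound checked in acceptance
is a one-sided floor, not a match to human data.

## A worked run

```{r example}
library(oriband)
set.seed(1)

g <- fourier_grid(128, 32)
spec <- filter_spec(center_sf = 5, sf_bandwidth = 1,
                    center_ori = 0, ori_bandwidth = 48)
cond <- noise_condition(g, spec)
ideal <- ideal_template(g, spec)

m <- measure_threshold(ideal, cond, n_sessions = 3)
m$fit

tl <- run_fixed_contrast_session(ideal, cond, m$threshold, n_trials = 2500)
ci <- classification_image(tl, keep_trials = TRUE)
plot(smooth_ci(ci))

prof <- orientation_profile(ci)
fit <- fit_dog(prof)
fit
plot(fit)
```

A full adjustable-versus-fixed comparison is one call each:

```{r experiments}
adj <- channel_experiment(grid = fourier_grid(128, 32), n_boot = 199)
fix <- channel_experiment(grid = fourier_grid(128, 32), n_boot = 199,
                          fixed_template = TRUE)
adj$trend   # percent increase ~ 50% for both parameters
fix$trend   # slope indistinguishable from zero
```

## Known limitations

- The analytic percent-correct formula ignores the contrast envelope; it is
  used for staircase starting points and cross-checks, never as the
  measurement.
- Orientation profiles inherit the angular quantization of the grid: at
  128 px a handful of 1-degree wedges near the crop edge are empty, and the
  profile noise floor depends on how much of the crop lies outside the
  signal annulus.
- `bootstrap_dog()` resamples the stored per-trial collapsed profiles; this
  is exact for both the raw and the smoothed pipeline because every step
  from difference spectrum to profile (including the smoothing kernel) is
  linear and applied per trial.
- The white-noise control can be simulated, but efficiency and channel
  analyses are defined for band-limited targets only.
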