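---
title: "Critical-band masking of multivoxel fMRI responses: models and methods"
author: "critband"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Critical-band masking of multivoxel fMRI responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(critband)
```

## The problem

Critical-band masking infers a spatial-frequency *channel* from how
octave-band noise at different center frequencies perturbs a response.
Psychophysically, noise inside a narrow band (about 1.5 octaves wide)
destroys object recognition while noise outside it barely matters. Adapted
to fMRI, the same stimuli yield two distinct channel estimates per visual
area:

* the **noise-response band** — which noise frequencies drive the overall
  BOLD response to noise-alone images;
* the **recognition band** — which noise frequencies impair decoding of
  scene identity from the multivoxel response pattern.

`critband` implements the full analysis chain: stimulus construction,
design enumeration, a generative simulator for trial-wise voxel responses,
the condition-summary matrices, both channel models, and the derived
metrics (FWHM, FW2M, noise threshold, noise tolerance). Everything runs
from a single seed with no external data.

## Stimuli: octave-band noise from a Laplacian pyramid

Stimuli live on an $N \times N$ grid of normalized luminance in $[0,1]$
($N = 512$ by default). Scenes are reduced to 20% of their original RMS
contrast about a midgray of 0.449, so that even the strongest noise
($\sigma = 0.16$) rarely clips. Noise is Gaussian white noise filtered
into one of seven one-octave bands and rescaled to an exact sample
standard deviation $\sigma \in \{0, 0.02, 0.04, 0.08, 0.16\}$; it is added
to the low-contrast scene or to a uniform midgray field, then clipped once
to $[0,1]$.

The band filters are built from the Burt–Adelson Laplacian pyramid with
the classic 5-tap binomial kernel ($a = 0.4$). One construction detail is
worth spelling out, because it is easy to get wrong. The pyramid's finest
level is the residual *highpass* $G_0 - \mathrm{expand}(G_1)$: on white
noise its orientation-pooled spectrum keeps rising toward Nyquist
($\approx 0.98 \cdot N/2$ cycles/image empirically), so it is not an
octave-wide band and sits more than an octave above the finest nominal
center $0.21875\,N$ (112 cycles/image at $N = 512$). `critband` therefore
builds the pyramid on a twofold-oversampled copy of the field and takes
levels $2 \ldots 8$ as the seven band operators. The half-step offset
makes the finest band a genuine bandpass filter. With this construction
the measured radial spectral peaks of the seven bands fall within half an
octave of the nominal centers $\{1.75, 3.5, 7, 14, 28, 56, 112\}$ and
their geometric mean lands near 14 cycles/image (the test suite and
`scripts/acceptance.R` recompute this). `laplacianPyramid()` /
`reconstructPyramid()` remain the textbook invertible decomposition, with
reconstruction error at floating-point level.

Band centers are validated empirically with `radialSpectralPeak()`, which
pools the 2-D power spectrum over orientation into integer radial bins.
We pool by annulus *total* (not mean) power: this makes the white-noise
control deterministic (power grows with annulus area, so unfiltered noise
peaks near Nyquist) and matches how band energy is distributed across the
discrete spectrum.

Interpolation choices (bilinear resampling in the 256 → 224 crop → 512
preparation chain) follow the standard ImageNet protocol; the exact
interpolant is a free parameter of the original displays that we fix to
bilinear and document here. Any square grayscale image is accepted;
`proceduralScene()` synthesizes $1/f$ textures as deterministic stand-ins
for natural photographs.

## Design

The canonical design crosses 10 object categories with 7 bands and 4
non-zero contrasts, plus scene-only, noise-only and blank conditions:
$(C+1)(|F||\Sigma \setminus 0| + 1) = 11 \times 29 = 319$ unique
conditions. Repetition schemes are per-participant; the three published
schemes give 1133, 1307 and 1305 trials:

```{r design}
d <- experimentDesign()          # reps (3, 9, 19, 23)
nrow(enumerateConditions(d))
nrow(buildTrialTable(d, nRuns = 15, seed = 1))
```

Trials are shuffled deterministically and dealt to runs round-robin. The
source experiment reports "87 images per scan", which is consistent with
only one of the three published totals, so per-run composition is a
package choice (maximally even), not a reproduced quantity.

## The generative model behind the simulator

No voxel-level generative model is specified by the analysis itself — it
only consumes trial-wise beta weights. The simulator therefore implements
the *minimal* forward model under which every downstream quantity is
recoverable:

$$ y_t = a\,\mu_c\,[\mathrm{scene}] \;+\; g(\sigma, f)\, s_t\, n_t \;+\;
   \beta_{base}\,\mathbf{1} \;+\; \epsilon_t $$

with noise drive
$g(\sigma,f) = \beta_{max} \frac{\sigma}{\sigma + \sigma_{50}}
\exp\!\big({-\tfrac{(\log_2 f - \log_2 \mu)^2}{2 w^2}}\big)$,
a fresh random pattern $n_t$ per trial, $s_t = \lambda$ on scene trials
(1 otherwise), and i.i.d. measurement noise of SD $\tau$.

Two modelling choices deserve a rationale:

* **$n_t$ has unit mean and unit variance.** With a zero-mean pattern the
  noise drive would cancel in the voxel-mean and the noise-response
  matrix would carry no tuning signal; the unit mean makes the expected
  voxel-mean on noise-only trials exactly the channel model's prediction
  (verified by a Monte-Carlo test against the closed form), while the
  unit variance makes the noise interfere with the multivoxel pattern
  and hence with decoding.
* **Prototypes are i.i.d. $N(1, \mathrm{protoSd}^2)$ per voxel** (default
  `protoSd = 0.3`). The unit mean gives scene trials a positive mean
  response $a$ above baseline, which keeps scene normalization and the
  noise threshold (defined at the scene-alone response level) well
  defined; the pattern SD controls decodability independently. With the
  defaults ($a = 0.8$, $\tau = 1$, $\beta_{base} = 0.2$) the scene-alone
  voxel-mean is $\approx 1$, baseline decoding is well above chance but
  below ceiling, and in-band noise visibly degrades it.

Behavioral outcomes are simulated directly from the recognition channel
(below) as independent Bernoulli draws — emulating a psychophysical
data set at any trial budget.

Voxel metadata are uniform draws: eccentricity on $[0^\circ, 8^\circ]$ so
that about a quarter of voxels fall outside the $[0^\circ, 6^\circ]$
selection window, and variance explained on $[0, 0.5]$ so the 5% cut is
exercised. The eccentricity interval is treated as *closed* and the $R^2$
criterion as *strict* (> 5%), matching the stated selection rules; both
boundary behaviors are pinned by tests.

The response scale of real betas (percent signal change) is not
prescribed anywhere; the simulator defaults are chosen for a healthy but
not extreme signal-to-noise ratio and are documented as arbitrary.

## The two channel models

**Noise-response channel.** The noise-response matrix $R(\sigma, f)$
(mean over noise-only trials of the voxel-mean beta) is fit by least
squares with

$$ \hat R(\sigma,f) = \beta_{base} + \beta_{max}
   \frac{\sigma}{\sigma+\sigma_{50}}
   \exp\!\Big({-\frac{(\log_2 f - \log_2 \mu)^2}{2w^2}}\Big), $$

a Naka–Rushton contrast-response function times a log2-Gaussian tuning
curve plus a baseline. The response bandwidth is
$\mathrm{FWHM} = 2\sqrt{2\ln 2}\,w$ octaves. The fit is canonically run
on the *scene-normalized* matrix (every cell divided by the scene-alone
mean response), so the **noise threshold** — the noise power at which
noise alone matches the scene response — is the solution of
$\hat R(\sigma^*, \mu) = 1$:
$\sigma^* = \sigma_{50}(1-\beta_{base})/(\beta_{max}-(1-\beta_{base}))$,
reported as power $\sigma^{*2}$, flagged infinite when the saturating
response cannot reach the target. A flag permits fitting raw matrices;
normalization is kept a separate, explicit step so both views exist.
Whether the original analysis fit raw or normalized matrices is not
stated in its methods; we follow the figure convention (normalized),
which also makes the threshold target exactly 1. Because there are no
zero-contrast noise-only trials, the $\sigma = 0$ row of the matrix is an
explicit missing marker and is excluded from the fit.

**Recognition channel.** Scene trials are decoded with a Pearson
nearest-centroid classifier: prototypes are the mean patterns over
noiseless trials, a test trial is assigned to the prototype with the
highest correlation, and noiseless trials are decoded leave-one-out (the
test trial is removed from its own prototype) to prevent circularity.
Ties break toward the lowest category index; undefined correlations
(zero-variance pattern) never win. The trial-wise outcomes are modeled
with

$$ S(f) = e^{-\frac{(\log_2 f - \log_2 \mu)^2}{2w^2}}, \qquad
   D = \sigma S(f), \qquad
   E = \frac{(1+\kappa) D}{D + \kappa}, \qquad
   P(\mathrm{correct}) = \frac{1}{1 + e^{-m(E-b)}}, $$

fit by binomial maximum likelihood to single-trial outcomes
(zero-noise trials included: they pin the baseline
$P_0 = 1/(1+e^{mb})$ through $m$ and $b$). The printed logistic increases
with $E$, so on well-formed data the fitted slope $m$ must come out
*negative* for accuracy to fall with noise; we keep the printed form and
leave the sign unconstrained, asserting $m < 0$ on synthetic data. The
**threshold curve** $\Theta(f)$ — the noise power at which accuracy drops
to $P_0/2$ — has the closed form
$E^* = b - \log(1/(P_0/2) - 1)/m$,
$D^* = \kappa E^*/((1+\kappa) - E^*)$,
$\Theta(f) = (D^*/S(f))^2$, flagged infinite when $E^* \ge 1+\kappa$
(the normalized response is bounded). Because
$\Theta(f) \propto 1/S(f)^2$, the recognition bandwidth — full width at
twice the minimum power, $\mathrm{FW2M}$ — is $2w\sqrt{\ln 2}$ octaves,
independent of $\kappa$, $m$, $b$, and the **noise tolerance** is
$\Theta(\mu) = D^{*2}$. All closed forms are tested against bisection
oracles at $10^{-8}$.

**Numerical choices.** Both fits use a multi-start bounded search: $\mu$
starts at each band center, $w \in \{0.5, 1, 2\}$ octaves,
$\sigma_{50}$ at each non-zero design contrast,
$\kappa \in \{0.1, 1, 10\}$; the amplitude pair of the response model is
profiled out analytically at each start; the three best starts are
refined with `L-BFGS-B` (bounds $\mu \in [0.875, 224]$ cycles/image — one
octave beyond the design — $w \in [0.05, 8]$, $\sigma_{50} \in [10^{-4},
1]$, $\kappa \in [10^{-2}, 10^{3}]$; finite-difference step $10^{-6}$,
`factr = 100`). Degenerate inputs are flagged rather than fit: a constant
response matrix, perfectly separated outcomes, a zero logistic slope.
The two models are fit independently — no parameter sharing.

## The simulated dissociation

The headline scientific pattern is a *dissociation*: along the ventral
stream the noise-response band widens (about 2 octaves in V1 to about 5
in VTC) while the recognition band stays near 2 octaves, with noise
threshold and noise tolerance both rising. `regionPresets()` encodes five
synthetic regions with exactly this structure (response FWHM 2 → 5
octaves, centers drifting from 14 to 7 cycles/image, falling relative
noise-response amplitude, recognition channel fixed at 19 cycles/image
and FW2M 2 octaves with strengthening divisive normalization
$\kappa$, and growing scene suppression $\lambda$ of the noise drive on
scene trials).

One structural limitation must be understood when interpreting pipeline
output. In this forward model the *only* mechanism by which noise
interferes with decoding of simulated betas is the noise drive
$g(\sigma, f)$ — the response channel. MVPA outcomes computed from
simulated betas therefore inherit the response-channel tuning; a
generator this minimal cannot make the MVPA recognition band narrower
than the response band, which in real cortex is an empirical discovery,
not an analytic consequence. The pipeline accordingly fits the
recognition model to classification outcomes simulated from each
region's recognition-channel parameters (its ground truth includes
them for exactly this purpose), and *additionally* fits the MVPA
outcomes (`fw2mMvpa` in the summary) so the two routes can be compared.
Passing tests therefore demonstrate that the analysis recovers whatever
channel structure the data contain — not that the dissociation is
inevitable in real data.

```{r pipeline, eval = FALSE}
cfg <- pipelineConfig(regions = regionPresets()[c("V1", "VTC")],
                      nSubjects = 5, nVoxels = 150)
res <- runPipeline(cfg, seed = 2024, quiet = TRUE)
res$groupSummary[, c("region", "fwhmResponse", "fw2mRecognition",
                     "noiseThreshold", "noiseTolerance")]
```

## Problem sizes and what the tests show

The test suite exercises the pipeline at deliberately chosen scales: the
spectral validation uses ten 512-px white-noise fields; parameter
recovery runs 50 independent simulated subjects at the published
per-subject budget (280 × 3 scenes-in-noise, 28 × 9 noise-only, 10 × 19
scene-only trials), checking that the median recovered center is within
0.25 octave (response channel) and 0.5 octave (recognition channel) of
truth, with FWHM within 20% and FW2M within 30%; the dissociation check
simulates a 5-subject, 2-region cohort and verifies that fitted response
bandwidths differ by more than 2 octaves while FW2M differs by less than
0.5 octave. These sizes are the package's chosen study conditions for
simulation-based validation.

## Known limitations

* Measurement noise is i.i.d. across voxels and trials — no spatial or
  temporal autocorrelation, no hemodynamics, no GLM estimation stage; the
  simulator emits beta weights directly.
* The noise pattern $n_t$ is a single rank-one perturbation per trial;
  real noise responses have structured covariance.
* Scene suppression ($\lambda$) is a single multiplicative factor used
  for qualitative emulation only; no dedicated superposition analysis is
  provided.
* The behavioral correction for differing category counts between tasks
  is out of scope, as are eccentricity-binned matrices (the voxel filter
  is general enough to build them, but no dedicated operation ships).
* Error bars produced by the pipeline are across-seed (simulated-subject)
  SEMs, not empirical between-subject variability.
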