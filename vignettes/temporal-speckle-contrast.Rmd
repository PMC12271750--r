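---
title: "Temporal speckle contrast with inter-frame correlation: model, simulator and pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal speckle contrast with inter-frame correlation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tspeckle)
```

## The problem

Laser speckle contrast imaging (LSCI) infers sample dynamics from the
contrast $K = \sigma / \langle I \rangle$ of time-integrated speckle. The
*temporal* algorithm computes $K$ per pixel across $L$ consecutive frames,
preserving spatial resolution. Classic models relate $K$ to the
dimensionless exposure $x = T/\tau_c$ (exposure time over field
decorrelation time) under the assumption that successive frames are
statistically independent. For slow dynamics — bacterial colonies, drying
paint, seed viability — frames acquired within $\tau_c$ are strongly
correlated: the per-pixel variance collapses and the measured temporal
contrast approaches zero, while independent-frame models predict a contrast
near one. This package implements a model that restores agreement by
carrying the inter-frame correlation through the variance calculation.

## The temporal model

Frames are indexed $\psi = 0, \dots, L-1$, captured with exposure $T$ and
dead time $\delta$ between frames ($\Delta = \delta/T$). Each ordered frame
pair is classified by its separation $\psi = |m - n|$: there are $L$
*central* pairs ($\psi = 0$), $2(L - \psi)$ *lateral* pairs for each
$1 \le \psi \le S$, and $(L - S - 1)(L - S)$ *outsider* pairs treated as
uncorrelated (`correlation_pair_census()`); the counts always sum to
$L^2$. $S$ is the number of frame intervals treated as correlated;
$S = L - 1$ correlates every pair.

The correlation factor between frames separated by $\psi$ intervals is the
double average of the squared field correlation over the two exposure
windows,
$$\frac{1}{\nu_\psi} = \frac{1}{T^2} \int_0^T \!\!
  \int_{\psi(T+\delta)}^{(\psi+1)T + \psi\delta} g_1^2(t - t')\, dt'\, dt,$$
and the expected squared temporal contrast (unbiased variance, divisor
$L - 1$) is
$$K_t^2(x, L, S) = \frac{1}{\nu_0} - \frac{2}{L(L-1)}
  \sum_{\psi=1}^{S} (L - \psi) \frac{1}{\nu_\psi}.$$
With $S = 0$ only $1/\nu_0$ survives and the classic independent-frame
expressions are recovered.

Two field correlation families are built in, both normalized to Mandel's
definition of the correlation time,
$\tau_c = \int |g_1(\tau)|^2 d\tau$:

* **Gaussian** (ordered/laminar motion):
  $g_1(\tau) = \exp(-\pi \tau^2 / 2\tau_c^2)$. The closed form for
  $1/\nu_\psi$ combines error functions with arguments
  $\sqrt{\pi}(\cdot)x$ and Gaussians $\exp[-\pi(\cdot)^2 x^2]$; at
  $\psi = 0$, $\Delta = 0$ it reduces exactly to
  $\mathrm{erf}(\sqrt{\pi}x)/x + (e^{-\pi x^2} - 1)/(\pi x^2)$. This pair
  of properties (Mandel normalization plus exact reduction) fixes the
  radicals in the closed forms unambiguously, and both are verified
  numerically in the test suite.
* **Lorentzian** (Brownian motion):
  $g_1(\tau) = \exp(-|\tau|/\tau_c)$, giving
  $1/\nu_0 = (2x + e^{-2x} - 1)/2x^2$ — the classic single-exposure
  result — and a three-exponential form for $\psi > 0$.

Every closed form is validated against `nu_inv_quadrature()`, an adaptive
quadrature of the equivalent triangular-weight single integral (absolute
tolerance $10^{-10}$), which itself is cross-checked against the raw 2-D
double integral. The quadrature oracle, not the closed forms, is the
ground truth for the frozen expected values in the tests.

Qualitative behavior worth knowing: with $S = L - 1$ the contrast curve
$K_t(x)$ is non-monotone with a single interior maximum; increasing the
dead time shifts the Lorentzian maximum toward smaller $x$; and the
correlated and independent-frame models converge for fast dynamics. At the
experimental window $L = 30$ the two models differ by less than 2% (on
$K$) for $x > 1$ (Lorentzian) and $x > 0.5$ (Gaussian); the residual
correlation term scales like $\sum_\psi (L-\psi)\nu_\psi^{-1} / L(L-1)$,
so the agreement threshold moves to larger $x$ for shorter windows
(about $x \approx 1.25$ and $0.8$ at $L = 15$) and sharpens for longer
ones.

## Spatial and spatio-temporal contrast

A physical pixel integrates speckle over its area; with the
pixel-to-grain area ratio $M$, the no-correlation spatial factor is
$\beta^{1/2}(M) = \mathrm{erf}(\sqrt{\pi M})/\sqrt{M} -
(1 - e^{-\pi M})/\pi M$. Within an $n \times n$ sliding window, pixels up
to $p$ offsets apart may additionally be correlated. Because the field
correlation separates in space and time, the pixel-offset factors are
separable products of 1-D pixel-integral factors, each identical in form
to the temporal $1/\nu_\psi$ at $x = \sqrt{M}$ (the *linear*
pixel-to-grain ratio) and zero dead time:
$1/\mu_{\eta,\xi} = f_\eta(\sqrt{M}) f_\xi(\sqrt{M})$. The correlated
window contrast `spatial_contrast_sq()` weights these factors by the
number of pixel pairs at each offset inside the window (hence the
$(n - \eta)$ multiplicities, with $n$ the *linear* window size) and
normalizes over all $n^2(n^2 - 1)$ ordered distinct pixel pairs. Design
note: the pair-count sums must use the linear size $n$ while the
normalizing prefactor must use the pixel count $n^2$ — this is the only
combination under which the weighted counts balance the pair census, and
it reproduces every entry of the published calibration table (`table1()`)
to all printed digits, which the test suite enforces as a hard
requirement. The Lorentzian spatial correlation is likewise taken
separable per axis, $\exp(-|\Delta r|/\ell)$ per dimension, mirroring the
temporal form; it is validated by the same table.

The combined spatio-temporal contrast is the separable product
$K^2 = \alpha\, K_s^2(M, n, p)\, K_t^2(x, L, S) + C_n$.

## The classic reference model

`classic_contrast()` implements the widely used independent-frame model
with normalization $\alpha$, dynamic fraction $\rho$, noise $C_n$ and the
$\beta^{1/2}(M)$ pixel factor. Two conventions coexist in the literature
for the noise term; we keep $C_n$ inside the bracket (before the square
root), as most commonly printed, and document rather than resolve the
discrepancy. With $\alpha = \rho = 1$, $C_n = 0$, $M \to 0$ the model
reduces exactly to the square root of the Lorentzian independent-frame
contrast, which the tests assert to $10^{-10}$.

## The simulator

`simulate_stack()` generates fully developed dynamic speckle with known
ground truth, standing in for a slow-dynamics experiment (e.g. a bacterial
colony under coherent illumination) whose raw frames are not otherwise
available:

1. **Space.** Circular complex Gaussian phasors are drawn on an elliptical
   pupil in the FFT plane; the image-plane field is their FFT. By
   Parseval, the pupil occupancy fraction *equals* the pixel-to-grain
   coherence-area ratio, so `speckle_M` is rendered exactly in the
   Mandel (coherence-area) sense.
2. **Time.** The Lorentzian family evolves the field by an exact
   Ornstein-Uhlenbeck (first-order autoregressive) update between
   sub-steps, which reproduces $g_1(\tau) = e^{-|\tau|/\tau_c}$ for
   arbitrary (including dead-time) steps. The Gaussian family has no
   Markovian representation, so the full sub-step timeline covariance
   $C_{ij} = g_1(t_i - t_j)$ is factorized (Cholesky with an escalating
   diagonal nugget from $10^{-12}$, falling back to a clipped eigenvalue
   factorization; the Gaussian kernel is near-singular for dense
   sampling, and the nugget perturbs the realized correlation by at most
   $10^{-6}$). Correctness was preferred over speed; the timeline length
   `L * substeps` is capped (default 4096).
3. **Exposure.** Each frame averages `substeps` midpoint sub-samples
   across the exposure and skips the dead time. The default
   `substeps = 32` keeps the within-exposure sampling error in the
   rendered contrast below about 0.5% up to $x = 2$; a guard warns when
   the sub-step exceeds $\tau_c / 5$.

Pixels are *point samples* of the field: there is no intra-pixel area
integration, so per-pixel temporal statistics follow the temporal model
directly (spatial factor 1) while `speckle_M` shapes only the spatial
grain structure (as seen by THSP and spatial sampling-error
considerations). The simulator does not model camera noise (beyond
optional quantization), light transport, non-separable flow fields, or
partially developed speckle — so closed-loop agreement demonstrates the
statistical model, not robustness to instrument effects.

Defaults mirror the slow-dynamics acquisition the model targets:
$T = 1$ s exposure, $L = 30$ frame windows, `speckle_M = 0.5` (the
Nyquist-Shannon case of the calibration table; the actual experimental
grain-to-pixel ratio is not documented, so the Nyquist case is adopted as
the conventional choice), dead-time ratio $\Delta = 0.347$ where a
realistic camera gap is wanted.

## Estimators: per-pixel mean versus ensemble ratio

The conventional report is the mean (and SD) of the per-pixel contrast
map over an ROI (`roi_contrast_summary()`). The theory, however, predicts
the *ensemble* ratio $E[\hat\sigma^2] / \langle I \rangle^2$. The
per-pixel statistic $\hat\sigma/\hat m$ is biased low when the window
spans few decorrelation times: $\hat\sigma^2$ then has few effective
degrees of freedom and $E[\hat\sigma] < \sqrt{E[\hat\sigma^2]}$ (Jensen).
At $L = 30$, $x = 0.1$ the bias is around $-7\%$; in fitted data it is
absorbed into the normalization $\alpha$, which is one reason $\alpha$ is
routinely freed when fitting experimental curves. For closed-loop
validation we therefore use `roi_contrast_ensemble()`,
$\sqrt{\mathrm{mean}(v)}/\mathrm{mean}(m)$ over the ROI, which estimates
exactly the predicted quantity and is unbiased to $O(1/N_\mathrm{pixels})$.
Both estimators are exposed, and `contrast_vs_x_experiment()` lets you
choose.

## Fitting

`fit_correlation_time()` fits the frame-correlation curve (Pearson
coefficients between a reference frame and later frames) to the intensity
correlation implied by a family. By the Siegert relation
$g_2 - 1 = |g_1|^2$, intensity correlations decay as $|g_1|^2$
(`use_siegert = TRUE`, the default: $e^{-2\tau/\tau_c}$ Lorentzian,
$e^{-\pi\tau^2/\tau_c^2}$ Gaussian); whether a published correlation curve
was fitted to $g_1$ or $|g_1|^2$ is often ambiguous, so both are exposed.
The single parameter is found by golden-section search on
$\log \tau_c$ — no starting value, no convergence failures on monotone
curves. Family selection is by residual comparison.

`fit_contrast_model()` fits
$K(x) = \sqrt{\alpha K_t^2(x \cdot s_\tau, L, S, \Delta) + C_n}$ with any
subset of $(\alpha, C_n, s_\tau)$ freed (box-constrained BFGS; fixed
values $\alpha = 1$, $C_n = 0$, $s_\tau = 1$). Which parameters to free is
an experimental-design question — the package exposes the choice rather
than fixing it.

## Exposure binning

`bin_frames()` averages non-overlapping groups of $\omega$ frames to
emulate longer exposures from a single acquisition. The effective
exposure includes the interior dead times,
$T_\mathrm{eff} = \omega T + (\omega - 1)\delta$ (the physical span of
the integrated window); `gap_policy = "exclude"` gives the
light-only convention $\omega T$. With $\delta = 0$ binning is *exactly*
equivalent to a longer exposure, which is what the closed-loop binning
test exploits.

## Numerical choices

* `expm1` throughout the closed forms: the $\psi > 0$ factors are
  differences of exponentials that all approach 1 as $x \to 0$; the
  constant parts cancel exactly, avoiding catastrophic cancellation at
  small $x$. A small-$M$ series protects $\beta^{1/2}$ below $M = 10^{-4}$.
* $K_t^2$ is analytically non-negative; values in $(-10^{-12}, 0)$ from
  round-off are truncated to zero, anything more negative raises an error
  (it would indicate a bug, not round-off).
* $\psi$ is the absolute frame separation; the $2(L-\psi)$ pair
  multiplicity already accounts for the symmetry, so only $\psi \ge 0$ is
  exposed, and non-integer $\psi$ (fractional delays) is not supported.
* $L$ is the number of frames, full stop; a window needs $L \ge 2$
  because the unbiased variance is undefined at $L = 1$.
* ROIs are `c(row_min, row_max, col_min, col_max)`, 1-based inclusive,
  matching R indexing conventions.
* Problem sizes used by the closed-loop tests: $256 \times 256$ stacks of
  $L = 30$ frames over $x \in \{0.01, 0.1, 0.5, 1, 2\}$ and
  $\Delta \in \{0, 0.347\}$ for both families, plus 128-pixel recovery
  runs with 150-200 frames; these give sampling errors comfortably below
  the 5% (closure) and 10% (recovery) validation tolerances while keeping
  the suite's runtime modest.

## Known limitations

* The correlated temporal model assumes fully dynamic scatterers
  ($\rho = 1$); a static fraction enters only the classic reference model
  (and the simulator's `rho` knob, provided for exercising it).
* The spatial pixel-offset factors are derived from separability rather
  than from an independent spatial theory; their validation is the exact
  reproduction of the published calibration table plus a two-pixel
  quadrature oracle.
* Whether the spatial `M` inside the offset factors should be read per
  linear dimension or per area is resolved here as area ratio with
  $x = \sqrt{M}$ mapping — the only reading consistent with the $p = 0$
  reduction and the calibration table.
* The quadrature oracle accepts user kernels but no symbolic forms; very
  heavy-tailed custom kernels may need a larger `abs.tol`.
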