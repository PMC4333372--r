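---
title: "astigTrack: models, conventions and numerical decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{astigTrack: models, conventions and numerical decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(astigTrack)
```

This vignette documents the physical model, the coordinate and sign
conventions, and the numerical decisions behind the package — the details
a user needs to interpret results or to compare against their own
implementation.

## Astigmatic PSF model

An astigmatic detection path focuses the x and y image axes at different
depths. The per-axis width follows the Gaussian-beam law

$$\sigma_{x,y}(z) = \sigma_0 \sqrt{1 + \left(\frac{z \pm s/2}{d}\right)^2},$$

where $\sigma_0$ is the in-focus width (default 0.16 µm), $d$ the depth
scale (0.4 µm), and $s$ the focal-plane separation (0.8 µm): the x focal
plane sits at $z = -s/2$, the y focal plane at $z = +s/2$, and at $z = 0$
(the effective focal plane) both widths are equal. The camera defaults are
0.24 µm pixels, a background of 5 ± 2 photons per pixel, and an EM excess
factor of $\sqrt{2}$ that inflates the Poisson shot noise.

`renderFrame()` integrates the elliptical Gaussian exactly over the pixel
grid (differences of per-axis normal CDFs at the pixel edges) rather than
sampling it at pixel centers. At this sampling ($\sigma_0 = 0.67$ px) the
difference matters: a least-squares fit of a *sampled* Gaussian to a
rendered spot overestimates the widths by 4.7% (in focus) to 9.6% (minor
axis at $z = 0.4$ µm). For this reason the width/precision oracle
`gaussianFitSpot()` also fits the pixel-integrated (erf) model.

Coordinates are micron with the origin at the image corner; the center of
pixel (row $i$, column $j$) is at $y = (i - \tfrac12)\,p$,
$x = (j - \tfrac12)\,p$ for pixel size $p$. Matrices are `[row = y,
col = x]`.

## Axial calibration and localization

Two 11×11 templates are cut from calibration-stack slices at $z = \mp0.4$
µm. For an image, the normalized covariances $\xi_1, \xi_2$ (Pearson
correlation against each template, computed in C++ via `.znccMapCpp`) are
evaluated at the patch maximizing $\xi_1 + \xi_2$, and the contrast metric

$$\frac{\xi_2 - \xi_1}{\xi_1 + \xi_2} = a\,z + b$$

is fitted by least squares over the inter-template range. With the default
optics the noise-free slope is $a \approx 0.398\,\mu m^{-1}$ and $b
\approx 0$ by symmetry.

Two guards make the metric well-defined everywhere: negative covariances
are floored at $10^{-6}$ before forming the ratio, and positions where
both covariances fall below 0.1 are flagged out of range rather than
converted to a z value.

**Linearity limitation.** The metric is only approximately linear in $z$.
The least-squares line leaves an S-shaped residual that peaks near
$|z| = 0.2$ µm at about 20 nm (noise-free, default optics) and the signed
mean bias over the linear range is ≈ 0. Axial estimates inherit this
systematic ~20 nm floor; it also sets the closed-loop accuracy floor
(below).

**SNR independence of the slope.** A *single* noisy exposure per slice at
peak SNR 5 cannot identify the slope to 5% — the seed-to-seed spread is
25–30% with protocol-dependent bias of either sign. Real bead calibrations
integrate many exposures per z position, so `renderCalibrationStack()` has
a `framesPerSlice` argument (averaged exposures). With frame averaging the
fitted slopes at SNR 5 and SNR 50 agree to 0.8%, verifying that the
calibration has no systematic brightness dependence. At low SNR the
template peak is additionally located on a 3×3 box-smoothed slice so a
single hot background pixel cannot hijack the template window.

## The feedback loop

The loop convention is a *sample-stage* move: `feedbackStep()` returns
$-g\,\hat z_{rel}$, and moving the stage by $m$ displaces the focal plane
by $-m$ in specimen coordinates, so `runClosedLoop()` applies
`stageZ <- stageZ - move`. With $z_{rel} = z_{abs} - z_{stage}$ this
re-centers the particle; absolute coordinates are reconstructed as
$z_{abs} = z_{stage} + \hat z_{rel}$. Moves are applied after a
configurable latency (default one frame); out-of-range estimates hold the
stage. A run terminates with a loss flag when the particle leaves the
axial capture range, escapes the lateral tracking window, or localization
fails on three consecutive frames.

For a particle moving at constant axial speed $v$ with gain $g$ and
one-frame latency, the steady-state tracking lag is $v\,\Delta t / g$
(tested arithmetically). For a diffusing particle the absolute axial RMSE
plateaus at ≈ 45 nm regardless of photon count: at $D = 1\,\mu m^2/s$ and
$\Delta t = 16.5$ ms the particle moves $\sqrt{2 D \Delta t} \approx 0.18$
µm per frame, so the true $z_{rel}$ sweeps most of the metric range, where
the calibration nonlinearity dominates.

## Mobility analysis

`fitCJDD()` fits the cumulative jump-distance distribution

$$P(r^2, \Delta t) = 1 - \sum_i a_i\,e^{-r^2 / (4 D_i \Delta t)}$$

(2D kernel; the 3D variant uses the $\chi^2_3$ survival function) by least
squares against the empirical CDF, with log-parameterized coefficients,
softmax fractions, and a deterministic multi-start over a log-spaced D
grid.

**Weighting (documented deviation).** Residuals are weighted by the
inverse pointwise ECDF variance $1/\max(p(1-p), 10^{-3})$ by default.
Measured on the two-component configuration used by the acceptance targets
($D$ = 0.85/1.69 µm²/s, 10 × 250 jumps), the unweighted fit is badly
biased (pooled slow fraction 39.5% vs 30% generated; global slow D 0.784
vs 0.85, ~4.5 seed-mean standard errors) and cannot meet the 3-s.e.
recovery criteria at any trajectory length. The weighted fit gives
32.4 ± 5.2% and 0.834 ± 0.007 (mean ± s.e. over 20 seeds). The unweighted
variant remains available as `weights = "none"`, and `fitCJDDML()` /
`fitJDDHistogram()` provide independent cross-checks. Note that a 2×
coefficient ratio is intrinsically hard: single-seed slow-fraction
estimates on 2500 pooled jumps scatter with a standard deviation of ~25
percentage points, which is why the acceptance criteria average over ≥ 20
seeds.

`globalFitCJDD()` shares the coefficients across trajectories with free
per-trajectory fractions; for two components the fractions are profiled
out in closed form (simplex-clipped weighted linear least squares),
leaving a two-parameter outer problem. The residual ~2 s.e. downward bias
of the shared slow D is incidental-parameter bias from the per-trajectory
fractions and shrinks with jumps per trajectory.

## Run-length (dwell) statistics

The probability that $n$ Bernoulli($p$) trials contain no success run of
length $\ge k$ has a printed alternating-sum form (Eq. 4 of the source
analysis). Evaluated literally it cancels catastrophically for small $k$
at large $n$ (terms ~$e^{125}$ for a result in [0, 1]), so `probNoRun()`
uses the algebraically equivalent, exact first-passage recurrence

$$a_i = a_{i-1} - (1-p)\,p^k\,a_{i-k-1},$$

which is stable for all arguments; the literal sum is retained internally
and agrees in its stable regime. The recurrence is verified against
exhaustive enumeration of all $2^n$ sequences for every $n \le 16$,
$k \le n$ and a grid of $p$, to $10^{-12}$.

Dwell significance is $P' = 1 - \mathrm{probNoRun}(n, k, p)$ — the
probability of observing *at least one* run of length $\ge k$ — with $p$
taken from the whole-trajectory ECDF at the threshold (conservative). The
worked example reproduces the published rRNA values: inverting
$P'(221, 26, p) = 5.2\times10^{-5}$ gives $p^* = 0.577$, and
$P'(221, 28, p^*) = 1.7\times10^{-5}$ to two significant figures.

`scanThresholds()` scans all candidate thresholds and reports raw
(uncorrected) significances, as in the source analysis. On pure Brownian
data the *fixed-threshold* per-state false-positive rate is ≈ 0.04 at
$\alpha = 0.05$ (slightly conservative, as expected for a discrete test),
but the *scan* selects over ~n correlated thresholds and flags an event in
~65% of null trajectories; an optional Bonferroni mode (rate ~0.005) is
provided. Interpret scan output as candidate events, not calibrated
p-values. `transitionStats()` implements the transition-deficit test with
the printed $n$-pair expectation $2 p_A p_B n$; the exact i.i.d. mean is
$2 p_A p_B (n-1)$, an $O(1/n)$ difference the tests document.

## Known limitations

- The axial metric's nonlinearity leaves a ~20 nm systematic residual
  (default optics) over the calibrated range; recalibrate the optics
  parameters rather than the line if tighter accuracy is needed.
- The closed-loop simulator renders a single emitter; crowding and
  background structure are out of scope.
- `linkNearestNeighbor()` is deliberately conservative: ambiguous
  encounters terminate trajectories rather than guessing, so dense scenes
  fragment. The displacement limit must budget for localization noise
  (~0.15 µm/axis at SNR ~7), not just diffusion.
- CJDD component fractions for closely spaced coefficients (ratio ≲ 2)
  have very wide single-trajectory sampling distributions; pool data and
  average over replicates, as the acceptance protocol does.
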