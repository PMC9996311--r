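---
title: "Passive microrheology from single-particle tracking: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Passive microrheology from single-particle tracking: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rheoSPT)
```

## The measurement

Passive microrheology infers the mechanical state of the cytoplasm from the
thermal motion of tracer particles — either exogenous probes such as
self-assembling μNS–GFP nanoparticles, or endogenous ones such as mRNP
granules visualized through stem-loop/coat-protein labelling. A confocal
movie of such particles (typically 500 ms per frame for about 2 minutes, at
0.18 μm per pixel with a 63x objective) yields a set of trajectories, and
everything downstream is a function of those trajectories.

For a single trajectory with positions $\mathbf{r}_i$ sampled at interval
$\Delta t$, the time-averaged mean-squared displacement at lag
$\tau = k\Delta t$ uses all overlapping displacement pairs:

$$\mathrm{MSD}(k\Delta t) \;=\; \frac{1}{N-k}\sum_{i=1}^{N-k}
  \lVert \mathbf{r}_{i+k} - \mathbf{r}_i \rVert^2 .$$

Two summary statistics are extracted over the first ten lags (5 s at
$\Delta t = 0.5$ s):

* the **effective diffusion coefficient** from the through-origin linear
  model $\mathrm{MSD}(\tau) = 4\,D_\mathrm{eff}\,\tau$, whose least-squares
  solution is the closed-form projection
  $D_\mathrm{eff} = \sum_k \tau_k \mathrm{MSD}_k \,/\, 4\sum_k \tau_k^2$
  (this is what `fitDeff()` computes, and the identity is asserted in the
  test suite);
* the **anomalous exponent** $\alpha$ as the slope of an unweighted OLS fit
  of $\log_{10}\mathrm{MSD}$ on $\log_{10}\tau$, matching the power-law
  model $\mathrm{MSD}(\tau) = 4 D \tau^{\alpha}$; $\alpha = 1$ is Brownian,
  $\alpha < 1$ subdiffusive.

Condition-level results are medians over trajectories (`summarizeCondition`),
fold changes of those medians between conditions (`foldChange`), and
replicate-paired two-tailed t-tests across biological replicates
(`pairedTTest`, `compareConditions`). The ensemble-time-averaged MSD
(`computeEnsembleMSD`) is the unweighted mean of per-trajectory curves at
each lag, restricted to trajectories long enough to contribute that lag.

## Trajectory filtering

Short tracks are dominated by linking errors, so only trajectories with
*more than ten* time points are analyzed. We read that rule literally as
$\geq 11$ localizations (`filterTrajectories(minPoints = 11)`); the
threshold is exposed as a parameter. Trajectories with a zero MSD at any
fitted lag cannot enter the log-log fit; they are excluded from the
$\alpha$ analysis only (their count is reported) and retained for
$D_\mathrm{eff}$, where the fit degrades gracefully to 0.

## The synthetic-data generator

No raw movies accompany the kind of acquisition this package targets, so a
simulator stands in for them and doubles as the ground truth for every
test. Each coordinate of a trajectory follows an independent fractional
Brownian motion with Hurst exponent $H = \alpha/2$, scaled so that
$\mathrm{Var}[x(t)] = 2 D t^{\alpha}$ — the standard stationary-increment
Gaussian process realizing the power-law MSD $4 D \tau^{\alpha}$. Synthesis
uses circulant embedding of the fractional-Gaussian-noise covariance
(exact, Davies–Harte construction; eigenvalues memoized per path length)
with a Cholesky fallback for very short paths or indefinite embeddings, so
parameter-recovery tests compare against the exact covariance rather than
an approximation. At $\alpha = 1$ the increments are drawn i.i.d.
directly.

Static localization noise is added per localization (measurement noise, not
process noise), which raises the observed MSD by a constant
$\approx 4\sigma_\mathrm{loc}^2$. The through-origin $D_\mathrm{eff}$ fit is
therefore positively biased at small $\tau$ when noise is large relative to
motion; the tests quantify this against the analytic expectation, and a
free-intercept option (`fitDeff(intercept = TRUE)`) is available when the
offset matters. Defaults mirror a typical yeast-cytoplasm acquisition:
$\Delta t = 0.5$ s, 240 frames, 0.18 μm pixels, several hundred
trajectories per condition, $D$ of order $10^{-2}$ μm²/s and
$\alpha \le 1$, localization noise 0.02 μm.

Start positions are uniform over the field with no boundary reflection (no
confinement model is imposed); motion is 2D; photobleaching, blinking and
camera gain are not modelled. Because fBm is *assumed*, recovery tests show
that the estimators are correct for a process that exactly obeys the
power-law MSD — they cannot show that real μNS or mRNP motion is fBm, nor
do they probe obstructed-diffusion alternatives with the same MSD form.

`renderMovie()` turns trajectories into synthetic 16-bit TIFF movies:
particles become 2D Gaussians (σ default 1.2 px, truncated at 4σ) at their
subpixel positions on a constant background, with optional Poisson or
Gaussian camera noise. Per-particle peak amplitudes are log-normal
(`peakSdLog`) to emulate the brightness heterogeneity of self-assembling
probes, which the intensity-distribution analysis needs as input.

## Tracking

The detector is a deliberately simplified re-implementation of the
percentile-threshold local-maximum scheme used by common SPT plugins, with
the published parameter semantics: candidate spots are strict local maxima
in a $(2r+1)$ square window whose value exceeds the $(100-p)$th intensity
quantile of the frame (with `radius` $r = 2$ and `percentile` $p$ set per
movie), refined by an intensity-weighted centroid over the radius-$r$ disk.
Two implementation choices matter numerically:

* the frame median is subtracted (clamped at zero) before the centroid, a
  robust flat-background estimate;
* the centroid disk is iteratively re-centred on the refined estimate
  (up to 8 iterations, converging in 2–3). A disk fixed at the integer
  maximum shrinks subpixel offsets toward the pixel grid ("pixel locking",
  ~0.14 px bias at a 0.3 px offset for σ = 1.2 px); re-centring reduces the
  bias to ~0.03 px, within the 0.1 px the round-trip tests require.

The `cutoff` score filter of the original tools is not reproduced: the
published setting `cutoff = 0` disables it, and only that value is
accepted. Linking is frame-to-frame (link range 1, no gap closing) among
pairs within `maxDisp` (default 5 px), minimizing squared displacement as
appropriate for Brownian dynamics. The default assignment is greedy in
ascending distance with deterministic (track id, detection order)
tie-breaking; an exact Hungarian solver (`method = "hungarian"`,
$O(n^3)$ shortest augmenting paths) is available when crossing particles
make greedy matching suboptimal. Particle intensity is measured along each
trajectory as the mean of raw pixel values within a fixed disk of radius
3 px of the rounded position (centre pixel included, distances between
pixel centres), averaged over tracked frames; edge-clipped disks use their
in-field portion and are flagged.

## Statistics across conditions

Fold changes are computed per replicate and then averaged (mean ± SD),
mirroring the "median $D_\mathrm{eff}$ from 3 biological replicates"
construction, rather than pooling trajectories across replicates. The
paired t-test runs on the per-replicate medians; with three replicates this
is a 2-df test, a real limitation of the design that the package reports
rather than repairs. Because it is ambiguous whether such a test should be
formed on the paired raw medians or on the fold changes against 1, both are
computed and labelled in `ComparisonResult`. If every paired difference is
exactly zero the statistic is undefined and the result is flagged
degenerate instead of being given a p-value. Intensity distributions are
summarized as normalized histograms with median and IQR, and compared
between conditions with a Wilcoxon rank-sum test.

## Numerical choices and tie-breaks

* Frames are 0-based everywhere; times in seconds; positions in μm in all
  analysis tables (pixels exist only inside tracking and rendering).
* Pixel centres sit at integer 0-based coordinates; x is the column index,
  y the row index.
* The median uses the standard mean-of-central-two definition for even
  counts.
* Detection returns spots ordered by (y, x); linking sorts detections by
  (frame, y, x) before assignment, so results are independent of input row
  order.
* `fitDeff` on an all-zero MSD returns $D_\mathrm{eff} = 0$ with an
  undefined $R^2$ rather than failing.
* One integer seed drives each simulated condition through a single RNG
  stream; identical configurations reproduce outputs bitwise. The pipeline
  derives one stream per condition entry from the top-level seed.

## Problem sizes in the test suite

The parameter-recovery checks run at the scale of a real experiment where
that is cheap (1000 trajectories × 240 frames for the Brownian-prefactor
and exponent-recovery checks; 800 trajectories per condition for
fold-change recovery) and at reduced scale where rendering is involved
(20 particles × 100 frames × 160² px for the movie round trip, SNR 10).
Monte-Carlo tolerances (3% on the Brownian prefactor, 10% on fold changes,
±0.05 on $\alpha$, 15% through the rendering round trip) reflect the
sampling noise of those ensemble sizes.

## Known limitations

* Gap closing (`linkRange > 1`), track splitting/merging, drift correction
  and 3D tracking are out of scope.
* The detector assumes a flat background; structured cellular background
  would need local background estimation.
* $D_\mathrm{eff}$ from a through-origin fit inherits the localization-noise
  offset; comparisons between conditions with very different noise levels
  should use the free-intercept option.
* The fBm generator models stationary increments only; confined or
  obstructed diffusion with the same short-time MSD is indistinguishable to
  these estimators.
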