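---
title: "speckleQuant: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{speckleQuant: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speckleQuant)
```

# Scope

speckleQuant quantifies punctate sub-nuclear protein accumulations
("nuclear speckles", here diffraction-limited foci of roughly 0.24 µm) in
single-channel time-lapse fluorescence microscopy, and the molecular
mobility of the tagged protein measured by photobleaching. It covers five
analysis stages — speckle segmentation and morphometry, single-particle
tracking, motion classification by the moment scaling spectrum, FRAP/FLIP
curve analysis, and two-channel co-localization — plus a synthetic-data
module that generates every input with known ground truth, so each stage
is validated against planted truth rather than against another tool.

This vignette documents the models behind each stage, the tunable
parameters with their defaults and units, the numerical choices, and what
the synthetic validation does and does not establish about real data.

# The synthetic-data module

Every simulator is deterministic given a seed and leaves the caller's RNG
stream untouched.

## Trajectories

`simulateTrajectory()` draws 2-D paths under five motion models:

* **static** — the particle does not move;
* **brownian** — i.i.d. Gaussian steps with per-axis variance $2 D \Delta
  t$ (µm², with $D$ in µm²/s);
* **confined** — Brownian steps with a reflecting circular boundary of
  radius `corralRadius` (µm) about the starting point. A step that would
  leave the corral is reflected radially ($r \mapsto 2R - r$). This is the
  simplest mechanism that reproduces sub-Brownian moment scaling and
  stands in for speckles trapped at, or tethered to, nuclear structures;
* **directed** — Brownian steps plus a constant drift $v \Delta t$ along
  one random direction fixed per trajectory (directionality without a
  prescribed route, as for motor-driven cargo);
* **ballistic** — pure drift (a perfectly straight line).

Localization noise (i.i.d. Gaussian per frame and axis, s.d. `locNoise`
µm) is added after the true path is built. With this per-axis convention
the ensemble 2-D MSD acquires a constant offset of $4\sigma^2$ (two axes
times two independently-perturbed frames), which the tests assert.

Defaults mirror the acquisition this package targets: 50 ms frame
interval and 0.1 µm/px. The pixel size is a required calibration input
everywhere — it is never hard-coded into an analysis result.

## Movies, photobleach traces, channel pairs

`renderSpeckleMovie()` renders each speckle as a 2-D Gaussian (s.d.
`speckleSigma`, default 0.1 µm ≈ 1 px) on a constant background inside an
elliptical nucleus; all planted centres lie inside the ellipse, optionally
with a minimum pairwise separation. Photon noise is applied last; the
default is Gaussian with s.d. proportional to the local intensity
(`noiseSd` is the relative s.d.), which is adequate for the estimators
tested here and simpler than a full Poisson–Gaussian camera model; a
Poisson option exists.

`simulateFrapTrace()` produces the three raw ROI series of a FRAP
experiment — bleached region (ROI1), acquisition control (ROI2), constant
background (ROI3) — with the protocol defaulting to 10 pre-bleach and 290
post-bleach frames at 300 ms. ROI1 drops by `bleachDepth` at the bleach
and recovers as a single exponential with rate $c = \ln 2 / t_{1/2}$
toward the plateau set by the mobile fraction; ROI1 and ROI2 share a
per-frame multiplicative acquisition-bleach decay; a constant offset is
added to every ROI and noise is multiplicative. On the noiseless trace the
full-scale-normalized plateau equals the mobile fraction exactly — this is
an invariant of the construction, not a fitted property.

`simulateFlipTrace()` generates the complementary fluorescence-loss
experiment: the monitored, non-bleached region drains exponentially toward
a floor while another region is bleached repeatedly.

`simulateColocPair()` renders two channels that share a planted fraction
of spot centres; the remainder are placed independently. The planted
fraction is the ground truth against which the Manders estimates are
checked.

What the generator deliberately does **not** emulate: 3-D optics and
z-drift, realistic PSFs, anomalous diffusion (CTRW/fBm), nucleolar
exclusion beyond the elliptical mask, uneven illumination, and detector
artefacts. Passing the planted-truth suites therefore demonstrates
estimator correctness under the stated models, not robustness to every
property of real images.

# Segmentation

Per frame: (1) background subtraction; (2) Li threshold; (3) watershed
split; (4) hole filling; (5) size filter; measurements are redirected to
the original, unprocessed frame.

* **Background** (`bgRadius`, default 5 px): greyscale morphological
  opening with a disc — the standard rolling-ball interpretation of a
  "5-pixel" background filter. A median-filter alternative sits behind
  `bgMethod = "median"`. Objects must be smaller than the structuring
  element to survive subtraction, which holds for diffraction-limited
  speckles.
* **Threshold**: Li's minimum cross-entropy threshold, iterated on the
  full intensity histogram of the background-subtracted frame
  (`liThreshold()`); frames where the iteration degenerates fall back to
  Otsu with a warning. Empty or constant frames yield zero speckles, not
  an error.
* **Watershed**: touching objects are split by a watershed on the lightly
  smoothed (Gaussian, σ = 1 px) background-subtracted intensity restricted
  to the mask. A watershed on the distance transform of the binary mask —
  the classic binary watershed — cannot separate overlapping Gaussian
  spots at all: their joint above-threshold mask is oval, with no waist
  for the distance map to cut, and we verified the distance map is flat
  across such a blob. Intensity saddles do separate them. The merge
  tolerance adapts to the dynamic range above the threshold (20% of it),
  so noise-induced maxima inside a single spot do not oversplit it.
* **Size filter** (`minAreaPx`, default 10 px): components below the
  minimum area are discarded; raising the minimum can only reduce the
  count (a tested monotonicity property).
* **Measurements**: intensity-weighted centroids (0-based continuous
  pixel coordinates, sub-pixel), pixel and physical area
  (`area_um2 = area_px * pixelSize^2`), mean intensity — all on the
  original frame.

`summarizeSpeckles()` reports arithmetic per-frame means of count and
area plus the fraction of the nucleus area covered (total speckle area
over nucleus-mask area); the fraction is `NA` without a mask, never a
silent zero.

# Tracking

`detectParticles()` restores the frame by boxcar smoothing over a disc of
`radiusPx` (default 5 px), keeps local maxima in the upper `percentile`
(default 5%) of restored intensity, refines each candidate to an
intensity-weighted sub-pixel centroid within the disc (on the raw frame
after subtracting the local window minimum) and records the intensity
moments m0 and m2. The cited particle tracker's non-particle
discrimination operates on clustering of intensity moments; here the
discrimination score is defined directly as the restored peak height above
the image median in units of five robust standard deviations of the
restored image, so the default `cutoff = 1` keeps peaks that stand at
least five robust s.d. above background — the same intent (reject noise
maxima that survive the percentile gate) in an explicitly verifiable form.

`linkParticles()` assigns detections between consecutive frames by
optimal bipartite matching on squared displacement among pairs within
`maxDisplacementPx` (default 5 px), maximizing the number of links first
and the total squared displacement second; a greedy nearest-neighbour
variant sits behind `method = "greedy"`. Detections are sorted by (x, y)
within each frame before matching, making the result invariant to
detection order. Unmatched detections open tracks; tracks not extended
within `linkRange` frames (default 1 — consecutive linking, gap closing
available) terminate. Every detection belongs to exactly one track.

# Motion analysis

For a trajectory $r(t)$ sampled at interval $\Delta t$, the
displacement moments are

$$\mu_\nu(\delta) = \big\langle |r(t+\delta) - r(t)|^\nu \big\rangle_t,
\qquad \nu \in \{0, 0.5, \dots, 6\},$$

and the scaling exponent $\gamma_\nu$ is the least-squares slope of
$\log \mu_\nu$ against $\log \delta$. The slope of $\gamma_\nu$ versus
$\nu$ (free intercept) is the **SMSS** $\beta$: 0 for a static object,
0.5 for free Brownian diffusion ($\gamma_\nu = \nu/2$), 1 for ballistic
motion ($\gamma_\nu = \nu$); confinement pushes $\beta$ below 0.5 and
drift pushes it above. The raw slope is preserved; the reported value is
clamped to the physical range [0, 1].

**Lag range.** Moments are estimated at lags from one frame up to 5% of
the trajectory length (floor of 5 lags; `maxLagFraction` is
configurable). Long lags are excluded deliberately: at a lag of
$\delta$ frames a track of $n$ points holds only about $n/\delta$
effectively independent displacements, and sample moments of order up to
6 collapse badly in that regime, biasing $\gamma_\nu$ — and hence
$\beta$ — downward. Empirically, on 1000-step Brownian tracks the
ensemble-mean SMSS is ≈ 0.49 with the 5% rule but drops to ≈ 0.46 when
lags up to 25% of the track are fitted; the short-lag rule is the
standard bias/variance compromise for moment estimation and is what the
package validates its anchors against.

**Speed** is the mean frame-to-frame displacement magnitude divided by
the frame interval, in µm/s (for a 2-D Brownian walk the expected step is
$\sqrt{\pi D \Delta t}$, a closed form the tests exploit). The net speed
(net displacement over elapsed time) is computed alongside, since either
convention appears in practice; the mean step speed is the reported one.
Speed without calibration is an error, never silently px/frame.

**Classification** bins $\beta$ with defaults symmetric around the
analytic anchors: static $< 0.05$; restricted Brownian $[0.05, 0.45)$;
Brownian $[0.45, 0.55]$; directed $(0.55, 0.9)$; ballistic $\ge 0.9$.
No published threshold set exists for this choice, so the bins are fully
configurable; consequently a reported static/restricted split is a
function of these bins and is not claimed as an exact reproduction of any
particular observed split. Tracks shorter than 20 points (configurable)
or with frame gaps are flagged and excluded from the MSS rather than
fabricated.

# Photobleaching analysis

## FRAP normalization

With ROI1 = bleached region, ROI2 = control, ROI3 = background:

1. subtract the time-averaged ROI3 from ROI1 and ROI2;
2. divide each by its own pre-bleach mean;
3. form $R(t) = \mathrm{ROI1}(t)/\mathrm{ROI2}(t)$ — any multiplicative
   acquisition bleaching shared by the two regions cancels *exactly* in
   this ratio (a tested 1e-10 property, not an approximation);
4. full-scale normalize with the first post-bleach value $R_p$:
   $F(t) = (R(t) - R_p)/(1 - R_p)$, so $F = 0$ at the first post-bleach
   frame and $F = 1$ at complete recovery. Time is 0 at the first
   post-bleach frame.

The exact algebra of this chain is a reconstruction: steps (1)–(2) and
the role of $R_p$ as the first post-bleach value follow the source
protocol's prose, and the full-scale step is the standard double
normalization of the FRAP literature. A plain-ratio variant (stop after
step 3) sits behind `fullScale = FALSE`. $R_p \ge 1$ ("no detectable
bleach") and non-positive control intensities are hard errors.

## Curve fitting

`fitFrap()` fits $f(t) = b + (a-b)e^{-ct}$ by Levenberg–Marquardt least
squares with multi-start initialization ($a$ from the first point, $b$
from the tail mean, $c$ from the time to half recovery, plus rate and
plateau perturbations of these), keeping the lowest-RSS converged fit.
The **mobile fraction** is the fitted plateau $b$ on the full-scale
curve — fitted, not read off the last points, so over-recovery values
slightly above 1 are expected on noisy traces and are preserved raw
(clip only for summaries). The **half-time** is $t_{1/2} = \ln 2 / c$,
an identity that holds to machine precision for every converged fit. A
fit driven to the rate lower bound, or whose amplitude is buried in the
residual noise, reports `converged = FALSE` with `NA` parameters — a
noise-only trace never yields a fabricated half-time.

`fitFlip()` applies the same machinery to the monitored (non-bleached)
ROI of a FLIP experiment: background subtraction, pre-bleach
normalization, then a single-exponential decay toward a free floor.

**Acquisition design for validation.** The parameter-recovery suite runs
a grid of mobile fraction {0.5, 0.8, 0.95, 1.0} × half-time {5, 34, 60} s
at 2% multiplicative noise. The plateau of an exponential is only
identifiable when the acquisition spans several half-lives, so the grid
is acquired over 300 s (1000 post-bleach frames at 300 ms), five
half-lives of the slowest cell; an 87 s acquisition covers just 1.45
half-lives of a 60 s recovery and leaves the plateau under-determined
regardless of the estimator. Recovered medians are within 0.02 (mobile
fraction) and 5% (half-time) across the grid.

# Co-localization

`costesThreshold()` finds automatic per-channel thresholds: an orthogonal
regression line $ch_2 = m\,ch_1 + q$ is fitted, a candidate threshold
$T_1$ descends through the sorted distinct channel-1 intensities with
$T_2 = m T_1 + q$, and the scan stops at the highest pair whose
below-threshold pixels ($ch_1 < T_1$ and $ch_2 < T_2$) are no longer
positively correlated. Three deliberate choices:

* **Regression on standardized intensities** (equivalently, reduced major
  axis, $m = \mathrm{sign}(s_{12}) \cdot sd_2/sd_1$). Raw-unit total
  least squares is not equivariant under per-channel intensity scaling —
  rescaling one channel would change the thresholds and hence the
  Manders coefficients, violating a property these coefficients must
  have — and its slope is numerically unstable when the channels are
  weakly correlated. The standardized form fixes both; ordinary least
  squares remains available (`regression = "ols"`).
* **Stopping rule** (`criterion`): the default `"nonsignificant"` stops
  when the below-threshold correlation is no longer *significantly*
  positive ($r \le 1.96/\sqrt{n-3}$, with at least 10 pixels below). The
  canonical strict rule $r \le 0$ is kept as `"nonpositive"`, but on
  truly independent channels the sample correlation fluctuates around
  zero and the strict rule walks arbitrarily deep into the intensity
  distribution before a chance crossing, producing large spurious
  coefficients; the significance rule stops at the top, reporting
  thresholds near the maxima and co-localization near zero, which is the
  correct answer for independent channels. A `"fraction"` variant
  ($r < 0.05\,r_{global}$) is also exposed.
* **Scan over distinct intensities**, not unit steps, for bit-exact
  determinism at any bit depth; the scan's incremental-sum implementation
  is tested for exact threshold agreement against an exhaustive
  brute-force search on small discrete images.

A non-positive regression slope means no positive-correlation region
exists (anti-correlated channels): thresholds are reported at the channel
maxima with a warning flag rather than scanned.

`mandersCoefficients()` reports the thresholded convention by default —
$tM_1 = \sum ch_1[ch_1 > T_1 \wedge ch_2 > T_2] / \sum ch_1[ch_1 > T_1]$
and symmetrically — with the single-condition variants $M_1, M_2$
computed alongside, since implementations differ and the source tool's
exact variant is not printed. A coefficient with no above-threshold
signal in its denominator is `NA` (flagged), never 0.

# Pipeline, units and I/O

Internally everything is pixels and frames; conversion to µm and seconds
happens in exactly one place per quantity (trajectory/speckle accessors),
driven by the mandatory `pixel_size` and `frame_interval` of the run
configuration. `runSpecklePipeline()` writes every intermediate (speckle
table, summaries, tracks, per-track motion table) plus a provenance
record with all parameters, the seed and the package version. Movies
travel as multi-page 16-bit TIFF (intensities scaled by 1/65535 on
write), tables as comma/UTF-8/header CSV, configuration as YAML.
`makeFixtures()` materializes the canonical validation suites
deterministically (byte-identical per seed). A thin command-line wrapper
(`inst/scripts/specklequant.R`) exposes segment / track / motion / frap /
flip / coloc / pipeline / fixtures subcommands over these functions.

# Validation scales and limitations

The shipped validation uses problem sizes chosen to exercise the
estimators well inside their asymptotic regime while keeping the whole
suite interactive: 200 trajectories of 1000 steps for the SMSS anchors
(ensemble mean 0.5 within ±0.03 for Brownian input, 1 for ballistic, 0
within ±0.03 for static-with-noise); 50 replicate traces per cell of the
FRAP grid; 20 replicate scenes for planted segmentation counts and
planted co-localization fractions.

Known limitations: segmentation assumes speckles smaller than the
background-filter radius; the tracker's discrimination score is a
simplified stand-in for moment-space clustering and is calibrated on
Gaussian spots; MSS classification needs gap-free tracks of ≥ 20 frames
and its class boundaries are conventions; FRAP fitting is a single-pool
reaction-free model (no reaction–diffusion, two-component or spatial
profile analysis); co-localization is single-plane and offers no
scrambling-based significance test. All synthetic validation shares the
generator's simplifications listed above.
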