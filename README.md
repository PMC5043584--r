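# speckleQuant

Quantitative analysis of nuclear speckle dynamics from fluorescence
microscopy, in R.

Some nuclear transcription factors — the hypoxia-inducible factor subunit
HIF-2α is the motivating case — concentrate in small, highly mobile
sub-nuclear foci ("speckles", ~0.24 µm across, tens to hundreds per
nucleus) instead of distributing homogeneously. Quantifying that biology
from time-lapse microscopy needs four linked analyses, and this package
implements all of them against a common set of calibrated data
structures, for cell biologists and imaging scientists who want the whole
chain scriptable and testable:

* **Segmentation & morphometry** — per-frame speckle counts, areas and
  intensities: rolling-ball background subtraction, Li (minimum
  cross-entropy) threshold, watershed splitting of touching spots, hole
  filling, size filter, with measurements redirected to the unprocessed
  frame (`segmentSpeckles`, `summarizeSpeckles`).
* **Single-particle tracking** — sub-pixel spot detection (radius 5 px,
  top 5% intensity candidates, discrimination cutoff 1) and optimal
  frame-to-frame linking within a 5 px gate (`detectParticles`,
  `linkParticles`, `trackSpeckles`).
* **Motion classification** — per-trajectory speed and the moment
  scaling spectrum: displacement moments
  µ_ν(δ) = ⟨|r(t+δ) − r(t)|^ν⟩ for ν = 0…6 scale as δ^γ_ν, and the slope
  β of γ_ν versus ν (the SMSS) classifies motion — β = 0 static, 0.5
  free Brownian, 1 ballistic, with restricted (confined) and directed
  Brownian in between (`computeMSS`, `computeSMSS`, `classifyMotion`,
  `analyzeMotion`).
* **Photobleaching** — FRAP/FLIP traces are background-subtracted,
  pre-bleach normalized, ratio-corrected for acquisition bleaching and
  full-scale normalized, then fitted with f(t) = b + (a−b)·exp(−ct): the
  mobile fraction is the fitted plateau b and the half-time ln 2 / c
  (`normalizeFrap`, `fitFrap`, `fitFlip`).
* **Co-localization** — Costes automatic thresholding (descending scan
  along the orthogonal-regression line until the below-threshold
  correlation is no longer significantly positive) and thresholded
  Manders coefficients tM1/tM2 (`costesThreshold`,
  `mandersCoefficients`, `colocalize`).

A first-class synthetic-data module (`simulateTrajectory`,
`renderSpeckleMovie`, `simulateFrapTrace`, `simulateFlipTrace`,
`simulateColocPair`, `makeFixtures`) generates movies, traces and channel
pairs with known ground truth, so every estimator above is validated
against planted truth in the test suite.

## Worked example

Simulate a nucleus with 30 confined speckles (D = 0.1 µm²/s inside
0.2 µm corrals, 60 frames at 50 ms, 0.1 µm/px), then run the full
pipeline:

```r
library(speckleQuant)

scene <- sceneSpec(nSpeckles = 30L, imageSize = c(256L, 256L),
                   nFrames = 60L, minSeparation = 18, noiseSd = 0.03)
movie <- renderSpeckleMovie(scene,
                            motionModel("confined", D = 0.1,
                                        corralRadius = 0.2), seed = 1)
cfg <- runConfig(pixel_size = 0.1, frame_interval = 0.05, seed = 1,
                 motion = list(minPoints = 50L))
res <- runSpecklePipeline(movie$stack, cfg,
                          nucleusMask = movie$nucleusMask)
str(res$speckleSummary)
#> List of 3
#>  $ meanCountPerFrame  : num 30
#>  $ meanAreaUm2        : num 0.154
#>  $ fractionNucleusArea: num 0.014
str(res$motionSummary[c("nTracks", "meanSpeed", "meanSMSS")])
#> List of 3
#>  $ nTracks  : int 30
#>  $ meanSpeed: num 2.11
#>  $ meanSMSS : num 0.198
```

All 30 planted speckles are found in every frame; the mean SMSS of 0.198
sits in the restricted-Brownian band (0.05–0.45), which is exactly what
corralled diffusion should produce, and every track is classified
restricted Brownian. A FRAP trace simulated at the conditions typical for
this protein (mobile fraction 0.95, half-time 34 s, 10 pre-bleach + 290
post-bleach frames at 300 ms, 2% noise) fits back to:

```r
fitFrap(simulateFrapTrace(frapSimParams(mobileFraction = 0.95,
                                        tHalf = 34), seed = 1))
#> FrapFit (recovery): a = -0.002495, b = 0.9612, c = 0.02031 1/s;
#>   tHalf = 34.13 s, mobile fraction = 0.9612 (rss 0.176, n = 290)
```

and a two-channel pair with half the spot centres shared recovers the
planted overlap:

```r
pair <- simulateColocPair(100, 0.5,
                          sceneSpec(imageSize = c(192L, 192L),
                                    minSeparation = 5), seed = 1)
colocalize(pair$ch1, pair$ch2, mask = pair$nucleusMask)
#> ColocResult: 18513 pixels, global Pearson r = 0.466
#>   Costes thresholds: T1 = 10.9, T2 = 10.9
#>   tM1 = 0.504 (50.4%), tM2 = 0.503 (50.3%)
```

A thin CLI over the same functions lives at
`inst/scripts/specklequant.R` (subcommands `segment`, `track`, `motion`,
`frap`, `flip`, `coloc`, `pipeline`, `fixtures`).

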