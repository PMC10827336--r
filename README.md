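# lascaTrack

Laser speckle contrast imaging (LSCI) turns raw coherent-light images of
tissue into maps of relative blood flow: moving red blood cells blur the
speckle pattern during the exposure, so the local speckle contrast

```
K = sigma / <I>          (std. dev. over mean of intensity in a window)
```

falls from 1 (static tissue) towards 0 (fast flow), and the relative flow
index `1/K^2` rises proportionally to flow speed (reported in arbitrary
units, AU). Clinicians quantify wound perfusion by averaging the flow
index inside a region of interest (ROI) drawn over the lesion — but
patients with painful wounds cannot hold still, the lesion drifts out of
the fixed ROI, and the perfusion trace is corrupted.

`lascaTrack` is an R package for this whole analysis chain, aimed at
researchers building or validating LSCI perfusion pipelines:

* **speckle contrast & flow index** — spatial (sliding-window) and
  temporal contrast, `1/K^2` flow maps, blue-to-red perfusion rendering,
  contrast-threshold background segmentation;
* **ROI geometry** — circular and polygonal ROIs with sub-pixel
  positions, rasterization, analytic areas, mean-intensity extraction,
  circumscribed bounding boxes;
* **automatic ROI tracking** — a discriminative correlation filter with
  spatial reliability (foreground masking of the trained filter) and
  channel reliability (peak-to-sidelobe-weighted feature channels),
  plus the displacement-threshold rule that suppresses bounding-box
  jitter: the ROI moves only when the tracked displacement exceeds a
  threshold (default 1 px);
* **agreement statistics** — two-way random, single-measure,
  absolute-agreement intraclass correlation, ICC(2,1):
  `rho = sigma_B^2 / (sigma_B^2 + sigma_W^2)`, computed from ANOVA mean
  squares, with the conventional poor/moderate/good/excellent bands at
  0.5 / 0.75 / 0.9, and a moving-average motion-artifact filter;
* **a dynamic-speckle simulator** — fully developed speckle (exponential
  intensity statistics), per-region decorrelation times, occluding lesion
  patches, rigid motion with ground-truth trajectories, physiological
  flow modulation and 16-bit digitization — so the entire chain is
  testable without hardware.

## Worked example

Simulate a moving lesion, track it, and measure manual-vs-automatic
agreement:

```r
library(lascaTrack)

cfg <- slowScenario(seed = 11)       # 1 x 2 cm occluding patch, 2 px/frame
res <- runAgreementExperiment(cfg, runConfig())
res@icc$R1
#> ICC(2,1) = 0.9420 [excellent]  (sigmaB2 = 2941, sigmaW2 = 181.2, n = 48, k = 2)

fast <- runAgreementExperiment(fastScenario(seed = 11), runConfig())
fast@icc$C1
#> ICC(2,1) = 0.0173 [poor]  (sigmaB2 = 2807, sigmaW2 = 1.598e+05, n = 48, k = 2)
```

The slow scenario is the regime where tracking works: the tracked trace
matches perfect per-frame repositioning and the ICC lands in the
excellent band. In the fast scenario a small circular ROI at the tissue
edge sweeps at 15 px/frame — beyond the tracker's 10 px search radius —
so the tracker lags, the ROI reads the wrong tissue/background mixture,
and agreement collapses; with `runConfig(tracking = FALSE)` the ROI stays
at its initial coordinates and agreement is again substantially worse
than with tracking.

Single pieces work standalone:

```r
k <- spatialContrast(matrix(1:9, 3, 3, byrow = TRUE), 3)
kValues(k)[2, 2]                     # 0.5163978 = popsd(1:9) / mean(1:9)

roiArea(circleRoi(0, 0, 20), pixelScaleCm = 0.025)   # 0.7853982 cm^2
roiArea(rectRoi(0, 0, 40, 80), pixelScaleCm = 0.025) # 2 cm^2
```

A thin CLI wraps the same functions
(`Rscript inst/cli/lasca.R <simulate|process|agree|filter> ...`), reading
multi-page TIFF stacks or PNG/PGM frame directories and writing trace,
trajectory and ICC-report CSVs.

## Package layout

S4 classes with validity checks (`FrameStack`, `ContrastImage`,
`FlowIndexImage`, `CircleRoi`/`PolygonRoi`, `BoundingBox`,
`TrackerState`, `PerfusionTrace`, `IccResult`, `SimulationConfig`,
`ExperimentResult`) with accessor generics; module code under `R/`
(`speckle-core`, `roi-geometry`, `dcf-tracker`, `speckle-simulator`,
`reliability-stats`, `pipeline`, `io`); methods vignette under
`vignettes/`.
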