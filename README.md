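# pdquant

Quantitative microscopy and assay analysis for chitin-triggered
plasmodesmata closure in plants.

Plasmodesmata are membrane-lined channels that connect the cytoplasms of
neighbouring plant cells; callose deposition around their necks closes them
during immune signalling. The experimental readouts of this process are
almost entirely quantitative-microscopy statistics, and `pdquant`
implements each of them together with a synthetic-data generator that
produces every input modality with known ground truth, so the whole
analysis chain is testable without any raw microscope exports:

* **Callose punctum quantification** — 3D spot detection in confocal
  z-stacks (Gaussian smooth → top-hat background suppression → threshold →
  26-connected components → size gate), with per-spot integrated
  fluorescence measured on the original voxels.
* **PD index** — the ratio of mean fluorescence in plasmodesmata ROIs to
  neighbouring plasma-membrane ROIs, `PD index = I_PD / I_PM`; values > 1
  indicate plasmodesmal enrichment of a tagged protein.
* **Steady-state fluorescence anisotropy** (homo-FRET) with the
  objective-NA-corrected formula
  `r = (I∥ − G·I⊥) / ((1 − 3L2)·I∥ + (2 − 3L1)·G·I⊥)`,
  default calibration G = 0.481, L1 = 0.013, L2 = 0.037; photon-weighted
  per-ROI estimates.
* **FRET-FLIM** — TCSPC decay fitting by Poisson maximum likelihood under a
  periodic (40 MHz) multi-exponential model convolved with the IRF;
  amplitude-weighted average lifetime `τ_Av = Σαᵢτᵢ / Σαᵢ`; FRET efficiency
  `E = 1 − τ_DA/τ_D` and condition contrasts with bootstrap CIs.
* **FRAP** — double normalization against background and reference ROIs,
  endpoint (60 s) or exponential-plateau mobile fraction
  `Mf = 100·(F_eval − F₀)/(1 − F₀)`, Welch group comparisons.
* **ROS burst** — trapezoidal integration of background-corrected luminol
  luminescence over the first 25 min after elicitation.
* **Connectivity statistics** — bombardment-assay GFP-spread counts
  normalized to within-genotype mock means, Mann–Whitney / permutation
  treatment tests, notched boxplot summaries, and one-way ANOVA + Tukey HSD
  with a compact letter display.

## Worked example

```r
library(pdquant)

## callose quantification on a synthetic 3-plane stack
mosaic  <- makeCellMosaic(192, 192, 10, seed = 1)
callose <- renderMembraneStack(mosaic, nZ = 3, pdPer100um = 6,
                               pdIndexTrue = 8, pmIntensity = 10,
                               readNoiseSd = 2, seed = 2)
detectSpots(callose$stack, SpotDetectionParams())
#> SpotSet: 7 spots, total fluorescence 2.37e+04, mean 3386

## PD index on a single-plane membrane image rendered at truth 2.0,
## with ROIs at annotated punctum positions (hand-drawn in practice)
img  <- renderMembraneStack(mosaic, nZ = 1, pdIndexTrue = 2,
                            pmIntensity = 50, psfSigma = 0.8,
                            readNoiseSd = 2, seed = 3, nPuncta = 10)
rois <- deriveRois(spotTruth(img$truth), boundaryMask(img$truth))
computePdIndex(img$stack, rois, plane = 1)
#> $pdMean   99.9
#> $pmMean   50.2
#> $pdIndex  1.99

## FLIM: fit a quenched biexponential decay and convert to FRET efficiency
h   <- simulateDecay(c(1.2, 2.9), c(0.17, 0.83), 1e5, seed = 4)
fit <- fitDecay(h, IRFModel("gaussian", center = 2, sigma = 0.1), 2)
fit
#> LifetimeFit (2 components): tau = 1.205, 2.910 ns, alpha = 0.177, 0.823
#>   tau_Av = 2.6086 ns, background = 5.63e-08 counts/bin, deviance = 259
fretEfficiency(tauAv(fit), 2.9)
#> 0.100  (10% of donor excitations transferred)

## anisotropy with the instrument calibration constants
computeAnisotropy(PolarizedPair(200, 100), CalibrationConstants())
#> 0.558
```

The detected spot count (7), the recovered PD index (1.99 against a
constructed truth of 2.0) and the FRET efficiency (0.100 against an
injected 0.10) are what the code above actually prints; the lifetime fit
recovers the injected 1.2 / 2.9 ns components and their amplitudes from
10^5 photons.

## Acceptance script

`scripts/acceptance.R` recomputes, from scratch, the package's headline
recovery target: it simulates paired mock/chitin FLIM decay sets whose
ground-truth FRET-efficiency difference is 3.4 percentage points
(donor-only lifetime 2.9 ns, 50 biexponential ROI decays per condition,
10^5 photons each, Gaussian IRF σ = 0.1 ns, 40 MHz repetition), runs the
full fit → τ_Av → ΔE chain, and writes the recovered change to JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Layout

* `R/` — S4 classes (`ImageStack`, `SpotSet`, `ROISet`, `DecayHistogram`,
  `LifetimeFit`, `PolarizedPair`, `FrapTrace`, `MosaicGroundTruth`) and the
  analysis/generator functions.
* `tests/testthat/` — unit, property and end-to-end recovery tests.
* `vignettes/pdquant-methods.Rmd` — models, assumptions, parameter
  defaults, numerical choices and known limitations.
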