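---
title: "pdquant: models, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pdquant: models, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdquant)
```

`pdquant` analyses the quantitative readouts used to study
chitin-triggered plasmodesmata closure: callose punctum quantification,
the PD index, steady-state anisotropy (homo-FRET), FRET-FLIM lifetimes,
FRAP mobile fractions, ROS-burst integrals, and bombardment connectivity
counts. This vignette records the models behind each estimator, the
defaults and why they were chosen, what the synthetic generators do and do
not emulate, and the numerical decisions a maintainer would want written
down.

## The synthetic world

Raw data for these assays are microscope exports that are not publicly
deposited, so every analysis stage is validated against a generator with
known ground truth.

**Cell mosaics and membrane stacks.** `makeCellMosaic()` draws a seeded
Voronoi tessellation as a stand-in for an epidermal pavement; the boundary
mask (pixels with a 4-neighbour of another cell) is where plasmodesmata
live. `renderMembraneStack()` paints plasma-membrane signal over the
boundary dilated by `membraneHalfWidth` (default 3 px — cell walls in
confocal sections are several pixels wide), then multiplies small boundary
patches (radius `spotRadius`, default 4 px) by `pdIndexTrue` to make
puncta. Puncta are *multiplicative enrichments of an extended patch*, not
added point impulses, deliberately: the PD-index ground truth is defined
as punctum peak over membrane plateau, and a true point impulse is
attenuated by the PSF far more than the quasi-one-dimensional membrane
ridge, which would make peak-ratio recovery impossible by construction
rather than by measurement error. Each plane is blurred with a circular
(FFT) Gaussian PSF, which conserves total intensity exactly — the sum of
the noiseless image equals the painted membrane mass plus punctum mass to
machine precision — and Poisson shot noise plus Gaussian read noise are
applied last. The 2D blur is applied per plane only; with a typical 0.5 µm
z-step, axial PSF overlap between planes is secondary and is not
modelled. Punctum placement enforces a minimum separation (12 px) so that
ground-truth matching is unambiguous.

What this world does *not* contain: vectorial/asymmetric PSFs, spectral
bleed-through, 3D cell shape (the mosaic is a 2D tessellation extruded
through z), depth-dependent attenuation, or structured autofluorescence.
A green detection test therefore establishes correctness of the pipeline
logic and its noise robustness, not performance on arbitrary tissue.

**TCSPC decays.** Expected bin counts follow a periodic (wrapped) sum of
exponentials convolved with a Gaussian IRF plus a uniform background,
scaled to the requested photon count; observed counts are Poisson. The
25 ns repetition period encodes 40 MHz pulsed excitation, and wrapping
matters: a 2.9 ns fluorophore retains ~18 percent of its intensity at the
end of a 25 ns window, so an unwrapped model would bias fits. The Gaussian
IRF (default σ = 0.1 ns) is a stand-in — the measured instrument response
of the actual TCSPC hardware is not published — and `IRFModel` accepts a
measured histogram where one exists.

**FRAP traces.** Prebleach plateau, instantaneous bleach to
`bleachDepth`, single-exponential recovery toward the mobile plateau, all
fluorescent channels multiplied by `exp(-acquisitionBleachRate * t)`, plus
Gaussian noise; background and reference channels are included. A single
recovery timescale is the minimal identifiable model when the assay
reports only a 60 s endpoint.

**Counts.** Bombardment sites are zero-truncated negative binomial
(mean/dispersion): a scored site shows at least the transformed cell, and
raw count data of this kind are overdispersed. The mock mean defaults to
10 cells/site — the typical scale of GFP spread through one to two rings
of neighbours — chosen once at design time; at much smaller means the zero
truncation itself distorts the treatment ratio. The dispersion default of
5 and the treated/mock ratio of 0.6 reproduce a decisively significant
closure effect at the n ≈ 90 sites/group scale of the real assay.

All generators take a mandatory seed, use an isolated RNG (the caller's
`.Random.seed` is never touched), and are bit-reproducible.

## Spot detection

The pipeline is Gaussian smoothing (σ = 1 px), grayscale top-hat with a
disk of radius 5 px (larger than a diffraction-limited punctum, so compact
bright detail survives and smooth background does not), thresholding, 3D
connected components (26-connectivity), and a 3–200 voxel size gate.
Per-spot statistics are computed on the *original* voxels so smoothing
never biases intensities; spots are reported sorted by integrated
intensity with lexicographic tie-breaks, making output order
deterministic.

Two numerical choices deserve a note:

* **Robustified Otsu.** Otsu's threshold always splits whatever
  distribution it is given; on a spotless noise image it lands inside the
  noise and floods the detector with false components. The default
  threshold is therefore `max(otsu, median + 5·MAD)` of the
  background-suppressed image. On images that contain real puncta the Otsu
  value dominates by an order of magnitude, so behaviour there is
  unchanged; on pure noise the MAD floor keeps false positives at or below
  about one per stack.
* **Monotonicity regime.** Raising an absolute threshold shrinks the
  foreground set, but the *count* of size-gated components is only
  monotone above the background-residual floor: below it, neighbouring
  puncta bridge through residual foreground and merge, so counts can rise
  again as the threshold increases and the bridges break. The property
  tests assert monotonicity in the regime where detection is meaningful.

Detection is intended for the callose channel, where puncta are bright
against faint walls. On low-contrast membrane images (punctum:membrane
ratios near 2, as in PD-index measurements) thresholding cannot separate
puncta from the membrane ridge and ROIs should come from annotation —
which is how the real assay is analysed.

## PD index

`computePdIndex()` is the mean intensity over PD-class ROI pixels divided
by the mean over PM-class pixels on a single user-selected plane, matching
single-plane acquisitions. `deriveRois()` builds PD disks (radius 2 px) at
spot positions and PM ROIs from boundary-mask pixels in a 7–14 px annulus.
Two exclusion rules keep the PM reference honest: PD pixels are removed,
and any pixel within `exclusionRadius` (7 px ≈ punctum radius + 3 PSF σ)
of *any* spot is removed, so a clustered punctum never leaks its PSF skirt
into a neighbour's membrane reference. Without the second rule the index
is biased low by 5–25 percent whenever puncta sit within ~15 px of each
other. Spots whose PM ROI is empty after exclusion are dropped with a
warning rather than silently measured against nothing.

## Anisotropy

The printed form of the corrected anisotropy equation in the source
methods is typographically ambiguous once extracted to plain text. The
implemented default is the standard objective-NA-corrected grouping

r = (I∥ − G·I⊥) / ((1 − 3·L2)·I∥ + (2 − 3·L1)·G·I⊥)

which reduces exactly to the classic (I∥ − I⊥)/(I∥ + 2I⊥) when G = 1 and
L1 = L2 = 0 — the limiting behaviour any correction must have. Two
alternatives are selectable for sensitivity analysis: `"literal"` (no G in
the denominator, the literal character-level parse) and `"classic"`
(L corrections ignored). Per-ROI estimates pool photons (sum both channels
over the ROI, then take the ratio) because averaging per-pixel r is
noise-biased at low counts. The default calibration G = 0.481,
L1 = 0.013, L2 = 0.037 is the instrument calibration used throughout the
worked examples.

## FLIM fitting and FRET

`fitDecay()` maximizes the Poisson likelihood — correct for low-count
TCSPC bins, where least squares is not — of a one- or two-component
periodic exponential model convolved with the IRF, plus a free uniform
background floored at zero. Optimization is BFGS on unconstrained
transforms (log lifetimes, softmax amplitude weights, logit background)
with multi-starts over the lifetime grid {0.5, 1, 2, 4} ns (all pairs for
two components). The two-component search additionally starts from a
perturbed copy of the one-component solution, which guarantees the nested
deviance inequality (two-component deviance ≤ one-component) holds on
every histogram. Fits with fewer than 100 photons are refused.

τ_Av is amplitude-weighted, Σαᵢτᵢ/Σαᵢ, the convention named by the assay's
"average amplitude" phrasing; intensity weighting (Σαᵢτᵢ²/Σαᵢτᵢ) is
available as an option. FRET efficiency is E = 1 − τ_DA/τ_D; negative
values are reported with a warning, not clipped, because they are
informative about fit quality. `deltaFret()` averages per-ROI efficiencies
within condition and reports 100·(E_a − E_b) with a seeded 2000-resample
bootstrap percentile CI. Identifiability note: at 10^5 photons the two
lifetimes of a weakly quenched biexponential are individually noisy, but
τ_Av is strongly constrained — which is exactly why the FRET readout is
built on τ_Av rather than on individual components.

## FRAP

Double normalization,
F_norm(t) = [(F−B)/(R−B)] / mean_pre[(F−B)/(R−B)],
cancels background and acquisition bleaching and fixes the prebleach mean
at exactly 1 (the per-timepoint ratio is normalized by its own prebleach
mean, a formulation that keeps the identity exact even when channels drift
during the prebleach frames). The mobile fraction defaults to the 60 s
endpoint — the assay's reported readout — as
Mf = 100·(F̄_eval − F₀)/(1 − F₀) with F₀ the first postbleach frame and
F̄_eval the mean of `endpointWindow` (default 3) frames nearest t_eval; an
exponential-plateau fit is provided for sensitivity checks and agrees with
the endpoint within 2 percentage points whenever the recovery timescale is
at most t_eval/4. Both estimates are bleach-depth-corrected (the 1 − F₀
denominator); this convention is stated because uncorrected percentages
are also in circulation. Group comparisons use Welch t-tests: different
constructs have no reason to share variances.

## ROS integration

Trapezoidal integration of background-corrected luminescence over 0–25 min
after elicitation, with interpolation at window edges so the integral is
exactly additive over adjacent sub-windows. Background defaults to the
mean of pre-elicitation samples (before t = 0, independent of the chosen
window — estimating it from "pre-window" samples would contaminate
sub-window integrals with burst signal); a paired water-control integral
is the alternative. Trapezoids tolerate the coarse, potentially irregular
sampling of plate readers; no kinetic model of the burst shape is fitted.

## Connectivity statistics

Counts are normalized to the within-genotype mock mean, so mock
normalized counts average exactly 1 per genotype and treatment effects are
comparable across genotypes. The default mock-vs-treated test is the
two-sided Mann–Whitney rank-sum test — counts are non-normal and the
source analysis does not name its test — with a seeded permutation test on
the difference of means as an alternative (optionally stratified by
biological replicate); both are exposed and they agree on strong effects.
Boxplot summaries use type-7 (linear interpolation) quartiles — stated
explicitly because quartile conventions differ across tools — whiskers at
the most extreme values within 1.5 IQR of the quartiles, and notches at
median ± 1.58·IQR/√n, the standard approximate 95% CI of the median.
`anovaTukeyLetters()` runs one-way ANOVA with Tukey HSD and builds a
compact letter display by greedy insert-and-absorb; letters are assigned
in order of decreasing group mean, so output is deterministic, and the
defining bipartite property — two groups share a letter if and only if
their adjusted p-value is ≥ α — is verified exhaustively by the test
suite on every random instance.

Replicate structure is carried as a column but the default analysis pools
sites, as the per-site plots of this assay do; mixed-effects modelling is
out of scope.

## I/O and configuration

No TIFF reader/writer is available in this R environment, so image stacks
round-trip through plain text: a long-format CSV (z, y, x, value) with a
JSON sidecar carrying pixel sizes and channel names. Decays, FRAP traces
and count tables are CSV with JSON sidecars for scalar metadata. The
pipeline configuration is a single hierarchical list validated by
`validateConfig()` (unknown keys rejected, ranges checked, violations
reported together); `runPipeline()` reports carry the package version,
seed and a config hash, and are byte-identical for identical config and
seed.

## Known limitations

* The spot detector is not a deconvolution method; touching puncta merge.
* The PD index assumes the annotated plane contains the punctum; it is a
  2D measurement by design.
* The Gaussian IRF is a stand-in for an unpublished instrument response.
* Anisotropy is steady-state only (no time-resolved anisotropy decays,
  no pixel-wise FLIM maps).
* FRAP yields mobile fractions, not diffusion coefficients — bleach
  geometry is not modelled.
* Synthetic calibration: intensity scales are chosen for realistic SNR,
  not to match any particular detector's gain.
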