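---
title: "Segmenting retinal non-perfusion with local variance maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting retinal non-perfusion with local variance maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vmseg)
```

## The problem and the model

In diabetic retinopathy, capillary occlusion produces retinal non-perfusion.
On en-face OCT-angiography, flow appears bright and avascular tissue dark, so
non-perfused retina is characterized by *two* local properties at once: low
intensity and low spatial texture. On widefield photomontages the vessel
brightness falls off from the macular center toward the periphery, which is
why a single global intensity threshold cannot separate dropout from dim but
perfused periphery. The pipeline therefore classifies each pixel by its
*local variance* — the population variance of its k×k neighborhood — and
keeps an intensity criterion only as a one-sided override: a sufficiently
bright pixel is always vessel, however smooth its neighborhood.

The stages, in order, with the data each consumes:

1. **Normalization.** Min–max rescale to `[0, 255]`. A constant image maps
   to zeros (the degenerate case is exercised in the tests: the whole frame
   then segments as one non-perfusion region, which is the contractually
   correct answer for a texture-free dark image).
2. **Bilateral pre-filter** (window 9 px, σ = 40 for both the spatial and the
   intensity kernel, reflect padding). Damps speckle while preserving
   vessel/dropout boundaries; a Gaussian blur here would smear the very
   edges the variance map must localize.
3. **Variance maps.** `E[X²] − E[X]²` over 3×3 and/or 5×5 and/or 7×7 windows
   (population divisor, reflect padding, negatives from floating-point
   cancellation clipped to 0); several maps are combined by their pixelwise
   mean. Small windows localize boundaries; larger windows suppress noise.
4. **Modification.** The raw map is min–max rescaled to `[0, 255]` with
   homogeneous areas LOW, then every pixel whose *normalized* intensity is at
   or above the **intensity threshold** (default 75) is set to 255. The
   inclusive `≥` resolves ties toward vessel, the conservative direction for
   a non-perfusion detector.
5. **Second bilateral pass** with the same parameters, then **grayscale
   morphology**: closing applied *n* times, then opening applied *n* times
   (cross-shaped 5-px element; default n = 1; n = 0 skips the stage).
   Closing lifts isolated dark specks inside vessel-rich texture; opening
   removes isolated bright pips. We iterate each operation rather than
   alternating close/open pairs; with the default n = 1 the two readings
   coincide.
6. **Binarization** strictly *below* the **variance threshold** (default 17
   on the 0–255 modified scale). Strictness is tested at the boundary: a
   pixel exactly at the threshold is not a candidate.
7. **Hole filling and size filtering.** Background is flood-filled from the
   frame border with 4-connectivity; unreached background (interior holes of
   the 8-connected foreground) is filled, then filled components smaller
   than **250 px** are dropped (a 250-px component is kept, 249 is dropped).
   The pixel pitch is configurable metadata; no mm² constant is hard-coded,
   because the physical area of 250 px depends on the montage scale.

Eliminated pixels (manually cropped artifact areas, conventionally painted
white) are forced to 255 in the modified map *before* smoothing and
morphology — so they can never seed a candidate region — and are subtracted
from the final mask, which guarantees the mask/elimination disjointness
invariant checked in the tests. The whole pipeline is deterministic.

## Parameters

| parameter | default | unit | role |
|---|---|---|---|
| `kernel_sizes` | {3, 5} | px | variance window(s), maps averaged |
| `variance_threshold` | 17 | 0–255 scale | binarization cut, strict `<` |
| `intensity_threshold` | 75 | 0–255 scale | vessel override, inclusive `≥` |
| `morph_iterations` | 1 | count | closing×n then opening×n |
| `size_threshold_px` | 250 | px | minimum kept component area |
| `bilateral_diameter` | 9 | px | both bilateral passes |
| `bilateral_sigma` | 40 | intensity/px | both bilateral kernels |

The three thresholds and the kernel combination are the tuned quantities;
`grid_spec()` defaults to the tuning protocol's ranges (intensity 50–100
step 1, variance 10–30 step 0.5, morphology 0–4, all seven nonempty window
subsets). `grid_search()` evaluates the full Cartesian product — the
coordinate-wise 1-D curves shown in tuning figures are recovered from the
full grid as marginals at the optimum, so the full-grid reading subsumes the
sequential one. Ties are broken toward the smallest variance threshold, then
the smallest intensity threshold, then the fewest iterations: explicit and
reproducible, and biased toward the least aggressive segmentation.

`robustness_analysis()` reruns the search on resampled subsets (default 10
subsets of 70% of the images, drawn image-wise without replacement, seeded).
Because the search is deterministic per image, the per-image × per-grid-point
Dice table is computed once and each repeat only reduces it over its subset —
numerically identical to rerunning the search, at a fraction of the cost.

## The phantom generator

`generate_phantom()` synthesizes what the algorithm keys on, not anatomy:

- background speckle (mean 140, σ = 20) modulated by a radial brightness
  falloff (default 20% center-to-corner) emulating montage vignetting;
- vessels as biased random walks with stroke widths 1–4 px, about half
  branching off existing vessels, drawn until a target density (18%) is
  reached, at intensity ~235 — bright, high-variance curvilinear texture;
- non-perfusion patches as radially jittered ellipses (semi-axes 25–45 px)
  where vessels are erased, intensity drops to ~40 and noise amplitude to a
  quarter — dark and homogeneous, with the closed-form patch area
  πab(1 + amp²/2) kept as bookkeeping (rasterization agrees within 2%);
- an eliminated band painted pure white along one border (4% of the frame).

All randomness flows from one explicit seed; suites vary patch counts so
ground-truth NPIs spread. The phantom reproduces the *contrast structure* of
OCT-A — it does not simulate decorrelation physics, projection artifacts or
device noise spectra, and its dropout contrast is deliberately high. Passing
the phantom suite therefore demonstrates that the implementation does what
the design says on images with the assumed structure; it does not certify
clinical accuracy, which in the study setting was established on expert
annotations (mean test-set Dice ≈ 0.68 on cropped clinical images, i.e.
considerably harder than the phantoms).

## Numerical choices and degenerate inputs

- Population (divide-by-n) variance via mean-of-squares; reflect padding for
  both the variance windows and the bilateral filter; the `E[X²] − E[X]²`
  form can go ~1e-12 negative, so values are clipped at 0.
- Min–max rescales map constant inputs to all-zero rather than erroring.
- The bilateral filter is a convex combination, so its output range is
  bounded by the input range up to floating-point error.
- `bwlabel`'s 4-connected labels are merged across diagonal adjacencies via
  a graph components pass to get the 8-connected foreground components.
- Elimination masks may be supplied as files or derived from pure-white
  paint; the derivation keeps only white regions larger than 100 px so that
  saturated vessel pixels are not mistaken for crop paint.
- Both-empty Dice is defined as 1 (perfect agreement on absence), and
  eliminated pixels are excluded from the Dice tallies, mirroring their
  exclusion from the NPI denominator.

## Problem sizes used in the checks

The test suite exercises the full-size conditions where they matter and
smaller ones elsewhere: the default-parameter accuracy check runs 20
phantoms at 512×512 (mean Dice ≥ 0.8 and NPI Spearman ρ ≥ 0.9 required);
parameter recovery runs 3 phantoms at 256×256 over a reduced grid around
the default optimum (recovery must be exact with mean Dice 1.0, since the
truth is synthesized by the pipeline itself at grid-interior parameters);
the robustness protocol runs 10 resampled 70% subsets of 8 phantoms at
256×256 on a coarsened grid. Variance-map correctness is established
against a brute-force double-loop oracle on one hundred random 32×32
images, and morphology against direct min/max computation on 15×15
fixtures.

## Known limitations

- Parameters tuned on one image format/disease do not necessarily transfer;
  the defaults reflect widefield diabetic-retinopathy montages.
- On uncropped ("raw") clinical images, artifact regions depress accuracy
  substantially; the method expects elimination masks for low-quality areas.
- The phantom's vessel texture is a random-walk caricature; algorithms that
  exploit vascular geometry would be flattered by it, but this pipeline only
  sees local variance and intensity.
- Very large homogeneous dark artifacts (e.g. shadowing) are
  indistinguishable from true dropout by construction; they must be
  eliminated upstream.
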