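---
title: "Detecting retinal red lesions with superpixel multichannel features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting retinal red lesions with superpixel multichannel features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcmf)
```

## The problem

Microaneurysms and hemorrhages — collectively *red lesions* — are the
earliest visible signs of diabetic retinopathy in color fundus
photographs. They appear as small dark reddish spots, easily confused
with two normal dark structures: the blood vessels and the fovea.
`mcmf` implements a complete screening pipeline that classifies
*superpixels* (perceptually coherent pixel groups) rather than pixels:

1. **Preprocess**: contrast-limited adaptive histogram equalization
   (CLAHE) per RGB channel inside the camera aperture, then a 5×5
   Gaussian (σ = 1) for denoising.
2. **Candidates**: SLIC superpixel segmentation in CIELAB + position
   space, with the distance
   \(D_{ik} = \sqrt{d_{lab}^2 + (m/S)^2\, d_{xy}^2}\),
   where \(S\) is the grid interval (*region size*) and \(m \in [1, 40]\)
   the compactness weight.
3. **Features**: each candidate gets a 31-dimensional vector — max, min,
   mean, median over seven derived channels (raw green, enhanced green,
   ASF dark-structure enhancement, shade-corrected small-lesion channel,
   disc-closing, HSV hue, CMYK magenta), plus the image's global mean and
   standard deviation, plus a contextual score
   \(S_i = \frac{1}{N_i}\sum_{j \in N(i)}
   \frac{\overline{g}_i}{\overline{g}}\cdot\frac{d_1}{d_2}\)
   that is positive when a candidate is darker than its neighbours
   (within 7 region sizes), as lesions are.
4. **Classifier**: two-class Fisher discriminant analysis on z-normalized
   features; the threshold is the midpoint of the projected class means.
5. **Postprocess**: a multiscale morphological vessel map (disc scales
   2–5, fused by logical OR) removes candidates lying on vessels, and a
   geometric rule removes the fovea zone (2.5 optic-disc diameters from
   the disc toward the image centre).
6. **Evaluation**: image-based (max candidate score per image, ROC/AUC)
   and pixel-based (connected components validated at ≥ 75 % overlap with
   ground truth).

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `region_size` | 50 (full-res), 16 in the tests | SLIC grid interval in px; smaller tracks small lesions better but costs time |
| `compactness` | 10 | color-vs-space weight in the SLIC distance, valid range 1–40 |
| `clahe_clip`, `tile` | 0.01, 8 | CLAHE clip limit (fraction of tile count) and tile grid; not stated by the method's source, standard values |
| `asf_radii` | 10, 20, 40 | disc radii of the alternating sequential filter that estimates lesion-free background |
| `median_kernel` | 25 | background window of the small-lesion channel; must exceed the lesion diameter |
| `line_length`, `line_angles` | 9; 0°,15°,…,165° | linear openings that separate elongated vessels from round lesions; "15–165 step 15" enumerates 11 angles, 0° is added to reach the stated 12 |
| `vessel_scales` | 2–5 | disc radii of the multiscale vessel detector |
| `vessel_overlap_frac` | 0.5 | red candidates overlapping the vessel mask by more than this are suppressed (strict inequality) |
| fovea geometry | 2.5 / 1.0 | fovea centre displacement and suppression radius, in optic-disc diameters |
| `epsilon` | `1e-6·tr(S_w)/31` | ridge on the within-class scatter; FDA is otherwise singular for correlated features |

Classification can also be run at a fixed operating point
(`c_override = 0.01` is the published choice) instead of the
projected-means midpoint; both are exposed.

## Design choices where the design was open

* **Structuring-element scaling.** Phantom images are 512 px wide, real
  screening images ~1500 px. With `scale_se = TRUE` only the
  *background-scale* elements (ASF radii, closing radius) shrink with
  image width. The median window and line length do **not** scale: they
  are matched to the absolute pixel size of lesions and vessel calibres,
  which the phantom reproduces one-to-one. Scaling them down (first
  implementation) collapses the lesion channel — a 9 px window cannot
  treat an 8 px lesion as foreground against background.
* **Small-lesion channel polarity.** Grayscale opening removes *bright*
  structures only, so the linear openings must run on the
  dark-structures-positive residue `I_bg − I_green`. The output is kept
  with lesions high-valued and clipped at zero, so downstream max/mean
  features increase with lesion likelihood.
* **Vessel-map binarization (step 5).** The reconstruction output `f4`
  is sparse and almost perfectly precise — its support *is* the vessel
  phase. The default therefore thresholds at a small quantile (0.9) of
  the FOV values, which in practice means `f4 > 0`. Otsu and a
  regional-minima-complement mode are selectable (`step5_mode`); Otsu
  measured 2–4× lower recall on the phantom because the response
  distribution is extremely skewed.
* **Reconstruction marker.** The source does not state the marker of the
  reconstruction in step 4; we use erosion of `f3` by a radius-1 disc
  under mask `f3` (standard opening-by-reconstruction). A radius-2
  marker was measured to erase width-3 vessels outright — erosion maps
  any 3-px ridge to zero, so nothing is left to reconstruct — which
  would defeat the smallest scales entirely.
* **Contextual-feature denominator.** The printed formula divides the
  neighbour sum by the candidate's *pixel count*; a neighbour-count
  denominator is at least as plausible. We implement the printed form as
  the default and expose `denominator = "neighbors"`.
* **FOV rim.** Aperture-edge pixels that scrape past the FOV threshold
  form sliver superpixels whose hue and intensity statistics are noise;
  a single such sliver can dominate an image's score. The pipeline
  erodes the FOV mask by 2 px before segmentation (`fov_erode`); the raw
  mask remains available.
* **Image-level score.** An image's score is the maximum candidate score
  *among candidates the postprocessing retains* (label-blind vessel and
  fovea suppression). Without this, healthy images are ranked by their
  strongest vessel superpixel. Images with no retained candidate score
  `-Inf` and rank below all scored images.
* **Candidate labelling for training.** A superpixel is a positive
  example if lesion pixels make up ≥ 25 % of it, or if it covers ≥ 50 %
  of some ground-truth component (small lesion inside a large
  superpixel). These fractions are training plumbing, not evaluation
  quantities.

## The synthetic phantom: what it does and does not establish

`generate_synthetic_fundus()` renders the named anatomy — black
surround, circular field of view, reddish background with a smooth
illumination gradient, bright optic disc, dark fovea at 2.5 disc
diameters, a random-walk vessel tree with widths 2–6 px, round
microaneurysms (radius 2–4 px) and irregular hemorrhage blobs (unions of
2–5 discs) at a stated green-channel contrast (default 0.15) below local
background, plus Gaussian pixel noise (default σ = 0.02). Truth masks
are recorded before noise; lesions are planted off-vessel and outside
the fovea suppression zone, making every planted lesion a recoverable
target. Datasets use a fixed screening mix (3 healthy images per block
of 10) so both classes are always present.

What it does *not* emulate: camera blur and JPEG artifacts, true color
texture of the retina, exudates and other bright pathology, vessel
central reflexes, lesions touching vessels, and annotator imprecision.
A green end-to-end test therefore establishes that the pipeline's
machinery recovers known structure under realistic geometry and noise —
not clinical performance, which requires a clinical benchmark.

## Numerical notes

* Morphology uses flat structuring elements; out-of-bounds neighbours
  are ignored (equivalently ±∞ padding), so constants are preserved and
  closing stays extensive at borders. Disc erosions/dilations run in
  O(HW·r) via a column decomposition with van Herk sliding extrema and
  are exactly equal to the direct definition.
* The median filter quantizes to 16 bits over the image range and slides
  a two-tier histogram; the result is exact on the quantized scale
  (error ≤ range/131070).
* SLIC iterates at most `n_iters` (10) times, stopping early when no
  centre moves > 0.5 px; fragments below `min_region_fraction·S²` are
  absorbed into an adjacent superpixel. Pixels claimed by no 2S×2S
  window fall back to the global nearest centre.
* Population (not sample) standard deviations are used in the global
  statistics and feature normalization; constant feature dimensions map
  to 0 with a warning.
* Ties: candidates at exactly the neighbour radius 7·S are neighbours;
  a score exactly at the classification threshold is non-red (strict
  `>`); optic-disc location ties break toward the smallest (row, col).
* `pixel_based_validation` counts a ground-truth component as detected
  at ≥ 75 % overlap *including* exact 100 % coverage; the stricter
  published reading (< 100 %) would label perfect detections false and
  is available via `strict_upper = TRUE`.

## Worked example

```{r example, eval = FALSE}
set.seed(1)
ph <- generate_synthetic_fundus(phantom_spec(seed = 7))
p  <- mcmf_process_image(ph$image, region_size = 16,
                         channel_cfg = channel_config(scale_se = TRUE))
y  <- label_candidates(p$cands, ph$truth$lesion_mask)
model <- mcmf_train(list(p$features), list(y))
det <- mcmf_detect(model, p)
pixel_based_validation(det$lesion_map$mask, ph$truth$lesion_mask)
```

The acceptance script (`Rscript scripts/acceptance.R --seed 1 --out
results/acceptance.json`) re-runs every acceptance measurement from
scratch — including a 40-image train/test experiment — and writes the
resulting numbers as JSON.

## Known limitations

* The vessel map is tuned for dark vessels on the CLAHE green plane; very
  low-contrast vessel tips are missed at all scales (recall ≈ 0.7 on the
  phantom), so some vessel superpixels survive suppression.
* Optic-disc localization is a brightest-region heuristic; images with
  large exudates would defeat it (no exudates are modelled here).
* Training assumes at least two positive and two negative superpixels;
  screening sets with no diseased image cannot be fitted.
* TIFF input is not supported (no reader in the dependency footprint);
  PNG, JPEG and PPM are.
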