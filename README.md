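# mcmf — superpixel multichannel multifeature detection of retinal red lesions

Red lesions — microaneurysms and hemorrhages — are the earliest visible
signs of diabetic retinopathy in color fundus photographs, and finding
them automatically is the core task of large-scale screening. `mcmf`
implements a complete detector whose atomic unit is the *superpixel*
rather than the pixel:

1. **Preprocessing** — per-channel CLAHE inside the camera aperture,
   then 5×5 Gaussian smoothing (σ = 1).
2. **Candidate extraction** — SLIC clustering in CIELAB + position
   space with distance
   `D_ik = sqrt(d_lab² + (m/S)² d_xy²)`
   (`S` = region size, `m` = compactness in [1, 40]).
3. **Features** — 31 per candidate: {max, min, mean, median} over seven
   derived channels (raw green `I_G`, enhanced green `I_green`, ASF
   dark-structure enhancement, shade-corrected small-lesion channel,
   disc closing, HSV hue, CMYK magenta), the image's global mean and
   standard deviation, and a contextual score
   `S_i = (1/N_i) Σ_{j∈N(i)} (avG_i / avI) · d1/d2`
   that is positive when a candidate is darker than its neighbours.
4. **Classification** — two-class Fisher discriminant analysis
   (`S_b φ = λ S_w φ`) on z-normalized features, threshold at the
   projected-means midpoint `c = wᵀ(μ₁+μ₂)/2` (a fixed operating point
   such as `c = 0.01` can be supplied instead).
5. **Postprocessing** — multiscale morphological vessel segmentation
   (disc scales 2–5, logical-OR fusion) suppresses candidates on
   vessels; a geometric rule suppresses the fovea zone located 2.5
   optic-disc diameters from the disc toward the image centre.
6. **Evaluation** — image-based (max candidate score, ROC/AUC) and
   pixel-based (connected components validated at ≥ 75 % overlap).

A seeded synthetic fundus phantom (aperture, illumination gradient,
optic disc, fovea, vessel tree, plantable lesions, per-pixel ground
truth) makes the whole pipeline testable without clinical data.

## Worked example

```r
library(mcmf)

# a 512x512 phantom with 6 microaneurysms and 2 hemorrhages
ph <- generate_synthetic_fundus(phantom_spec(seed = 7))
ph$image
#> <fundus_image 512 x 512, range [0.000, 0.916]>

# front half of the pipeline on that image
p <- mcmf_process_image(ph$image, region_size = 16,
                        channel_cfg = channel_config(scale_se = TRUE))
dim(p$features)
#> [1] 683  31

# train on a small seeded dataset (3 healthy images per block of 10)
ds <- generate_labeled_dataset(10, phantom_spec(), seed = 1)
proc <- lapply(ds$phantoms, function(q)
  mcmf_process_image(q$image, region_size = 16,
                     channel_cfg = channel_config(scale_se = TRUE)))
labs <- lapply(1:10, function(i)
  label_candidates(proc[[i]]$cands, ds$phantoms[[i]]$truth$lesion_mask))
model <- mcmf_train(lapply(proc, `[[`, "features"), labs)
model
#> <fda_model: 31 features, threshold c = 0.520216>

# detect on the held-out phantom
det <- mcmf_detect(model, p)
sum(det$pred)          # red superpixels after vessel/fovea suppression
#> [1] 10
round(det$image_score, 3)
#> [1] 1.612

pixel_based_validation(det$lesion_map$mask, ph$truth$lesion_mask)
#> <eval_report [pixel_based]: TP 8 FP 1 TN 0 FN 0 | sens 1 spec 0>
```

All 8 planted lesions are recovered at the ≥ 75 % component-overlap
rule (sensitivity 1), with one false-positive component; TN is not
defined at component level unless a negative-unit count is supplied,
hence the 0.

## Command line

```sh
Rscript inst/cli/mcmf.R synth       --n 20 --seed 42 --out-dir fixtures/
Rscript inst/cli/mcmf.R superpixels --region-size 50 IN.png OUT.png
Rscript inst/cli/mcmf.R train       --train-dir fixtures --model model.json --scale-se
Rscript inst/cli/mcmf.R detect      --model model.json --scale-se IN.png --out-dir out/
Rscript inst/cli/mcmf.R evaluate    --criterion pixel --pred-dir out/ --gt-dir gt/
```

## Documentation

The methods vignette (`vignettes/red-lesion-detection.Rmd`) explains the
model, the tunable parameters and their defaults, what the phantom does
and does not emulate, the numerical choices (tie-breaks, tolerances,
degenerate inputs), and known limitations.
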