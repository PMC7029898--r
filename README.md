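# hairsem

Quantitative scoring of hair cuticle surface damage in scanning electron
microscopy (SEM) images.

Morphological hair damage — lifted, cracked or missing cuticle scales, holes,
adhering debris — has traditionally been assessed by eye against qualitative
feature checklists. `hairsem` implements an automated, feature-free
alternative for 8-bit greyscale SEM micrographs of single hair segments:
damage features sit elevated or depressed relative to the cuticle surface and
therefore appear *brighter* (light grey to white) than the dark-grey
undamaged surface, so the asymmetry of the pixel-brightness histogram is a
proxy for surface roughness and damage severity. The package is aimed at
forensic, cosmetic and material scientists who need an objective damage score
per micrograph, plus a way to map scores onto an existing ordinal grading
scheme.

## The pipeline

Given a micrograph and two user-drawn lines (an *axis* line along the hair
and a *diagonal* spanning the segment's bounding corners, supplied as a
CSV/JSON sidecar):

1. **ROI extraction.** The image is rotated so the hair axis is horizontal.
   From the diagonal's extremes the region of interest is the centred
   rectangle with origin ((7x_min + x_max)/8, (7y_min + y_max)/8), length
   l = 3/4 (x_max − x_min) and width w = 3/4 (y_max − y_min) — 9/16 (56 %) of
   the segment bounding box, excluding the abnormally bright bands along the
   segment edges.
2. **Row-wise normalization.** Each row of pixels along the hair length is
   scaled so its mean brightness is 109 (43 % of full scale, the dark grey of
   undamaged cuticle), then values above 109 are min–max rescaled per row so
   the row maximum reaches 255:
   `I' = 146 (I − 109) / (I_max,row − 109) + 109` for `I > 109`.
3. **Damage metrics.**
   - *Mean brightness* (excluded as a damage score by construction — the
     normalization pins it — but reported for magnification QC);
   - *average image roughness*: the per-row polyline arc length
     `Σ √(ΔI² + run²) / l` over n = 100 sections (flat profile = 1);
   - *tailing factor* of the brightness histogram, adapted from
     chromatographic peak-shape analysis:
     `t_f = (I_lag,fH − I_lead,fH) / (2 (I_h − I_lead,fH))`
     at f = 2 % of peak height, with the apex I_h redefined through the
     count-weighted mean over the full-width-at-half-maximum window whenever
     that mean departs from the mode by more than 3 brightness units.
     A symmetric histogram scores exactly 1; bright damage tails push it up.
4. **Grading.** A k-nearest-neighbour model (k = 3, Euclidean distance on the
   single tailing-factor feature) maps scores onto the ordinal Scu 1–4 SEM
   cuticle damage scale, after a condition-stratified 50/50 train/test split.

A seeded synthetic micrograph generator renders tube-shaped hair segments
with bright edge bands, cuticle scale edges, smooth surface texture and
controllable damage-feature density, so the whole pipeline is testable
without real SEM data.

## Worked example

```r
library(hairsem)

clean   <- generate_fixture(fixture_spec(seed = 42))
damaged <- generate_fixture(fixture_spec(seed = 42, n_clusters = 12,
                                         n_rings = 4, n_specks = 20))
rbind(clean   = score_image(clean$image, clean$axis, clean$diagonal),
      damaged = score_image(damaged$image, damaged$axis, damaged$diagonal))
#>         image_id magnification mean_brightness roughness tailing_factor    f n_sections
#> clean   synth-42          2000        113.4509  4.322961       1.424056 0.02        100
#> damaged synth-42          2000        112.5557  4.230036       1.769437 0.02        100
```

The damaged fixture's bright features fatten the right tail of its brightness
histogram: its tailing factor (1.77) clearly exceeds the clean segment's
(1.42), while mean brightness barely moves (the normalization pins it near
109 by design) and roughness hardly separates the two — the same ordering of
usefulness seen on real micrographs.

Grading a synthetic cohort end to end:

```r
co     <- generate_cohort(seed = 7)          # 8 images each, Scu 1 / Scu 2 regimes
scored <- score_cohort(co)
halves <- split_train_test(scored, seed = 7)
model  <- knn_fit(halves$train$tailing_factor, halves$train$grade, k = 3)
res    <- evaluate(model, halves$test)
res$accuracy
#> [1] 0.875
res$table[1:4, c("image_id", "grade", "tailing_factor", "predicted_grade", "probability")]
#>      image_id grade tailing_factor predicted_grade probability
#> 1 img-Scu1-01 Scu 1       1.379394           Scu 1   1.0000000
#> 5 img-Scu1-05 Scu 1       1.793070           Scu 2   0.6666667
#> 6 img-Scu1-06 Scu 1       1.354171           Scu 1   1.0000000
#> 7 img-Scu1-07 Scu 1       1.272124           Scu 1   1.0000000
```

Seven of the eight held-out images are graded correctly; the one miss is a
clean-regime image whose realized texture produced an unusually long tail —
exactly the kind of borderline case that misclassifies in real data.

The published 16-image kNN test table ships with the package
(`table1_test_set()`) and is used by the regression tests: agreement between
its true and predicted grade columns is 13/16 (81 %).

## Command line

`inst/scripts/hairsem-cli.R` wraps the package for shell use:

```sh
Rscript inst/scripts/hairsem-cli.R simulate  --out-dir sim --seed 4 --n-per-grade 8
Rscript inst/scripts/hairsem-cli.R score     --images-dir sim --annotations sim/annotations.csv --out metrics.csv
Rscript inst/scripts/hairsem-cli.R grade     --train labeled.csv --test metrics.csv --out predictions.csv
```

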