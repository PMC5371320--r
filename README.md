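# hestain

Structure-centric color normalization for H&E histology images.

## The problem

Hematoxylin-and-eosin staining varies widely across laboratories, staining
protocols and scanners, and that color variability degrades any downstream
analysis that reads pixel color as a proxy for tissue identity. `hestain`
normalizes H&E tiles by exploiting the correlation between color and
tissue structure: instead of decomposing stains chemically, it identifies
which colors belong to which structures *in each image* and then moves
every structure onto a standardized target color while preserving each
pixel's deviation about its structure mean.

The pipeline:

1. **Color reduction** — convert to HSV, embed cylindrical coordinates as
   `(s·cos 2πh, s·sin 2πh, v)`, and k-means the pixels into `k = 10`
   palette colors. The mean intra-/inter-cluster variance ratio
   (`variance_curve()`) is the diagnostic for choosing `k`: it declines
   and plateaus around ten clusters for H&E material.
2. **Structure assignment** — map palette colors to white/lumen, stroma,
   nuclei or cytoplasm (JSON file, or `auto_assign()` against ground
   truth), leaving ambiguous colors unassigned.
3. **Pixel classification** — a decision tree of three linear soft-margin
   SVMs (box constraint `C = 1`) trained on the assigned pixels: white vs.
   tissue, stroma vs. epithelium, nuclei vs. cytoplasm. Every pixel gets a
   class plus a four-channel signed hyperplane-distance certainty record.
4. **Normalization** — per structure, measure the image's mean color
   (circular in hue); remap each pixel to `target(class) + Δd`, where
   `Δd` is its per-channel deviation about the structure mean; constrain
   to `[0, 1]` (hue wraps). Mean colors land on the targets; within-
   structure detail survives exactly wherever nothing clips.

The evaluation toolkit mirrors the method's validation: inter-/intra-image
variability of structure means, histogram mutual information normalized by
self-information (`nmi()`), a Gaussian-noise NMI calibration curve, and a
synthetic H&E tile generator with ground-truth structure maps so the whole
pipeline can be exercised without external data.

## Worked example

```r
library(hestain)

cohort <- generate_cohort(n = 6, size = c(128, 128), seed = 1)  # synthetic tiles
run <- normalize_cohort(cohort, seed = 2)                       # full pipeline
run$report
#>        class channel pre_sd  post_sd reduction
#> 10     white       s 0.0253 2.73e-05  9.24e+02
#> 11     white       v 0.0476 3.85e-05  1.24e+03
#> 7     stroma       h 0.0430 0.00e+00        NA
#> 8     stroma       s 0.0267 0.00e+00        NA
#> 9     stroma       v 0.0553 0.00e+00        NA
#> 4     nuclei       h 0.0431 0.00e+00        NA
#> 5     nuclei       s 0.0267 0.00e+00        NA
#> 6     nuclei       v 0.0554 0.00e+00        NA
#> 1  cytoplasm       h 0.0432 0.00e+00        NA
#> 2  cytoplasm       s 0.0268 2.27e-17  1.18e+15
#> 3  cytoplasm       v 0.0553 0.00e+00        NA
```

`pre_sd` is the standard deviation across images of each structure's mean
color — the stain drift the generator injected (≈ 0.05 per channel, here
seen through six images). After normalization the per-image structure
means coincide with the shared targets, so `post_sd` collapses to zero
(an `NA` reduction factor means the denominator is exactly 0, i.e. the
drift was removed completely; white retains a trace because its
saturation clips at the gamut floor).

```r
p <- run$processed[[1]]
nmi(p$hsv, run$normalized[[1]])
#>  value huesat
#>  0.795  0.731
```

The normalized image still shares most of its mutual information with the
original — the deviation term carries the within-structure detail through
the remapping — whereas the flat class-color control
(`normalize_without_deviation()`) scores far lower.

A thin command-line front end (`inst/cli/hestain.R`) exposes `synth`,
`normalize` and `evaluate` subcommands over the same functions.

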