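# cellafe

Automatic feature extraction and neuro-fuzzy classification of
single-cell cervical cytology images.

Cervical-cytology screening (Pap smear / liquid-based cytology) sorts
single squamous cells into **normal**, **LSIL** and **HSIL** (low-/
high-grade squamous intraepithelial lesion). The morphological signal is
classic: abnormal cells show an enlarged, darker nucleus and a shrunken
cytoplasm. `cellafe` is for image-analysis and machine-learning
researchers who want a complete, testable implementation of a classical
two-stage recognition pipeline for such images:

1. **AFE (automatic feature extraction).** The grey-level histogram of an
   8-bit single-cell image is clustered into nucleus/cytoplasm/background
   centres \(C_N < C_C < C_B\) with **moving k-means** (a k-means variant
   whose relocation step keeps every cluster alive), giving two
   segmentation thresholds

   \[ \beta_{NC} = \lfloor (C_N + C_C)/2 \rfloor, \qquad
      \beta_{CB} = \lfloor (C_C + C_B)/2 \rfloor . \]

   A seed-based region growing pass from the image corner strips
   background and cytoplasm; the raw-moment centroid
   \((m_{10}/m_{00},\, m_{01}/m_{00})\) of what remains seeds a modified
   region-growing pass that segments the image (nucleus 0, cytoplasm 127,
   background 255) while simultaneously accumulating the six features
   \(n,\ P_N,\ \bar{GL}_N,\ c,\ P_C,\ \bar{GL}_C\)
   (size, perimeter and mean grey level of nucleus and cytoplasm).

2. **MANFIS.** Three parallel first-order Sugeno ANFIS models (generalized
   bell memberships, 64-rule grid partition) map the six features to
   per-class scores \(f_1, f_2, f_3\); training alternates an exact
   least-squares solve of the linear consequents with a backpropagation
   step on the membership parameters; prediction is the argmax. A
   five-fold harness (five independent random 80/20 splits) reports
   per-fold, per-class and overall accuracy.

Because no clinical images ship with the reference measurements, the
package includes a synthetic single-cell generator with exact ground
truth (`generate_cell_image()`, `generate_feature_dataset()`); every
stage is tested against brute-force oracles on that data.

## Worked example

```r
library(cellafe)

# a synthetic normal cell, 160 x 120, Gaussian noise SD 5
cell <- generate_cell_image(cell_spec(noise_sd = 5, seed = 42))
res  <- run_afe_pipeline(cell$image)

round(res$centres, 2)
#> [1] 152.81 190.01 226.93
res$thresholds
#> beta_NC beta_CB
#>     171     208
res$centroid
#>  x  y
#> 80 60
round(res$features, 3)
#>        nucleus_size   nucleus_perimeter        nucleus_grey      cytoplasm_size
#>             316.000              76.000             152.753            8829.000
#> cytoplasm_perimeter      cytoplasm_grey
#>             428.000             190.006
```

The clustering recovers the generator's grey centres (153/190/227) to a
fraction of a grey level; the thresholds 171 and 208 are their truncated
midpoints; the centroid (80, 60) is the true nucleus centre; the
extracted nucleus/cytoplasm sizes (316/8829 px) sit within 0.5% of the
rasterized ground truth (317/8828 px).

Classification and evaluation on a synthetic screening population
(376 normal, 79 LSIL, 45 HSIL):

```r
tab <- generate_feature_dataset(c(376, 79, 45), seed = 2024)
rep <- run_crossval(tab, k = 5, test_frac = 0.2, seed = 2024)
rep$overall_test_accuracy
#> [1] 99.8
```

`print(rep)` renders the per-fold original/predicted count tables with
per-fold, per-class and overall accuracies, rounded half-up to one
decimal.

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/afe.R synth -o cells --n 3 --noise 3 --seed 5
Rscript inst/cli/afe.R thresholds cells/cell_001_normal.png
# 153.11,190.04,226.95,171,208
Rscript inst/cli/afe.R centroid cells/cell_001_normal.png
# x=80, y=60
Rscript inst/cli/afe.R segment cells/cell_001_normal.png -o mask.png
Rscript inst/cli/afe.R crossval features.csv --folds 5
```

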