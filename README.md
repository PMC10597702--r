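# ramanmtn

Multi-task deep learning for Raman spectral diagnosis of oral lesions.

Fiber-optic Raman spectroscopy measures a biochemical fingerprint of
tissue *in situ*: an intensity trace over Raman shifts (here the
400–1400 cm⁻¹ fingerprint region). For an oral lesion, three correlated
diagnostic calls matter — primary tumor extent (T stage: Tis, T1–T4),
regional lymph-node involvement (N stage: N0–N2), and histological grade
(well / moderately / poorly differentiated, plus benign-or-dysplastic and
healthy tissue). `ramanmtn` implements a single multi-task network (MTN)
for all three: a shared one-dimensional ResNet-50 backbone

```
input (2076 pts) → stem 7×1 conv (64 kernels, /2) + 3×1 max-pool (/2) → 519×64
                → bottleneck stages (3,4,6,3 blocks; 12 identity + 4 projection)
                  519×256 → 260×512 → 130×1024 → 65×2048
                → global average pooling (neck, with feature standardisation)
                → heads: T 2048→512→128→7 | N 2048→256→5 | grade 2048→5
```

trained jointly by SGD (momentum 0.9, weight decay 2·10⁻⁵) on the summed
per-head softmax cross-entropies, and evaluated by stratified ten-fold
cross-validation in the 7 train / 2 validation / 1 test pattern with
accuracy, macro one-vs-rest sensitivity/specificity, macro ROC/AUC and
cumulative confusion matrices. Grad-CAM heatmaps on the last backbone
feature map attribute predictions to spectral bands, with an annotated
band table for molecular assignment. Because no clinical cohort is
publicly deposited, the package also ships a class-conditional spectrum
simulator (Lorentzian bands on a fluorescence background) whose class
profiles encode the published band assignments and stage-progression
directions; it is first-class, tested code and drives the end-to-end
benchmarks.

The whole stack — preprocessing, the convolutional engine with exact
backpropagation, training, metrics, Grad-CAM — is base R on BLAS matrix
products; the only runtime dependencies are `signal` (Savitzky–Golay) and
`jsonlite` (reports).

## Worked example

Simulate a small balanced cohort, preprocess it, cross-validate a narrow
model, and inspect the result:

```r
library(ramanmtn)

scfg <- sim_benchmark_config(seed = 1, n_per_class = 60)   # 360 spectra
ds   <- simulate_dataset(scfg)
ds   <- preprocess(ds, preprocess_config(target_length = 132,
                                         averaging_k = numeric(0)))
mcfg <- mtn_config(input_length = 132, stem_channels = 8,
                   stage_channels = c(16, 32, 64, 128))
rep  <- mtn_cv(ds, mcfg, train_config(seed = 1), scaled_down = TRUE)
rep
```

```
<mtn_report> 10-fold cross-validation over 360 spectra (macro (one-vs-rest, unweighted))
  T staging              acc 98.89% +- 1.43  sens 98.67% +- 1.72  spec 99.81% +- 0.25  AUC 1.0000
  N staging              acc 99.17% +- 1.34  sens 99.00% +- 1.61  spec 99.78% +- 0.35  AUC 1.0000
  Histological grading   acc 98.61% +- 1.96  sens 98.50% +- 2.28  spec 99.65% +- 0.51  AUC 0.9999
```

Reading it: each simulated class is recovered nearly perfectly
(accuracy ~99% per task, macro specificity ~99.8%, macro AUC ~1), which is
the expected behaviour on this strongly separated synthetic cohort — it
validates the pipeline and optimiser, not clinical performance.

Per task the report carries the cumulative confusion matrix (its grand
total is the cohort size — every spectrum is tested exactly once), the ten
per-round metric rows, their mean ± sd, and pooled ROC points;
`write_report()` persists it as JSON. The architecture itself is
inspectable without training:

```r
mtn(mtn_config())
#> <mtn_model> 1D ResNet-50 backbone, input 2076 points (untrained)
#>   5 conv modules, 12 identity blocks, heads 7/5/5 classes (6 FC layers)
#>   stage length channels
#>    stem    519       64
#>  stage2    519      256
#>  stage3    260      512
#>  stage4    130     1024
#>  stage5     65     2048
#>    neck      1     2048
```

Band-level interpretation of a fitted model:

```r
h <- class_mean_heatmap(fit$model, ds, task = "g", target_class = "PD")
top_bands(h, k = 3)   # ranked regions annotated from the band table
```

A thin command-line front end (`inst/cli/ramanmtn.R`) exposes `simulate`,
`preprocess` and `describe` subcommands over the same functions.

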