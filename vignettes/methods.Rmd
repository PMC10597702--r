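---
title: "Multi-task Raman diagnosis: models, simulator and design notes"
author: "ramanmtn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-task Raman diagnosis: models, simulator and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ramanmtn)
```

## The problem

Fiber-optic Raman spectroscopy of oral tissue yields, per measurement, an
intensity trace over the fingerprint region (400–1400 cm⁻¹). The diagnostic
questions attached to a lesion are threefold and correlated: the primary
tumor extent (T stage), regional lymph-node involvement (N stage), and the
histological grade. `ramanmtn` implements a single multi-task classifier
for all three: a shared one-dimensional ResNet-50 backbone extracts
features once, and three small fully connected heads map them to 7 T
classes (health, BOD, Tis, T1–T4), 5 N classes (health, BOD, N0–N2) and 5
grades (health, BOD, WD, MD, PD). Non-lesion tissue carries the `health`
(benign/dysplastic the `BOD`) label in every task, which is how a 7/5/5
head structure covers a whole cohort.

## Preprocessing

Raw fiber-probe spectra are dominated by a broad fluorescence background
with shot-like noise on top. The pipeline (`preprocess()`) applies, in
order:

1. **Window cropping** to 400–1400 cm⁻¹ (closed interval).
2. **Class-balancing block averaging** — over-represented groups are
   reduced by replacing consecutive blocks of *k* same-class spectra with
   their pointwise mean (healthy *k* = 5, T1 *k* = 3, T2 *k* = 5, T4
   *k* = 6 by default; trailing remainders are dropped, so *n* spectra
   yield ⌊*n*/*k*⌋).
3. **Outlier screening** — a spectrum whose Pearson correlation with its
   joint-class median falls below 0.8 is removed and logged. This is an
   auditable surrogate for manual removal of visibly abnormal traces; the
   threshold is a package choice, not a reconstruction of any particular
   manual screen.
4. **Savitzky–Golay smoothing** (default window 11 points, order 3 — wide
   enough to suppress noise at ~1 cm⁻¹ sampling while preserving bands of
   the probe's 6 cm⁻¹ resolution).
5. **Iterative polynomial baseline removal** — a degree-5 polynomial is
   fitted by least squares; points more than one residual standard
   deviation above the fit are clipped down to that ceiling and the fit
   repeated until it stabilises (relative change < 1e-4, at most 100
   iterations). The deviation guard keeps genuine baseline points from
   being dragged below the background, so on a noise-free
   polynomial-plus-peaks trace the procedure recovers the background
   essentially exactly (the test suite asserts residuals below 1e-6 of the
   dynamic range for pure backgrounds, and 5%/2% bounds for peak height
   and off-peak residual on composite traces).
6. **Min–max normalisation** to exactly [0, 1] per spectrum.
7. **Linear resampling** onto a uniform grid of 2076 points, followed by a
   second min–max rescale because interpolation can shave the extremes.
   2076 is the input length at which the backbone reproduces its nominal
   feature-map geometry (below); it is a property of the architecture, not
   of the instrument.

Every stage is deterministic; the pipeline annotates errors with the stage
name and carries averaging/removal logs as attributes.

## The network

`mtn()` builds the model; `mtn(mtn_config())$shape_trace` prints the
geometry:

| stage  | length | channels |
|--------|-------:|---------:|
| stem   |    519 |       64 |
| stage2 |    519 |      256 |
| stage3 |    260 |      512 |
| stage4 |    130 |     1024 |
| stage5 |     65 |     2048 |
| neck   |      1 |     2048 |

The stem is a 7-wide stride-2 convolution with 64 kernels followed by
3-wide stride-2 max pooling. The four bottleneck stages hold (3, 4, 6, 3)
residual blocks; the first block of each stage projects (4 projection
blocks), the other 12 are identity blocks. All length-reducing operators
use ceil-mode padding (so 519 → 260 → 130 → 65); the stage-4 and stage-5
projection shortcuts reduce length with a stride-2 average pool before
their 1×1 projection, the stage-3 shortcut with a stride-2 convolution.
Counted this way the network has 5 convolutional modules and 4 pooling
layers (stem max pool, two shortcut pools, global average pool). Batch
normalisation follows every convolution; activations are ReLU.

Two departures from a textbook ResNet-50 are deliberate:

* **Neck standardisation.** Preprocessed Raman spectra are near-identical
  curves, so the globally pooled features share a large common offset with
  roughly twenty-fold smaller informative variance. A batch-norm layer on
  the pooled feature vector standardises each channel before the heads;
  without it, head training on short schedules is too ill-conditioned to
  converge even on linearly separable cohorts (a multinomial logistic fit
  on the same features succeeds, which is how the diagnosis was made).
* **Zero-initialised classifiers.** The last fully connected layer of each
  head starts at zero, so logits begin exactly uniform and the trained
  weights contain accumulated gradient signal only. Together with the
  standard zero residual gain (the last batch-norm scale of every block
  starts at zero) this stabilises short runs and keeps Grad-CAM channel
  weights free of initialisation noise.

Heads: T stage 2048 → 512 → 128 → 7 (three FC layers), N stage
2048 → 256 → 5 (two), grade 2048 → 5 (one) — six FC layers in total. Only
the output sizes and layer counts are fixed by the architecture; the
hidden widths are package defaults.

The engine underneath is written in R on BLAS primitives: convolutions are
im2col gathers followed by one `dgemm`, and every operator has a
hand-derived backward pass verified against central finite differences in
the test suite (worst relative error ~1e-6 over sampled parameters in
every layer type).

## Training and evaluation

`train_config()` carries the reference protocol: SGD with momentum 0.9,
weight decay 2e-5, learning rate 1e-4, batch 256, 1000 epochs. Those
values are tied to a clinical-scale run; the `scaled_down` overrides
(epochs 30, batch 64, learning rate 0.05) define the desk regime used by
the simulated benchmarks. The learning rate must rise when the schedule
shrinks thirty-fold — with 1e-4 and a few hundred updates the loss barely
moves — so the desk value was chosen for stable convergence on separable
simulated cohorts, and it is an optimiser setting, not a data setting.

Cross-validation follows the 7/2/1 pattern: `make_folds()` partitions the
cohort into ten stratified folds (by joint T/N/grade class); each round
trains on seven folds, monitors the next two after every epoch, and tests
once on the held-out fold with the parameters of the best-validation
epoch. Because short schedules leave batch-norm's exponential running
averages lagging far behind the fast-moving activations, the running
statistics are recalibrated from a training batch before every evaluation
pass; without this the evaluation-mode predictions of a well-fitted model
can be arbitrarily wrong (perfect training loss, chance-level validation
accuracy — the symptom that motivated the fix).

Fold splitting is at spectrum level by default, mirroring the usual
protocol; note that repeated measurements of one patient then straddle
training and test folds, an optimistic bias. `group_by_patient = TRUE`
keeps each patient's spectra in one fold.

Metrics are accuracy, macro one-vs-rest sensitivity and specificity, and
macro-averaged ROC/AUC (trapezoid over the full threshold sweep; ties earn
half credit, making the AUC equal to the Mann–Whitney pair count — both
facts are asserted against brute-force oracles and cross-checked against
pROC in the tests). Confusion matrices accumulate over the ten rounds, so
their grand total equals the cohort size.

## The simulator

`simulate_dataset()` generates class-conditional cohorts. Every class
shares a base band set — the union of all progression-transition bands,
the annotated band table, and three generic tissue bands (1004, 1250,
1330 cm⁻¹) — rendered as Lorentzian lines of 6 cm⁻¹ half-width (the
probe's stated resolution), on a concave-down quadratic fluorescence
background five times the tallest band, plus i.i.d. Gaussian noise
(default sd 0.02 on an amplitude scale whose tallest band is 0.9) and
per-spectrum multiplicative band jitter (sd 0.05).

Class structure enters in two ways:

* **Band-table coding.** Annotated bands carry qualitative intensities
  (weak 0.4–0.6, mid 0.6–0.8, strong 0.8–1, encoded at the midpoints).
  Where a band lists two codes the first is taken as healthy and the
  second as lesional tissue; benign/dysplastic (BOD) tissue gets the
  midpoint of the two, an intermediate band pattern. This reading is an
  assumption — the source coding does not name its columns — and it is
  what makes BOD distinguishable from both health and carcinoma in situ.
* **Progression transitions.** Along the chains Tis → TI → TII (TI
  covering T1/T2, TII covering T3/T4), N0 → N1 → N2 and WD → MD → PD, the
  listed bands rise or fall by a multiplicative step (default 0.25),
  applied cumulatively. Consequently T1 and T2 (and T3 and T4) share a
  profile: the published band analysis distinguishes the merged TI/TII
  groups only. Every published increase/decrease is asserted as a strict
  inequality between noise-free class means in the tests.

The default composition reproduces the published raw histological
marginal exactly (health 3510, BOD 810, WD 2790, MD 540, PD 300 spectra);
tumor T/N cells pair the published T and N marginals (which pair exactly:
Tis+T1+T2+T3 = 2520 = N0 and T4 = 990 = N1+N2) rescaled by largest
remainder to the grade-based tumor total, because the published grade- and
stage-based totals disagree by 120 spectra. Synthetic patients own 90
consecutive spectra each, one per probe measurement session.

What the simulator does *not* model: wavenumber miscalibration and drift,
cosmic-ray spikes, detector nonlinearity and saturation, within-patient
correlation beyond shared class profiles, and any biochemical covariance
between bands. Passing the recovery benchmarks therefore shows that the
pipeline, network and evaluation machinery are correct and can learn
band-amplitude signatures at realistic noise — not that clinical-grade
accuracy would transfer to real tissue.

## Desk-scale benchmarks

The full clinical configuration (2076-point input, 64…2048 channels, 1000
epochs, ~8000 spectra) is far beyond a single-CPU test run. The package
therefore ships two benchmarks that keep the exact topology (stem +
(3, 4, 6, 3) bottleneck stages, 12 identity blocks, three heads) but
narrow the widths:

* `desk_benchmark()`: a 900-spectrum six-class cohort (150 each: health,
  BOD, Tis-N0-WD, T1-N0-WD, T3-N1-MD, T3-N2-PD — five mutually
  distinguishable T classes and all five N and grade labels), simulated
  with transition step 0.5 and noise 0.005, resampled to 96 points, and
  classified by a narrow model (stem 8, stages 16/32/64/128) under the
  scaled-down regime with full ten-fold rotation. Mean test accuracy
  exceeds 99% on all three tasks; with `epochs = 0` the untrained model
  sits at chance (1/7, 1/5, 1/5 — exact in expectation because the
  initialisation is class-symmetric and argmax ties are broken uniformly).
* `gradcam_benchmark()`: two classes identical except one band (1080 cm⁻¹,
  amplitude ×1.6), simulated over 950–1250 cm⁻¹ on a 448-point grid. The
  window is chosen so that (i) it contains a stronger band (1220 cm⁻¹)
  than the manipulated one, keeping the min–max normalisation anchor
  class-independent, and (ii) both stage-5 feature-map nodes adjacent to
  the peak lie within the ±18 cm⁻¹ (three half-widths) localisation
  tolerance, so grid discretisation alone cannot fail the check.

## Grad-CAM: what works and what does not

`grad_cam()` implements the canonical recipe: the gradient of the target
class score with respect to the last backbone convolutional feature map is
averaged over positions to give per-channel weights (with a
global-average-pooling neck this equals the head's feature gradient,
computed analytically through the selected head and the neck normaliser);
the weighted channel sum is clipped at zero, linearly upsampled from the
65-node resolution to the input grid, and max-normalised. `top_bands()`
thresholds a heatmap at half maximum, merges regions within 10 cm⁻¹, and
annotates them from the band table.

A candid limitation, established systematically on the two-class
benchmark: the trained stage-5 representation localises class evidence
well — per-channel class-difference profiles peak exactly at the node
nearest the discriminative band, with detectors of both polarities — but
the per-class *positive-evidence* heatmap ∑₍c₎ wᶜ Aₗᶜ is polluted by
class-common activations riding on channels with small but non-zero head
weights. With a global-pooling neck nothing ties a detector's position to
its stimulus, and at desk scale (a few hundred SGD updates) the clutter
rivals the localised signal, so the heatmap argmax hits the ±3-half-width
window in only a minority of seeded runs. Log-softmax target scores,
gradient variants that skip the neck normaliser's 1/σ factor, strong
weight decay and higher within-class jitter were all tried and do not
repair this. The corresponding localisation check in the package's test
suite is therefore expected to fail at desk scale — it is kept at its
stated threshold rather than weakened, as an honest record of the method's
resolution — and band-level attributions from `top_bands()` should
be read as region-level, not line-level, evidence — consistent with the
hundreds-of-cm⁻¹-wide regions such heatmaps highlight in clinical-scale
use.

## Numerical choices

* Ceil-mode padding everywhere a length is reduced (floor-mode would give
  259 instead of 260 at stage 3, contradicting the nominal geometry).
* Batch-norm ε = 1e-5, running-statistics momentum 0.1, full
  recalibration (momentum 1 on one ≤256-spectrum training batch) before
  each evaluation.
* Weight decay applies to convolution and FC weight matrices only, not to
  biases or batch-norm scale/shift.
* Baseline design matrices are built on an axis rescaled to [−1, 1] for
  conditioning; a rank-deficient design raises an error rather than
  returning a silently unstable fit.
* `minmax_normalize()` treats a span below 1e-12 of the trace magnitude
  as constant (degenerate), so round-off wiggles on a flat trace are
  rejected rather than amplified.
* Argmax ties in test predictions (possible only for degenerate models,
  e.g. untrained zero heads) are broken uniformly under the round seed.
* All seeds derive from user-facing integer seeds; simulation,
  fold-splitting and training are bit-reproducible, and the simulator
  restores the caller's RNG state.

## Limitations

Beyond the Grad-CAM caveat above: the clinical spectra behind the
reference study are not publicly deposited, so nothing here validates
diagnostic performance on real tissue; the simulator's class separations
are, by construction, more regular than biology; spectrum-level
cross-validation leaks patient identity (use `group_by_patient`); and the
published cohort tables contain internal inconsistencies (raw-to-analysis
counts that are not multiples of the stated averaging factors, and grade-
versus stage-based tumor totals differing by 120 spectra) that the package
carries as published rather than resolves.
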