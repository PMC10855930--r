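# hypersort

Hyperspectral discrimination of gluten-bearing cereal kernels (wheat,
oat) in legume lots (broad bean, chickpea, lentil), from raw acquisition
to a simulated industrial optical sorter.

Gluten-free production lines must remove *every* cereal kernel from a
legume stream; size/shape/colour sorting cannot guarantee that. In the
400–1700 nm reflectance range (261 bands at 5 nm) the two product groups
differ at a handful of wavelengths. This package implements the full
statistical pipeline around that fact:

* **Reflectance calibration** — flat-field normalisation
  `Rc = (R − D)/(W − D)` with dark (`D`) and white (`W`) reference
  frames; ENVI cube input/output (BSQ/BIL/BIP, float32/float64/uint16).
* **Seed extraction** — background removal (Otsu on the band-mean image),
  connected-component labelling, per-seed mean spectra.
* **FS-MRMR wavelength selection** — forward addition ranked by the
  mutual information quotient `MIQ = V/W`, with relevance
  `V = I(band, class)` and redundancy `W = mean over selected bands of
  I(band, z)` (plug-in estimates on discretized reflectance), stopped by
  a wrapper classifier's validation accuracy.
* **Linear maximum-margin classification** — 50/25/25 stratified split,
  5-fold cross-validation, and a zero-false-positive decision threshold:
  positives are legumes, so a false positive is a contaminant admitted
  into the accepted product.
* **Industrial sorter simulation** — broadband (15 nm) deployment on
  contaminated free-fall streams, accept/eject vessels, replicated runs,
  across-run one-way ANOVA + Tukey HSD.
* **Synthetic data generator** — spectral libraries with planted
  discriminative bands, rendered scenes with reference frames and ground
  truth, and labelled seed streams, so the whole pipeline is testable
  without any external data.

## Worked example

Plant a five-band chickpea/oat contrast, stream 443 seeds, select
wavelengths, train, and evaluate on the held-out test split:

```r
library(hypersort)

lib <- make_spectral_library(list(
  list(pair = c("chickpea", "oat"), bands = c(845, 1075, 1310, 1510, 1660),
       contrast = 0.3)), rng_seed = 1)
stream <- make_seed_stream(300, "chickpea", c(oat = 0.5), lib,
                           orientation_noise = 0, rng_seed = 4)
sp  <- split_data(stream, rng_seed = 3)
sel <- forward_select(sp$train, make_svm_wrapper(sp$train, sp$validation),
                      target_ccr = 100)
sel
#> selection_result: 2 wavelengths [ 1070, 1660 ] stop: target_reached
#>   wrapper CCR trace: 97.4 100.0

model <- set_zero_fpr_threshold(train_linear(sp$train, sort(sel$selected)),
                                sp$validation)
confusion_metrics(predict(model, sp$test), binary_labels(sp$test$labels),
                  dataset_name = "chickpea-oat",
                  wavelengths = sort(sel$selected))
#> chickpea-oat  CCR 100.00  TPR 100.00  FPR 0.00  FNR 0.00  (acc 100.00, n=75+41)
```

One band (1070 nm, adjacent to the planted 1075 nm peak) classifies 97.4%
of the validation split; adding 1660 nm reaches 100%, and selection
stops. On the untouched test split the model accepts every chickpea and
rejects every oat. `CCR` follows the result-table convention of the
field: it is the legume-class rate (TPR), so FNR = 100 − CCR counts
legumes lost to the reject stream, while FPR counts contaminants admitted
— the number a gluten-free line needs to be exactly zero.

The deployment side (`train_sorter_model()`, `sorter_config()`,
`replicate_and_test()`) pools both contaminants against one legume,
aggregates the selected bands to 15 nm windows, and streams 5000-seed
contaminated lots through the accept/eject decision; see
`vignettes/methods.Rmd` for the model, its assumptions, and the
threshold policy that keeps the accept vessel contaminant-free.

## Analysis workflow

The numbered drivers under `analysis/` regenerate the study tables under
`results/` (scene binaries go to `scratch/`):

```sh
Rscript analysis/01_simulate_and_extract.R   # scenes -> ENVI -> spectra CSVs
Rscript analysis/02_select_wavelengths.R     # FS-MRMR per pair
Rscript analysis/03_train_evaluate.R         # validation/test tables, CV, families
Rscript analysis/04_sorter_simulation.R      # replicated sorter runs + ANOVA
```

A typical `results/sorter_results.csv` row set for one legume:

```
broad_bean-contaminant-run 1   99.46  99.46  0.00  0.54
...
broad_bean-contaminant-average 99.54  99.54  0.00  0.46
```

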