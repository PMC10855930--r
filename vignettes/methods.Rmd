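---
title: "Discriminating gluten contaminants in legume streams: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminating gluten contaminants in legume streams: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Lots of broad beans, chickpeas or lentils destined for gluten-free
production must be cleared of gluten-bearing cereal kernels (wheat, oat).
Mechanical and colour sorting cannot do this reliably, because the seeds
overlap in size, shape and colour. Hyperspectral reflectance imaging can:
in the 400–1700 nm range (VNIR + SWIR, fused into one 261-band axis at
5 nm sampling) legumes and cereals differ at a small number of
wavelengths. The pipeline in this package runs from the raw acquisition to
a simulated industrial sorter:

1. **Reflectance calibration.** Raw counts are converted to relative
   reflectance with the flat-field rule `Rc = (R − D) / (W − D)`, where
   `D` is the dark frame (shutter closed) and `W` the white-panel frame,
   applied per pixel and band (`calibrate()`).
2. **Segmentation.** The acquisition background is removed by thresholding
   the band-averaged reflectance (Otsu by default), connected components
   become seeds, and each seed contributes its mean spectrum
   (`background_mask()`, `extract_mean_spectra()`).
3. **Wavelength selection.** Minimum-redundancy maximum-relevance forward
   selection over the 261 candidate bands, ranked by the mutual
   information quotient (`forward_select()`).
4. **Classification.** A linear maximum-margin classifier (linear SVM) on
   the selected bands, with a 50/25/25 stratified split, 5-fold
   cross-validation inside the training half, and a zero-false-positive
   decision threshold set on the validation split (`train_linear()`,
   `set_zero_fpr_threshold()`).
5. **Sorter simulation.** Deployment in broadband (15 nm) mode on a
   contaminated free-fall stream, replicated runs, and across-run
   one-way ANOVA with Tukey HSD (`simulate_run()`,
   `replicate_and_test()`).

Throughout, the *positive* class is the legume: the false-positive rate
(FPR) counts contaminant kernels admitted into the accepted product — the
quantity a gluten-free line must drive to zero. The headline
correct-classification rate (CCR) in all result tables equals the
legume-class rate (TPR), so CCR = 100 − FNR; the overall two-class
accuracy is reported separately (`accuracy` in `confusion_metrics()`),
and it — not the CCR — drives the selection stopping rule, because a
degenerate accept-everything model already has a perfect legume-class
rate.

## The selection statistic

For a candidate band $\lambda$ with discretized reflectance codes and
class labels $y$, relevance and redundancy are

$$V_\lambda = I(\lambda, y), \qquad
  W_\lambda = \frac{1}{|S|}\sum_{z \in S} I(\lambda, z),$$

with $I$ the plug-in mutual information (in bits) over the empirical
joint distribution of the discretized values, and $S$ the already-selected
set. Candidates are ranked by the mutual information quotient
$\mathrm{MIQ} = V_\lambda / W_\lambda$ (guarded by
$\max(W_\lambda, 10^{-12})$); the first band is chosen by $V_\lambda$
alone, since $W_\lambda$ is undefined for an empty set. After every
addition a wrapper classifier is trained on the training split and scored
on the validation split; selection stops when that score reaches the
target, at the size cap (default 10), or when candidates run out. Ties
break toward the lower wavelength so selections are reproducible.

Choices a user may care about:

* **Discretization** (`discretize()`): equal-frequency binning with 8 bins
  per band. Equal-frequency is invariant to monotone rescaling of the
  reflectance axis; 8 bins keep the plug-in estimator's bias modest at the
  sample sizes the pipeline uses (hundreds of seeds).
* **Stopping target**: the laboratory analyses in `analysis/` run with
  target 100 — selection continues until the validation split is
  classified perfectly — which matches the protocol of adding wavelengths
  until the highest classification rate is reached. A target of 99 stops
  one band earlier on strongly contrasted material and leaves a weaker
  operating margin.
* **A known limitation of MIQ**: once several strongly relevant bands are
  selected, every further relevant candidate is also redundant with them
  *through the class label*, so the mean redundancy term saturates and a
  near-duplicate neighbour of an already-selected band can tie with a new
  informative band. The wrapper stopping rule usually ends selection
  before this matters; with the stopping rule disabled, expect selected
  sets to include neighbours of informative bands rather than noise
  bands.

## The zero-false-positive operating point

After training, the decision threshold is moved so that no validation
contaminant is accepted, and then pushed halfway into the observed score
gap (anchored at the 5th percentile of accepted validation legumes). The
margin matters: a finite validation set cannot certify the extreme tail
of the contaminant score distribution, so a threshold hugging the largest
observed contaminant score leaks tail contaminants on new material.

For deployed sorter models (`train_sorter_model()`) the threshold
additionally dominates the decision value of the *zero spectrum*
(`guard_zero = TRUE`). The decision value is affine in the spectrum, so a
seed imaged at exposure $e$ scores
$e\,\mathrm{dv}(s) + (1-e)\,\mathrm{dv}(0)$; once both ends of that path
are below the threshold, every under-exposed contaminant stays rejected
no matter how weak its signal. This guard is deliberately *not* applied
to laboratory pairwise models: when a model identifies the legume as the
darker class at its bands, the zero spectrum scores on the legume side
and the guard would reject the whole stream. Deployed models also carry a
low-signal floor: seeds whose broadband mean reflectance falls below 75%
of the 1st percentile of training legumes are ejected regardless of
score, as a physical sorter ejects anything it cannot recognize.

Even with the margin, zero FPR on held-out material is a designed-for
property, not a theorem: with only two selected bands and a few dozen
validation contaminants, an occasional test-set contaminant can cross the
threshold. The deployed configuration (more bands, the zero-spectrum
guard, the floor) is the one engineered for exact zero admission, and the
replicated sorter experiments measure precisely that.

## What the synthetic generator emulates

No public acquisitions exist for this system, so every experiment runs on
synthetic data with known ground truth.

* **Spectral library** (`make_spectral_library()`): one smooth base
  reflectance curve (Gaussian-kernel smoothed noise, correlation length
  80 nm, range 0.28–0.52) shared by all classes, a small class-specific
  smooth perturbation (≤ 0.01, scaled down further for low-contrast
  pairs), and, per class pair, localized Gaussian peaks (width 12 nm) of
  the requested contrast planted at given band centers with alternating
  signs. At the planted centers the pair differs by at least the
  contrast; far from them by at most a fifth of it.
* **Scenes** (`render_scene()`): non-touching ellipses (broad bean large,
  lentil small) on a dark background, a parabolic column illumination
  profile, additive Gaussian sensor noise (sd 8 counts against a white
  span of 4000), and noiseless dark/white reference frames built from the
  same dark level and illumination — so calibrating a noiseless scene
  recovers the planted endmembers exactly, which the tests exploit.
* **Seed streams** (`make_seed_stream()`): per-seed spectra with three
  variation components — multiplicative lognormal brightness
  (sdlog 0.06; intact/broken units, presentation), a *smooth* spectral
  deviation (per-band sd 0.07, correlation length 450 nm; seed-coat
  scattering and composition shift the baseline coherently over hundreds
  of nm — this is the dominant term), and a small independent residual
  (sd 0.008). With probability `orientation_noise` (default 0.005) a seed
  presents its profile to the optics and its whole spectrum is attenuated
  by a uniform factor in [0.2, 0.6]. Laboratory analyses set
  `orientation_noise = 0`: degraded exposure is an in-flight phenomenon.

The smooth long-range deviation is what makes the *pair* of planted bands
worth more than either alone: a single band carries the full baseline
noise, while a linear combination of two bands with opposite-sign
contrasts cancels much of it. That is also why forward selection needs
the second band to reach a 99% validation score on 0.2-contrast material,
mirroring how multi-band selections arise in practice.

What the generator does **not** model: touching or overlapping seeds,
heteroscedastic or spatially structured sensor noise, the VNIR/SWIR
sensor boundary at 1000 nm (treated as one fused axis), spectral smile,
stone contaminants with realistic spectra (a flat dark curve is available
but disabled by default), and any seed-transport physics. Passing tests
therefore demonstrate the statistical machinery, not radiometric
fidelity on real acquisitions.

## Study sizes and numerical choices

The packaged analyses and tests use: ~400–900 seeds per laboratory pair
(30 from a rendered scene, the rest streamed), 50/25/25 splits, 5-fold
cross-validation, deployment training streams of 3000 legumes with 5%
wheat + 5% oat doses, and sorter runs of 5000 seeds replicated five
times. Planted contrasts are 0.3 (reflectance units) for the
paper-configuration experiments — laboratory-grade material separates
essentially perfectly, as the published validation tables show — and 0.2
for the harder band-recovery experiments. The across-run ANOVA uses the
per-seed correct/incorrect indicator grouped by run (a single CCR per run
leaves no within-group variance); when every seed in every run is
classified identically the ANOVA is flagged degenerate rather than
computed. Division guards: `eps = 1e-12` for the calibration reference
span (dead pixels yield 0 with a counted warning) and for the MIQ
denominator. Band-recovery claims are asserted at the acquisition
resolution: the planted peaks are 12 nm wide against a 5 nm grid, so a
selected band one grid step from the planted center identifies the same
optical feature.

## Reproducing the tables

The numbered drivers under `analysis/` regenerate every table from
scratch: `01_simulate_and_extract.R` (scenes → ENVI → calibration →
per-seed spectra), `02_select_wavelengths.R` (per-pair FS-MRMR),
`03_train_evaluate.R` (validation/test tables, cross-validation, family
comparison), `04_sorter_simulation.R` (replicated broadband sorter runs
with ANOVA/Tukey). `scripts/acceptance.R --seed <s> --out <path>`
recomputes the headline quantities end to end and writes them as JSON.
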