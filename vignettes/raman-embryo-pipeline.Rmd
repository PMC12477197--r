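---
title: "Methods: classifying embryo culture outcomes from spent-medium Raman spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying embryo culture outcomes from spent-medium Raman spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(ramanblast)
```

## The problem

In IVF laboratories, Day 3 (cleavage-stage) embryos are selected mostly by
morphology, which predicts poorly which embryos would develop into good
blastocysts under extended culture. The metabolic footprint an embryo
leaves in its culture medium is an attractive non-invasive alternative
readout: a 10 µL droplet of spent medium, air-dried and probed by Raman
micro-spectroscopy, yields 30–40 replicate spectra per sample whose
fingerprint region encodes amino-acid, protein and carbohydrate turnover.

`ramanblast` implements the complete analysis for a three-class outcome:
**A** — morphologically good blastocyst, **B** — non-good blastocyst,
**C** — clinically non-useful embryo. The stages are: spectral
preprocessing, per-peak group statistics, dimensionality-reduction views,
a twelve-family classifier comparison with class balancing, stacking of
the best models, and mode-based aggregation of spectrum-level predictions
into one decision per sample.

Because no raw spectra are publicly deposited for this kind of study, the
package ships a synthetic-spectrum generator that reproduces the
*statistical structure* the analysis assumes, so every stage is testable
end to end. Published real-data performance figures are consequently not
reproduction targets; what the test suite establishes is that each
algorithmic component behaves correctly and that the pipeline's
statistical properties (chance-level behaviour under label shuffling,
vote amplification, stacking non-degradation) hold.

## The synthetic generator

Each spectrum is

$$y(\nu) = b(\nu) + \sum_{j=1}^{18} a_j
  \exp\!\left(-\frac{(\nu-\mu_j)^2}{2\sigma_j^2}\right)
  + \varepsilon(\nu) + \text{spikes},$$

on a 300–3400 cm⁻¹ grid at 1 cm⁻¹ (3101 points). The 18 peak centres
$\mu_j$ are the core positions observed in dried spent medium (506, 620,
642, 662, 750, 850, 898, 938, 1000, 1030, 1120, 1202, 1332, 1446, 1605,
1654, 2874, 2926 cm⁻¹). Gaussian widths default to 4–8 cm⁻¹ in the
fingerprint region and 10–11 cm⁻¹ for the CH-stretch bands; peak shape is
a design choice (a Voigt profile would change nothing structurally).

Peak amplitudes are hierarchical log-normal:
$a_j = m_{gj} \cdot L_{\text{sample}} \cdot L_{\text{replicate}}$ with a
per-sample random effect (CV 0.10 by default, per template) shared by all
replicates of one sample and a per-replicate effect (CV 0.15). This is
what makes per-sample majority voting a meaningful operation to test:
replicate spectra of one sample are correlated, as in real acquisitions.

The group means $m_{gj}$ encode the ten published intensity patterns —
for example A > B > C at 750 and 938 cm⁻¹, A < B < C at 1202 cm⁻¹, and
A ≈ B ≈ C at 1120 and 1654 cm⁻¹. Tied groups receive *exactly* equal
means, so significance between them can arise only as a type-I error.
Strictly ordered groups are separated by 12 % of the base amplitude per
rank step, scaled by a single `separability` knob (1 = the default subtle
structure; 0 erases all group differences; ≥ 3 gives well-separated
classes for calibration experiments). For the two single-significant-pair
patterns (B > A at 506 cm⁻¹ with C in between; C > B at 2874 cm⁻¹) the
in-between group sits at the midpoint. Note that with group sizes
58/25/89 the standard errors of the three pairwise contrasts are too
similar for the extreme pair to be significant while both half-gaps stay
non-significant — such panels are intrinsically marginal outcomes, which
is why pattern-recovery checks use a 16-of-18 floor.

Defaults mirror the study conditions: 58/25/89 samples per group, a
uniform 30–40 replicate count per sample, baseline drift (offset, slope,
and a broad Gaussian hump centred near 1400 cm⁻¹ with width 600 cm⁻¹ to
exercise the baseline corrector), additive noise (SD 0.02 in peak
amplitude units), and Poisson cosmic-ray spikes (rate 0.2 per spectrum,
height ~20× the local signal). One master seed drives deterministic
per-sample substreams, so a fixed seed fixes every array bit for bit.

What the generator does **not** emulate: instrument line-shape functions,
detector etaloning, wavenumber miscalibration, water-band interference,
site-to-site heterogeneity on the dried droplet, and any real biochemical
covariance between peaks. Passing tests therefore demonstrate algorithmic
correctness and statistical calibration, not clinical performance.

## Preprocessing

The pipeline applies, in this order: quality control → despiking →
truncation/resampling → baseline correction → smoothing → normalization.
Order matters (normalizing before baseline correction redistributes the
baseline area) and is regression-tested.

* **Quality control.** No SNR definition is standard for this material, so
  the package uses: signal = maximum linearly-detrended intensity in the
  600–1800 cm⁻¹ fingerprint region, read off a lightly Savitzky–Golay
  smoothed copy of the spectrum — over ~1000 grid points the *maximum* of
  pure noise already reaches 3–4 noise SDs, so an unsmoothed maximum would
  let featureless spectra pass; noise = 1.4826 × MAD of the residuals of a
  linear fit over the 1800–2600 cm⁻¹ Raman-silent region of the raw
  spectrum. Spectra with SNR below `snr_min` (default 3) are excluded,
  each with a logged reason code.
* **Despiking.** The "filter size 4, dynamic factor 6" rule of the
  instrument software is undocumented; it is interpreted as a running
  median over ±4 points with a spike threshold of 6 × the scaled window
  MAD, spikes replaced by the window median. This is idempotent and
  matches a brute-force oracle in the tests.
* **Resampling.** Linear interpolation onto 300–3400 cm⁻¹ at 1 cm⁻¹
  (3101 points, inclusive endpoints).
* **Baseline.** Asymmetric least squares (iteratively reweighted Whittaker
  smoothing): minimize $\sum_i w_i (y_i - z_i)^2 + \lambda \sum (\Delta^2
  z)^2$ with $w_i = p$ above the baseline and $1-p$ below. Defaults
  λ = 10⁵, p = 0.01, 10 iterations — the canonical values; the inner
  pentadiagonal solve is compiled for speed. At p = 0.5 the scheme reduces
  to a symmetric Whittaker smoother, which the tests exploit as an oracle.
* **Smoothing.** Savitzky–Golay with polynomial order 3. A window
  "length 10" is even and inadmissible for the centred construction, so
  the default is the nearest odd value, 11, configurable.
* **Normalization.** Total (summed) intensity scaled to 100. On the
  uniform grid this differs from a trapezoidal integral only at the two
  endpoints.

## Peak statistics and pattern labels

Peak intensity is the maximum within ±5 cm⁻¹ of the nominal position
(tolerant to jitter). Pairwise group differences use two-sided
Mann–Whitney U tests by default (spectral intensities are not normal;
Welch t is available), starred at 0.05/0.01/0.001 with no multiplicity
correction — mirroring per-pair annotation practice; a Holm option
exists. The unit of analysis defaults to individual spectra; a
`unit = "sample"` option first averages each sample's replicates, which is
the statistically safer choice given within-sample correlation and is
what the package's own recovery checks use.

The classifier maps (three means, three significance flags) to one of the
ten enumerated pattern labels. Full orderings require all three pairs
significant; one tied pair gives the A≈B<C / A>B≈C / A≈C>B forms when the
direction matches; exactly one significant pair is labelled by its
direction only when the label is one of the enumerated ten (B>A, C>B);
no significance gives A≈B≈C; every other configuration returns `"other"`
rather than guessing a nearest pattern.

## Embeddings

* **t-SNE** — exact (dense) implementation with perplexity calibration by
  bisection, early exaggeration 12 for the first 100 iterations, momentum
  0.5→0.8, learning rate 200. O(n²) per iteration, fine at desk scale.
* **LaDA** — the supervised framing in the source material is ambiguous
  (Latent Dirichlet Allocation is unsupervised); the package fits an
  unsupervised LDA topic model by vectorized variational EM on
  pseudo-counts `round(100 × intensity)` and colours the topic-proportion
  embedding by the known labels. Small negative post-processing ripples
  are clipped; genuinely negative input errors.
* **OPLS-DA** — NIPALS-based, implemented from scratch: one-hot class
  matrix, removal of `n_orth` (default 1) X-components orthogonal to
  class membership, then predictive PLS components (two for three
  classes; the embedding is predictive score 1 × 2, or score 1 ×
  orthogonal score 1 for two classes). R²X is reported split into
  predictive and orthogonal parts; invariance of predictive scores to
  class-orthogonal nuisance directions — the property OPLS is defined
  by — is tested directly.

## Models

Twelve families: MLP, ANN, GRU (deep) and GB, KNN, RF, LSVM, LDA, LR,
QDA, RSVM, NB (traditional). Splitting is at the **sample** level, 80 %
per group to training (floor), so 58/25/89 gives exactly 137 training and
35 prediction samples; no spectrum of a prediction sample ever reaches
training or SMOTE. SMOTE (k = 5) is applied to the training spectra after
the split, equalizing classes to the majority count with convex
same-class interpolants; synthetic rows get fresh pseudo-sample
identifiers so cross-validation folds stay honest.

Traditional families train on principal-component scores of the spectra
(up to 30 components) — standard chemometrics, and required for LDA/QDA
covariance estimates at p = 3101 ≫ n. Deep families consume the full
spectrum, centred per channel and scaled by the *pooled* standard
deviation: per-channel autoscaling would inflate the silent spectral
region into unit-variance noise, which measurably harms the recurrent
model. Architectural choices (the source names the families but not the
architectures): ANN = one hidden layer of 64 ReLU units; MLP = two hidden
layers 128/64; GRU = unidirectional single layer (32 units) over the
spectrum chunked into 50-point patches, softmax head on the final hidden
state. All three are trained full-batch with Adam, early stopping on a
fixed 15 % validation split (patience 8), best weights restored;
gradients are verified against finite differences in the tests. RSVM is
read as a reduced support-vector machine: an RBF SVM fitted on a random
stratified ~10 % subset of candidate support vectors, which reproduces
its characteristically weak ranking. Cross-validation is stratified at
the sample level, k = 5, with deliberately small hyperparameter grids
(≤ 3 configurations per family); the deep families are scored at fixed
defaults.

Evaluation is one-vs-rest: per-class sensitivity (recall) and specificity
(true-negative rate), macro averages, accuracy, and per-class ROC-AUC
from predicted probabilities.

## Stacking and per-sample decisions

The top-4 models by prediction accuracy (ties: sensitivity, then name)
feed a Wolpert stack: 5-fold out-of-fold class probabilities on the
training spectra form the design of a multinomial logistic-regression
meta-learner (the source does not name one; multinomial LR is the
standard choice and keeps the meta-model convex), after which the bases
are refitted on all training data. Per sample, the final label is the
mode of its spectra's predicted labels; ties break by highest mean
predicted probability among the tied labels, then training-set class
prevalence, then alphabetically — fully deterministic. The per-sample
fraction of correctly predicted spectra is histogrammed in fixed 10 %
bins together with the share of samples above 50 %.

## Numerical choices and degenerate inputs

Seeds: every stochastic routine takes an explicit seed and derives
independent substreams (multiplicative hashing), so results are
reproducible without touching the caller's RNG state. Degenerate cases
are errors with actionable messages: spectra shorter than the despiking
window, grids not covering the target range, non-positive total
intensity, single-class OPLS-DA, classes smaller than the SMOTE
neighbourhood, groups whose split side would be empty. Constant columns
after centring are dropped with a warning in OPLS-DA; probability columns
from base learners are aligned and renormalized defensively.

## Problem sizes used by the test-suite

The suite emulates the study at reduced scale so the whole run stays
desk-sized: most property checks use 34 samples (12/10/12) with 5–6
replicate spectra on a 4 cm⁻¹ grid (776 points), while the
generator-fidelity check runs the full default configuration (172
samples, 30–40 replicates, 3101 points) once. The ensemble properties
(stack accuracy within 0.03 of the best base; sample-level ≥
spectrum-level accuracy) are asserted pooled over five seeded replicate
runs, because single prediction sets of ~7 samples are too small for a
per-seed guarantee.

## Known limitations

* The generator's independence assumptions (peaks vary independently up to
  the shared sample effect) make the classification task better behaved
  than real spectra; absolute accuracies on synthetic data say nothing
  about clinical accuracy.
* Significance-based pattern labels for the single-significant-pair
  panels are intrinsically unstable at these group sizes (see above).
* libsvm's internal probability calibration is not seed-controlled by R,
  so SVM probability outputs can vary at the last digit across platforms;
  deterministic families are byte-reproducible.
* The t-SNE and LDA implementations are exact/dense and intended for at
  most a few thousand spectra.
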