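---
title: "Methods: channel-isolated ECG deep learning, per-lead saliency, and risk stratification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: channel-isolated ECG deep learning, per-lead saliency, and risk stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Saliency methods for multilead electrocardiograms usually attribute a
prediction to a map shared across leads, because the first convolution
mixes all leads into common channels. That makes statements of the form
"lead V1 drove this diagnosis" impossible. `cardiolens` implements an
*isolation-integration* architecture that keeps the leads separate long
enough to make per-lead attribution exact: each of the L leads passes
through its own small convolutional encoder (same architecture,
independent parameters), the per-lead channel blocks are concatenated
into one feature matrix, and only then does a shared residual trunk
integrate information across leads for classification. Because channel
block j is a function of lead j alone, any class-activation weighting of
the feature matrix decomposes exactly into per-lead maps.

## Model

Each per-lead encoder applies two 1-d convolutions (kernel 17, C = 8
channels) of which one has stride 2, so the concatenated feature matrix
has exactly half the temporal length of the input; upsampling a map back
to the input grid is then a magnification by exactly 2. The integration
trunk applies 4 residual blocks (kernel 9, 16 channels, stride-4 average
pooling after each block), a global average pool and a linear sigmoid
head per label. The trunk width and depth are free choices of this
implementation, sized so that the benchmark tasks train in CPU minutes;
the architectural *contract* — per-lead parameter isolation, downsample
factor exactly 2 — is what the saliency procedure depends on, not the
layer inventory.

Training uses binary cross-entropy with positive-class weights
`n_neg/n_pos` capped at 20, the Adam optimizer (learning rate 1e-3),
per-lead input standardization with training-set statistics stored in
the model, an internal validation split (20%) and early stopping on
validation loss; the returned parameters are those of the best
validation epoch. All randomness (initialization, split, shuffling)
derives from one seed, and two runs with the same seed on the same
machine (fixed BLAS threading) produce identical histories.

## Per-lead saliency

For a chosen label the procedure is:

1. gradient of the label's *pre-sigmoid logit* with respect to every
   entry of the concatenated feature matrix (backpropagation through
   the trunk only);
2. per-channel kernel weights: the temporal mean of that channel's
   gradient (per recording — no batch averaging);
3. within each lead's channel block, the weighted channel sum followed
   by a ReLU, so only positively contributing time points survive;
4. linear-interpolation upsampling by exactly 2 (nearest-neighbour
   available behind a flag when bit-exact block maps are wanted);
5. normalization by the single global maximum across all 12 leads, so
   per-lead masses remain comparable; an all-zero map stays zero.

Targeting the logit rather than the probability is the conventional
choice; for a single label the two differ by the positive factor
`p(1-p)` and produce identical normalized maps. Global (rather than
per-lead) normalization is required because downstream lead ranking
compares heatmap mass *across* leads. Both choices are exposed as
arguments.

Dominant-lead derivation filters records with predicted probability
strictly greater than 0.8, sums the heatmap per lead, takes the argmax
lead (ties break to the lowest index in the fixed lead order; all-zero
maps are excluded), and tabulates occurrences with a bootstrap over
records (B = 1000) for dispersion. Lead subsets are chosen by the
strict >10% occurrence rule, and reduced-lead models are *retrained
from scratch* on the selected leads rather than zero-masking the
12-lead model, so the comparison measures the information content of
the leads, not the robustness of one fitted network.

## Synthetic data: what it emulates, and what it does not

No large clinical ECG repository can ship with a package, so every
stage is validated against a generator with planted ground truth.

* **Beat morphology** is a sum of Gaussian deflections (P, Q, R, S, T,
  U) per lead with a fixed 12-lead mixing table (DII as reference, AVR
  inverted, an rS complex in V1, growing R across the precordial
  leads). Q/R/S centres and widths scale with the QRS duration; the P
  wave is placed so that the designed PR interval (2-sigma onsets)
  equals the rhythm's parameter.
* **Abnormalities** follow textbook thresholds, since the source
  labelling criteria are not public: first-degree AV block draws PR in
  [0.21, 0.36] s; bundle branch blocks draw QRS in [0.12, 0.16] s with
  opposite V1/V6 signatures; sinus bradycardia draws 40-55 bpm and
  sinus tachycardia 101-150 bpm; atrial fibrillation removes P waves,
  draws an RR coefficient of variation in [0.15, 0.30] and adds a
  4-9 Hz fibrillatory wave. A rule-based measurer (threshold R-peak
  detection, slope-based QRS delineation, P-window search) recovers
  every injected abnormality on noise-free records; its two calibrated
  details are documented in the code: QRS boundaries use steep-slope
  excursions because amplitude walks fail when T waves merge at high
  rates, and PR is not assessed above 99 bpm for the same reason.
* **Covariates in the tracing**: male sex scales the T wave by 1.2 and
  lowers heart rate by 4 bpm; hypertension raises the V1 R amplitude by
  30% and widens the DII P wave by 50%. These magnitudes are free
  parameters of the simulator chosen to be learnable but not trivial.
* **Cohort structure** defaults: 60.26% female, 31.66% hypertensive,
  age 53.64 +/- 17.42 years (truncated to [18, 95]), abnormality
  prevalences of 1-3%, and a 3.34% event fraction over 7 follow-up
  years with a mean follow-up shortened by 10% uniform dropout.
* **Survival times** are exponential with hazard
  `lambda0 * exp(x' beta)`; `lambda0` is tuned by solving the
  closed-form expected event fraction for the realized covariates.
  Censoring is the minimum of 7-year administrative follow-up and the
  uniform dropout time.
* **Noise** is pink-ish baseline wander (three low-frequency sinusoids
  with amplitude rising toward low frequency) plus white noise at a
  configurable SNR (default 20 dB).

The generator's records are stationary, single-rhythm, and noise-benign;
they contain no electrode artefacts, no pacing, no atrioventricular
dissociation and no morphology drift within a record. Passing the
planted-signal benchmarks therefore demonstrates that the architecture,
saliency math and lead ranking behave as designed — not that the model
reaches clinical performance on real tracings.

A single global seed drives everything; per-subject streams are derived
by a counter split, so any subset of a cohort regenerates bit-identically.

## Planted benchmarks

The interpretability benchmark plants a cosine-tapered 30 Hz, 0.4 mV
sinusoid of 0.8 s at a random onset in lead V1 of half the records. The
standard study size is 500 training and 200 test records of 1024
samples; module-level tests use a compact variant (2.56 s at 100 Hz,
160/80 records) so the default suite runs in minutes. A trained model
must reach test AUC at least 0.95, assign at least 90% of confidently
predicted records a V1 dominant lead, and place at least 60% of each
confident record's V1 heatmap mass inside the planted window dilated by
0.1 s.

The survival benchmark plants known hazard ratios: cohorts of 20,000
subjects with the event fraction tuned to 3.3% and either a single
binary covariate (prevalence 0.32) or an adjusted design with age, sex,
hypertension and low-prevalence rhythm indicators. At these event
counts (roughly 650) the standard error of a log hazard ratio is about
0.07 for the common covariate and 0.13 for the 4-5% indicators, so
single-replicate estimates scatter accordingly around the planted
values; the suite checks recovery at a fixed seed, and a separate
Monte Carlo (30 replicates) verified the estimator is unbiased.

## Evaluation statistics

AUC is the rank-based Mann-Whitney statistic (ties counted one half) —
verified in the tests against exhaustive pair counting, trapezoidal ROC
integration and an established external implementation. Micro-averaged
F1 pools TP/FP/FN across labels before computing precision and recall
(a regression test guards against the macro average). The diagnostic
odds ratio is (TP*TN)/(FP*FN) with the Haldane-Anscombe +0.5 correction
whenever a cell is zero, and a log-normal Wald interval. The G-mean
operating point scans all candidate thresholds for the maximum of
sqrt(sensitivity * specificity), ties to the lowest threshold.
Uncertainty is quantified by a seeded percentile bootstrap over records
(B = 1000, 95% by default); undefined precision at zero predicted
positives is reported as 0 with a warning rather than NaN; age
subgroups use half-open bins [0, 45), [45, 75), [75, Inf). The paired
model comparison doubles the sign-flip fraction of the bootstrap
metric difference, capped at 1 — a documented stand-in, since the
source of published p-values for such comparisons is not stated.

## Survival stage

Kaplan-Meier curves and Cox proportional-hazards fits are delegated to
the survival package (product-limit estimator; Newton-Raphson partial
likelihood with the Efron tie correction by default and Breslow behind
a flag), surfaced through `km_estimate()`, `cumulative_events()`,
`cox_fit()` and `hazard_ratios()` with Wald 95% intervals. The tests
hold these against hand-computed product limits and a grid search of
the partial likelihood. Age enters adjusted models as a continuous
covariate in years; the published age bins are treated as
presentational. Model-predicted phenotypes are binarized at the G-mean
operating point (`binarize_at_gmean()`) before entering survival
models, since the operating point used in the source analyses is not
stated.

## Numerical choices and degenerate inputs

* Convolutions use "same" padding with odd kernels, so temporal lengths
  are `ceiling(T / stride)` exactly; the encoder's stride pattern (1, 2)
  is hard-coded to guarantee the half-length contract.
* Early stopping compares against the best validation loss with strict
  improvement; `patience = 1` on a constant loss stops after 2 epochs.
* An all-zero heatmap yields an undefined dominant lead, which is
  excluded from distributions; an empty confident set is an explicit
  error.
* `lambda0` tuning solves on the log scale with `uniroot` over
  [e-20, e5].
* Bootstrap resamples that cannot compute a metric (single-class
  resample) propagate as NA and are dropped from the percentile
  interval.

## Problem sizes in the shipped suite

The default test suite trains the compact benchmark (160/80 records of
256 samples, about 15 s), three reduced-lead variants, and one
full-scale benchmark (500/200 records of 1024 samples) inside the
acceptance tests; the bootstrap coverage study uses 200 simulations of
100 records with B = 200. These sizes were chosen so the whole suite
completes in well under half an hour on a single CPU while still
exercising every stage at the standard study scale.

## Known limitations

* The generator's abnormality thresholds are stand-ins for the source
  data's (unpublished) annotation criteria; agreement of the rule-based
  measurer with the injected labels says nothing about agreement with
  clinical annotators.
* Heatmap *localization* inherits the encoder's receptive field
  (about 50 samples), so attribution sharper than ~0.1 s at 400 Hz is
  not meaningful.
* The survival stage models a single terminal event with
  administrative censoring and uniform dropout; competing risks and
  time-varying covariates are out of scope.
* Dataset bundles are plain text (gzipped CSV tracings with a hashed
  manifest) rather than a binary scientific container; at a few
  thousand records this is adequate, far beyond that it is not.
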