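# cardiolens

Interpretable deep learning for multilead electrocardiograms, with the
downstream epidemiology to use its predictions: an
*isolation-integration* convolutional network whose saliency maps are
exact per lead, dominant-lead ranking and reduced-lead retraining,
classification metrics with bootstrap uncertainty, and mortality risk
stratification via Kaplan–Meier curves and Cox proportional-hazards
models. A synthetic 12-lead ECG and cohort simulator with planted
ground truth makes every stage verifiable without access to clinical
data.

**Who it is for.** Researchers studying ECG interpretability — which
leads carry the signal for a given diagnosis, and whether a reduced
lead set suffices — and anyone who needs a fully testable, CPU-scale
reference implementation of per-lead gradient saliency for 1-d
multichannel signals.

## The model in brief

Each lead ℓ of a 12 × T recording passes through its **own**
convolutional encoder (shared architecture, independent weights) with
total temporal stride 2, producing a channel block **F**⁽ℓ⁾ of size
C × T/2. The concatenated feature matrix **F** (12·C × T/2) feeds a
shared residual trunk g(·) and sigmoid heads. For a label with logit
z, the per-lead saliency is

  α_c = (2/T) Σ_t ∂z/∂F[c, t]    (kernel weight per channel)

  M⁽ℓ⁾(t) = ReLU( Σ_{c ∈ block ℓ} α_c · F[c, t] )

upsampled ×2 to the input grid and normalized by the single global
maximum over all leads. Because block ℓ depends only on lead ℓ (an
architectural invariant, asserted to machine precision in the tests),
M⁽ℓ⁾ is an exact per-lead attribution. Records predicted with
probability > 0.8 are summarized by their **dominant lead**
argmax_ℓ Σ_t M⁽ℓ⁾(t); leads dominating > 10% of confident records form
the reduced lead subset, which is retrained from scratch for
evaluation. Survival uses Cox models, HR = exp(β) with Wald 95% CIs
(Efron ties), on recorded or G-mean-binarized predicted phenotypes.

## Worked example

Train on the planted-lead benchmark — synthetic 12-lead ECGs where
positive records carry a 30 Hz transient hidden in lead V1 — then ask
the model which lead mattered:

```r
library(cardiolens)
bm <- planted_lead_benchmark(n_train = 160, n_test = 80,
                             input_length = 256, fs = 100, seed = 0)
cfg <- ecgnet_config(n_leads = 12, input_length = 256, seed = 0)
model <- ecgnet(bm$x_train, bm$y_train, cfg, epochs = 10, seed = 0)
roc_auc(predict(model, bm$x_test)[, 1], bm$y_test)
#> [1] 1
dominant_distribution(model, bm$x_test, 1, tau = 0.8, B = 500, seed = 1)
#> Dominant-lead distribution for label 'label1' (43 confident records, B = 500)
#>  lead count percent  occurrences
#>    DI     0    0.0%  0.0 +/- 0.0
#>   ...
#>    V1    43  100.0% 43.0 +/- 0.0
#>   ...
```

All 43 confidently predicted records are attributed to V1 — the planted
lead. `explain(model, record)` returns the full 12 × T heatmap
(`plot(record, heatmap = explain(model, record))` overlays it), and
`reduced_lead_train(x, y, "V1")` retrains on the selected lead alone.

The survival stage recovers planted hazard ratios from simulated
cohorts (n = 20,000, event fraction tuned to 3.3% over 7 years):

```r
hr <- cox_recovery_benchmark(c(hypertension = 1.70),
                             c(hypertension = 0.32),
                             mode = "univariate", seed = 0)
hr$fit
#> Cox proportional-hazards fit (efron ties): n = 20000, events = 636
#>     covariate      beta         se      HR (95% CI)            p
#>  hypertension 0.5378113 0.07979017 1.71 (1.46-2.00) 1.580386e-11
```

A thin command-line front end (`exec/cardiolens`) exposes the pipeline
as `simulate`, `train`, `predict`, `explain`, `leads`, `eval` and
`survival` subcommands over plain-text dataset bundles.

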