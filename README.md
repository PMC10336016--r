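# mcispan

Joint modelling of mild cognitive impairment (MCI) stage and time to
conversion to Alzheimer's disease (AD) from two tabular feature blocks — a
clinical block (demographics, cognitive scores, volumetric biomarkers) and
a radiomics block (quantitative image-derived features). The package is
aimed at researchers studying MCI progression who want a single model that
simultaneously

* classifies early vs late MCI (eMCI = 0, lMCI = 1), and
* scores each subject's hazard of converting to AD, under right censoring.

## The model

Each feature block `Z` is encoded by a **stacked polynomial attention
network (SPAN)**. One sub-network forms

```
X1 = W_Z Z + b_Z                    (affine projection)
Xk = X(k-1) ∘ X1,  k = 2..n         (componentwise monomials, Xk = X1^k)
M  = softmax(w_n Xn + … + w_1 X1 + b)   (attention over feature channels)
Ẑ  = X1 ∘ M                         (attended representation)
```

Two sub-networks are chained per stack, with a SELU activation on the
second stack's output; stacks alternate with dropout to form a branch.

The two branch encodings are mixed by a learned **adaptive exponential
decay (AED) gate**

```
τ = maxpool( sigmoid( W_τ exp(-max(0, U_τ I_clinical)) + b_τ ) )
I_fused = τ I_clinical + (1 − τ) I_radiomic ,    τ ∈ (0, 1)
```

and a fully connected head feeds two outputs that share the fused
representation: `ŷ_pr = sigmoid(W_cl I + b_cl)` (lMCI probability) and
`ŷ_hr = W_hr I + b_hr` (log-relative hazard). Training jointly minimizes

```
L = BCE(ŷ_pr, y) + CoxPartialNLL(ŷ_hr; T, E)
```

with full-batch risk sets, Adam with decoupled weight decay, and an
internal validation split that checkpoints the best epoch. Gradients are
analytic (hand-derived backpropagation, verified against finite
differences to < 1e-4 relative error).

Around the model the package provides leakage-safe preprocessing (one-hot
encoding, z-score and maximum normalization, intracranial-volume scaling,
chained-equations imputation), time-to-event construction from visit
histories, survival metrics (Harrell's concordance, IPCW Brier score,
Breslow baseline hazard with median-survival-time MAE), classification
metrics, stratified 5-fold cross-validation with provenance-tagged fit
statistics, a seeded synthetic cohort generator, and a fusion-by-encoder
ablation grid.

Because the MCI cohorts this model targets are access-restricted, the
package ships a **synthetic cohort generator**: Weibull proportional
hazards driven by standardized latent clinical and radiomics effects, a
stage label correlated with the latent risk, uniform administrative
censoring calibrated to realistic per-stage censoring rates, and MCAR
missingness in the clinical block.

## Worked example

```r
library(mcispan)

tab <- generate_cohort(cohort_spec(seed = 1))   # 800 subjects
dm  <- build_design_matrices(tab, default_schema(tab))
fit <- span_mtl(dm$clinical, dm$radiomics, dm$stage, dm$time, dm$event,
                control = train_control(epochs = 100))
print(fit)
#> Multimodal multitask MCI model (span encoder, aed fusion)
#>   800 subjects, 275 events (65.6% censored), 11 + 20 input features
#>   trained 100 epochs: BCE 0.4680, Cox NLL 5.2859, total 5.7539

head(predict(fit, type = "risk"), 3)   # log-relative hazard per subject
#> [1] -6.549  2.025 -1.927
head(predict(fit, type = "prob"), 3)   # P(lMCI)
#> [1] 0.187 0.967 0.269
head(predict(fit, type = "time"), 3)   # predicted conversion days
#> [1] 2172  290 2172

rep <- cross_validate(tab, k = 5, seed = 1)     # held-out evaluation
round(rep$mean, 3)
#>       CI       BS MAE_days      Acc       AP      Pre      Rec       F1      AUC
#>    0.769    0.123  651.038    0.779    0.918    0.822    0.834    0.827    0.860
```

The held-out concordance (0.77) and AUC (0.86) sit well above their
permuted-null counterparts (≈ 0.5), showing that both the ranking and the
classification head recover the simulated signal; the Brier score at the
median-event-time horizon is 0.12.

A YAML-configured command line (installed at `exec/mcispan`) wraps the
same functions:

```sh
mcispan simulate      --config run.yaml --with-truth
mcispan preprocess    --config run.yaml
mcispan cv            --config run.yaml
mcispan ablation-grid --config run.yaml
```

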