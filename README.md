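# dfbcsp — discriminative filter-bank CSP for motor-imagery EEG

`dfbcsp` is an R package for decoding upper-limb motor imagery from
few-channel EEG (C3/Cz/C4 at 250 Hz). It is aimed at BCI and
neurorehabilitation researchers who want a complete, testable reference
implementation of the filter-bank common spatial pattern pipeline —
from raw multichannel signal to cross-validated statistics — plus a
synthetic ERD/ERS generator so everything can be exercised without
access to recordings.

## The method

Imagined limb movement suppresses mu (8–12 Hz) and beta band power over
the contralateral sensorimotor cortex (ERD) and enhances it
ipsilaterally (ERS). **CSP** finds spatial filters that maximize the
variance ratio between two classes: with trace-normalized class
covariances R̄₁, R̄₂, whiten the composite R = R̄₁+R̄₂ = UλUᵀ with
P = λ^(−1/2)Uᵀ, diagonalize S₁ = PR̄₁Pᵀ = Bλ₁Bᵀ (so λ₁+λ₂ = I), and
project trials through W = BᵀP; features are normalized variance shares
f_j = Var(Z_j)/ΣVar(Z). **DFBCSP** applies this per sub-band after
splitting 4–40 Hz into nine 4-Hz bands, ranks bands by the mutual
information MI_k = Σ p(f,y) log₂ p(f,y)/(p(f)p(y)) between discretized
features and labels, and concatenates the top-m bands' features for a
linear SVM, a 64-unit ReLU MLP, or shrinkage LDA. Evaluation covers
stratified 5-fold cross-validation, Cohen's kappa, (macro-)ROC AUC,
t-based confidence intervals, and repeated-measures ANOVA with
Bonferroni-corrected paired t-tests.

See `vignettes/dfbcsp-methods.Rmd` for the full model description,
parameter rationale, and validation design.

## Worked example

Simulate a two-class session (left-limb imagery vs. rest, 100 trials
per class), preprocess it exactly as the pipeline prescribes, and
cross-validate the filter-bank decoder:

```r
library(dfbcsp)

sim <- generate_recording(sim_spec(n_trials_per_class = 100, seed = 1))
es  <- preprocess_recording(sim$recording)   # epoch, reject >100 uV, 4-40 Hz

fit <- fit_dfbcsp(es)                        # 9-band CSP + MI ranking
print(fit)
#> dfbcsp_model (left vs relax)
#>   MI (bits): 0.181 0.293 0.217 0.348 0.195 0.140 0.051 0.032 0.037
#>   selected bands: 16-20 Hz, 8-12 Hz, 12-16 Hz, 20-24 Hz

res <- evaluate_method(es, feature = "dfbcsp", classifier = "mlp", seed = 1)
print(res)
#> DFBCSP + MLP: accuracy 0.9400 (folds: 0.900 0.950 0.950 0.950 0.950), kappa 0.880, AUC 0.980
```

The MI ranking concentrates on the modulated rhythms — mu (8–12 Hz)
and the lower beta bands (16–24 Hz) — while the unmodulated high-beta
bands (28–40 Hz) score near zero, and the decoder reaches the
mid-90s accuracy and kappa ≈ 0.9 expected for a clearly expressed
ERD/ERS pattern; the AUC close to 1 indicates a wide decision margin. A ready-made comparison of all six method
combinations (CSP/DFBCSP × LDA/SVM/MLP) is available through
`run_pipeline()`, or from the shell:

```sh
exec/dfbcsp run --out results/demo --seed 1
exec/dfbcsp report --report results/demo/report.json
```

The package also ships the per-subject accuracy and kappa tables of a
published 16-subject study of this pipeline (`study_table()`), whose
aggregate rows `column_summary()` reproduces.

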