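# pairsurv

Prognostic analysis of paired tumor and tumor-adjacent normal
transcriptomes.

## The scientific question

Tumor-adjacent normal tissue is usually treated as a mere control for
differential expression, yet in several cancer types its expression
profile predicts patient survival *better* than the tumor profile
itself. `pairsurv` provides the full analysis stack needed to study
this question on paired tumor/normal cohorts:

- **Survival statistics from scratch** — Cox proportional-hazards
  fitting by Newton–Raphson on the partial likelihood (Breslow or Efron
  ties, optional ridge penalty), Harrell's concordance index (C-index),
  Kaplan–Meier estimation, log-rank, Wilcoxon rank-sum/signed-rank and
  Pearson correlation.
- **DEG ratio features** — differentially expressed genes (|log2FC| > 2
  and adjusted p < 0.05, strict) taken from an external DE results
  table or from a clearly labelled built-in paired-test fallback, and
  patient-wise expression-ratio features
  `Ratio_individual = ln(T_ij / N_ij)` and
  `Ratio_median = ln(T_ij / median_i(N_ij))`.
- **Distance-correlation screening** — genes ranked by Székely's
  distance correlation between their expression and the linear
  predictor `Xβ` of a clinical-covariate Cox model (age, stage,
  optionally metastasis) fitted on an *external* screening cohort.
- **A Cox partial-likelihood neural network** — two hidden layers of
  width ⌈√d⌉, ReLU or Tanh, trained by full-batch gradient descent on

  `l(θ) = Σ_{i:E_i=1} [ h_θ(x_i) − log Σ_{t_j ≥ t_i} exp h_θ(x_j) ] − λ‖θ‖²`

  with analytically derived gradients (verified against central finite
  differences), plus a uniform fit/predict adapter contract and an
  event-stratified 3-fold CV hyperparameter harness.
- **Evaluation protocols** — repeated 70/30 hold-out with one split
  shared across all models and data types per repetition, per-gene
  informative-gene density, feature-size sweeps, median-risk
  Kaplan–Meier stratification, cross-cohort prognostic similarity
  (per-gene train/test C-index correlation) and log-fold-change vs.
  Cox-coefficient correlation.
- **A paired-cohort simulator** — proportional-hazards survival with
  calibrated censoring, planted prognostic genes (optionally only via
  normal tissue), planted DEG fold changes, clinical covariates coupled
  to latent disease severity, and a correlated external screening
  cohort — so the entire pipeline runs and is tested without any
  external download.

## Worked example

```r
library(pairsurv)

config <- simulation_config(seed = 1)       # 300 patients x 500 genes,
                                            # 30 prognostic genes in normal tissue
bench <- run_screening_benchmark(config, n_repeats = 20, seed = 2)
round(tapply(bench$eval$c_index, bench$eval$data_type, mean), 3)
#>          normal normal_screened           tumor  tumor_screened
#>           0.765           0.828           0.494           0.486
bench$comparisons[, c("a", "b", "delta", "p_adj")]
#>                 a      b        delta        p_adj
#> 1          normal  tumor  0.271402365 0.0001435376
#> 2 normal_screened normal  0.062911570 0.0001435376
#> 3  tumor_screened  tumor -0.008112719 0.4666215087
```

With prognostic signal planted only through normal tissue, the
Cox-NN's mean test C-index on normal expression (0.77) far exceeds the
tumor arm (at chance, 0.49); distance-correlation screening against
the external cohort's clinical risk predictor lifts the normal arm to
0.83 while leaving the signal-free tumor arm unchanged — the
qualitative pattern this package exists to dissect.

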