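---
title: "Methods: prognostic analysis of paired tumor and adjacent normal transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: prognostic analysis of paired tumor and adjacent normal transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(pairsurv)
```

## The analysis in one paragraph

`pairsurv` asks whether the transcriptome of tumor-adjacent normal
tissue carries prognostic information beyond — or instead of — the
tumor transcriptome. Four feature families are compared under one
evaluation protocol: tumor expression, paired normal expression, and
two patient-wise DEG expression ratios. Survival models (a Cox
partial-likelihood neural network, ridge Cox regression, and any
learner plugged into the adapter contract) are scored by test-set
concordance over repeated event-stratified 70/30 hold-outs, with the
identical split reused for every model and data type within a
repetition so that arm-vs-arm comparisons can be paired. A second,
external cohort supports a screening step: genes are ranked by the
distance correlation between their expression and the linear predictor
of a clinical-covariate Cox model fitted on that cohort, and the top-k
set is carried back to the discovery cohort.

## Survival models and their assumptions

**Cox proportional hazards.** The hazard for subject $i$ is
$h_0(t)\exp(x_i^\top\beta)$; $\beta$ maximizes the partial likelihood,
optionally penalized by $-\lambda\lVert\beta\rVert^2$. Fitting is
Newton–Raphson with step-halving; risk-set sums are accumulated by
reverse cumulative sums so one evaluation of the score and information
is $O(np^2)$. Convergence requires the largest absolute (penalized)
score component below $10^{-8}$ or a relative log-likelihood change
below $10^{-10}$. A coefficient path escaping $|\beta| > 15$ on
standardized inputs is reported as possible separation with
`converged = FALSE`. Tied event times default to the Breslow
convention (tied events share the full risk set); Efron is available
by flag. Both conventions are verified against the `survival` package
to $10^{-8}$.

**Concordance.** Harrell's C with the conventions stated precisely,
because implementations disagree: pair $(i,j)$ is comparable iff
$E_i = 1$ and $t_i < t_j$ (tied event times are not comparable);
concordant iff $r_i > r_j$; tied risks count $1/2$. The implementation
is checked for exact equality against exhaustive pair enumeration.

**Cox partial-likelihood network.** A feed-forward network
$h_\theta : \mathbb{R}^d \to \mathbb{R}$ with two hidden layers of
width $\lceil\sqrt{d}\rceil$ (the rounding is a choice; the rule only
fixes the order of magnitude) outputs a per-sample log-relative
hazard. The loss is the negative penalized partial log-likelihood

$$-\sum_{i:E_i=1}\Big[h_\theta(x_i) - \log\!\!\sum_{j:t_j\ge t_i}\!\!\exp h_\theta(x_j)\Big] + \lambda\lVert\theta\rVert^2,$$

with the risk set read as all subjects still under observation at the
event time (the standard Cox risk set), Breslow handling of ties, and
a globally shifted log-sum-exp for stability. The squared-norm form of
the penalty follows from reading $\lambda$ as an L2 regularization
parameter. Gradients are derived analytically and backpropagated;
property tests require agreement with central finite differences to a
relative $10^{-5}$ on random instances, and the depth-0 (linear)
special case must match the Newton–Raphson Cox fit. One activation
(Tanh default, ReLU by flag) is used for both hidden layers; mixing
activations within one model is not supported.

**Training.** Plain full-batch gradient descent with a fixed step
(an Adam-style variant sits behind a flag), the gradient divided by
the event count so the learning rate transfers across sample sizes.
Weights initialize uniformly on $\pm 1/\sqrt{\text{fan-in}}$ under the
configured seed; biases start at zero; training is bit-reproducible
given seed, configuration and data. Divergence (non-finite loss) stops
with an error advising a smaller learning rate. Optional early
stopping monitors a held-out event-stratified validation fold.
Defaults (`learning_rate = 0.05`, `max_epochs = 300`,
`lambda_l2 = 1e-3` in the benchmark driver) were chosen by watching
loss trajectories converge on standardized inputs of a few hundred
features.

## Screening by distance correlation

Sample distance correlation (the classical V-statistic, not the
unbiased variant) is computed from double-centered pairwise
absolute-difference matrices; a constant argument is assigned dCor 0
by convention — the population quantity is undefined there, and a
constant gene must not rank. Screening correlates each gene with the
linear predictor $X\beta$ (no centering) of a Cox model on clinical
covariates only — age, ordinal stage, metastasis when recorded —
fitted on the external cohort. Expression is screened on the
standardized matrix for consistency with the rest of the pipeline;
dCor is invariant to per-gene location and positive scale, so this
affects interpretability only. Rankings break ties by lexicographic
gene id, as does every ranking in the package, so results are
invariant to row order. The $O(n^2)$ per-gene cost is the accepted
contract: 500 genes × 300 samples screen in a few seconds.

## Preprocessing

Genes with zero mean (all-zero columns of nonnegative data) are
discarded; cross-cohort analyses retain the sorted intersection of
gene universes; genes are standardized to mean 0 and standard
deviation 1. Two fixed conventions: the **population** (divisor $n$)
standard deviation, so standardization is exactly idempotent, and
dropping zero-variance genes before standardization (with a warning)
rather than emitting undefined values. Inside the evaluation
protocols, standardization parameters are estimated on the training
fold and applied to the test fold — the leakage-safe default — while
`standardize = "global"` reproduces whole-matrix normalization for
comparison with analyses that normalize before splitting.

## DEG features

A gene is a DEG when $|\log_2 FC| > 2$ and adjusted $p < 0.05$, both
strict. DE statistics are expected from an external results table
(e.g. a count-based negative-binomial analysis performed elsewhere);
the built-in fallback is a per-gene paired t-test (Wilcoxon
signed-rank by flag) on $\log_2(x+1)$ tumor−normal differences with
Benjamini–Hochberg adjustment, and is labelled as such in its output —
it is a location test on transformed values, not a count model. Ratio
features use the natural log exactly as defined
($\ln$ for features, $\log_2$ for DEG calling; the two scales coexist
deliberately) with a $+1$ pseudocount on the raw scale before the
ratio, surfaced as an argument because zero handling in FPKM-like data
is a policy, not a fact; unit tests pin the closed forms at
pseudocount 0.

## The simulator: what it emulates, and what it does not

`simulate_paired_study()` draws, per patient, latent standard-normal
signals per gene and tissue; a chosen set of genes feeds the hazard
through per-gene effects $\beta$ (defaults: 30 genes at $\beta = 0.6$
via normal tissue only, on a 500-gene, 300-patient study). Survival
times come from an exponential baseline by inverse transform — so
doubling $\exp(\text{lp})$ halves median survival in closed form — and
censoring times are independent exponentials whose rate is solved by
root-finding so the expected censored fraction equals `censor_rate`
(default 0.3). Expression is $\exp(\mu_g + z + \varepsilon)$ with
gene baselines $\mu_g \sim N(3, 1)$ (FPKM-like median ≈ 20) and
log-scale noise sd 0.3; the map is monotone and positive, which is all
the pipeline assumes. Planted DEGs multiply tumor expression by
$2^{\text{lfc}}$, so the expected tumor−normal log2 difference equals
the configured fold change. Age is uniform on [40, 85]; stage is
ordinal 1–4 with marginal probabilities (0.30, 0.35, 0.25, 0.10).

Two couplings make the design coherent rather than a collection of
independent noise sources. First, planted prognostic genes load on a
shared severity factor (`prog_cor`, default 0.3) — prognostic genes in
real data form co-expressed modules, not independent axes. Second, the
score discretized into tumor stage correlates with latent severity
(`stage_coupling`, default 0.8) — stage is precisely a clinical
readout of disease progression. This second coupling is what makes
external screening meaningful at all: a clinical-only Cox predictor
contains a trace of the planted genes, so distance correlation can
find them. With both couplings at their defaults, planted genes score
dCor ≈ 0.25 on a 300-sample screening cohort whose null level is
≈ 0.10.

`simulate_screening_cohort()` re-draws a cohort over the same gene
universe whose normal-tissue effect vector is
$s\,b + (1-s)\,b_{\text{new}}$ (`shared_normal_fraction`, default 0.9)
and whose tumor-tissue effects are re-drawn with weight
`tumor_divergence` (default 0.9): normal-tissue prognostic structure
transfers across cohorts, tumor structure is cohort-specific.

What the simulator does **not** emulate: RNA-seq count mechanics
(library size, overdispersion, length bias), batch effects,
tumor/normal correlation of the same patient's baseline expression,
non-proportional hazards, or informative censoring. Passing tests
therefore demonstrate correctness of the machinery and the qualitative
direction of the planted contrasts, not performance on real cohorts.
No public effect-size estimates exist for the study conditions, so
defaults were chosen once for testability at desk scale and are not
revisited.

## Evaluation protocols

Repetitions share one event-stratified split across every model and
data type (asserted by split-id equality), so Wilcoxon comparisons
between arms are paired signed-rank tests whenever the compared rows
carry identical split ids, and rank-sum otherwise. Adjusted p-values
are Benjamini–Hochberg over the family of comparisons issued in one
call. The informative-gene threshold is explicit
($|C - 0.5| \ge \tau$, default $\tau = 0.1$) because "far from 0.5" is
otherwise qualitative. Feature-size sweeps report the size of maximal
mean C alongside an all-gene baseline evaluated under the same splits;
median-risk grouping sends risk ties at the median to the low-risk
group and refuses constant risk vectors. Degenerate draws are handled
explicitly: test folds without comparable pairs are redrawn and
logged, per-gene Cox failures are assigned C = 0.5 (density) or
skipped with a count (similarity), and cross-validation candidates
failing on all folds are excluded with a warning.

## Problem sizes

The test suite and the acceptance script run at desk scale, chosen as
the package's own working sizes: the headline benchmark uses the
default 300 × 500 study with 20 hold-out repetitions; oracle
comparisons use 100–1000 random instances at $n \le 30$; calibration
checks use 500–1000 replicates at $n = 100$. The full suite completes
in roughly two minutes on one CPU.

## Known limitations

- Rank-based tests use normal approximations with tie and continuity
  corrections; exact small-sample p-values are not computed (they are
  cross-checked against enumeration at small $n$ in the tests).
- The ridge Cox standard errors come from the penalized information
  matrix and are not debiased.
- Random survival forests and survival SVMs are deliberately not
  reimplemented; the adapter contract (`survival_model()`) and the CV
  harness treat any external implementation identically to the
  built-ins.
- dCor significance testing and partial distance correlation are out
  of scope; the screening step only ranks.
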