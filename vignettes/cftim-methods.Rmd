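---
title: "Methods: models, parameters and design choices in cftim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in cftim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistical machinery it
implements: the models and their assumptions, the parameters that matter and
their defaults, what the synthetic-data generator does and does not emulate,
and the choices made where the design was genuinely open.

## 1. The deconvolution model

Plasma cfDNA is a mixture of fragments released by many tissues. For sample
$s$ and TIM-centred region $\ell$, each sequenced read is assumed to originate
from tissue $k$ with probability $\alpha_{sk}$ (the tissue proportions, a
point on the simplex) and to be methylated with probability $\beta_{k\ell}$
(the tissue's regional methylation). With $x_{s\ell}$ methylated of
$d_{s\ell}$ total reads, and reference counts $y_{k\ell}$ of $r_{k\ell}$ for
the known tissues, the joint log-likelihood is

$$
\sum_{s,\ell} \log \mathrm{Bin}\!\left(x_{s\ell}\,\middle|\,d_{s\ell},
  \textstyle\sum_k \alpha_{sk}\beta_{k\ell}\right)
+ \sum_{k,\ell} \log \mathrm{Bin}\!\left(y_{k\ell}\,\middle|\,r_{k\ell},
  \beta_{k\ell}\right).
$$

Both $\alpha$ and $\beta$ are estimated by EM (`celfie_em()`): the E-step
apportions each region's methylated and unmethylated reads to tissues in
proportion to $\alpha_{sk}\beta_{k\ell}$ and $\alpha_{sk}(1-\beta_{k\ell})$;
the M-step renormalizes the reads assigned to each tissue into
$\alpha_{sk}$ and pools reference plus assigned sample reads into
$\beta_{k\ell}$. Because the reference term anchors the known $\beta$ rows
while the sample term lets them drift, noisy references are refined by the
cfDNA data. *Unknown* components are rows with zero reference counts; they
are identified only through **between-sample variation** in the mixtures — a
cohort in which every sample has near-identical proportions gives the unknown
profile very little leverage, which is why the unknown-recovery tests draw
heterogeneous proportions (low Dirichlet concentration). Zero-depth regions
contribute nothing to the likelihood ($0\log 0 := 0$).

Key choices, made where the upstream description is silent:

* **Initialization.** $\alpha$ rows $\sim$ symmetric Dirichlet(1); known
  $\beta$ at reference proportions with a 0.5/1 pseudocount (avoids exact 0/1
  which would pin the E-step); unknown $\beta \sim U(0,1)$.
* **Convergence.** Stop at $\max|\Delta\alpha| < 10^{-4}$ or 1000 iterations.
  $\beta$ is clamped to $[10^{-12}, 1-10^{-12}]$ for numerical stability; the
  monotonicity test allows $10^{-9}$ of float noise per step.
* **Restarts.** 10 random restarts; the restart with the highest final joint
  log-likelihood is returned, ties going to the lowest restart index.
* **Unknowns.** Default `n_unknown = 2`, the choice appropriate for a
  cohort of roughly one hundred samples; three-unknown runs are a config
  change, not a different code path.
* **Region aggregation.** Reads are summed over CpGs within ±250 bp of the
  target (inclusive window), because neighbouring CpGs are locally correlated
  and summing reduces binomial sampling noise.

## 2. TIM selection and probe conversion

A tissue-informative marker is a CpG whose methylation in one tissue is far
from the mean of all other tissues. The selection pipeline order is fixed and
tested: per-tissue top-$N$ by score, removal of CpGs claimed by ≥ 2 tissues,
cfDNA coverage screen (mean depth ≥ 10 in **every** supplied coverage table —
the stricter reading of "covered in both datasets", chosen because the
filter's purpose is to keep sites observable in cfDNA), SNP/repeat masking
(BED, 0-based half-open), then 500 bp spacing. The spacing rule uses
*chain-run* semantics: within a maximal run of sorted sites whose successive
gaps are all < 500 bp, only the first site survives. Score ties at the top-N
boundary break by lower position then chromosome, for determinism; a site
whose tissue methylation exactly equals the others' mean carries no
information and is never selectable.

Probe conversion is literal on the given forward-strand window: the
unmethylated probe converts every G→A, the methylated probe converts every G
not immediately preceded by a C (a leading G has no preceding base and is
non-CpG by convention). The strand of the physical capture oligo after
bisulfite conversion is left to the caller; the two hand-derived transforms
`"ACGT" → "ACGT"/"ACAT"` and `"GCGG" → "ACGA"/"ACAA"` are frozen in the test
suite.

## 3. Feature engineering

Pipeline order is pinned: sample QC (> 10 % zero-depth sites removed, before
site QC because site medians change with the sample set) → site QC (median
depth of 1 read or less removed; a fractional median such as 1.5 survives) →
methylation proportions (zero depth = missing) → SoftImpute → bottom-5 %
variance filter, with normalized coverage (depth / per-sample total reads,
zero depth = 0) filtered in parallel; the methylation and coverage survivor
sets are **not** forced to coincide. SoftImpute is the classic iterative
soft-thresholded SVD: fill missing entries with column means, repeatedly
SVD-shrink-refill (observed entries never change), clip imputed values to
$[0,1]$. The off-target configuration instead drops sites with > 5 %
missingness and does not impute.

Standardization scales **each matrix with its own column means and SDs**
(`scale_test = "separate"`), reproducing the conservative train/test
separation as described; the conventional train-parameter mode is available
behind a flag. Sex and SIRE are fully one-hot encoded (no reference level
dropped — the covariates are unpenalized, so the overparameterization is
harmless and keeps coefficients interpretable per level).

## 4. CMSA prediction models

`cmsa_fit()` splits the training samples into K = 10 outcome-stratified folds.
For each fold, an elastic-net path (glmnet; 100 λ values spanning four orders
of magnitude below the data-driven maximum; α over {0, 0.25, 0.5, 0.75, 1},
"evenly spaced between ridge and lasso") is fit on the other K−1 folds with
covariates unpenalized, the (α, λ) pair minimizing that fold's held-out
deviance/MSE is kept, and the K fold-wise coefficient vectors are averaged
into the final model — no single λ is ever refit. A covariate-only baseline
uses the same folding and averaging with an unpenalized GLM per fold.

**Two CV AUC estimators exist deliberately.** The fold-validation AUC
(`fit$cv_auc`) scores each sample with the model whose hyperparameters were
chosen *on that sample's fold*; it is the quantity a CMSA user reports as
"ten-fold cross-validated AUC" and the package uses it for the power and
downsampling analyses, but it is mildly optimistic under the null.
`cross_validate_cmsa()` wraps the entire CMSA procedure in an outer CV and is
unbiased; it is the estimator used for null-calibration and
label-permutation checks. Conflating the two would either fail honest null
calibration or change the meaning of the reported within-cohort AUC.

Phenotype models reuse the machinery with `family = "linear"` on the top 1000
methylation + top 1000 coverage features by |averaged β|. Epigenetic age
acceleration is the residual of predicted age regressed on true age (OLS), so
it is uncorrelated with true age by construction and invariant to constant
offsets or rescalings of the predictions.

## 5. The synthetic world

The generator states the cohort the tests run against; its defaults were
chosen once, from the study design being emulated, and are not tuned:

* **Depth** is negative binomial with dispersion 0.3 (variance
  $\mu + 0.3\mu^2$): targeted capture coverage has SD exceeding its mean,
  ruling out Poisson. Reference panels default to mean 200×, cohorts 150×.
* **Tissue proportions** are Dirichlet around a blood-dominant control
  simplex ($\propto 2^{-(k-1)}$; the muscle-like component last, ≈ 3 %),
  concentration 100 (between-subject SD ≈ 0.02 on a 5 % component). Cases add
  `case_muscle_shift` (default 0.03) to the muscle-like component, other
  components renormalized proportionally — an infeasible shift is a loud
  error, never silent renormalization.
* **Covariates**: age ~ N(64, 9) years; sex Bernoulli(0.5); three SIRE
  categories (0.6/0.25/0.15); cfDNA concentration lognormal in **ng/µL**
  (one consistent unit), control median 0.15, sdlog 0.7, case mean 2× control
  — cases release more cfDNA, so concentration is a genuinely informative
  covariate, as in the emulated cohorts; total input lognormal around 20 ng.
  Case phenotypes (ALSFRS-R clipped to [0, 48], slope, FVC %) are drawn
  independently of the methylation signal.
* **Missingness** is site-level MCAR (default 2 %), matching a workflow that
  treats zero-depth sites as missing without modelling a mechanism.
* **TIM planting**: a hypermethylated TIM sets the target tissue to
  $(1+m)/2$ and all others to $(1-m)/2$ (margin $m$, default 0.6), so the
  tissue-vs-others gap equals the margin exactly; non-TIM sites share a
  baseline with small (SD 0.03) tissue noise. A *capture panel* world — as in
  the power tests — plants TIMs at every site, since a real probe panel
  contains only TIM regions.
* **Genetic sex**: chr19 reads ~ Poisson(2·rate) for everyone; chrX ~
  Poisson(2·rate) for XX and Poisson(rate) for XY. The XX call threshold
  (ratio ≥ 0.75) is the midpoint of the expected ratios 1.0 and 0.5.

What the generator does **not** emulate: fragment lengths, bisulfite
conversion errors, UMI/PCR artefacts, capture-efficiency differences between
probes, correlated (non-MCAR) missingness, batch effects between cohorts, and
any genuine phenotype–methylation coupling. A green test therefore
establishes correctness of the estimators on the stated stochastic model, not
performance on real cfDNA.

## 6. Degenerate inputs and numerical edges

Zero-depth replicates are excluded from reference means (all-zero → missing);
a single remaining feature survives the variance filter (the quantile is
degenerate); constant tissue proportions yield a Mann–Whitney p of 1 with a
warning rather than an error; perfect separation in association models is an
explicit error (detected via the separation warning, a vanishing residual
deviance, or a diverging coefficient); binomial thinning at the count level
is the exact equivalent of uniform read subsampling; `downsample_counts()`
at proportion 0 leads to a clean "all samples dropped" QC error rather than a
degenerate fit.

## 7. Known limitations

The EM estimate of an unknown component's *level* is attenuated when the
known profiles are re-estimated jointly (part of the unknown's mass is
absorbed), even when its methylation profile and per-sample tracking are
recovered well — the tests assert profile correlation and tracking, not the
absolute level. ALSFRS-R slope/FVC missingness handling beyond dropping
samples with missing outcomes is not modelled. Real-cohort headline numbers
(cross-cohort AUCs, TIM panel counts) depend on external reference methylomes
and the deposited cohort and are out of scope at desk scale.
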