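---
title: "Pathway-based super signatures: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-based super signatures: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(passig)
```

## The problem

Only a minority of patients with metastatic melanoma derive durable benefit
from anti-PD1 immune checkpoint blockade, and transcriptomic biomarkers
built from single genes or short gene lists have repeatedly failed to
replicate across cohorts. `passig` implements a pathway-level alternative:
instead of individual genes, the predictive features are single-sample
enrichment scores of a small number of pathways selected by the data, and
the final predictor — the pathway-based super signature (PASS) score — is a
weighted average of those pathway scores. Pathway-level aggregation trades
single-gene resolution for robustness to expression noise and
platform/batch differences, which is the property that matters when a
signature trained on one cohort is applied to another.

Two signature families are supported:

* **PASS-PRE / PASS-ON** — candidate pathways come from comparing
  responders (R) with nonresponders (NR) at one biopsy timepoint
  (pre-treatment or on-treatment), and the model is trained at that same
  timepoint.
* **TimeANLS-PRE / TimeANLS-ON** — candidate pathways come from the
  *dynamic* contrast (responder on-treatment vs responder pre-treatment
  samples, unpaired), and two independent models are then trained on those
  shared candidates, one per timepoint.

## The pipeline, stage by stage

### Responder definition

Patients with complete or partial response are responders; stable disease
counts as response only when progression-free survival exceeds 180 days;
progressive disease is nonresponse. The boundary case of exactly 180 days
is not covered by either clause of the usual phrasing ("longer than" /
"shorter than" 180 days); `classify_response()` resolves it to
nonresponder, i.e. strict inequality is required for response. This is a
documented package decision, not an inference about any particular study.

### Differential expression

`nb_wald_test()` is a self-contained negative-binomial Wald test: counts
are normalized by median-of-ratios size factors, the per-gene dispersion
$\phi$ is the method-of-moments estimate
$\max(0, (s^2-\bar\mu)/\bar\mu^2)$ on normalized counts, the effect is
$\log_2(\hat\mu_A+\varepsilon)-\log_2(\hat\mu_B+\varepsilon)$ with
$\varepsilon = 0.5$ (configurable), and its standard error comes from the
delta method applied to $\mathrm{Var}(c/s) = \mu/s + \phi\mu^2$. This
preserves the inferential form of the popular NB-Wald DE tools while
remaining fully transparent; it deliberately does **not** reproduce their
empirical-Bayes dispersion shrinkage, Cook's-distance outlier filtering,
or fold-change shrinkage. Consequently per-gene results will differ
numerically from such tools; what the package guarantees (and tests) is
calibration — on null NB data at 10 samples per arm the fraction of raw
p-values below 0.05 stays within [0.035, 0.065].

The volcano-style gene count uses **raw** p-values
($\log_2 FC > 1$, $p < 0.05$), matching the convention of reporting
"Wald test p"; the BH-adjusted values are carried alongside. The ranked
list fed to enrichment uses the Wald statistic by default; the ranking
metric is configurable because reasonable alternatives (fold change,
signed $-\log_{10}p$) exist and the choice is rarely stated in published
workflows. Ties are broken lexicographically by gene id so every
downstream step is deterministic.

### Preranked GSEA

`gsea_es()` is the classical weighted Kolmogorov–Smirnov walk with
exponent $p = 1$: hits advance the running sum by $|r|^p / \sum_S |r|^p$,
misses by $1/(N-N_S)$, and the enrichment score is the signed maximal
deviation (ties between the positive and negative extreme resolve to the
positive one). The leading edge is the set members at or before the peak
(positive ES) or at or after it (negative ES). Significance comes from
gene-label permutations: random size-matched sets drawn from the ranked
universe (the scheme used by preranked GSEA tools), with
$p = (1 + \#\{\text{same-sign } |ES_{perm}| \ge |ES|\}) /
(1 + \#\text{same-sign})$, and $NES = ES / \overline{|ES_{perm}|}$ over
same-sign permutations. The default is 10,000 permutations. The
"FDR < 0.05" candidate filter is Benjamini–Hochberg over the permutation
p-values of all tested pathways (matching an "adjusted p-value" filter),
not the classic permutation-FDR of the original GSEA; positively enriched
pathways passing it are ranked by NES and truncated to the top 15.

An empty candidate list is an explicit error rather than a silent empty
model: a cohort in which nothing is enriched cannot support signature
construction, and the pipeline says so. (The acceptance checks therefore
disable the FDR filter, `gsea_fdr_max = 1`, when deliberately running
*null* cohorts whose chance-level behaviour is the point being measured.)

### ssGSEA

`ssgsea_score()` ranks genes within each sample (competition ranking,
average ties, gene-id tie-break in the walk order) and accumulates the
difference between the $rank^\alpha$-weighted in-set ECDF and the
unweighted out-of-set ECDF over all positions, with $\alpha = 0.25$. Being
rank-based, a sample's scores are invariant under any strictly increasing
transform of that sample's expression — which is also why TPM (rather
than counts) only matters through gene length re-ordering. With
`normalize = TRUE` (default) the score matrix is divided by its global
range; this couples the samples scored together, so validation cohorts
are always scored within their own matrix — per-cohort normalization is
also the package's batch-robustness stance. Leading-edge genes absent
from a validation cohort are dropped with a warning; losing more than
half a set is an error.

### The elastic-net model and the PASS score

`fit_enlr()` minimizes the weighted penalized logistic objective
$$\frac1n\sum_i w_i\big[\log(1+e^{\eta_i}) - y_i\eta_i\big] +
\lambda\Big[\tfrac{1-\alpha}{2}\|\beta\|_2^2 + \alpha\|\beta\|_1\Big]$$
over a 100-point log-spaced $\lambda$ path from the KKT critical value
$\lambda_{max}$ (above which all coefficients vanish) down to
$10^{-4}\lambda_{max}$, with the quadratic-programming inner loop
delegated to coordinate descent (glmnet) on internally standardized
features (population variance, as glmnet uses); coefficients are reported
back on the original scale. Three design points deserve note:

* **Cost sensitivity.** Class imbalance is handled by observation weights
  inversely proportional to class frequency, normalized to sum to $n$ —
  the standard cost-sensitive device. A phrase like "the offset" in a
  methods section could alternatively mean an additive offset term, but
  an offset cannot change rank-based discrimination, so weights are the
  interpretation implemented.
* **Cross-validation.** Stratified three-fold CV on the weighted binomial
  deviance, fold assignment seeded; $\lambda$ is chosen by the
  one-standard-error rule (the largest $\lambda$ whose CV error is within
  one SE of the minimum), which is the sparser, more conservative choice.
  Whether the original workflow's CV loss was deviance, error rate or AUC
  is unknowable from prose; deviance is glmnet's default and is what the
  package uses.
* **Mixing parameter.** $\alpha = 0.5$, the conventional equal L1/L2
  blend when "elastic net" is stated without a value; it is a prominent
  configuration knob.

The PASS score of a sample is the effect-size-weighted average of its
pathway scores, $\sum_k \beta_k x_{kj} / \sum_k |\beta_k|$. The
$\sum|\beta|$ normalizer makes the score invariant to positive rescaling
of the coefficient vector and stays well defined if coefficients have
mixed signs; the intercept does not enter the score (it does enter the
odds). Per-sample odds are the logistic model's
$e^{\beta_0 + \sum_k \beta_k x_{kj}} = p/(1-p)$. The classification
cutoff is chosen on training scores by the Youden index (candidate
thresholds are midpoints of consecutive sorted unique scores plus
infinite sentinels; ties resolve to the smallest threshold).

A trained signature stores *all* candidate leading-edge sets together
with the full coefficient vector (zeros included), and scoring always
computes ssGSEA on all candidates. This keeps the range normalization
identical between training and validation, so validating a signature on
its own training cohort reproduces the training scores and AUC exactly —
a self-consistency property the tests assert.

### Evaluation, comparison, survival

ROC/AUC uses the Mann–Whitney concordance count (ties half-weighted),
which provably equals the trapezoidal area under the empirical curve;
accuracy and the Matthews correlation coefficient are computed at the
training cutoff, with MCC defined as 0 when a denominator factor
vanishes. Signature-vs-signature comparison follows a stratified
resampling scheme: 1000 repetitions of sampling 80% of samples without
replacement within each cohort-by-class stratum (rounding up per
stratum), computing each signature's AUC on the subsample, and comparing
AUC vectors by a one-sided rank-sum test. Sampling is without
replacement because the scheme resamples a fixed fraction, not a
bootstrap.

Survival stratification splits samples at the **mean** of their odds
(strictly above the mean is "high"; exact ties go to "low"), then runs
Kaplan–Meier, the two-sided log-rank test, and a Cox proportional-hazards
fit with the Efron tie correction. The hazard ratio is reported for the
low- versus high-score stratum (HR > 1 means low scores progress or die
faster); the orientation is stated in the output rather than left
implicit. A group without events yields a monotone partial likelihood;
the fit is flagged unconverged with an infinite-HR sentinel instead of a
spurious number. A Schoenfeld-style proportionality p-value is attached
as a diagnostic but never gates results.

Comparator "published signature" scores (mean-expression sets, geometric
means, gene ratios, gene-pair counts) are computed by a generic engine
whose gene lists live in an editable JSON
(`inst/extdata/published_signatures_reconstruction.json`). Those lists
are reconstructions assembled from the literature, clearly labeled as
such — the exact published lists live in their source papers and should
be substituted before drawing comparative conclusions; the gene-pair list
in particular is illustrative.

## The synthetic cohort generator

Because the real cohorts are partly controlled-access, every stage is
exercised on synthetic data with the structure the analysis assumes:

* counts $c_{ij}\sim NB(s_j\,2^{\mu_i + a_{p(j)} + m_{g(i),j} +
  \Delta_i(j)},\ \phi)$ with $\mathrm{Var}=\mu+\phi\mu^2$, $\phi = 0.2$,
  log-normal library sizes (sd 0.3), baseline $\log_2$ means
  $N(5, 2^2)$, and a patient-level offset $a_p$ (sd 0.2) shared by
  paired biopsies;
* a per-sample **pathway-activity** offset $m_{g(i),j}$ (sd 0.5): every
  gene inherits, in each sample, a normal offset drawn for its home
  pathway, so member genes fluctuate jointly. This term is what gives
  single-sample enrichment scores realistic spread — a purely gene-level
  noise model lets rank-based pathway scores average noise away almost
  entirely, and any systematic effect then separates classes nearly
  perfectly, which no real cohort shows. Correlation is deliberately
  confined to a gene's single home pathway; transcriptome-wide
  correlation structure is out of scope;
* three driver pathways whose member genes gain $\delta_{pre} = 0.5$
  (pre-treatment) or $\delta_{on} = 1.5$ (on-treatment) $\log_2$ units
  in responders. With activity noise of sd 0.5 this puts the
  pre-treatment pathway signal-to-noise at 1 and the on-treatment at 3,
  reproducing the qualitative regime that motivates the method: modest,
  unstable pre-treatment discrimination and strong on-treatment
  discrimination;
* cohorts of 100 patients at 40% responders by default, biopsied at both
  timepoints;
* exponential progression/survival times with a responder median of 500
  days and a nonresponder hazard ratio of 3, censored by an independent
  uniform time whose horizon is solved numerically to hit the requested
  expected censoring fraction (0.2) — the simplest mechanism satisfying
  the non-informative censoring assumed by Kaplan–Meier and Cox;
* RECIST codes drawn consistently with the true response label and the
  observed progression time, so `classify_response()` recovers the truth
  exactly.

What passing tests on this generator do **not** show: robustness to
batch effects between cohorts, to partially responding pathways (the
driver effect is uniform across member genes), to annotation mismatch,
or to non-exponential survival. The generator is a correctness and
calibration instrument, not a claim about biology.

## Numerical choices and degenerate inputs

* All randomness is seeded; a pipeline seed fans out to fixed per-stage
  offsets (GSEA +101, model fit +202, comparison +303) so stages can be
  rerun in isolation. Two runs with one seed produce byte-identical
  artifacts, and every artifact carries its configuration hash.
* GSEA permutations use an $O(|S|)$ hit-position formula per draw; its
  agreement with the full running-sum recomputation is tested to
  $10^{-12}$, and permutation p-values are checked against exhaustive
  enumeration on instances small enough to enumerate.
* If every set member has a zero ranking statistic the hit weights fall
  back to equal increments rather than dividing by zero.
* When the one-SE model keeps no pathway, the signature is explicitly
  empty: `pass_score()` errors, and cohort scoring falls back to constant
  scores with a warning (AUC 0.5 by tie-counting) so evaluation pipelines
  degrade loudly but gracefully.
* Welch tests guard zero-variance rows (t = 0, p = 1 for equal means;
  the limiting-normal p otherwise). Missing counts are rejected, never
  imputed; gene identifiers are opaque strings and no id conversion is
  attempted.
* Test and acceptance problem sizes are the package's own choices: the
  end-to-end recovery runs use the generator defaults with 2,000 GSEA
  permutations (p-resolution 1/2001 amply clears the BH filter over 50
  pathways), 20 replicate seeds in the test suite and 8 in the
  acceptance script; calibration checks use 2,000 null genes × 20 seeds
  (Wald) and 500 seeds at 200 subjects per arm (log-rank).

## Known limitations

Single-factor DE only (no covariates, no paired test — the dynamic
contrast is unpaired by design); no empirical-Bayes moderation, so
per-gene power at very small n is below that of shrinkage-based tools;
phenotype-permutation GSEA and multilevel p refinement are not offered;
the elastic-net mixing parameter is not tuned by nested CV; comparator
gene lists are reconstructions. The published headline numbers (external
validation AUCs, DEG/pathway counts, hazard ratios) depend on cohorts
that are partly controlled-access and are therefore not reproduced here;
the package's guarantees are the property-based ones its tests compute.
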