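---
title: "Methods: simulating, building and evaluating a type 2 diabetes polygenic score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating, building and evaluating a type 2 diabetes polygenic score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`pgscreen` is a testbed for the analyses that surround a clinical type 2
diabetes (T2D) polygenic score (PGS): how much risk stratification a
clumping-and-thresholding score provides, what it adds to first-degree
family history, and what happens when screening guidelines gain a
"high-PGS" criterion. Because individual-level data of the consumer
cohorts that motivate these analyses are not publicly available, the
package pairs every analysis with a synthetic-cohort generator that keeps
its full ground truth, so each estimator can be checked against the
quantity it is supposed to estimate.

## The generative model

The simulator uses the standard liability-threshold model. Each
individual carries a latent liability

$$ L = G + C + E, \qquad G = \sum_j \beta_j (x_j - 2p_j), $$

where the dosages \(x_j \in \{0,1,2\}\) are Hardy-Weinberg binomial draws
for the parents and Mendelian transmissions (one allele per parent) for
the offspring. The causal effects \(\beta_j\) are scaled so
\(\operatorname{Var}(G) = h^2_{\mathrm{snp}}\); the family-shared
component \(C\) (variance \(c^2\)) is identical for the offspring and
both parents; the unique environment \(E\) takes the remainder, so
\(L\) is standardized. A single latent variable drives every phenotype:

* **Disease status.** Case iff
  \(L + b_{\mathrm{age}} z_{\mathrm{age}} + b_{\mathrm{BMI}} z_{\log \mathrm{BMI}} \)
  exceeds a threshold set at the empirical \(1-K\) quantile of that linear
  predictor, so the realized cohort prevalence equals the target \(K\)
  (default 3.2%) exactly rather than only in expectation. Parents are
  thresholded against the same cutoff with their own age/BMI draws and
  environmental noise; family history is positive when at least one
  parent is affected.
* **Age of diagnosis (AOD)** for cases:
  \(\mathrm{aod} = \mu_{\mathrm{aod}} - s_{\mathrm{aod}} L + \varepsilon\),
  truncated to \([20, \mathrm{age}]\), with \(s_{\mathrm{aod}} = 1.37\)
  years per liability SD by default.
* **Prediabetes** (controls only), **one-year incident conversion**
  (followed controls), and six **treatment/complication** indicators
  (cases only) are Bernoulli with log-odds linear in \(L\) (and in years
  since diagnosis for the complications). Default log-odds slopes are
  \(\log 1.23\) for prediabetes and \(\log 1.43\) for incidence per
  liability SD; insulin and neuropathy carry moderate positive slopes
  while metformin, nephropathy and retinopathy are null, mirroring the
  qualitative severity pattern such scores show in survey cohorts.

Demographics default to an adult survey population: age truncated normal
(mean 47.6, SD 15.8, range 20-79), 60.4% female, log-normal BMI (median
26.5), and a re-survey interval around 446 days (SD 102) for the followed
subset. The standard exclusion filters (age outside 20-79, BMI outside
18.5-69, onset before 20 or after the current age, more than 40 years
since diagnosis) are applied after generation with a per-reason tally.

**What the generator does not emulate.** Dosages are independent across
SNPs - there is no linkage disequilibrium, so "clumping" acts only
through physical distance windows; there are no rare large-effect
variants, no X chromosome, no genotyping error, and ancestry labels are
sampling labels rather than different allele-frequency strata. Passing
tests therefore demonstrate that the estimators recover the truth of
*this* model, not that the score-building recipe is optimal on real
genomes.

A deliberate artefact worth knowing about: truncating AOD at the current
age is what a cross-sectional survey implies, but with ages and onset
drawn independently it produces a sizeable mass of cases with
`aod == age`, pulling the mean AOD a few years below the location
parameter and flattening the AOD-score gradient relative to the
underlying \(-1.37\) per liability SD. The recovery tests therefore
compare fitted slopes to a Monte-Carlo oracle that regenerates AOD from
the known liabilities (including the truncation) rather than to the raw
parameter.

## Score construction

The association scan is a per-SNP maximum-likelihood logistic regression
(dosage + intercept + optional covariates) with Wald inference;
monomorphic SNPs are flagged with \(p = 1\). Clumping is greedy and
distance-based: visit SNPs below the p-value threshold in ascending
p-value (ties broken by position, then id) and accept a SNP iff no
accepted SNP lies within the window. A default \(3 \times 3\) grid -
thresholds \(\{10^{-2}, 10^{-4}, 10^{-6}\}\) by windows
\(\{50, 250, 500\}\) kb - yields nine candidate variant sets; both grids
are configurable. Candidates
are scored on a tuning set disjoint from the scan individuals and the
one with the best tuning AUC wins (ties: fewer SNPs, then the smaller
threshold, then the smaller window). Selection optimizes the AUC of the
score alone, not score plus demographics. The winner's raw-score mean
and SD in the tuning set become the standardization reference carried in
the scoring file, which uses the PGS Catalog text format.

## Evaluation analytics

* **Percentile bins.** Percentile rank is \(100(r-1)/n\) with average
  ranks for ties; intervals are half-open \([lo, hi)\) with the final
  interval closed at 100. The bin-versus-total odds ratio is
  \((\mathrm{cases}_b/\mathrm{controls}_b)/(\mathrm{cases}/\mathrm{controls})\);
  since bin and total overlap, its interval uses the Woolf SE of the
  bin-versus-complement table - a conservative stand-in, tagged in the
  output - with Haldane-Anscombe 0.5 corrections for zero cells.
  Per-bin means and proportions get seeded percentile-bootstrap
  intervals (2,000 replicates by default). Cells smaller than the
  privacy floor (5) are suppressed.
* **Screening rules** are disjunctions of age/BMI/family-history/PGS
  criteria. USPSTF: age 35-70 and BMI >= 25; its PGS variant adds
  age >= 35 (no upper bound, read literally), BMI in [18.5, 25), PGS at
  or above the 90th percentile. Simplified ADA: age >= 45, or age >= 18
  with BMI >= 25 and positive family history; its PGS variant adds the
  normal-BMI high-PGS disjunct from age 18 - kept literal even though
  the simulator's age floor is 20. Cases are evaluated at their age of
  diagnosis, controls at their current age; PGS percentiles are computed
  within the evaluation cohort unless supplied. Sensitivity and
  specificity carry Wilson intervals. Because an augmented rule screens a
  superset, its sensitivity can only rise and specificity only fall -
  an exact property the tests fuzz.
* **Regression suite.** The four-model comparison (base with female sex,
  decade of age as age/10, standardized log BMI; plus family history;
  plus the standardized PGS; plus both) uses a seeded 75/25
  outcome-stratified split; coefficients and the Cox-Snell pseudo
  \(R^2 = 1 - \exp\{(2/n)(\ell_0 - \ell_1)\}\) come from the training
  rows (a labelled choice - the split on which it is computed is often
  left unstated) and AUC with a percentile-bootstrap interval from the
  held-out rows. Log BMI and the PGS are standardized by the training
  subset's moments. Auxiliary models: family history on the PGS (the
  per-SD odds ratio and its raw coefficient are both reported, since
  both rounded forms circulate), OLS for age of onset among cases,
  logistic prediabetes among controls, logistic incident conversion
  restricted to follow-up in (365, 730] days, and the six severity
  models (complications additionally adjusted for years since
  diagnosis). The study-wise significance threshold is Bonferroni
  \(0.05/28 \approx 0.0018\).

## Numerical and design choices

* One global seed expands into fixed per-stage substreams
  (`substream_seed()`), so any stage can be re-run in isolation and the
  whole pipeline is bit-for-bit reproducible under a fixed
  configuration.
* Decade of age enters models as the continuous `age/10`; categorical
  decades can be constructed by the caller.
* The case threshold uses the empirical quantile of the realized linear
  predictor rather than a closed-form normal quantile; this pins the
  realized prevalence to the target and stays correct when covariate
  effects make the predictor non-normal.
* Family history means "at least one affected parent": two parents are
  simulated; siblings are out of scope by default since survey items
  rarely separate them cleanly.
* Perfect separation in a logistic fit is flagged (`converged = FALSE`)
  rather than silently reported; degenerate zero-variance predictors are
  dropped with a warning, collapsing the affected model onto its nested
  neighbour.
* Clumping tie-breaks (p, then position, then id) and tuning tie-breaks
  (fewer SNPs, smaller threshold, smaller window) are fixed for
  determinism.

## Problem sizes

The packaged tests exercise the generator at up to 50,000 families
(200 SNPs) for variance-decomposition and model-recovery checks, a
100,000-family run (800 SNPs, 160 causal) for the end-to-end signal
recovery suite, and 100 replicates of 5,000 families for interval
calibration under a null architecture; these sizes give the recovery
tests comfortable power while keeping a full test run in the minutes
range. Larger runs only sharpen the same comparisons.

## Known limitations

* Distance-only clumping and LD-free genotypes mean the selected SNP
  counts are not comparable to LD-aware pipelines on real data.
* Case-conditioning attenuates the AOD-score gradient (the fitted slope
  estimates \(-1.37 \cdot b(L \sim \mathrm{PGS} \mid \mathrm{case})\),
  not \(-1.37\)); the package reports what the model implies, and the
  oracle tests quantify exactly that.
* Crude incidence uses person-time from survey intervals, not survival
  modelling; complications have no onset ages, so no time-to-event
  analysis is attempted.
* The multivariate models assume linear age and log-BMI effects.
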