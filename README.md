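# pgscreen

Tools for studying what a polygenic score (PGS) adds to type 2 diabetes
(T2D) risk stratification and screening. The package is aimed at
statistical geneticists and epidemiologists who want to prototype and
stress-test the full analysis chain — score construction, percentile
risk stratification, screening-guideline evaluation, and
family-history-versus-genetics model comparison — on synthetic cohorts
whose ground truth is known, and to run the same analytics on their own
delimited cohort tables and PGS Catalog scoring files.

## What it implements

**Liability-threshold cohort simulation with families.** Each offspring
has two simulated parents; dosages follow Mendelian transmission. The
liability `L = G + C + E` splits into a genetic term
`G = Σ βⱼ(xⱼ − 2pⱼ)` scaled to SNP heritability `h²`, a family-shared
term of variance `c²`, and unique environment. Disease is a probit-style
threshold on `L` plus age and log-BMI terms, calibrated so realized
prevalence hits the target (3.2% by default). One latent `L` also drives
age of diagnosis (−1.37 years/SD by default), prediabetes (log-odds
slope `log 1.23`), one-year incident conversion (`log 1.43`),
first-degree family history (≥1 affected parent), and
treatment/complication indicators. Full per-individual truth is
returned for recovery tests.

**Clumping + thresholding score construction.** Per-SNP logistic
association scan → greedy distance-window clumping over a p-value ×
window grid (3 × 3 = nine candidate variant sets by default) → tuning-set
selection by AUC → scoring with reference standardization. Weights
round-trip through the PGS Catalog scoring-file text format.

**Evaluation analytics.** Percentile/ventile bin statistics with
bin-versus-total odds ratios and bootstrap intervals; USPSTF and
simplified-ADA screening rules, with optional "PGS at or above the 90th
percentile" criteria, evaluated with cases tested at their age of
diagnosis; nested logistic model comparison (base / family history /
PGS / combined) with Cox–Snell pseudo `R² = 1 − exp{(2/n)(ℓ₀ − ℓ₁)}` and
held-out AUC; age-of-onset, prediabetes, incidence and severity
regressions; crude incidence per 1,000 person-years with exact Poisson
intervals; Bonferroni study-wise threshold `0.05/28 ≈ 0.0018`.

See `vignettes/pgs-screening-methods.Rmd` for the model, its
assumptions and the design decisions.

## Worked example

```r
library(pgscreen)

cfg <- pipeline_config(
  sim_config(n = 20000, m_snps = 300, n_causal = 60,
             h2_snp = 0.3, c2_shared = 0.1, seed = 1),
  n_boot = 200
)
res <- run_pipeline(cfg, out_dir = "run1")

attr(res$weights, "selected")   # which candidate won the tuning set
#>   p_threshold window n_snps tuning_auc
#> 1        0.01  50000     21  0.7832536

print(res$comparison)
#> Model comparison (train n = 5805, test n = 1934)
#>                        base family_history_only pgs_only combined
#> Intercept            -4.654              -4.728   -5.455   -5.464
#> Family history           NA               1.170       NA    0.795
#> Standardized PGS         NA                  NA    1.191    1.144
#> Female sex           -0.086              -0.094   -0.066   -0.061
#> Decade of age         0.191               0.160    0.223    0.197
#> Standardized log BMI  0.855               0.883    0.917    0.938
#> Cox-Snell pseudo R2   0.025               0.032    0.059    0.061
#> Test-set AUC          0.779               0.790    0.859    0.862

print(res$screening$uspstf)
#> uspstf: sens 0.811 (0.758, 0.855) spec 0.521 (0.509, 0.532) [TP 202 FP 3591 TN 3899 FN 47]
#> uspstf+pgs: sens 0.839 (0.789, 0.880) spec 0.491 (0.479, 0.502) [TP 209 FP 3816 TN 3674 FN 40]
#> delta sensitivity +0.0281, delta specificity -0.0300; 232 newly screened
```

Reading this: the clumping+thresholding search kept 21 SNPs at the
`p ≤ 0.01` / 50 kb grid point; on held-out data the model combining
family history and the PGS is the most predictive (AUC 0.862, pseudo-R²
0.061), and both single-factor models beat the demographics-only base —
family history and the score carry partly non-overlapping information.
Adding the normal-BMI/high-PGS criterion to the USPSTF rule finds 7 more
true cases at the cost of 225 additional screened controls
(Δsens +0.028, Δspec −0.030). Other headline fits from the same run:

```r
res$fits$fh$or_per_sd               # 1.59  odds of positive FH per PGS SD
res$fits$prediabetes$or_per_sd      # 1.16  prediabetes odds per PGS SD
res$fits$incidence$or_per_sd        # 1.37  incident-T2D odds per PGS SD
res$incidence$rate                  # 6.78  cases per 1,000 person-years
```

Every output table (cohort, weights, association scan, bin statistics,
screening report, model comparison, manifest with checksums) is also
written to `out_dir` as delimited text; rerunning the same configuration
reproduces the bundle bit for bit.

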