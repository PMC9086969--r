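test_that("logistic fits match closed forms and the IRLS oracle", {
  # intercept-only: logit of the prevalence
  y <- c(rep(1, 20), rep(0, 80))
  f0 <- fit_logistic(y, data.frame())
  expect_equal(f0$coefficients$estimate[1], log(0.25), tolerance = 1e-6)

  # single binary predictor encoding a 2x2 table (20/80 vs 10/90)
  x <- c(rep(1, 100), rep(0, 100))
  y2 <- c(rep(1, 20), rep(0, 80), rep(1, 10), rep(0, 90))
  f1 <- fit_logistic(y2, data.frame(x = x))
  expect_equal(f1$coefficients$estimate[2], log(2.25), tolerance = 1e-6)
  expect_equal(f1$coefficients$or[2], 2.25, tolerance = 1e-6)

  # random designs against the hand-written IRLS oracle
  set.seed(17)
  for (i in 1:10) {
    n <- sample(100:800, 1)
    X <- cbind(rnorm(n), rbinom(n, 1, 0.4), runif(n))
    yy <- rbinom(n, 1, plogis(-0.5 + X %*% c(0.8, -0.5, 0.3)))
    if (length(unique(yy)) < 2) next
    f <- fit_logistic(yy, as.data.frame(X))
    expect_equal(f$coefficients$estimate,
                 irls_logistic(cbind(1, X), yy), tolerance = 1e-6)
  }

  expect_error(fit_logistic(rep(1, 50), data.frame(x = rnorm(50))),
               "degenerate")
  expect_error(fit_logistic(y2, data.frame(k = rep(2, 200))), "constant")
})

test_that("perfect separation is flagged, not silently reported", {
  x <- c(rnorm(30, -3), rnorm(30, 3))
  y <- rep(c(0, 1), each = 30)
  f <- suppressWarnings(fit_logistic(y, data.frame(x = x)))
  expect_true(f$separation)
  expect_false(f$converged)
})

test_that("Cox-Snell pseudo R2 follows its closed form", {
  expect_equal(cox_snell_r2(-100, -100, 50), 0)
  expect_equal(cox_snell_r2(-100, -90, 100), 1 - exp(-0.2),
               tolerance = 1e-12)
  expect_gt(cox_snell_r2(-100, -80, 100), cox_snell_r2(-100, -90, 100))
  expect_error(cox_snell_r2(-90, -100, 100), "nested")
  expect_error(cox_snell_r2(-100, -90, 0), "positive")
})

test_that("Bonferroni threshold reproduces the study-wise cutoff", {
  expect_equal(signif(bonferroni_threshold(0.05, 28), 2), 0.0018)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 10), 0.005)
})

test_that("four-model comparison has Table-2 structure and obeys nesting", {
  cohort <- big_cohort_with_true_score()
  cmp <- compare_prevalence_models(cohort, seed = 5, n_boot = 100)
  expect_named(cmp$fits, c("base", "family_history_only", "pgs_only",
                           "combined"))
  tab <- as.data.frame(cmp)
  expect_setequal(rownames(tab),
                  c("Intercept", "Family history", "Standardized PGS",
                    "Female sex", "Decade of age", "Standardized log BMI",
                    "Cox-Snell pseudo R2", "Test-set AUC"))
  ll <- vapply(cmp$fits, `[[`, 0, "loglik")
  expect_gte(ll["family_history_only"], ll["base"])
  expect_gte(ll["pgs_only"], ll["base"])
  expect_gte(ll["combined"], max(ll["family_history_only"], ll["pgs_only"]))
  r2 <- cmp$pseudo_r2
  expect_gte(r2["combined"], max(r2["family_history_only"], r2["pgs_only"]))
  expect_gte(min(r2["family_history_only"], r2["pgs_only"]), r2["base"])
})

test_that("a zero-variance PGS collapses the PGS models onto the base models", {
  cohort <- big_cohort_with_true_score()
  cohort <- cohort[seq_len(8000), ]
  cohort$pgs_std <- 0
  cohort$pgs_raw <- 5
  expect_warning(
    cmp <- compare_prevalence_models(cohort, seed = 5, n_boot = 50),
    "zero variance")
  expect_equal(cmp$fits$pgs_only$loglik, cmp$fits$base$loglik,
               tolerance = 1e-9)
  expect_equal(cmp$fits$combined$loglik, cmp$fits$family_history_only$loglik,
               tolerance = 1e-9)
})

test_that("FH-PGS association recovers shared genetics and is scale-invariant", {
  cohort <- big_cohort_with_true_score()
  f <- fh_pgs_association(cohort)
  expect_gt(f$or_per_sd, 1)
  expect_lt(coef_row <- f$coefficients$p_value[f$coefficients$term == "std_pgs"],
            0.0018)
  expect_equal(f$beta_per_sd, log(f$or_per_sd))

  # affine rescaling of the raw score leaves the per-SD OR unchanged
  resc <- cohort
  resc$pgs_std <- 3 + 40 * cohort$pgs_std
  f2 <- fh_pgs_association(resc)
  expect_equal(f2$or_per_sd, f$or_per_sd, tolerance = 1e-9)
})

test_that("age-of-onset model: negative PGS slope, null under permutation", {
  cohort <- big_cohort_with_true_score()
  cases <- cohort[cohort$t2d_status == "case", ]
  f <- fit_aod_model(cases)
  row <- f$coefficients[f$coefficients$term == "std_pgs", ]
  expect_lt(row$estimate, 0)
  expect_equal(f$model, "linear")
  expect_true(is.finite(f$r_squared))

  set.seed(10)
  perm <- cases
  perm$aod <- sample(perm$aod)
  fp <- fit_aod_model(perm)
  rowp <- fp$coefficients[fp$coefficients$term == "std_pgs", ]
  expect_true(rowp$lo < 0 && rowp$hi > 0)

  expect_error(fit_aod_model(cohort), "cases only")
})

test_that("prediabetes model recovers the generator gradient, guards cases", {
  cohort <- big_cohort_with_true_score()
  controls <- cohort[cohort$t2d_status == "control", ]
  f <- fit_prediabetes_model(controls)
  expect_gt(f$or_per_sd, 1)
  expect_error(fit_prediabetes_model(cohort), "controls only")
})

test_that("incidence model applies the one-to-two-year window", {
  co <- random_cohort(300, seed = 6)
  co <- co[co$t2d_status == "control", ]
  co$incident_t2d <- sample(c("yes", "no"), nrow(co), TRUE, prob = c(.2, .8))
  co$followup_days <- sample(c(100, 400, 700, 800, 900), nrow(co), TRUE)
  f <- fit_incidence_model(co)
  kept <- co$followup_days %in% c(400, 700)
  expect_equal(f$n, sum(kept))
  expect_equal(f$n_events, sum(co$incident_t2d[kept] == "yes"))

  co$incident_t2d <- "no"
  expect_error(fit_incidence_model(co), "no incident events")
})

test_that("severity models find injected insulin signal and only that", {
  # strong insulin slope, all other severity slopes null, high prevalence
  # so the case subset is large enough
  sig_insulin <- 0L; sig_other <- 0L
  for (s in 1:5) {
    cfg <- sim_config(n = 6000, m_snps = 40, n_causal = 20, h2_snp = 0.4,
                      c2_shared = 0, seed = 500 + s,
                      prevalence = 0.5,
                      insulin = c(base = 0.2, l = log(3), dur = 0),
                      neuropathy = c(base = 0.12, l = 0, dur = 0.05))
    sim <- generate_cohort(cfg)
    co <- sim$cohort
    co$pgs_std <- drop(scale(sim$truth$liability_genetic))
    fits <- fit_severity_models(co[co$t2d_status == "case", ])
    thr <- bonferroni_threshold(0.05, 28)
    p_ins <- fits$insulin$coefficients$p_value[
      fits$insulin$coefficients$term == "std_pgs"]
    if (p_ins < thr && fits$insulin$or_per_sd > 1) sig_insulin <- sig_insulin + 1L
    for (nm in c("nephropathy", "retinopathy")) {
      p <- fits[[nm]]$coefficients$p_value[
        fits[[nm]]$coefficients$term == "std_pgs"]
      if (p < thr) sig_other <- sig_other + 1L
    }
  }
  expect_gte(sig_insulin, 4L)
  expect_lte(sig_other, 2L)
})

test_that("complication odds rise with disease duration", {
  cohort <- big_cohort_with_true_score()
  fits <- fit_severity_models(cohort[cohort$t2d_status == "case", ])
  expect_named(fits, c("insulin", "metformin", "lifestyle_only",
                       "neuropathy", "nephropathy", "retinopathy"),
               ignore.order = TRUE)
  for (nm in c("neuropathy", "nephropathy", "retinopathy")) {
    expect_true("years_since_dx" %in% fits[[nm]]$coefficients$term)
  }
  dur <- fits$neuropathy$coefficients[
    fits$neuropathy$coefficients$term == "years_since_dx", ]
  expect_gt(dur$estimate, 0)
  # treatment models exclude duration
  expect_false("years_since_dx" %in% fits$insulin$coefficients$term)
})

test_that("significance report labels comparisons at the corrected threshold", {
  cohort <- big_cohort_with_true_score()
  f1 <- fh_pgs_association(cohort)
  f2 <- fit_prediabetes_model(cohort[cohort$t2d_status == "control", ])
  rep <- significance_report(list(fh = f1, prediabetes = f2))
  expect_equal(rep$threshold, rep(0.05 / 28, 2))
  expect_named(rep, c("comparison", "term", "estimate", "or", "p_value",
                      "threshold", "significant"))
})
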