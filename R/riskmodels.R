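#' Maximum-likelihood logistic regression with Wald inference
#'
#' Thin wrapper around [stats::glm()] that validates its inputs (both
#' outcome classes present, no constant non-intercept column), flags
#' perfect separation / non-convergence instead of silently returning
#' estimates, and packages coefficients, odds ratios, Wald standard
#' errors/p-values and log-likelihoods into a `fit_result`.
#'
#' @param outcome binary vector (0/1, logical, or `"case"`/`"control"`).
#' @param design data frame of named covariate columns.
#' @param outcome_name label stored on the result.
#' @param conf confidence level for coefficient intervals.
#' @return A `fit_result` list: `coefficients` table (term, estimate, se,
#'   z, p_value, or, lo, hi), `loglik`, `loglik_null`, `n`, `converged`,
#'   `separation`.
#' @export
fit_logistic <- function(outcome, design, outcome_name = "outcome",
                         conf = 0.95) {
  y <- as_status01(outcome)
  if (length(unique(y)) < 2L) {
    stop("outcome is degenerate: both classes must be present", call. = FALSE)
  }
  design <- as.data.frame(design)
  stopifnot(nrow(design) == length(y) || ncol(design) == 0L)
  if (ncol(design) > 0L) {
    const <- vapply(design, function(v) stats::var(as.numeric(v)) == 0, TRUE)
    if (any(const)) {
      stop("constant non-intercept column(s): ",
           paste(names(design)[const], collapse = ", "), call. = FALSE)
    }
  }
  if (ncol(design) > 0L) {
    dat <- cbind(.y = y, design)
    fml <- .y ~ .
  } else {
    dat <- data.frame(.y = y)
    fml <- .y ~ 1
  }
  fit <- suppressWarnings(
    stats::glm(fml, data = dat, family = stats::binomial())
  )
  mu <- stats::fitted(fit)
  separation <- any(mu > 1 - 1e-10) || any(mu < 1e-10)
  converged <- isTRUE(fit$converged) && !separation
  z <- stats::qnorm(1 - (1 - conf) / 2)
  sm <- summary(fit)$coefficients
  coefs <- data.frame(
    term = rownames(sm),
    estimate = sm[, 1], se = sm[, 2], z = sm[, 3], p_value = sm[, 4],
    or = exp(sm[, 1]),
    lo = exp(sm[, 1] - z * sm[, 2]),
    hi = exp(sm[, 1] + z * sm[, 2]),
    row.names = NULL, stringsAsFactors = FALSE
  )
  null_fit <- stats::glm(y ~ 1, family = stats::binomial())
  structure(list(
    outcome = outcome_name,
    coefficients = coefs,
    loglik = as.numeric(stats::logLik(fit)),
    loglik_null = as.numeric(stats::logLik(null_fit)),
    n = length(y),
    converged = converged,
    separation = separation,
    model = "logistic",
    fit = fit
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, digits = 3, ...) {
  cat(sprintf("%s fit of '%s' (n = %d%s)\n", x$model, x$outcome, x$n,
              if (!isTRUE(x$converged)) ", NOT CONVERGED" else ""))
  print(format(x$coefficients, digits = digits), row.names = FALSE)
  if (!is.null(x$loglik)) cat(sprintf("log-likelihood: %.3f\n", x$loglik))
  if (!is.null(x$r_squared)) cat(sprintf("R-squared: %.4f\n", x$r_squared))
  invisible(x)
}

coef_of <- function(fit, term) {
  i <- match(term, fit$coefficients$term)
  if (is.na(i)) stop("no term '", term, "' in fit", call. = FALSE)
  fit$coefficients[i, , drop = FALSE]
}

#' Cox-Snell pseudo R-squared
#'
#' `1 - exp((2/n) * (ll_null - ll_model))` for a model nested above the
#' null fit on the same `n` observations.
#'
#' @param loglik_null,loglik_model log-likelihoods (model >= null).
#' @param n number of observations.
#' @return Pseudo R-squared in `[0, 1)`.
#' @export
cox_snell_r2 <- function(loglik_null, loglik_model, n) {
  if (n <= 0) stop("n must be positive", call. = FALSE)
  if (loglik_model < loglik_null - 1e-8) {
    stop("loglik_model must be >= loglik_null (nested models)", call. = FALSE)
  }
  1 - exp((2 / n) * (loglik_null - loglik_model))
}

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha family-wise error rate.
#' @param n_tests number of independent comparisons (default 28, the
#'   study-wise registry size, giving `p < 0.0018` at `alpha = 0.05`).
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests = 28L) {
  stopifnot(n_tests >= 1, alpha > 0, alpha < 1)
  alpha / n_tests
}

# Standardize using a reference subset's mean/sd (train-set convention).
std_by <- function(x, ref) {
  s <- stats::sd(ref)
  if (!is.finite(s) || s == 0) return(NULL)
  (x - mean(ref)) / s
}

analytic_subset <- function(cohort, need_pgs = TRUE) {
  ok <- !is.na(cohort$fh_t2d) & !is.na(cohort$bmi) & !is.na(cohort$age) &
    !is.na(cohort$sex)
  if (need_pgs) ok <- ok & !is.na(cohort$pgs_std)
  cohort[ok, , drop = FALSE]
}

prevalence_design <- function(dat, train_idx) {
  logbmi <- log(dat$bmi)
  pgs <- dat$pgs_std
  z_bmi <- std_by(logbmi, logbmi[train_idx])
  z_pgs <- std_by(pgs, pgs[train_idx])
  list(
    base = data.frame(
      female_sex = as.integer(dat$sex == "female"),
      decade_of_age = dat$age / 10,
      std_log_bmi = z_bmi
    ),
    fh = as.integer(dat$fh_t2d == "positive"),
    pgs = z_pgs
  )
}

#' Nested comparison of base / family-history / PGS / combined models
#'
#' Reproduces the four-model logistic comparison of prevalent disease:
#' a base model (female sex, decade of age = age/10, standardized log
#' BMI), the base plus first-degree family history, the base plus the
#' standardized PGS, and the combined model. Rows with complete family
#' history, BMI, age, sex and PGS form the analytic subset; a seeded
#' 75/25 split (stratified by outcome) separates training rows, on which
#' coefficients and Cox-Snell pseudo R-squared are computed, from held-out
#' rows used for AUC with a bootstrap interval. Log BMI and the PGS are
#' standardized by the training subset's mean/SD. A zero-variance PGS
#' column is dropped (the PGS models then equal their FH-free
#' counterparts).
#'
#' @param cohort cohort data frame with `pgs_std` populated.
#' @param split_fraction training fraction.
#' @param seed integer seed (split and bootstrap).
#' @param n_boot bootstrap replicates for held-out AUC.
#' @param min_n minimum analytic-subset size.
#' @return A `model_comparison` list: `fits` (named `fit_result`s),
#'   `pseudo_r2`, `auc` (per-model [auc_with_ci()]), `split`.
#' @export
compare_prevalence_models <- function(cohort, split_fraction = 0.75,
                                      seed = 1L, n_boot = 2000,
                                      min_n = 200L) {
  dat <- analytic_subset(cohort)
  if (nrow(dat) < min_n) {
    stop("analytic subset too small (", nrow(dat), " rows)", call. = FALSE)
  }
  y <- as.integer(dat$t2d_status == "case")
  set.seed(substream_seed(seed, "split"))
  idx_case <- which(y == 1); idx_ctrl <- which(y == 0)
  take <- function(idx, frac) {
    idx[sample.int(length(idx), round(frac * length(idx)))]
  }
  train <- sort(c(take(idx_case, split_fraction),
                  take(idx_ctrl, split_fraction)))
  test <- setdiff(seq_along(y), train)

  parts <- prevalence_design(dat, train)
  designs <- list(base = parts$base)
  designs$family_history_only <- cbind(parts$base, family_history = parts$fh)
  if (!is.null(parts$pgs)) {
    designs$pgs_only <- cbind(parts$base, std_pgs = parts$pgs)
    designs$combined <- cbind(parts$base, family_history = parts$fh,
                              std_pgs = parts$pgs)
  } else {
    warning("PGS has zero variance; PGS models collapse to their FH-free forms")
    designs$pgs_only <- parts$base
    designs$combined <- designs$family_history_only
  }

  fits <- lapply(names(designs), function(nm) {
    fit_logistic(y[train], designs[[nm]][train, , drop = FALSE],
                 outcome_name = paste0("t2d_", nm))
  })
  names(fits) <- names(designs)

  pseudo_r2 <- vapply(fits, function(f) {
    cox_snell_r2(f$loglik_null, f$loglik, f$n)
  }, 0)

  aucs <- lapply(names(designs), function(nm) {
    p <- stats::predict(fits[[nm]]$fit,
                        newdata = designs[[nm]][test, , drop = FALSE],
                        type = "response")
    auc_with_ci(p, y[test], n_boot = n_boot, seed = seed)
  })
  names(aucs) <- names(designs)

  structure(list(
    fits = fits, pseudo_r2 = pseudo_r2, auc = aucs,
    split = list(fraction = split_fraction, n_train = length(train),
                 n_test = length(test), seed = seed)
  ), class = "model_comparison")
}

#' Tabulate a model comparison
#'
#' @param x a [compare_prevalence_models()] result.
#' @param ... unused.
#' @return Data frame with one column per model, rows for each
#'   coefficient, pseudo R-squared and held-out AUC.
#' @export
as.data.frame.model_comparison <- function(x, ...) {
  terms <- c("(Intercept)", "family_history", "std_pgs", "female_sex",
             "decade_of_age", "std_log_bmi")
  labels <- c("Intercept", "Family history", "Standardized PGS",
              "Female sex", "Decade of age", "Standardized log BMI")
  cols <- lapply(x$fits, function(f) {
    v <- f$coefficients$estimate[match(terms, f$coefficients$term)]
    names(v) <- labels
    v
  })
  out <- as.data.frame(cols, check.names = FALSE)
  out <- rbind(out,
               `Cox-Snell pseudo R2` = unname(x$pseudo_r2),
               `Test-set AUC` = vapply(x$auc, `[[`, 0, "auc"))
  out
}

#' @export
print.model_comparison <- function(x, digits = 3, ...) {
  cat(sprintf("Model comparison (train n = %d, test n = %d)\n",
              x$split$n_train, x$split$n_test))
  print(round(as.data.frame(x), digits))
  invisible(x)
}

#' Association between family history and the polygenic score
#'
#' Logistic regression of positive first-degree family history on the
#' standardized PGS (optionally with covariates); the per-SD odds ratio
#' is reported alongside the raw coefficient since both rounded forms
#' circulate.
#'
#' @param cohort cohort data frame with non-missing `fh_t2d` rows used.
#' @param covariates optional extra design columns (data frame).
#' @return A `fit_result` with elements `or_per_sd` and `beta_per_sd`.
#' @export
fh_pgs_association <- function(cohort, covariates = NULL) {
  dat <- cohort[!is.na(cohort$fh_t2d) & !is.na(cohort$pgs_std), , drop = FALSE]
  design <- data.frame(std_pgs = std_by(dat$pgs_std, dat$pgs_std))
  if (!is.null(covariates)) design <- cbind(design, covariates)
  fit <- fit_logistic(as.integer(dat$fh_t2d == "positive"), design,
                      outcome_name = "family_history")
  row <- coef_of(fit, "std_pgs")
  fit$or_per_sd <- row$or
  fit$beta_per_sd <- row$estimate
  fit
}

#' Linear model of age of diagnosis among cases
#'
#' OLS of age of diagnosis on the standardized PGS, standardized log BMI
#' and family history, with coefficient confidence intervals and model
#' R-squared.
#'
#' @param cases case-only cohort rows with non-missing `aod`.
#' @param min_n minimum usable sample size.
#' @param conf confidence level.
#' @return A `fit_result` (`model = "linear"`, with `r_squared`).
#' @export
fit_aod_model <- function(cases, min_n = 30L, conf = 0.95) {
  if (any(cases$t2d_status != "case")) {
    stop("fit_aod_model expects cases only", call. = FALSE)
  }
  dat <- cases[!is.na(cases$aod) & !is.na(cases$fh_t2d) &
                 !is.na(cases$pgs_std), , drop = FALSE]
  if (nrow(dat) < min_n) {
    stop("too few cases with age of diagnosis (", nrow(dat), ")",
         call. = FALSE)
  }
  design <- data.frame(
    std_pgs = std_by(dat$pgs_std, dat$pgs_std),
    std_log_bmi = std_by(log(dat$bmi), log(dat$bmi)),
    family_history = as.integer(dat$fh_t2d == "positive")
  )
  fit <- stats::lm(dat$aod ~ ., data = design)
  sm <- summary(fit)
  z <- stats::qt(1 - (1 - conf) / 2, df = fit$df.residual)
  co <- sm$coefficients
  coefs <- data.frame(
    term = rownames(co), estimate = co[, 1], se = co[, 2], z = co[, 3],
    p_value = co[, 4], or = NA_real_,
    lo = co[, 1] - z * co[, 2], hi = co[, 1] + z * co[, 2],
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(
    outcome = "age_of_diagnosis", coefficients = coefs,
    loglik = as.numeric(stats::logLik(fit)), loglik_null = NULL,
    n = nrow(dat), converged = TRUE, separation = FALSE,
    model = "linear", r_squared = sm$r.squared, fit = fit
  ), class = "fit_result")
}

#' Logistic model of prediabetes among controls
#'
#' Fit on age, female sex, standardized log BMI, family history and the
#' standardized PGS; refuses case rows.
#'
#' @param controls control-only cohort rows with `prediabetes` set.
#' @return A `fit_result` with `or_per_sd`.
#' @export
fit_prediabetes_model <- function(controls) {
  if (any(controls$t2d_status != "control")) {
    stop("fit_prediabetes_model expects controls only", call. = FALSE)
  }
  dat <- controls[!is.na(controls$prediabetes) & !is.na(controls$fh_t2d) &
                    !is.na(controls$pgs_std), , drop = FALSE]
  design <- data.frame(
    age = dat$age,
    female_sex = as.integer(dat$sex == "female"),
    std_log_bmi = std_by(log(dat$bmi), log(dat$bmi)),
    family_history = as.integer(dat$fh_t2d == "positive"),
    std_pgs = std_by(dat$pgs_std, dat$pgs_std)
  )
  fit <- fit_logistic(as.integer(dat$prediabetes == "yes"), design,
                      outcome_name = "prediabetes")
  fit$or_per_sd <- coef_of(fit, "std_pgs")$or
  fit
}

#' Logistic model of one-year incident conversion
#'
#' Restricts to baseline controls followed between one and two years
#' (`followup_days` in (365, 730]) with a definite yes/no incident
#' status, then fits age, standardized log BMI, family history and the
#' standardized PGS.
#'
#' @param followed cohort rows (controls with follow-up).
#' @return A `fit_result` with `or_per_sd` and `n_events`.
#' @export
fit_incidence_model <- function(followed) {
  dat <- followed[followed$incident_t2d %in% c("yes", "no") &
                    !is.na(followed$followup_days) &
                    followed$followup_days > 365 &
                    followed$followup_days <= 730 &
                    !is.na(followed$fh_t2d) & !is.na(followed$pgs_std), ,
                  drop = FALSE]
  events <- sum(dat$incident_t2d == "yes")
  if (events == 0L) stop("no incident events in window", call. = FALSE)
  design <- data.frame(
    age = dat$age,
    std_log_bmi = std_by(log(dat$bmi), log(dat$bmi)),
    family_history = as.integer(dat$fh_t2d == "positive"),
    std_pgs = std_by(dat$pgs_std, dat$pgs_std)
  )
  fit <- fit_logistic(as.integer(dat$incident_t2d == "yes"), design,
                      outcome_name = "incident_t2d")
  fit$or_per_sd <- coef_of(fit, "std_pgs")$or
  fit$n_events <- events
  fit
}

#' Treatment and complication models among cases
#'
#' Six logistic fits on the case subset: insulin, metformin and
#' lifestyle-only treatment (adjusted for the standardized PGS, age,
#' female sex, standardized log BMI and family history), and neuropathy,
#' nephropathy and retinopathy (additionally adjusted for years since
#' diagnosis). Lifestyle-only means physician-directed lifestyle
#' modification without metformin or insulin. Outcomes with no variation
#' in the subset are skipped with a warning.
#'
#' @param cases case-only cohort rows.
#' @return Named list of `fit_result`s (skipped outcomes absent).
#' @export
fit_severity_models <- function(cases) {
  if (any(cases$t2d_status != "case")) {
    stop("fit_severity_models expects cases only", call. = FALSE)
  }
  dat <- cases[!is.na(cases$fh_t2d) & !is.na(cases$pgs_std) &
                 !is.na(cases$trt_insulin), , drop = FALSE]
  base_design <- data.frame(
    std_pgs = std_by(dat$pgs_std, dat$pgs_std),
    age = dat$age,
    female_sex = as.integer(dat$sex == "female"),
    std_log_bmi = std_by(log(dat$bmi), log(dat$bmi)),
    family_history = as.integer(dat$fh_t2d == "positive")
  )
  outcomes <- list(
    insulin = dat$trt_insulin,
    metformin = dat$trt_metformin,
    lifestyle_only = dat$trt_lifestyle & !dat$trt_metformin & !dat$trt_insulin,
    neuropathy = dat$cmp_neuropathy,
    nephropathy = dat$cmp_nephropathy,
    retinopathy = dat$cmp_retinopathy
  )
  fits <- list()
  for (nm in names(outcomes)) {
    y <- as.integer(outcomes[[nm]])
    if (length(unique(y[!is.na(y)])) < 2L) {
      warning("outcome '", nm, "' has no variation among cases; skipped")
      next
    }
    design <- base_design
    if (nm %in% c("neuropathy", "nephropathy", "retinopathy")) {
      design$years_since_dx <- dat$years_since_dx
    }
    fits[[nm]] <- fit_logistic(y, design, outcome_name = nm)
    fits[[nm]]$or_per_sd <- coef_of(fits[[nm]], "std_pgs")$or
  }
  fits
}

#' Study-wise significance report
#'
#' Collects the headline term of each supplied fit and labels it
#' significant at the Bonferroni-controlled threshold
#' `alpha / n_tests` (default `0.05 / 28 = 0.0018` to two significant
#' figures).
#'
#' @param fits named list of `fit_result`s.
#' @param terms term of interest per fit (recycled; default
#'   `"std_pgs"`).
#' @param alpha family-wise error rate.
#' @param n_tests comparison count for the Bonferroni correction.
#' @return Data frame: `comparison`, `term`, `estimate`, `or`,
#'   `p_value`, `threshold`, `significant`.
#' @export
significance_report <- function(fits, terms = "std_pgs", alpha = 0.05,
                                n_tests = 28L) {
  thr <- bonferroni_threshold(alpha, n_tests)
  terms <- rep_len(terms, length(fits))
  rows <- lapply(seq_along(fits), function(i) {
    row <- coef_of(fits[[i]], terms[i])
    data.frame(comparison = names(fits)[i], term = terms[i],
               estimate = row$estimate, or = row$or, p_value = row$p_value,
               threshold = thr, significant = row$p_value < thr,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
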