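#' Default phenotype-generation parameters
#'
#' Returns the parameter list consumed by [assign_phenotypes()]. Defaults
#' describe a contemporary adult survey cohort: age truncated normal with
#' mean 47.6 and SD 15.8 years on [20, 79], 60.4% female, log-normal BMI,
#' a target type-2-diabetes prevalence of 3.2% at the cohort margin, mean
#' age of diagnosis near 48 among cases, and one-year follow-up averaging
#' 446 days (SD 102) for the subset re-surveyed. Liability-scale slopes
#' (per SD of liability) default to an age-of-diagnosis gradient of 1.37
#' years, prediabetes log-odds slope `log(1.23)` and incident-conversion
#' slope `log(1.43)`; treatment and complication slopes are loosely
#' calibrated so insulin and neuropathy carry signal while metformin,
#' nephropathy and retinopathy are near-null.
#'
#' @param ... named overrides of any default.
#' @return Named list of parameters.
#' @export
pheno_params <- function(...) {
  p <- list(
    prevalence = 0.032,
    age_mean = 47.6, age_sd = 15.8, age_range = c(20, 79),
    female_frac = 0.604,
    bmi_meanlog = log(26.5), bmi_sdlog = 0.17,
    liability_age_slope = 0.15, liability_bmi_slope = 0.40,
    parent_age_offset = 28, parent_age_sd = 5, parent_age_max = 95,
    fh_missing_rate = 0,
    aod_mean = 51, aod_slope = 1.37, aod_sd = 8,
    prediab_base = 0.022, prediab_slope = log(1.23),
    followed_frac = 0.21, followup_mean = 446, followup_sd = 102,
    incidence_base = 0.006, incidence_slope = log(1.43),
    # per-outcome (baseline prob at L = 0, slope per liability SD,
    # slope per year since diagnosis)
    insulin = c(base = 0.15, l = log(1.40), dur = 0.03),
    metformin = c(base = 0.50, l = 0, dur = 0.02),
    lifestyle = c(base = 0.60, l = 0, dur = 0),
    neuropathy = c(base = 0.12, l = log(1.25), dur = 0.05),
    nephropathy = c(base = 0.05, l = 0, dur = 0.05),
    retinopathy = c(base = 0.05, l = 0, dur = 0.06),
    ancestry = c(european = 1)
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown)) {
    stop("unknown phenotype parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  p[names(dots)] <- dots
  p
}

logit <- stats::qlogis

#' Assign phenotypes to simulated families under a liability-threshold model
#'
#' Builds standardized liability `L = G + C + E` (genetic, family-shared,
#' unique environment; component variances `h2_snp`, `c2_shared` and the
#' remainder). Disease status is a probit-style threshold on
#' `L + b_age * z_age + b_bmi * z_logBMI`; the threshold is the empirical
#' `1 - prevalence` quantile of that linear predictor, so the realised
#' cohort prevalence matches the target. Parents receive their own age/BMI
#' draws and environmental noise (sharing `C` and the threshold), and
#' first-degree family history is positive when at least one parent is
#' affected. Cases get an age of diagnosis `aod_mean - aod_slope * L`
#' plus noise, truncated to `[20, age]`; controls get prediabetes, and a
#' followed subset a one-year incident conversion, with log-odds linear in
#' `L`; treatment and microvascular-complication indicators among cases
#' have log-odds linear in `L` and years since diagnosis.
#'
#' @param genotypes a [simulate_families()] object.
#' @param model the matching [draw_score_model()] object.
#' @param params a [pheno_params()] list.
#' @param seed integer seed.
#' @return List with `cohort` (one row per offspring; see package README for
#'   the column dictionary) and `truth` (per-individual liability components
#'   and the generator parameters as attributes).
#' @export
assign_phenotypes <- function(genotypes, model, params = pheno_params(),
                              seed = 1L) {
  stopifnot(inherits(genotypes, "genotype_set"), inherits(model, "score_model"))
  if (params$prevalence <= 0 || params$prevalence >= 1) {
    stop("target prevalence must be in (0, 1)", call. = FALSE)
  }
  set.seed(substream_seed(seed, "phenotypes"))
  n <- nrow(genotypes$offspring)
  h2 <- attr(model, "h2_snp")
  c2 <- attr(model, "c2_shared")
  e2 <- 1 - h2 - c2

  g_off <- true_score(genotypes$offspring, model)
  g_mo <- true_score(genotypes$mother, model)
  g_fa <- true_score(genotypes$father, model)
  shared <- stats::rnorm(n, 0, sqrt(c2))
  env <- stats::rnorm(n, 0, sqrt(e2))
  L <- g_off + shared + env

  age <- rtruncnorm(n, params$age_mean, params$age_sd,
                    params$age_range[1], params$age_range[2])
  female <- stats::rbinom(n, 1, params$female_frac) == 1
  bmi <- exp(stats::rnorm(n, params$bmi_meanlog, params$bmi_sdlog))
  z_age <- (age - params$age_mean) / params$age_sd
  z_bmi <- (log(bmi) - params$bmi_meanlog) / params$bmi_sdlog

  eta <- L + params$liability_age_slope * z_age +
    params$liability_bmi_slope * z_bmi
  threshold <- stats::quantile(eta, 1 - params$prevalence, names = FALSE)
  if (!is.finite(threshold)) {
    stop("infeasible prevalence target: liability threshold is not finite",
         call. = FALSE)
  }
  case <- eta > threshold

  parent_pheno <- function(g_par) {
    p_age <- clamp(age + stats::rnorm(n, params$parent_age_offset,
                                      params$parent_age_sd),
                   params$age_range[1], params$parent_age_max)
    p_bmi <- exp(stats::rnorm(n, params$bmi_meanlog, params$bmi_sdlog))
    L_par <- g_par + shared + stats::rnorm(n, 0, sqrt(e2))
    L_par + params$liability_age_slope * (p_age - params$age_mean) / params$age_sd +
      params$liability_bmi_slope * (log(p_bmi) - params$bmi_meanlog) / params$bmi_sdlog
  }
  mo_case <- parent_pheno(g_mo) > threshold
  fa_case <- parent_pheno(g_fa) > threshold
  fh <- ifelse(mo_case | fa_case, "positive", "negative")
  if (params$fh_missing_rate > 0) {
    fh[stats::runif(n) < params$fh_missing_rate] <- NA_character_
  }

  aod <- rep(NA_real_, n)
  n_case <- sum(case)
  if (n_case > 0) {
    aod[case] <- clamp(
      params$aod_mean - params$aod_slope * L[case] +
        stats::rnorm(n_case, 0, params$aod_sd),
      20, age[case]
    )
  }
  years_since_dx <- age - aod

  prediab <- rep(NA, n)
  ctrl <- !case
  prediab[ctrl] <- stats::runif(sum(ctrl)) <
    stats::plogis(logit(params$prediab_base) + params$prediab_slope * L[ctrl])

  incident <- rep("not_followed", n)
  followup_days <- rep(NA_integer_, n)
  followed <- ctrl & stats::runif(n) < params$followed_frac
  n_fol <- sum(followed)
  if (n_fol > 0) {
    followup_days[followed] <- as.integer(round(clamp(
      stats::rnorm(n_fol, params$followup_mean, params$followup_sd), 366, 730)))
    conv <- stats::runif(n_fol) < stats::plogis(
      logit(params$incidence_base) + params$incidence_slope * L[followed])
    incident[followed] <- ifelse(conv, "yes", "no")
  }

  case_flag <- function(par) {
    out <- rep(NA, n)
    if (n_case > 0) {
      out[case] <- stats::runif(n_case) < stats::plogis(
        logit(par[["base"]]) + par[["l"]] * L[case] +
          par[["dur"]] * years_since_dx[case])
    }
    out
  }

  labels <- sample(names(params$ancestry), n, replace = TRUE,
                   prob = params$ancestry)

  cohort <- data.frame(
    participant_id = sprintf("P%07d", seq_len(n)),
    age = age,
    sex = ifelse(female, "female", "male"),
    bmi = bmi,
    ancestry_label = labels,
    fh_t2d = fh,
    t2d_status = ifelse(case, "case", "control"),
    aod = aod,
    years_since_dx = years_since_dx,
    prediabetes = ifelse(is.na(prediab), NA_character_,
                         ifelse(prediab, "yes", "no")),
    incident_t2d = incident,
    followup_days = followup_days,
    trt_lifestyle = case_flag(params$lifestyle),
    trt_metformin = case_flag(params$metformin),
    trt_insulin = case_flag(params$insulin),
    cmp_neuropathy = case_flag(params$neuropathy),
    cmp_nephropathy = case_flag(params$nephropathy),
    cmp_retinopathy = case_flag(params$retinopathy),
    pgs_raw = NA_real_,
    pgs_std = NA_real_,
    stringsAsFactors = FALSE
  )

  truth <- data.frame(
    participant_id = cohort$participant_id,
    liability_genetic = g_off,
    liability_shared = shared,
    liability_env = env,
    liability = L,
    mother_genetic = g_mo,
    father_genetic = g_fa,
    stringsAsFactors = FALSE
  )
  attr(truth, "threshold") <- threshold
  attr(truth, "params") <- params
  attr(truth, "h2_snp") <- h2
  attr(truth, "c2_shared") <- c2
  list(cohort = cohort, truth = truth)
}

#' Apply the standard cohort exclusion filters
#'
#' Drops rows with age outside [20, 79], BMI outside [18.5, 69], case age
#' of diagnosis under 20 or greater than current age, or more than 40
#' years between diagnosis and current age. The per-reason exclusion tally
#' is attached as attribute `"filter_log"` (rows failing several filters
#' count once per reason, but are dropped once).
#'
#' @param cohort a cohort data frame.
#' @return The filtered cohort with a `filter_log` attribute.
#' @export
apply_cohort_filters <- function(cohort) {
  is_case <- cohort$t2d_status == "case"
  bad_age <- cohort$age < 20 | cohort$age > 79
  bad_bmi <- cohort$bmi < 18.5 | cohort$bmi > 69
  bad_aod_young <- is_case & !is.na(cohort$aod) & cohort$aod < 20
  bad_aod_order <- is_case & !is.na(cohort$aod) & cohort$aod > cohort$age
  bad_duration <- is_case & !is.na(cohort$aod) &
    (cohort$age - cohort$aod) > 40
  drop <- bad_age | bad_bmi | bad_aod_young | bad_aod_order | bad_duration
  out <- cohort[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filter_log") <- c(
    age_out_of_range = sum(bad_age),
    bmi_out_of_range = sum(bad_bmi),
    aod_under_20 = sum(bad_aod_young),
    aod_exceeds_age = sum(bad_aod_order),
    duration_over_40y = sum(bad_duration),
    n_excluded = sum(drop),
    n_retained = sum(!drop)
  )
  out
}

#' Generate a filtered family-based cohort with ground truth
#'
#' Orchestrates [draw_score_model()], [simulate_families()] and
#' [assign_phenotypes()], then applies [apply_cohort_filters()] to the
#' result (genotypes and truth are subset to the retained rows).
#'
#' @param config a [sim_config()] list.
#' @return List with `cohort`, `genotypes`, `model`, `truth` and
#'   `filter_log`.
#' @export
generate_cohort <- function(config = sim_config()) {
  model <- draw_score_model(config$m_snps, config$n_causal, config$h2_snp,
                            config$c2_shared, config$maf_range,
                            config$genome_length, config$seed)
  genotypes <- simulate_families(config$n, model, config$seed)
  ph <- assign_phenotypes(genotypes, model, config$pheno, config$seed)
  cohort <- apply_cohort_filters(ph$cohort)
  flog <- attr(cohort, "filter_log")
  if (nrow(cohort) == 0L) {
    stop("no rows remain after exclusion filters", call. = FALSE)
  }
  keep <- match(cohort$participant_id, ph$cohort$participant_id)
  genotypes$offspring <- genotypes$offspring[keep, , drop = FALSE]
  genotypes$mother <- genotypes$mother[keep, , drop = FALSE]
  genotypes$father <- genotypes$father[keep, , drop = FALSE]
  truth <- ph$truth[keep, , drop = FALSE]
  rownames(truth) <- NULL
  for (a in c("threshold", "params", "h2_snp", "c2_shared")) {
    attr(truth, a) <- attr(ph$truth, a)
  }
  list(cohort = cohort, genotypes = genotypes, model = model,
       truth = truth, filter_log = flog)
}

#' Simulation configuration
#'
#' Bundles the genetic-architecture and phenotype parameters with a global
#' seed. `pheno` entries can be overridden through `...` (anything not a
#' top-level field is passed to [pheno_params()]).
#'
#' @param n cohort size before exclusion filters.
#' @param m_snps,n_causal number of SNPs and causal SNPs.
#' @param h2_snp,c2_shared liability variance fractions.
#' @param maf_range,genome_length SNP sampling controls.
#' @param seed integer global seed.
#' @param ... overrides for [pheno_params()].
#' @return A `sim_config` list.
#' @export
sim_config <- function(n = 10000, m_snps = 500, n_causal = 50,
                       h2_snp = 0.3, c2_shared = 0.1,
                       maf_range = c(0.05, 0.5), genome_length = 1e8,
                       seed = 1L, ...) {
  structure(list(
    n = n, m_snps = m_snps, n_causal = n_causal, h2_snp = h2_snp,
    c2_shared = c2_shared, maf_range = maf_range,
    genome_length = genome_length, seed = as.integer(seed),
    pheno = pheno_params(...)
  ), class = "sim_config")
}
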