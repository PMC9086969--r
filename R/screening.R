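#' Build a screening rule
#'
#' A rule is a disjunction of criteria; each criterion is a conjunction of
#' an age interval (inclusive, in years), a BMI interval (`[lo, hi)` in
#' kg/m2), an optional positive-family-history requirement and an optional
#' PGS percentile floor. Implemented guidelines:
#'
#' * `uspstf`: screen adults aged 35-70 who are overweight or obese
#'   (BMI >= 25).
#' * `ada_simplified`: screen everyone aged 45 or older, plus adults
#'   (18+) with BMI >= 25 and positive first-degree family history.
#'
#' With `with_pgs = TRUE` a disjunct is added screening normal-BMI
#' (18.5 <= BMI < 25) individuals at or above `pgs_percentile` of the
#' score distribution, from age 35 (USPSTF variant) or age 18 (ADA
#' variant). The USPSTF augmentation carries no upper age bound
#' ("35 or older") unless `cap_age70 = TRUE`.
#'
#' @param guideline `"uspstf"` or `"ada_simplified"`.
#' @param with_pgs add the polygenic-score disjunct?
#' @param pgs_percentile percentile floor for the PGS disjunct, in (0, 100).
#' @param cap_age70 bound the USPSTF PGS disjunct at age 70.
#' @return A `screening_rule` object.
#' @examples
#' build_rule("uspstf", with_pgs = TRUE)
#' @export
build_rule <- function(guideline = c("uspstf", "ada_simplified"),
                       with_pgs = FALSE, pgs_percentile = 90,
                       cap_age70 = FALSE) {
  guideline <- match.arg(guideline)
  stopifnot(pgs_percentile > 0, pgs_percentile < 100)
  crit <- function(age_min = 0, age_max = Inf, bmi_min = 0, bmi_max = Inf,
                   fh = NA, pgs_min_pct = NA_real_) {
    list(age_min = age_min, age_max = age_max, bmi_min = bmi_min,
         bmi_max = bmi_max, fh = fh, pgs_min_pct = pgs_min_pct)
  }
  if (guideline == "uspstf") {
    criteria <- list(crit(age_min = 35, age_max = 70, bmi_min = 25))
    if (with_pgs) {
      criteria <- c(criteria, list(crit(
        age_min = 35, age_max = if (cap_age70) 70 else Inf,
        bmi_min = 18.5, bmi_max = 25, pgs_min_pct = pgs_percentile)))
    }
  } else {
    criteria <- list(
      crit(age_min = 45),
      crit(age_min = 18, bmi_min = 25, fh = TRUE)
    )
    if (with_pgs) {
      criteria <- c(criteria, list(crit(
        age_min = 18, bmi_min = 18.5, bmi_max = 25,
        pgs_min_pct = pgs_percentile)))
    }
  }
  name <- paste0(guideline, if (with_pgs) "+pgs" else "")
  structure(list(name = name, criteria = criteria),
            class = "screening_rule")
}

#' Construct a custom screening rule
#'
#' @param name rule name.
#' @param criteria list of criteria, each a named list with any of
#'   `age_min`, `age_max`, `bmi_min`, `bmi_max`, `fh`, `pgs_min_pct`.
#' @return A `screening_rule` object.
#' @export
screening_rule <- function(name, criteria) {
  defaults <- list(age_min = 0, age_max = Inf, bmi_min = 0, bmi_max = Inf,
                   fh = NA, pgs_min_pct = NA_real_)
  criteria <- lapply(criteria, function(cr) {
    unknown <- setdiff(names(cr), names(defaults))
    if (length(unknown)) {
      stop("unknown criterion field(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    out <- defaults
    out[names(cr)] <- cr
    out
  })
  structure(list(name = name, criteria = criteria), class = "screening_rule")
}

#' @export
print.screening_rule <- function(x, ...) {
  cat("Screening rule:", x$name, "\n")
  for (cr in x$criteria) {
    parts <- character(0)
    if (cr$age_min > 0 || is.finite(cr$age_max)) {
      parts <- c(parts, sprintf("age in [%g, %g]", cr$age_min, cr$age_max))
    }
    if (cr$bmi_min > 0 || is.finite(cr$bmi_max)) {
      parts <- c(parts, sprintf("BMI in [%g, %g)", cr$bmi_min, cr$bmi_max))
    }
    if (isTRUE(cr$fh)) parts <- c(parts, "FH positive")
    if (!is.na(cr$pgs_min_pct)) {
      parts <- c(parts, sprintf("PGS pct >= %g", cr$pgs_min_pct))
    }
    cat("  OR:", paste(parts, collapse = " AND "), "\n")
  }
  invisible(x)
}

rule_uses_pgs <- function(rule) {
  any(vapply(rule$criteria, function(cr) !is.na(cr$pgs_min_pct), TRUE))
}

# Screened indicator per row; ages for cases are their age of diagnosis.
apply_rule <- function(rule, eval_age, bmi, fh_positive, pgs_pct) {
  screened <- rep(FALSE, length(eval_age))
  for (cr in rule$criteria) {
    ok <- eval_age >= cr$age_min & eval_age <= cr$age_max &
      bmi >= cr$bmi_min & bmi < cr$bmi_max
    if (isTRUE(cr$fh)) ok <- ok & !is.na(fh_positive) & fh_positive
    if (!is.na(cr$pgs_min_pct)) ok <- ok & pgs_pct >= cr$pgs_min_pct
    screened <- screened | ok
  }
  screened
}

#' Evaluate a screening rule on a cohort
#'
#' Applies the rule row by row, testing the age criterion at the age of
#' diagnosis for cases and at current age for controls. Cases with missing
#' age of diagnosis are excluded and counted. PGS percentiles are taken
#' from a `pgs_pct` column when present, otherwise computed within the
#' evaluation cohort from `pgs_std` (the implicit choice when no external
#' reference distribution exists). Sensitivity/specificity get Wilson
#' intervals.
#'
#' @param cohort cohort data frame (`t2d_status`, `age`, `aod`, `bmi`,
#'   `fh_t2d`; `pgs_std` or `pgs_pct` if the rule uses the score).
#' @param rule a [build_rule()] / [screening_rule()] object.
#' @param conf confidence level.
#' @return A `rule_evaluation` list: confusion counts, sensitivity,
#'   specificity, their intervals, and the excluded-row count.
#' @export
evaluate_rule <- function(cohort, rule, conf = 0.95) {
  stopifnot(inherits(rule, "screening_rule"))
  is_case <- cohort$t2d_status == "case"
  if (!any(is_case) || all(is_case)) {
    stop("cohort must contain both cases and controls", call. = FALSE)
  }
  drop <- is_case & is.na(cohort$aod)
  n_excluded <- sum(drop)
  dat <- cohort[!drop, , drop = FALSE]
  is_case <- is_case[!drop]

  pgs_pct <- if ("pgs_pct" %in% names(dat)) {
    dat$pgs_pct
  } else if (rule_uses_pgs(rule)) {
    if (!"pgs_std" %in% names(dat) || anyNA(dat$pgs_std)) {
      stop("rule requires a PGS but the cohort has no usable pgs_std/pgs_pct",
           call. = FALSE)
    }
    pgs_percentile(dat$pgs_std)
  } else {
    rep(NA_real_, nrow(dat))
  }

  eval_age <- ifelse(is_case, dat$aod, dat$age)
  screened <- apply_rule(rule, eval_age, dat$bmi,
                         dat$fh_t2d == "positive", pgs_pct)
  tp <- sum(screened & is_case)
  fn <- sum(!screened & is_case)
  fp <- sum(screened & !is_case)
  tn <- sum(!screened & !is_case)
  structure(list(
    rule = rule$name,
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    sensitivity_ci = wilson_ci(tp, tp + fn, conf),
    specificity_ci = wilson_ci(tn, tn + fp, conf),
    n_excluded = n_excluded
  ), class = "rule_evaluation")
}

#' @export
print.rule_evaluation <- function(x, ...) {
  cat(sprintf(
    "%s: sens %.3f (%.3f, %.3f) spec %.3f (%.3f, %.3f) [TP %d FP %d TN %d FN %d]\n",
    x$rule, x$sensitivity, x$sensitivity_ci[1], x$sensitivity_ci[2],
    x$specificity, x$specificity_ci[1], x$specificity_ci[2],
    x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

criterion_in <- function(cr, criteria) {
  any(vapply(criteria, function(other) isTRUE(all.equal(cr, other)), TRUE))
}

#' Compare a base rule with an augmented superset rule
#'
#' Requires every base criterion to appear in the augmented rule, so the
#' augmented screened set is a superset and sensitivity can only rise
#' while specificity can only fall. Reports both evaluations, the deltas,
#' and a description of the newly screened subgroup.
#'
#' @param cohort cohort data frame.
#' @param base,augmented [screening_rule()] objects.
#' @param conf confidence level.
#' @return A `rule_comparison` list.
#' @export
compare_rules <- function(cohort, base, augmented, conf = 0.95) {
  if (!all(vapply(base$criteria, criterion_in, TRUE,
                  criteria = augmented$criteria))) {
    stop("augmented rule must contain every criterion of the base rule",
         call. = FALSE)
  }
  ev_base <- evaluate_rule(cohort, base, conf)
  ev_aug <- evaluate_rule(cohort, augmented, conf)

  # reconstruct screened indicators for the newly screened subgroup
  is_case <- cohort$t2d_status == "case"
  keep <- !(is_case & is.na(cohort$aod))
  dat <- cohort[keep, , drop = FALSE]
  is_case <- is_case[keep]
  pgs_pct <- if ("pgs_pct" %in% names(dat)) {
    dat$pgs_pct
  } else if (rule_uses_pgs(augmented) || rule_uses_pgs(base)) {
    pgs_percentile(dat$pgs_std)
  } else {
    rep(NA_real_, nrow(dat))
  }
  eval_age <- ifelse(is_case, dat$aod, dat$age)
  s_base <- apply_rule(base, eval_age, dat$bmi, dat$fh_t2d == "positive",
                       pgs_pct)
  s_aug <- apply_rule(augmented, eval_age, dat$bmi, dat$fh_t2d == "positive",
                      pgs_pct)
  new <- s_aug & !s_base
  newly <- list(
    n = sum(new),
    case_fraction = if (sum(new)) mean(is_case[new]) else NA_real_,
    mean_pgs_std = if (sum(new) && "pgs_std" %in% names(dat)) {
      mean(dat$pgs_std[new])
    } else NA_real_
  )
  structure(list(
    base = ev_base, augmented = ev_aug,
    delta_sensitivity = ev_aug$sensitivity - ev_base$sensitivity,
    delta_specificity = ev_aug$specificity - ev_base$specificity,
    newly_screened = newly
  ), class = "rule_comparison")
}

#' @export
print.rule_comparison <- function(x, ...) {
  print(x$base); print(x$augmented)
  cat(sprintf("delta sensitivity %+.4f, delta specificity %+.4f; %d newly screened\n",
              x$delta_sensitivity, x$delta_specificity, x$newly_screened$n))
  invisible(x)
}

#' Serialize / read a screening rule as structured text (YAML)
#'
#' @param rule a `screening_rule`.
#' @param path file path.
#' @return `read_rule()` returns a `screening_rule`.
#' @export
write_rule <- function(rule, path) {
  yaml::write_yaml(list(name = rule$name, criteria = rule$criteria), path)
  invisible(path)
}

#' @rdname write_rule
#' @export
read_rule <- function(path) {
  x <- yaml::read_yaml(path)
  crits <- lapply(x$criteria, function(cr) {
    cr$age_max <- if (is.null(cr$age_max) || cr$age_max == ".inf") Inf else cr$age_max
    cr$bmi_max <- if (is.null(cr$bmi_max) || cr$bmi_max == ".inf") Inf else cr$bmi_max
    cr
  })
  screening_rule(x$name, crits)
}
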