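#' End-to-end pipeline configuration
#'
#' Wraps a [sim_config()] with the score-construction and evaluation
#' settings: how the simulated cohort is partitioned into association-scan,
#' tuning and assessment subsets, the clumping+thresholding grid, the bin
#' scheme, the screening rules, the train/test split and bootstrap size
#' for the model comparison, and the privacy floor for emitted tables.
#'
#' @param sim a [sim_config()].
#' @param gwas_frac,tune_frac fractions of the cohort used for the
#'   association scan and for tuning-set selection; the remainder is the
#'   assessment subset on which every downstream analysis runs.
#' @param p_grid,window_grid candidate grid for [build_candidates()].
#' @param bin_breaks percentile break points for [bin_scheme()].
#' @param pgs_percentile screening-rule percentile floor.
#' @param split_fraction training fraction for
#'   [compare_prevalence_models()].
#' @param n_boot bootstrap replicates for interval estimates.
#' @param privacy_floor minimum cell count before suppression.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(),
                            gwas_frac = 0.5, tune_frac = 0.1,
                            p_grid = c(1e-2, 1e-4, 1e-6),
                            window_grid = c(5e4, 2.5e5, 5e5),
                            bin_breaks = seq(0, 100, by = 5),
                            pgs_percentile = 90,
                            split_fraction = 0.75,
                            n_boot = 500,
                            privacy_floor = 5L) {
  stopifnot(gwas_frac > 0, tune_frac > 0, gwas_frac + tune_frac < 1)
  cfg <- unclass(sim)
  cfg$pipeline <- list(
    gwas_frac = gwas_frac, tune_frac = tune_frac,
    p_grid = p_grid, window_grid = window_grid,
    bin_breaks = bin_breaks, pgs_percentile = pgs_percentile,
    split_fraction = split_fraction, n_boot = n_boot,
    privacy_floor = as.integer(privacy_floor)
  )
  structure(cfg, class = "pipeline_config")
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
}

eval_to_row <- function(ev) {
  data.frame(rule = ev$rule, tp = ev$tp, fp = ev$fp, tn = ev$tn, fn = ev$fn,
             sensitivity = ev$sensitivity, specificity = ev$specificity,
             sens_lo = ev$sensitivity_ci[1], sens_hi = ev$sensitivity_ci[2],
             spec_lo = ev$specificity_ci[1], spec_hi = ev$specificity_ci[2],
             stringsAsFactors = FALSE)
}

#' Run the full simulation-to-report pipeline
#'
#' Simulates the cohort, partitions it into disjoint association-scan,
#' tuning and assessment subsets, builds and selects the
#' clumping+thresholding score, scores every individual, and runs the
#' stratification, screening and regression analyses on the assessment
#' subset. Everything is written to `out_dir` as delimited text together
#' with a manifest (package version, configuration, per-stage seeds and
#' file checksums); re-running with the same configuration reproduces the
#' bundle bit for bit. When the configuration defines several ancestry
#' labels, the bin table and screening evaluations are additionally
#' emitted per label (a stratified replication of the main analyses).
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the cohort, weights, association table,
#'   per-bin tables, screening comparisons, model fits and the manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("run")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pl <- config$pipeline
  stage <- "simulate"
  res <- tryCatch({
    sim <- generate_cohort(structure(config, class = "sim_config"))
    cohort <- sim$cohort
    n <- nrow(cohort)

    stage <- "split"
    set.seed(substream_seed(config$seed, "split"))
    role <- sample(c("gwas", "tune", "assess"), n, replace = TRUE,
                   prob = c(pl$gwas_frac, pl$tune_frac,
                            1 - pl$gwas_frac - pl$tune_frac))
    i_gwas <- which(role == "gwas")
    i_tune <- which(role == "tune")
    i_assess <- which(role == "assess")

    stage <- "gwas"
    assoc <- run_gwas(sim$genotypes$offspring[i_gwas, , drop = FALSE],
                      cohort$t2d_status[i_gwas],
                      snp_info = sim$model)

    stage <- "build-score"
    cands <- build_candidates(assoc, pl$p_grid, pl$window_grid)
    weights <- tune_and_select(
      cands, sim$genotypes$offspring[i_tune, , drop = FALSE],
      cohort$t2d_status[i_tune],
      tune_ids = cohort$participant_id[i_tune],
      gwas_ids = cohort$participant_id[i_gwas],
      snp_info = sim$model
    )

    stage <- "score"
    scores <- compute_pgs(sim$genotypes$offspring, weights)
    cohort$pgs_raw <- scores$pgs_raw
    cohort$pgs_std <- scores$pgs_std

    assess <- cohort[i_assess, , drop = FALSE]

    stage <- "stratify"
    scheme <- bin_scheme(pl$bin_breaks)
    bins <- assign_bins(assess$pgs_std, scheme)
    bin_or <- bin_or_vs_total(bins, assess$t2d_status,
                              privacy_floor = pl$privacy_floor)
    is_case <- assess$t2d_status == "case"
    fh_by_bin <- summarize_by_bin(bins, assess$fh_t2d == "positive",
                                  "proportion", n_boot = pl$n_boot,
                                  seed = config$seed,
                                  privacy_floor = pl$privacy_floor)
    aod_by_bin <- summarize_by_bin(bins[is_case], assess$aod[is_case],
                                   "mean", n_boot = pl$n_boot,
                                   seed = config$seed,
                                   privacy_floor = pl$privacy_floor)
    prediab_by_bin <- summarize_by_bin(bins[!is_case],
                                       assess$prediabetes[!is_case] == "yes",
                                       "proportion", n_boot = pl$n_boot,
                                       seed = config$seed,
                                       privacy_floor = pl$privacy_floor)
    followed <- assess$incident_t2d %in% c("yes", "no")
    inc <- if (any(followed)) {
      incidence_rate(sum(assess$incident_t2d[followed] == "yes"),
                     assess$followup_days[followed])
    } else NULL

    stage <- "screen"
    screen_cmp <- list(
      uspstf = compare_rules(
        assess, build_rule("uspstf"),
        build_rule("uspstf", with_pgs = TRUE,
                   pgs_percentile = pl$pgs_percentile)),
      ada_simplified = compare_rules(
        assess, build_rule("ada_simplified"),
        build_rule("ada_simplified", with_pgs = TRUE,
                   pgs_percentile = pl$pgs_percentile))
    )

    stage <- "models"
    comparison <- compare_prevalence_models(
      assess, split_fraction = pl$split_fraction, seed = config$seed,
      n_boot = pl$n_boot)
    fh_fit <- fh_pgs_association(assess)
    aod_fit <- fit_aod_model(assess[is_case, , drop = FALSE])
    prediab_fit <- fit_prediabetes_model(assess[!is_case, , drop = FALSE])
    inc_fit <- tryCatch(fit_incidence_model(assess[!is_case, , drop = FALSE]),
                        error = function(e) NULL)
    severity <- fit_severity_models(assess[is_case, , drop = FALSE])

    headline <- c(
      list(family_history = fh_fit,
           prevalence_combined = comparison$fits$combined,
           prediabetes = prediab_fit),
      if (!is.null(inc_fit)) list(incidence = inc_fit),
      severity
    )
    sig <- significance_report(headline)

    stage <- "report"
    write_cohort(cohort, file.path(out_dir, "cohort.tsv"))
    write_weights(weights, file.path(out_dir, "weights.txt"))
    write_tsv(as.data.frame(assoc), file.path(out_dir, "assoc.tsv"))
    write_tsv(bin_or, file.path(out_dir, "bin_or.tsv"))
    write_tsv(fh_by_bin, file.path(out_dir, "fh_by_bin.tsv"))
    write_tsv(aod_by_bin, file.path(out_dir, "aod_by_bin.tsv"))
    write_tsv(prediab_by_bin, file.path(out_dir, "prediabetes_by_bin.tsv"))
    write_tsv(do.call(rbind, lapply(
      unlist(lapply(screen_cmp, function(cc) list(cc$base, cc$augmented)),
             recursive = FALSE), eval_to_row)),
      file.path(out_dir, "screening.tsv"))
    tab2 <- as.data.frame(comparison)
    write_tsv(cbind(term = rownames(tab2), tab2),
              file.path(out_dir, "model_comparison.tsv"))
    write_tsv(sig, file.path(out_dir, "significance.tsv"))
    if (!is.null(inc)) {
      write_tsv(data.frame(events = inc$events,
                           person_years = inc$person_years,
                           rate_per_1000py = inc$rate,
                           lo = inc$ci[1], hi = inc$ci[2]),
                file.path(out_dir, "incidence.tsv"))
    }
    write_config(config, file.path(out_dir, "config.yaml"))

    labels <- unique(assess$ancestry_label)
    if (length(labels) > 1) {
      for (lab in labels) {
        sub <- assess[assess$ancestry_label == lab, , drop = FALSE]
        if (sum(sub$t2d_status == "case") < pl$privacy_floor) next
        sub_bins <- assign_bins(sub$pgs_std, scheme)
        write_tsv(bin_or_vs_total(sub_bins, sub$t2d_status,
                                  privacy_floor = pl$privacy_floor),
                  file.path(out_dir, sprintf("bin_or_%s.tsv", lab)))
        cmp <- compare_rules(
          sub, build_rule("uspstf"),
          build_rule("uspstf", with_pgs = TRUE,
                     pgs_percentile = pl$pgs_percentile))
        write_tsv(rbind(eval_to_row(cmp$base), eval_to_row(cmp$augmented)),
                  file.path(out_dir, sprintf("screening_%s.tsv", lab)))
      }
    }

    files <- sort(setdiff(list.files(out_dir), "manifest.tsv"))
    manifest <- data.frame(
      file = files,
      md5 = unname(tools::md5sum(file.path(out_dir, files))),
      stringsAsFactors = FALSE
    )
    manifest <- rbind(
      data.frame(file = "__package_version__",
                 md5 = as.character(utils::packageVersion("pgscreen")),
                 stringsAsFactors = FALSE),
      data.frame(file = "__seed__", md5 = as.character(config$seed),
                 stringsAsFactors = FALSE),
      manifest
    )
    write_tsv(manifest, file.path(out_dir, "manifest.tsv"))

    list(cohort = cohort, weights = weights, assoc = assoc,
         subsets = list(gwas = i_gwas, tune = i_tune, assess = i_assess),
         bins = list(or = bin_or, fh = fh_by_bin, aod = aod_by_bin,
                     prediabetes = prediab_by_bin),
         incidence = inc, screening = screen_cmp,
         comparison = comparison,
         fits = list(fh = fh_fit, aod = aod_fit, prediabetes = prediab_fit,
                     incidence = inc_fit, severity = severity),
         significance = sig,
         filter_log = sim$filter_log,
         truth = sim$truth, model = sim$model,
         manifest = manifest, out_dir = out_dir)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(res)
}
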