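COHORT_REQUIRED <- c("participant_id", "age", "sex", "bmi", "fh_t2d",
                     "t2d_status")
COHORT_NUMERIC <- c("age", "bmi", "aod", "years_since_dx", "pgs_raw",
                    "pgs_std")
COHORT_INTEGER <- c("followup_days")
COHORT_LOGICAL <- c("trt_lifestyle", "trt_metformin", "trt_insulin",
                    "cmp_neuropathy", "cmp_nephropathy", "cmp_retinopathy")

#' Write / read a cohort table as tab-delimited text
#'
#' Tab-delimited with a header row; missing values are empty fields.
#' `read_cohort()` validates the required columns and their domains
#' (erroring with the offending rows listed), preserves unknown columns,
#' and can apply the standard exclusion filters with a logged tally
#' (attribute `"filter_log"`). Round-trips are lossless.
#'
#' @param cohort cohort data frame.
#' @param path file path.
#' @param apply_filters apply [apply_cohort_filters()] on read?
#' @return `read_cohort()` returns the cohort data frame.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path, apply_filters = FALSE) {
  x <- utils::read.delim(path, na.strings = "", stringsAsFactors = FALSE,
                         check.names = FALSE)
  missing_cols <- setdiff(COHORT_REQUIRED, names(x))
  if (length(missing_cols)) {
    stop("cohort file lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in intersect(COHORT_NUMERIC, names(x))) x[[col]] <- as.numeric(x[[col]])
  for (col in intersect(COHORT_INTEGER, names(x))) x[[col]] <- as.integer(x[[col]])
  for (col in intersect(COHORT_LOGICAL, names(x))) x[[col]] <- as.logical(x[[col]])

  bad <- list(
    sex = !is.na(x$sex) & !x$sex %in% c("female", "male"),
    t2d_status = !x$t2d_status %in% c("case", "control"),
    fh_t2d = !is.na(x$fh_t2d) & !x$fh_t2d %in% c("positive", "negative"),
    age = !is.finite(x$age),
    bmi = !is.finite(x$bmi)
  )
  if ("prediabetes" %in% names(x)) {
    bad$prediabetes <- !is.na(x$prediabetes) &
      !x$prediabetes %in% c("yes", "no")
  }
  if ("incident_t2d" %in% names(x)) {
    bad$incident_t2d <- !is.na(x$incident_t2d) &
      !x$incident_t2d %in% c("yes", "no", "not_followed")
  }
  offending <- lapply(bad, which)
  offending <- offending[vapply(offending, length, 0L) > 0L]
  if (length(offending)) {
    msg <- vapply(names(offending), function(nm) {
      sprintf("%s: row(s) %s", nm,
              paste(utils::head(offending[[nm]], 10), collapse = ", "))
    }, "")
    stop("out-of-domain values in cohort file\n  ",
         paste(msg, collapse = "\n  "), call. = FALSE)
  }
  if (apply_filters) x <- apply_cohort_filters(x)
  x
}

#' Write / read score weights in PGS Catalog scoring-file format
#'
#' Header lines start with `#`; key=value metadata lines carry the
#' standardization reference (`ref_mean`, `ref_sd`) and SNP count. The
#' column block has `rsID`, `effect_allele`, `effect_weight` and,
#' tolerated/preserved when present, `other_allele` and
#' `allele_frequency_effect`. Duplicate rsIDs are a schema error.
#' Round-trips (including the reference metadata) are lossless.
#'
#' @param weights a `score_weights` data frame.
#' @param path file path.
#' @return `read_weights()` returns a `score_weights` data frame.
#' @export
write_weights <- function(weights, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "### PGS scoring file",
    "#format_version=2.0",
    sprintf("#variants_number=%d", nrow(weights)),
    sprintf("#ref_mean=%.17g", attr(weights, "ref_mean") %||% NA_real_),
    sprintf("#ref_sd=%.17g", attr(weights, "ref_sd") %||% NA_real_)
  ), con)
  cols <- c("rsID" = "snp_id", "effect_allele" = "effect_allele",
            "other_allele" = "other_allele", "effect_weight" = "effect_weight",
            "allele_frequency_effect" = "allele_frequency_effect")
  cols <- cols[cols %in% names(weights)]
  tab <- weights[, cols, drop = FALSE]
  names(tab) <- names(cols)
  if ("effect_weight" %in% names(tab)) {
    tab$effect_weight <- sprintf("%.17g", tab$effect_weight)
  }
  if ("allele_frequency_effect" %in% names(tab)) {
    tab$allele_frequency_effect <- sprintf("%.17g", tab$allele_frequency_effect)
  }
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  meta_lines <- grep("^#[^#]*=", lines[hdr], value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- strsplit(sub("^#", "", ln), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) meta[[kv[1]]] <- kv[2]
  }
  body <- lines[!hdr]
  tab <- utils::read.delim(text = paste(body, collapse = "\n"),
                           stringsAsFactors = FALSE, na.strings = "")
  if (!"effect_weight" %in% names(tab)) {
    stop("scoring file lacks an effect_weight column", call. = FALSE)
  }
  if (!"rsID" %in% names(tab)) {
    stop("scoring file lacks an rsID column", call. = FALSE)
  }
  if (anyDuplicated(tab$rsID)) {
    stop("duplicate rsID in scoring file", call. = FALSE)
  }
  out <- data.frame(snp_id = tab$rsID, stringsAsFactors = FALSE)
  for (col in c("effect_allele", "other_allele")) {
    if (col %in% names(tab)) out[[col]] <- tab[[col]]
  }
  out$effect_weight <- as.numeric(tab$effect_weight)
  if ("allele_frequency_effect" %in% names(tab)) {
    out$allele_frequency_effect <- as.numeric(tab$allele_frequency_effect)
  }
  if (!is.null(meta$ref_mean) && !is.na(as.numeric(meta$ref_mean))) {
    attr(out, "ref_mean") <- as.numeric(meta$ref_mean)
  }
  if (!is.null(meta$ref_sd) && !is.na(as.numeric(meta$ref_sd))) {
    sd <- as.numeric(meta$ref_sd)
    if (sd <= 0) stop("reference SD must be positive", call. = FALSE)
    attr(out, "ref_sd") <- sd
  }
  class(out) <- c("score_weights", "data.frame")
  out
}

#' Write / read a genotype dosage matrix with SNP metadata
#'
#' Tab-delimited: metadata header lines (`##snp`, id/position/effect
#' allele/frequency) followed by an individuals x SNPs dosage block.
#'
#' @param dosages integer dosage matrix, SNP-id column names.
#' @param model matching [draw_score_model()] (metadata source).
#' @param path file path.
#' @return `read_dosages()` returns the dosage matrix (metadata in
#'   attribute `"snp_info"`).
#' @export
write_dosages <- function(dosages, model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("##snp\t%s\t%d\t%s\t%.17g", model$snp_id,
                     model$position, model$effect_allele,
                     model$allele_freq), con)
  utils::write.table(dosages, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_dosages
#' @export
read_dosages <- function(path) {
  lines <- readLines(path)
  meta <- grepl("^##snp\t", lines)
  info <- do.call(rbind, strsplit(sub("^##snp\t", "", lines[meta]), "\t"))
  snp_info <- data.frame(
    snp_id = info[, 1], position = as.integer(info[, 2]),
    effect_allele = info[, 3], allele_freq = as.numeric(info[, 4]),
    stringsAsFactors = FALSE
  )
  dos <- as.matrix(utils::read.delim(
    text = paste(lines[!meta], collapse = "\n"), check.names = FALSE))
  storage.mode(dos) <- "integer"
  attr(dos, "snp_info") <- snp_info
  dos
}

#' Serialize / read a run configuration (structured text)
#'
#' Configurations round-trip through YAML unchanged, including the
#' embedded phenotype parameter list.
#'
#' @param config a [sim_config()] or [pipeline_config()] list.
#' @param path file path.
#' @return `read_config()` returns the configuration list.
#' @export
write_config <- function(config, path) {
  # YAML keeps names for maps but not for atomic vectors
  yamlify <- function(x) {
    if (is.list(x)) lapply(x, yamlify)
    else if (!is.null(names(x))) as.list(x)
    else x
  }
  yaml::write_yaml(yamlify(unclass(config)), path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  cls <- if (!is.null(x$pipeline)) "pipeline_config" else "sim_config"
  if (!is.null(x$seed)) x$seed <- as.integer(x$seed)
  # YAML maps come back as lists; restore the named-vector fields
  vec_fields <- c("insulin", "metformin", "lifestyle", "neuropathy",
                  "nephropathy", "retinopathy", "ancestry")
  if (!is.null(x$pheno)) {
    for (f in intersect(vec_fields, names(x$pheno))) {
      x$pheno[[f]] <- unlist(x$pheno[[f]])
    }
  }
  structure(x, class = cls)
}
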