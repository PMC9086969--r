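#' Per-SNP logistic association scan
#'
#' Fits one maximum-likelihood logistic regression per SNP
#' (intercept + optional covariates + dosage) and reports the dosage
#' coefficient with its Wald standard error and p-value. Monomorphic SNPs
#' are returned with beta 0 and p 1, flagged `"monomorphic"`;
#' non-converging fits are flagged `"nonconverged"` rather than raising.
#'
#' @param dosages n x m dosage matrix, columns named by SNP id.
#' @param status binary case/control labels (0/1, logical, or
#'   `"case"`/`"control"`).
#' @param covariates optional numeric matrix/data frame of adjustment
#'   columns.
#' @param snp_info optional data frame with `snp_id` and `position`
#'   matching the dosage columns (defaults to column names with positions
#'   parsed from ids of the form `rs<position>`; otherwise column index).
#' @return An `assoc_table` data frame: `snp_id`, `position`, `beta_hat`,
#'   `se`, `p_value`, `flag`.
#' @export
run_gwas <- function(dosages, status, covariates = NULL, snp_info = NULL) {
  y <- as_status01(status)
  if (length(unique(y)) < 2L) {
    stop("need at least one case and one control", call. = FALSE)
  }
  stopifnot(nrow(dosages) == length(y))
  m <- ncol(dosages)
  if (is.null(snp_info)) {
    ids <- colnames(dosages)
    if (is.null(ids)) ids <- sprintf("snp%05d", seq_len(m))
    pos <- suppressWarnings(as.integer(sub("^rs", "", ids)))
    if (anyNA(pos)) pos <- seq_len(m)
    snp_info <- data.frame(snp_id = ids, position = pos,
                           stringsAsFactors = FALSE)
  }
  stopifnot(nrow(snp_info) == m)

  C <- if (is.null(covariates)) NULL else as.matrix(covariates)
  X <- cbind(`(Intercept)` = rep(1, length(y)), C, dosage = 0)
  k <- ncol(X)

  beta_hat <- numeric(m); se <- rep(NA_real_, m)
  p_value <- rep(1, m); flag <- character(m)
  for (j in seq_len(m)) {
    x <- dosages[, j]
    if (stats::var(x) == 0) {
      flag[j] <- "monomorphic"
      next
    }
    X[, k] <- x
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(X, y, family = stats::binomial())),
      error = function(e) NULL
    )
    ok <- !is.null(fit) && fit$converged && !fit$boundary
    if (!is.null(fit)) {
      b <- fit$coefficients[k]
      v <- tryCatch({
        XtWX <- crossprod(X * sqrt(fit$weights))
        diag(chol2inv(chol(XtWX)))[k]
      }, error = function(e) NA_real_)
      if (is.finite(b) && is.finite(v) && v > 0) {
        beta_hat[j] <- b
        se[j] <- sqrt(v)
        p_value[j] <- 2 * stats::pnorm(-abs(b / se[j]))
      } else {
        ok <- FALSE
      }
    }
    if (!ok) {
      flag[j] <- "nonconverged"
      p_value[j] <- 1
    }
  }
  out <- data.frame(snp_id = snp_info$snp_id, position = snp_info$position,
                    beta_hat = beta_hat, se = se, p_value = p_value,
                    flag = flag, stringsAsFactors = FALSE)
  class(out) <- c("assoc_table", "data.frame")
  out
}

#' Inverse-variance-weighted meta-analysis of association scans
#'
#' Combines per-stratum association tables (e.g. ancestry strata) by
#' fixed-effect inverse-variance weighting of the per-SNP estimates.
#' Flagged rows contribute no information in their stratum.
#'
#' @param assoc_list list of [run_gwas()] tables over the same SNPs.
#' @return An `assoc_table` with the combined estimates.
#' @export
meta_analyze <- function(assoc_list) {
  stopifnot(length(assoc_list) >= 1)
  ids <- assoc_list[[1]]$snp_id
  for (a in assoc_list) stopifnot(identical(a$snp_id, ids))
  w_sum <- b_sum <- numeric(length(ids))
  for (a in assoc_list) {
    usable <- a$flag == "" & is.finite(a$se) & a$se > 0
    w <- ifelse(usable, 1 / a$se^2, 0)
    w_sum <- w_sum + w
    b_sum <- b_sum + w * ifelse(usable, a$beta_hat, 0)
  }
  beta <- ifelse(w_sum > 0, b_sum / w_sum, 0)
  se <- ifelse(w_sum > 0, sqrt(1 / w_sum), NA_real_)
  p <- ifelse(w_sum > 0, 2 * stats::pnorm(-abs(beta / se)), 1)
  out <- data.frame(snp_id = ids, position = assoc_list[[1]]$position,
                    beta_hat = beta, se = se, p_value = p,
                    flag = ifelse(w_sum > 0, "", "monomorphic"),
                    stringsAsFactors = FALSE)
  class(out) <- c("assoc_table", "data.frame")
  out
}

#' Greedy distance-window clumping
#'
#' Keeps SNPs with `p_value <= p_threshold`, visits them in order of
#' ascending p-value (ties by position, then id), and accepts a SNP iff no
#' previously accepted SNP lies within `window` base pairs. Deterministic.
#'
#' @param assoc an [run_gwas()] table.
#' @param p_threshold p-value cutoff.
#' @param window exclusion half-width in base pairs (`>= 0`).
#' @return Character vector of retained SNP ids, in acceptance order.
#' @export
clump <- function(assoc, p_threshold, window) {
  stopifnot(window >= 0, p_threshold > 0)
  cand <- assoc[assoc$p_value <= p_threshold & assoc$flag == "", , drop = FALSE]
  if (nrow(cand) == 0L) return(character(0))
  cand <- cand[order(cand$p_value, cand$position, cand$snp_id), , drop = FALSE]
  kept_pos <- numeric(0)
  kept_id <- character(0)
  for (i in seq_len(nrow(cand))) {
    pos <- cand$position[i]
    if (length(kept_pos) == 0L || all(abs(pos - kept_pos) > window)) {
      kept_pos <- c(kept_pos, pos)
      kept_id <- c(kept_id, cand$snp_id[i])
    }
  }
  kept_id
}

#' Build the candidate grid for clumping + thresholding
#'
#' One candidate variant set per (p-threshold, window) pair; weights are
#' the association-scan log-odds of the retained SNPs. The default 3 x 3
#' grid yields nine variant sets.
#'
#' @param assoc an [run_gwas()] table.
#' @param p_grid p-value thresholds.
#' @param window_grid window half-widths in base pairs.
#' @return A `ct_candidates` list: per-candidate `p_threshold`, `window`,
#'   `snp_ids`; the association table is carried along for scoring.
#' @export
build_candidates <- function(assoc,
                             p_grid = c(1e-2, 1e-4, 1e-6),
                             window_grid = c(5e4, 2.5e5, 5e5)) {
  stopifnot(length(p_grid) >= 1, length(window_grid) >= 1)
  grid <- expand.grid(p_threshold = p_grid, window = window_grid,
                      KEEP.OUT.ATTRS = FALSE)
  cands <- lapply(seq_len(nrow(grid)), function(i) {
    ids <- clump(assoc, grid$p_threshold[i], grid$window[i])
    list(p_threshold = grid$p_threshold[i], window = grid$window[i],
         snp_ids = ids, n_snps = length(ids))
  })
  structure(list(candidates = cands, assoc = assoc), class = "ct_candidates")
}

candidate_weights <- function(assoc, snp_ids, model_info = NULL) {
  rows <- assoc[match(snp_ids, assoc$snp_id), , drop = FALSE]
  data.frame(snp_id = rows$snp_id, effect_weight = rows$beta_hat,
             stringsAsFactors = FALSE)
}

#' Mann-Whitney AUC
#'
#' Concordance probability that a random case outscores a random control;
#' ties count one half.
#'
#' @param scores numeric vector.
#' @param labels binary labels.
#' @return AUC in `[0, 1]`.
#' @export
auc_mw <- function(scores, labels) {
  y <- as_status01(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L) {
    stop("both classes must be present to compute AUC", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' AUC with percentile-bootstrap confidence interval
#'
#' @param scores numeric vector.
#' @param labels binary labels.
#' @param n_boot bootstrap replicates (resampling individuals).
#' @param seed integer seed.
#' @param conf confidence level.
#' @return List with `auc`, `ci` (length 2) and `n_boot`.
#' @export
auc_with_ci <- function(scores, labels, n_boot = 2000, seed = 1L,
                        conf = 0.95) {
  y <- as_status01(labels)
  est <- auc_mw(scores, y)
  set.seed(substream_seed(seed, "boot"))
  n <- length(y)
  reps <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    yb <- y[idx]
    if (any(yb == 1) && any(yb == 0)) reps[b] <- auc_mw(scores[idx], yb)
  }
  alpha <- (1 - conf) / 2
  ci <- stats::quantile(reps, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
  list(auc = est, ci = ci, n_boot = n_boot)
}

#' Compute polygenic scores from a weight set
#'
#' Raw score is the weighted sum of effect-allele dosages; weight SNPs
#' absent from the dosage matrix are mean-imputed as `2 x allele frequency`
#' (requires an `allele_frequency_effect` column) up to a configurable
#' missingness cap. Standardized scores use the reference mean/SD stored
#' on the weights (attributes `ref_mean`, `ref_sd`); without a reference
#' the score is standardized in-sample with a warning.
#'
#' @param dosages n x m dosage matrix with SNP-id column names.
#' @param weights a `score_weights` data frame (see [tune_and_select()] or
#'   [read_weights()]).
#' @param max_missing maximum tolerated fraction of absent weight SNPs.
#' @return Data frame with `pgs_raw` and `pgs_std`.
#' @export
compute_pgs <- function(dosages, weights, max_missing = 0.2) {
  stopifnot(!anyDuplicated(weights$snp_id))
  idx <- match(weights$snp_id, colnames(dosages))
  miss <- is.na(idx)
  if (mean(miss) > max_missing) {
    stop(sprintf("%.1f%% of weight SNPs absent from dosages (cap %.1f%%)",
                 100 * mean(miss), 100 * max_missing), call. = FALSE)
  }
  raw <- drop(dosages[, idx[!miss], drop = FALSE] %*%
                weights$effect_weight[!miss])
  if (any(miss)) {
    freq <- weights$allele_frequency_effect
    if (is.null(freq) || anyNA(freq[miss])) {
      stop("missing weight SNPs require allele_frequency_effect for imputation",
           call. = FALSE)
    }
    raw <- raw + sum(weights$effect_weight[miss] * 2 * freq[miss])
  }
  ref_mean <- attr(weights, "ref_mean")
  ref_sd <- attr(weights, "ref_sd")
  if (is.null(ref_mean) || is.null(ref_sd)) {
    warning("weights carry no reference mean/SD; standardizing in-sample")
    ref_mean <- mean(raw); ref_sd <- stats::sd(raw)
  }
  if (!is.finite(ref_sd) || ref_sd <= 0) {
    stop("reference SD must be positive", call. = FALSE)
  }
  data.frame(pgs_raw = raw, pgs_std = (raw - ref_mean) / ref_sd)
}

#' Select the best candidate score on a tuning set
#'
#' Scores every non-empty candidate on the tuning individuals (who must be
#' disjoint from the association-scan individuals when ids are supplied),
#' ranks by tuning AUC against case/control status, and returns the winner
#' as a `score_weights` object whose standardization reference is the
#' tuning-set raw-score mean/SD. Ties break toward fewer SNPs, then the
#' smaller p-threshold, then the smaller window.
#'
#' @param candidates a [build_candidates()] object.
#' @param tune_dosages dosage matrix for the tuning individuals.
#' @param tune_status their case/control labels.
#' @param tune_ids,gwas_ids optional participant ids used to enforce
#'   disjointness between scan and tuning sets.
#' @param snp_info optional data frame with `snp_id`, `effect_allele`,
#'   `other_allele`, `allele_freq` (e.g. a [draw_score_model()]) used to
#'   annotate the weights.
#' @return A `score_weights` data frame (`snp_id`, `effect_allele`,
#'   `other_allele`, `effect_weight`, `allele_frequency_effect`) with
#'   attributes `ref_mean`, `ref_sd` and a `selection` grid holding every
#'   candidate's tuning AUC.
#' @export
tune_and_select <- function(candidates, tune_dosages, tune_status,
                            tune_ids = NULL, gwas_ids = NULL,
                            snp_info = NULL) {
  stopifnot(inherits(candidates, "ct_candidates"))
  if (!is.null(tune_ids) && !is.null(gwas_ids) &&
      length(intersect(tune_ids, gwas_ids)) > 0) {
    stop("tuning individuals overlap the association-scan set", call. = FALSE)
  }
  y <- as_status01(tune_status)
  cands <- candidates$candidates
  aucs <- rep(NA_real_, length(cands))
  raw_scores <- vector("list", length(cands))
  for (i in seq_along(cands)) {
    if (cands[[i]]$n_snps == 0L) next
    w <- candidate_weights(candidates$assoc, cands[[i]]$snp_ids)
    idx <- match(w$snp_id, colnames(tune_dosages))
    raw <- drop(tune_dosages[, idx, drop = FALSE] %*% w$effect_weight)
    raw_scores[[i]] <- raw
    aucs[i] <- auc_mw(raw, y)
  }
  if (all(is.na(aucs))) {
    stop("every candidate retained an empty SNP set", call. = FALSE)
  }
  grid <- data.frame(
    p_threshold = vapply(cands, `[[`, 0, "p_threshold"),
    window = vapply(cands, `[[`, 0, "window"),
    n_snps = vapply(cands, `[[`, 0L, "n_snps"),
    tuning_auc = aucs
  )
  ord <- order(-grid$tuning_auc, grid$n_snps, grid$p_threshold, grid$window,
               na.last = TRUE)
  best <- ord[1]

  w <- candidate_weights(candidates$assoc, cands[[best]]$snp_ids)
  if (!is.null(snp_info)) {
    rows <- snp_info[match(w$snp_id, snp_info$snp_id), , drop = FALSE]
    w$effect_allele <- rows$effect_allele
    w$other_allele <- rows$other_allele
    w$allele_frequency_effect <- rows$allele_freq
  } else {
    w$effect_allele <- "A"
    w$other_allele <- "G"
    w$allele_frequency_effect <- NA_real_
  }
  w <- w[, c("snp_id", "effect_allele", "other_allele", "effect_weight",
             "allele_frequency_effect")]
  raw <- raw_scores[[best]]
  attr(w, "ref_mean") <- mean(raw)
  attr(w, "ref_sd") <- stats::sd(raw)
  attr(w, "selection") <- grid
  attr(w, "selected") <- grid[best, , drop = FALSE]
  class(w) <- c("score_weights", "data.frame")
  w
}
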