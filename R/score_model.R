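#' Draw a generative polygenic score model
#'
#' Samples a set of biallelic SNPs (positions on one synthetic chromosome,
#' effect-allele frequencies, liability-scale effects) and scales the causal
#' effects so that the aggregate genetic term
#' \eqn{G = \sum_j \beta_j (x_j - 2p_j)} has variance `h2_snp` under
#' Hardy-Weinberg dosages. This is the ground truth against which score
#' construction and model fits are later checked.
#'
#' SNP heritability `h2_snp` and the family-shared environment fraction
#' `c2_shared` partition the unit-variance liability; the remainder is
#' independent environmental noise.
#'
#' @param m_snps number of SNPs.
#' @param n_causal number of SNPs with nonzero effect. May be 0 only when
#'   `h2_snp` is 0.
#' @param h2_snp fraction of liability variance explained by the modelled
#'   SNPs, in `[0, 1)`.
#' @param c2_shared fraction of liability variance shared within a family,
#'   in `[0, 1)`. `h2_snp + c2_shared` must be < 1.
#' @param maf_range length-2 interval for effect-allele frequencies.
#' @param genome_length length in base pairs of the synthetic chromosome on
#'   which positions are drawn (uniform, without replacement).
#' @param seed integer seed.
#' @return A `score_model` data frame with columns `snp_id`, `position`,
#'   `effect_allele`, `other_allele`, `allele_freq`, `true_beta`, and
#'   attributes `h2_snp`, `c2_shared`.
#' @examples
#' m <- draw_score_model(200, 20, h2_snp = 0.3, c2_shared = 0.1, seed = 1)
#' sum(m$true_beta != 0)
#' @export
draw_score_model <- function(m_snps, n_causal, h2_snp, c2_shared = 0,
                             maf_range = c(0.05, 0.5),
                             genome_length = 1e8, seed = 1L) {
  stopifnot(m_snps >= 1, n_causal >= 0, n_causal <= m_snps)
  if (h2_snp < 0 || c2_shared < 0 || h2_snp + c2_shared >= 1) {
    stop("variance fractions must satisfy 0 <= h2_snp + c2_shared < 1",
         call. = FALSE)
  }
  if (h2_snp > 0 && n_causal == 0) {
    stop("n_causal must be positive when h2_snp > 0", call. = FALSE)
  }
  stopifnot(length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2], genome_length >= m_snps)

  set.seed(substream_seed(seed, "model"))
  position <- sort(sample.int(genome_length, m_snps))
  allele_freq <- stats::runif(m_snps, maf_range[1], maf_range[2])
  alleles <- c("A", "C", "G", "T")
  effect_allele <- sample(alleles, m_snps, replace = TRUE)
  other_allele <- vapply(effect_allele,
                         function(a) sample(setdiff(alleles, a), 1L), "")

  true_beta <- numeric(m_snps)
  if (n_causal > 0 && h2_snp > 0) {
    causal <- sample.int(m_snps, n_causal)
    b <- stats::rnorm(n_causal)
    p <- allele_freq[causal]
    v_raw <- sum(2 * p * (1 - p) * b^2)
    true_beta[causal] <- b * sqrt(h2_snp / v_raw)
  }

  out <- data.frame(
    snp_id = sprintf("rs%09d", position),
    position = position,
    effect_allele = effect_allele,
    other_allele = unname(other_allele),
    allele_freq = allele_freq,
    true_beta = true_beta,
    stringsAsFactors = FALSE
  )
  attr(out, "h2_snp") <- h2_snp
  attr(out, "c2_shared") <- c2_shared
  class(out) <- c("score_model", "data.frame")
  out
}

#' Simulate parent-offspring trios under Mendelian transmission
#'
#' Parental dosages are binomial in the effect-allele frequency; each
#' offspring receives one allele per parent, drawn Bernoulli with
#' probability `dosage/2`. A homozygous parent therefore transmits its
#' allele deterministically and offspring dosages stay in `{0, 1, 2}`.
#'
#' @param n number of families (one offspring each).
#' @param model a [draw_score_model()] object.
#' @param seed integer seed.
#' @return A `genotype_set` list with integer matrices `offspring`,
#'   `mother`, `father` (n x m, columns named by `snp_id`).
#' @export
simulate_families <- function(n, model, seed = 1L) {
  stopifnot(n >= 1, inherits(model, "score_model"))
  set.seed(substream_seed(seed, "families"))
  m <- nrow(model)
  p <- model$allele_freq
  mk <- function() matrix(0L, n, m, dimnames = list(NULL, model$snp_id))
  mother <- mk(); father <- mk(); offspring <- mk()
  # column blocks keep peak memory flat for large n x m
  blocks <- split(seq_len(m), ceiling(seq_len(m) / 200L))
  for (idx in blocks) {
    pj <- rep(p[idx], each = n)
    nm <- n * length(idx)
    mo <- matrix(as.integer(stats::rbinom(nm, 2L, pj)), n)
    fa <- matrix(as.integer(stats::rbinom(nm, 2L, pj)), n)
    of <- matrix(
      as.integer(stats::rbinom(nm, 1L, mo / 2) + stats::rbinom(nm, 1L, fa / 2)),
      n
    )
    mother[, idx] <- mo; father[, idx] <- fa; offspring[, idx] <- of
  }
  structure(list(offspring = offspring, mother = mother, father = father),
            class = "genotype_set")
}

#' Centred true genetic score
#'
#' Computes \eqn{G = \sum_j \beta_j (x_j - 2 p_j)} from a dosage matrix and
#' a score model; by construction `var(G)` approaches `h2_snp`.
#'
#' @param dosages n x m dosage matrix with columns matching `model$snp_id`.
#' @param model a [draw_score_model()] object.
#' @return Numeric vector of length n.
#' @export
true_score <- function(dosages, model) {
  stopifnot(identical(colnames(dosages), model$snp_id))
  drop(dosages %*% model$true_beta) - sum(2 * model$allele_freq * model$true_beta)
}
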