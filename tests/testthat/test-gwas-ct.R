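test_that("association scan flags monomorphic SNPs and matches the allelic OR", {
  # haploid-expanded 2x2 table: cases 30/170, controls 10/190 effect alleles
  dos <- cbind(rs1 = c(rep(1, 30), rep(0, 170), rep(1, 10), rep(0, 190)),
               rs2 = rep(1, 400))
  status <- c(rep(1, 200), rep(0, 200))
  a <- run_gwas(dos, status)
  expect_equal(a$flag, c("", "monomorphic"))
  expect_equal(a$beta_hat[2], 0)
  expect_equal(a$p_value[2], 1)
  expect_equal(a$beta_hat[1], log((30 * 190) / (170 * 10)), tolerance = 1e-3)
})

test_that("scan coefficients agree with an independent IRLS oracle", {
  set.seed(31)
  for (rep in 1:5) {
    n <- 400
    dos <- cbind(s1 = rbinom(n, 2, 0.3), s2 = rbinom(n, 2, 0.1))
    cov <- cbind(z = rnorm(n))
    y <- rbinom(n, 1, plogis(-1 + 0.5 * dos[, 1] + 0.3 * cov[, 1]))
    a <- run_gwas(dos, y, covariates = cov)
    for (j in 1:2) {
      b <- irls_logistic(cbind(1, cov, dos[, j]), y)
      expect_equal(a$beta_hat[j], b[3], tolerance = 1e-6)
    }
  }
})

test_that("null scan p-values are uniform (type-I calibration)", {
  set.seed(55)
  n <- 300; m <- 2000
  dos <- matrix(rbinom(n * m, 2, 0.3), n, m)
  y <- rbinom(n, 1, 0.3)  # labels independent of every SNP
  a <- run_gwas(dos, y)
  expect_equal(mean(a$p_value < 0.05), 0.05, tolerance = 0.01 / 0.05)
})

test_that("clumping reproduces the worked example and edge cases", {
  assoc <- data.frame(
    snp_id = c("a", "b", "c", "d", "e"),
    position = c(100, 150, 300, 320, 900),
    beta_hat = 1, se = 1,
    p_value = c(.001, .0001, .01, .002, .03),
    flag = "", stringsAsFactors = FALSE
  )
  # by ascending p: 150 (p=1e-4) excludes 100; 320 (p=.002) is accepted
  # next and excludes 300; 900 stands alone
  expect_setequal(clump(assoc, 0.05, 100), c("b", "d", "e"))
  expect_setequal(clump(assoc, 0.05, 100), oracle_clump(assoc, 0.05, 100))
  expect_equal(clump(assoc, 1e-6, 100), character(0))
  expect_setequal(clump(assoc, 0.05, 0), assoc$snp_id)
})

test_that("candidate grids have one entry per pair and nest in p-threshold", {
  set.seed(7)
  assoc <- data.frame(
    snp_id = sprintf("s%03d", 1:60),
    position = sort(sample.int(5000, 60)),
    beta_hat = rnorm(60), se = 1,
    p_value = runif(60)^2, flag = "",
    stringsAsFactors = FALSE
  )
  cands <- build_candidates(assoc, p_grid = c(0.01, 0.1, 0.5),
                            window_grid = c(50, 200, 500))
  expect_length(cands$candidates, 9)
  one <- build_candidates(assoc, p_grid = 0.1, window_grid = 200)
  expect_identical(one$candidates[[1]]$snp_ids, clump(assoc, 0.1, 200))
  for (w in c(0, 50, 200, 500)) {
    narrow <- clump(assoc, 0.05, w)
    wide <- clump(assoc, 0.5, w)
    expect_true(all(narrow %in% wide))
  }
})

test_that("scores are weighted dosage sums with reference standardization", {
  w <- data.frame(snp_id = c("s1", "s2", "s3"),
                  effect_weight = c(0.1, -0.2, 0.3),
                  stringsAsFactors = FALSE)
  attr(w, "ref_mean") <- 0; attr(w, "ref_sd") <- 1
  dos <- matrix(c(0, 1, 2), 1, dimnames = list(NULL, c("s1", "s2", "s3")))
  expect_equal(compute_pgs(dos, w)$pgs_raw, 0.4)

  w0 <- w; w0$effect_weight <- 0
  attr(w0, "ref_mean") <- 0; attr(w0, "ref_sd") <- 1
  dos2 <- matrix(rbinom(30, 2, 0.4), 10, 3,
                 dimnames = list(NULL, c("s1", "s2", "s3")))
  expect_true(all(compute_pgs(dos2, w0)$pgs_raw == 0))

  # self-referential standardization gives mean 0 / SD 1
  set.seed(8)
  dos3 <- matrix(rbinom(300, 2, 0.4), 100, 3,
                 dimnames = list(NULL, c("s1", "s2", "s3")))
  raw <- drop(dos3 %*% w$effect_weight)
  attr(w, "ref_mean") <- mean(raw); attr(w, "ref_sd") <- sd(raw)
  std <- compute_pgs(dos3, w)$pgs_std
  expect_equal(mean(std), 0, tolerance = 1e-12)
  expect_equal(sd(std), 1, tolerance = 1e-12)

  # absent SNPs are imputed from the effect-allele frequency, capped
  w$allele_frequency_effect <- c(0.2, 0.3, 0.4)
  dos4 <- dos3[, 1:2]
  expect_error(compute_pgs(dos4, w, max_missing = 0.2), "absent")
  sc <- compute_pgs(dos4, w, max_missing = 0.5)
  expect_equal(sc$pgs_raw,
               drop(dos4 %*% w$effect_weight[1:2]) + 0.3 * 2 * 0.4)
})

test_that("AUC matches brute-force pair counting and handles ties", {
  expect_equal(auc_mw(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1.0)
  expect_equal(auc_mw(c(1, 3, 2, 4), c(0, 0, 1, 1)), 0.75)
  expect_equal(auc_mw(rep(1, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(auc_mw(1:4, c(1, 1, 1, 1)), "both classes")
  set.seed(12)
  for (i in 1:20) {
    n <- sample(10:200, 1)
    s <- round(rnorm(n), 1)
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    expect_equal(auc_mw(s, y), brute_auc(s, y))
  }
})

test_that("bootstrap AUC interval covers the point estimate and is seeded", {
  set.seed(3)
  s <- rnorm(200); y <- rbinom(200, 1, plogis(s))
  a1 <- auc_with_ci(s, y, n_boot = 200, seed = 5)
  a2 <- auc_with_ci(s, y, n_boot = 200, seed = 5)
  expect_identical(a1, a2)
  expect_lte(a1$ci[1], a1$auc)
  expect_gte(a1$ci[2], a1$auc)
})

test_that("tuning selection is an argmax with deterministic tie-breaks", {
  set.seed(21)
  assoc <- data.frame(
    snp_id = sprintf("s%02d", 1:20),
    position = seq(100, 2000, by = 100),
    beta_hat = rnorm(20, 0, 0.3), se = 1,
    p_value = runif(20), flag = "",
    stringsAsFactors = FALSE
  )
  dos <- matrix(rbinom(200 * 20, 2, 0.3), 200, 20,
                dimnames = list(NULL, assoc$snp_id))
  y <- rbinom(200, 1, 0.3)
  one <- build_candidates(assoc, p_grid = 0.8, window_grid = 0)
  w <- tune_and_select(one, dos, y)
  expect_setequal(w$snp_id, clump(assoc, 0.8, 0))

  grid <- build_candidates(assoc, p_grid = c(0.2, 0.8), window_grid = c(0, 500))
  w2 <- tune_and_select(grid, dos, y)
  sel <- attr(w2, "selection")
  expect_equal(max(sel$tuning_auc, na.rm = TRUE),
               attr(w2, "selected")$tuning_auc)
  expect_error(
    tune_and_select(one, dos, y, tune_ids = c("a", "b"), gwas_ids = c("b")),
    "overlap")
})

test_that("selected score separates cases when heritable, not under the null", {
  # heritable scenario: selected score lands between chance and the
  # true-score oracle on held-out data
  cfg <- sim_config(n = 16000, m_snps = 400, n_causal = 80,
                    h2_snp = 0.3, c2_shared = 0.1, seed = 301)
  sim <- generate_cohort(cfg)
  n <- nrow(sim$cohort)
  set.seed(1)
  role <- sample(c("gwas", "tune", "test"), n, TRUE, prob = c(.45, .15, .4))
  ig <- role == "gwas"; it <- role == "tune"; ih <- role == "test"
  assoc <- run_gwas(sim$genotypes$offspring[ig, ], sim$cohort$t2d_status[ig],
                    snp_info = sim$model)
  cands <- build_candidates(assoc)
  w <- tune_and_select(cands, sim$genotypes$offspring[it, ],
                       sim$cohort$t2d_status[it], snp_info = sim$model)
  sc <- compute_pgs(sim$genotypes$offspring[ih, ], w)
  auc_sel <- auc_mw(sc$pgs_std, sim$cohort$t2d_status[ih])
  auc_oracle <- auc_mw(true_score(sim$genotypes$offspring[ih, ], sim$model),
                       sim$cohort$t2d_status[ih])
  expect_gt(auc_sel, 0.52)
  expect_lt(auc_sel, auc_oracle + 0.01)
  expect_lt(auc_oracle - auc_sel, 0.1)
})
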