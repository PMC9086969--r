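# Independent oracles used to cross-check package computations.

# Logistic regression by hand-written iteratively reweighted least squares.
irls_logistic <- function(X, y, tol = 1e-12, max_iter = 100) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    beta_new <- solve(crossprod(X, w * X), crossprod(X, w * z))
    if (max(abs(beta_new - beta)) < tol) {
      return(unname(drop(beta_new)))
    }
    beta <- drop(beta_new)
  }
  unname(drop(beta))
}

# AUC by brute-force all-pairs counting (ties count one half).
brute_auc <- function(scores, labels) {
  s1 <- scores[labels == 1]
  s0 <- scores[labels == 0]
  cmp <- outer(s1, s0, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Clumping by iterative removal: repeatedly take the best remaining row
# and delete everything within the window (different mechanics from the
# accept-if-far greedy in the package).
oracle_clump <- function(assoc, p_thr, window) {
  cand <- assoc[assoc$p_value <= p_thr & assoc$flag == "", , drop = FALSE]
  cand <- cand[order(cand$p_value, cand$position, cand$snp_id), , drop = FALSE]
  kept <- character(0)
  while (nrow(cand) > 0) {
    top <- cand[1, , drop = FALSE]
    kept <- c(kept, top$snp_id)
    cand <- cand[abs(cand$position - top$position) > window, , drop = FALSE]
  }
  kept
}

# Row-by-row screening-rule application written against the rule text,
# independent of the package's vectorised evaluator.
oracle_screen_row <- function(rule, age, bmi, fh_pos, pct) {
  for (cr in rule$criteria) {
    ok <- age >= cr$age_min && age <= cr$age_max &&
      bmi >= cr$bmi_min && bmi < cr$bmi_max
    if (isTRUE(cr$fh)) ok <- ok && isTRUE(fh_pos)
    if (!is.na(cr$pgs_min_pct)) ok <- ok && pct >= cr$pgs_min_pct
    if (ok) return(TRUE)
  }
  FALSE
}

# Random small cohort for screening fuzz tests.
random_cohort <- function(n, seed) {
  set.seed(seed)
  status <- sample(c("case", "control"), n, replace = TRUE, prob = c(.3, .7))
  age <- runif(n, 20, 79)
  data.frame(
    participant_id = sprintf("F%04d", seq_len(n)),
    age = age,
    sex = sample(c("female", "male"), n, replace = TRUE),
    bmi = runif(n, 18.5, 45),
    fh_t2d = sample(c("positive", "negative"), n, replace = TRUE),
    t2d_status = status,
    aod = ifelse(status == "case", pmin(runif(n, 20, 79), age), NA),
    pgs_std = rnorm(n),
    stringsAsFactors = FALSE
  )
}
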