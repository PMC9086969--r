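hand_cohort <- function() {
  # six-row worked cohort: three cases (evaluated at age of diagnosis)
  # and three controls (evaluated at current age), with fixed percentiles
  data.frame(
    participant_id = paste0("H", 1:6),
    age = c(55, 45, 74, 50, 36, 25),
    sex = rep("female", 6),
    bmi = c(30, 22, 28, 24, 31, 22),
    fh_t2d = rep("negative", 6),
    t2d_status = c("case", "case", "case", "control", "control", "control"),
    aod = c(40, 30, 72, NA, NA, NA),
    pgs_std = rnorm(6),
    pgs_pct = c(60, 95, 70, 50, 40, 30),
    stringsAsFactors = FALSE
  )
}

test_that("guideline rules encode their criteria", {
  u <- build_rule("uspstf")
  # age 40, BMI 27 -> screen; age 40, BMI 22 -> no, unless PGS disjunct
  expect_true(pgscreen:::apply_rule(u, 40, 27, FALSE, 50))
  expect_false(pgscreen:::apply_rule(u, 40, 22, FALSE, 95))
  expect_false(pgscreen:::apply_rule(u, 72, 28, FALSE, 95))
  up <- build_rule("uspstf", with_pgs = TRUE)
  expect_true(pgscreen:::apply_rule(up, 40, 22, FALSE, 95))
  expect_false(pgscreen:::apply_rule(up, 30, 22, FALSE, 95))
  expect_true(pgscreen:::apply_rule(up, 80, 22, FALSE, 95))  # no upper bound

  a <- build_rule("ada_simplified")
  expect_true(pgscreen:::apply_rule(a, 46, 20, FALSE, 10))
  expect_true(pgscreen:::apply_rule(a, 30, 27, TRUE, 10))
  expect_false(pgscreen:::apply_rule(a, 30, 27, FALSE, 10))
  ap <- build_rule("ada_simplified", with_pgs = TRUE)
  expect_true(pgscreen:::apply_rule(ap, 19, 22, FALSE, 95))

  expect_error(build_rule("who"), "arg")
})

test_that("hand cohort evaluation reproduces brute-force confusion counts", {
  co <- hand_cohort()
  for (rule in list(build_rule("uspstf"),
                    build_rule("uspstf", with_pgs = TRUE),
                    build_rule("ada_simplified"),
                    build_rule("ada_simplified", with_pgs = TRUE))) {
    ev <- evaluate_rule(co, rule)
    is_case <- co$t2d_status == "case"
    screened <- vapply(seq_len(nrow(co)), function(i) {
      oracle_screen_row(rule, if (is_case[i]) co$aod[i] else co$age[i],
                        co$bmi[i], co$fh_t2d[i] == "positive", co$pgs_pct[i])
    }, TRUE)
    expect_equal(ev$tp, sum(screened & is_case))
    expect_equal(ev$fp, sum(screened & !is_case))
    expect_equal(ev$tn, sum(!screened & !is_case))
    expect_equal(ev$fn, sum(!screened & is_case))
  }

  # frozen counts for the base USPSTF rule: only the aod-40/BMI-30 case and
  # the age-36/BMI-31 control are screened
  ev_u <- evaluate_rule(co, build_rule("uspstf"))
  expect_equal(c(ev_u$tp, ev_u$fp, ev_u$tn, ev_u$fn), c(1, 1, 2, 2))
  expect_equal(ev_u$sensitivity, 1 / 3)
  expect_equal(ev_u$specificity, 2 / 3)

  # the aod-30/BMI-22/pct-95 case fails the USPSTF augmentation's age-35
  # floor but does screen under the ADA augmentation (age >= 18)
  ev_up <- evaluate_rule(co, build_rule("uspstf", with_pgs = TRUE))
  expect_equal(ev_up$sensitivity, 1 / 3)
  ev_a <- evaluate_rule(co, build_rule("ada_simplified"))
  ev_ap <- evaluate_rule(co, build_rule("ada_simplified", with_pgs = TRUE))
  expect_equal(ev_a$sensitivity, 1 / 3)
  expect_equal(ev_ap$sensitivity, 2 / 3)
  expect_equal(ev_ap$specificity, ev_a$specificity)
})

test_that("all/none rules hit the trivial operating points", {
  co <- random_cohort(300, seed = 1)
  everyone <- screening_rule("all", list(list()))
  noone <- screening_rule("none", list())
  ev_all <- evaluate_rule(co, everyone)
  ev_none <- evaluate_rule(co, noone)
  expect_equal(c(ev_all$sensitivity, ev_all$specificity), c(1, 0))
  expect_equal(c(ev_none$sensitivity, ev_none$specificity), c(0, 1))
})

test_that("evaluation is pure, partitions the cohort, excludes aod-less cases", {
  co <- random_cohort(400, seed = 2)
  co$aod[co$t2d_status == "case"][1:3] <- NA
  rule <- build_rule("uspstf", with_pgs = TRUE)
  e1 <- evaluate_rule(co, rule)
  e2 <- evaluate_rule(co, rule)
  expect_identical(e1, e2)
  expect_equal(e1$n_excluded, 3)
  expect_equal(e1$tp + e1$fp + e1$tn + e1$fn, nrow(co) - 3)
  expect_true(e1$sensitivity_ci[1] <= e1$sensitivity &&
                e1$sensitivity <= e1$sensitivity_ci[2])
})

test_that("superset rules never lose sensitivity nor gain specificity", {
  for (s in 1:25) {
    co <- random_cohort(150, seed = 100 + s)
    base_kind <- if (s %% 2) "uspstf" else "ada_simplified"
    base <- build_rule(base_kind)
    aug <- build_rule(base_kind, with_pgs = TRUE,
                      pgs_percentile = sample(c(50, 75, 90), 1))
    cmp <- compare_rules(co, base, aug)
    expect_gte(cmp$delta_sensitivity, 0)
    expect_lte(cmp$delta_specificity, 0)
  }
  # identical rules: both deltas zero
  co <- random_cohort(200, seed = 3)
  cmp0 <- compare_rules(co, build_rule("uspstf"), build_rule("uspstf"))
  expect_equal(cmp0$delta_sensitivity, 0)
  expect_equal(cmp0$delta_specificity, 0)
  # non-superset pairs are a protocol error
  expect_error(
    compare_rules(co, build_rule("ada_simplified"), build_rule("uspstf")),
    "every criterion")
})

test_that("PGS augmentation finds cases the base rule misses when heritable", {
  hits <- 0L
  for (s in 1:5) {
    cfg <- sim_config(n = 6000, m_snps = 40, n_causal = 20, h2_snp = 0.3,
                      c2_shared = 0.1, seed = 400 + s)
    sim <- generate_cohort(cfg)
    co <- sim$cohort
    g <- sim$truth$liability_genetic
    co$pgs_std <- drop(scale(g))
    cmp <- compare_rules(co, build_rule("uspstf"),
                         build_rule("uspstf", with_pgs = TRUE))
    if (cmp$delta_sensitivity > 0) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("rules round-trip through structured text", {
  rule <- build_rule("ada_simplified", with_pgs = TRUE, pgs_percentile = 85)
  path <- tempfile(fileext = ".yaml")
  write_rule(rule, path)
  back <- read_rule(path)
  expect_equal(back$name, rule$name)
  expect_equal(back$criteria, rule$criteria)
})
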