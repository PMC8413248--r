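test_that("reference OR is exactly 1 and quantile ORs rise with CRP", {
  ch <- small_sim()$cohort
  dr <- fit_doseresponse(ch, "dep_score", K = 5, model = 1)
  expect_equal(dr$groups$or[1], 1)
  expect_true(all(diff(dr$groups$beta) > -0.02))  # near-monotone rise
  expect_gt(dr$groups$or[5], dr$groups$or[2])
  expect_gt(dr$trend[["or"]], 1)
  expect_lt(dr$trend[["p"]], 0.001)
  expect_equal(sum(dr$groups$n), dr$n)
})

test_that("null cohort gives quantile ORs near 1", {
  zero <- lapply(default_confounder_effects(), function(v) v * 0)
  cfg <- sim_config(n_participants = 30000, seed = 71,
                    alpha_crp = 0, gamma_il6r = 0, delta_il6_to_crp = 0,
                    theta_il6_dep = 0, theta_crp_dep = 0,
                    theta_il6_anx = 0, theta_crp_anx = 0,
                    confounder_effects = zero)
  ch <- generate_cohort(cfg)$cohort
  dr <- fit_doseresponse(ch, "dep_score", K = 5, model = 1)
  expect_true(all(abs(dr$groups$beta) < 0.05))
  expect_gt(dr$trend[["p"]], 0.001)
})

test_that("adjusting for BMI attenuates the confounded association", {
  ch <- small_sim()$cohort
  m1 <- fit_doseresponse(ch, "dep_score", K = 5, model = 1)
  m2 <- fit_doseresponse(ch, "dep_score", K = 5, model = 2)
  expect_lt(m2$trend[["or"]], m1$trend[["or"]])
  expect_lt(log(m2$groups$or[5]), log(m1$groups$or[5]))
})

test_that("binary outcomes use logistic regression with sane ORs", {
  ch <- small_sim()$cohort
  dr <- fit_doseresponse(ch, "dep_dx", K = 5, model = 2)
  expect_true(dr$binary)
  expect_equal(dr$groups$or[1], 1)
  expect_gt(dr$groups$or[5], 1)
})

test_that("trend log-OR equals the balanced WLS line through group means", {
  # unadjusted linear model, balanced groups: slope on the group index
  # equals the OLS slope through the per-group mean outcomes
  set.seed(3)
  ch <- toy_cohort(500, crp = rep(c(0.4, 0.9, 1.5, 2.5, 6), 100))
  dr <- fit_doseresponse(ch, "dep_score", K = 5, model = 1)
  qa <- assign_quantiles(ch$crp, 5)
  m <- tapply(transform_outcome(ch$dep_score), qa$group_index, mean)
  oracle <- coef(lm(m ~ seq_len(5)))[[2]]
  expect_equal(log(dr$trend[["or"]]), oracle, tolerance = 1e-10)
})

test_that("quadratic term is detected exactly on a noiseless toy cohort", {
  crp <- exp(seq(-1.5, 1.5, length.out = 300))
  ch <- toy_cohort(300, crp = crp)
  ch$dep_score <- 0L  # overwritten response below via expm1 of the square
  ch$dep_score <- as.integer(pmin(round(expm1(pmin(log(crp)^2, 3))), 27))
  tl <- test_linearity(ch, "dep_score", model = 1)
  expect_lt(tl$p, 1e-10)
  expect_gt(tl$coef, 0.5)
})

test_that("sex-interaction coefficient equals stratified slope difference", {
  set.seed(9)
  n <- 2000
  ch <- toy_cohort(n, crp = exp(rnorm(n)),
                   sex = rep(c("female", "male"), n / 2))
  si <- test_sex_interaction(ch, "dep_score", model = 1)
  slope_w <- si$stratified$women$beta
  slope_m <- si$stratified$men$beta
  # saturated unadjusted model: product term = men slope - women slope
  expect_equal(si$coef, slope_m - slope_w, tolerance = 1e-10)
  expect_error(test_sex_interaction(
    ch[ch$sex == "female", ], "dep_score", model = 1), "both sexes")
})

test_that("equal sex multipliers give a null interaction", {
  ch <- small_sim()$cohort  # defaults: multipliers 1, 1
  si <- test_sex_interaction(ch, "dep_score", model = 2)
  expect_gt(si$p, 0.001)
})

test_that("empty stratum and bad outcomes raise errors", {
  ch <- small_sim()$cohort
  expect_error(fit_doseresponse(ch[ch$sex == "female", ], "dep_score",
                                sex_stratum = "men"), "stratum")
  expect_error(fit_doseresponse(ch, "nonsense"), "outcome")
})
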