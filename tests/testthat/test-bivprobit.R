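biv_data <- function(n, b1, b2, rho, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  X <- cbind("(Intercept)" = 1, log_crp = x)
  e1 <- rnorm(n)
  e2 <- rho * e1 + sqrt(1 - rho^2) * rnorm(n)
  list(X = X,
       y1 = as.integer(drop(X %*% b1) + e1 > 0),
       y2 = as.integer(drop(X %*% b2) + e2 > 0))
}

test_that("likelihood at rho = 0 factorises into univariate probits", {
  d <- biv_data(8000, c(-1, 0.3), c(-1.2, 0.2), 0, seed = 2)
  f1 <- glm.fit(d$X, d$y1, family = binomial("probit"))$coefficients
  f2 <- glm.fit(d$X, d$y2, family = binomial("probit"))$coefficients
  eta1 <- drop(d$X %*% f1); eta2 <- drop(d$X %*% f2)
  ll_uni <- sum(log(ifelse(d$y1 == 1, pnorm(eta1), pnorm(-eta1)))) +
    sum(log(ifelse(d$y2 == 1, pnorm(eta2), pnorm(-eta2))))
  q1 <- 2 * d$y1 - 1; q2 <- 2 * d$y2 - 1
  ll_biv <- sum(log(pbvnorm(q1 * eta1, q2 * eta2, 0 * q1)))
  expect_equal(ll_biv, ll_uni, tolerance = 1e-8)
  fit <- fit_bivariate_probit(d$y1, d$y2, d$X)
  expect_lt(max(abs(fit$b_dep - f1)), 0.02)
  expect_lt(abs(fit$rho), 3 * sqrt(diag(fit$vcov)[5]))
})

test_that("parameters are recovered within 3 SEs at large n", {
  b1 <- c(-1.3, 0.25); b2 <- c(-1.5, 0.10); rho <- 0.5
  d <- biv_data(50000, b1, b2, rho, seed = 4)
  fit <- fit_bivariate_probit(d$y1, d$y2, d$X)
  se <- sqrt(diag(fit$vcov))
  expect_lt(abs(fit$b_dep[2] - b1[2]), 3 * se[2])
  expect_lt(abs(fit$b_anx[2] - b2[2]), 3 * se[4])
  expect_lt(abs(atanh(fit$rho) - atanh(rho)), 3 * se[5])
  expect_lt(fit$convergence$grad_norm, 1e-3 * max(1, abs(fit$logLik)))
})

test_that("identical outcomes make the equality constraint free", {
  d <- biv_data(3000, c(-1.1, 0.3), c(-1.1, 0.3), 0.4, seed = 6)
  free <- fit_bivariate_probit(d$y1, d$y1, d$X)
  con <- fit_bivariate_probit(d$y1, d$y1, d$X, constrain_equal = TRUE)
  s <- lrt_specificity(free, con)
  expect_lt(s$LR, 0.01)
  expect_gt(s$p, 0.9)
  expect_equal(unname(free$b_dep), unname(free$b_anx), tolerance = 1e-3)
})

test_that("constrained log-likelihood never exceeds the free one", {
  for (seed in 1:4) {
    d <- biv_data(3000, c(-1.2, 0.35), c(-1.4, 0.1), 0.5, seed = seed)
    free <- fit_bivariate_probit(d$y1, d$y2, d$X)
    con <- fit_bivariate_probit(d$y1, d$y2, d$X, constrain_equal = TRUE)
    expect_lte(con$logLik, free$logLik + 1e-6)
    s <- lrt_specificity(free, con)
    expect_gte(s$LR, 0)
    expect_true(s$p >= 0 && s$p <= 1)
  }
})

test_that("specificity LRT rejects when the true effects differ", {
  d <- biv_data(20000, c(-1.2, 0.45), c(-1.4, 0.05), 0.5, seed = 8)
  free <- fit_bivariate_probit(d$y1, d$y2, d$X)
  con <- fit_bivariate_probit(d$y1, d$y2, d$X, constrain_equal = TRUE)
  s <- lrt_specificity(free, con)
  expect_lt(s$p, 1e-6)
  expect_error(lrt_specificity(free, fit_bivariate_probit(
    d$y1[1:1000], d$y2[1:1000], d$X[1:1000, ])), "same data")
})

test_that("probit coefficients convert to ORs by the 1.6 scaling", {
  expect_equal(probit_to_or(0, 0.1)[["or"]], 1)
  expect_equal(probit_to_or(log(2) / 1.6, 0)[["or"]], 2, tolerance = 1e-12)
  o <- probit_to_or(0.2, 0.05)
  expect_equal(o[["lo"]], exp(1.6 * (0.2 - 1.96 * 0.05)))
  expect_error(probit_to_or(0.2, -1), "non-negative")
})

test_that("bivariate Gaussian free fit equals equation-wise OLS", {
  set.seed(10)
  n <- 2000
  x <- rnorm(n)
  X <- cbind("(Intercept)" = 1, log_crp = x, z = rnorm(n))
  y1 <- 0.5 + 0.3 * x + rnorm(n)
  y2 <- 0.2 + 0.3 * x + rnorm(n)
  free <- fit_bivariate_gaussian(y1, y2, X)
  expect_equal(unname(free$b_dep), unname(lm.fit(X, y1)$coefficients),
               tolerance = 1e-10)
  con <- fit_bivariate_gaussian(y1, y2, X, constrain_equal = TRUE)
  expect_lte(con$logLik, free$logLik + 1e-6)
  expect_equal(con$b_dep[["log_crp"]], con$b_anx[["log_crp"]])
  s <- lrt_specificity(free, con)
  expect_gt(s$p, 0.01)  # effects truly equal
  expect_equal(s$analysis, "continuous")
})

test_that("mutual adjustment reveals a depression-specific association", {
  cfg <- sim_config(n_participants = 30000, seed = 14,
                    theta_crp_dep = 0.10, theta_crp_anx = 0,
                    theta_il6_dep = 0, theta_il6_anx = 0)
  ch <- generate_cohort(cfg)$cohort
  ma <- mutual_adjustment(ch, model = 2)
  un_dep <- fit_log_crp(ch, "dep_score", model = 2)$or
  un_anx <- fit_log_crp(ch, "anx_score", model = 2)$or
  expect_gt(ma$dep$or, 1)          # survives adjustment for anxiety
  expect_lt(ma$anx$or, un_anx)     # shrinks toward/below the null
  expect_lt(ma$anx$or, 1.005)
  expect_gt(un_dep, ma$dep$or)     # some attenuation, not elimination
})

test_that("a constant comorbid score leaves the model unadjusted", {
  set.seed(16)
  ch <- toy_cohort(1500, crp = exp(rnorm(1500)))
  ch$anx_score <- 3L
  ma <- mutual_adjustment(ch, model = 1)
  un <- fit_log_crp(ch, "dep_score", model = 1)
  expect_equal(ma$dep$or, un$or, tolerance = 1e-10)
})
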