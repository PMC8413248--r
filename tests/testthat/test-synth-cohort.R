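test_that("identical config and seed reproduce the cohort byte-for-byte", {
  cfg <- sim_config(n_participants = 2000, seed = 11)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$cohort, b$cohort)
  f1 <- tempfile(); f2 <- tempfile()
  write_cohort(a$cohort, f1, seed = 11)
  write_cohort(b$cohort, f2, seed = 11)
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(f1, f2))
})

test_that("invalid config fields raise errors naming the field", {
  expect_error(sim_config(n_participants = 0), "n_participants")
  expect_error(sim_config(eaf_range = c(0.5, 0.1)), "eaf_range")
  expect_error(sim_config(liability_correlation = 1.2),
               "liability_correlation")
  expect_error(sim_config(score_link = list(
    dep = list(intercept = 0, slope = 1, size = 5, max = 30),
    anx = default_score_link()$anx)), "score_link")
})

test_that("cohort respects the type invariants", {
  ch <- small_sim()$cohort
  expect_true(all(ch$crp > 0))
  expect_true(all(ch$dep_score >= 0 & ch$dep_score <= 27))
  expect_true(all(ch$anx_score >= 0 & ch$anx_score <= 21))
  g <- as.matrix(ch[, grep("^g_", names(ch))])
  expect_true(all(g >= 0 & g <= 2))
  expect_setequal(unique(ch$sex), c("female", "male"))
})

test_that("genotypes follow Hardy-Weinberg moments", {
  sim <- generate_cohort(sim_config(n_participants = 60000, seed = 3))
  eaf <- sim$truth$eaf
  for (j in seq_along(eaf)) {
    g <- sim$cohort[[sim$truth$snp_names[j]]]
    p <- eaf[j]
    expect_equal(mean(g), 2 * p, tolerance = 0.02 / sqrt(p))
    expect_equal(var(g), 2 * p * (1 - p), tolerance = 0.05)
  }
})

test_that("null configuration decouples genotypes, CRP and scores", {
  zero <- default_confounder_effects()
  zero <- lapply(zero, function(v) v * 0)
  cfg <- sim_config(n_participants = 40000, seed = 13,
                    alpha_crp = 0, gamma_il6r = 0, delta_il6_to_crp = 0,
                    theta_il6_dep = 0, theta_crp_dep = 0,
                    theta_il6_anx = 0, theta_crp_anx = 0,
                    confounder_effects = zero)
  ch <- generate_cohort(cfg)$cohort
  for (s in grep("^g_", names(ch), value = TRUE)) {
    sl <- coef(lm(log(ch$crp) ~ ch[[s]]))[2]
    se <- summary(lm(log(ch$crp) ~ ch[[s]]))$coefficients[2, 2]
    expect_lt(abs(sl), 4 * se)
  }
  expect_lt(abs(cor(log(ch$crp), ch$dep_score)), 0.02)
})

test_that("exposure chain: IL6R SNP effect on log-CRP is gamma * delta", {
  sim <- generate_cohort(sim_config(n_participants = 120000, seed = 21))
  tr <- sim$truth
  for (j in seq_len(3)) {
    f <- summary(lm(log(sim$cohort$crp) ~ sim$cohort[[paste0("g_IL6R_", j)]]))
    est <- f$coefficients[2, 1]; se <- f$coefficients[2, 2]
    expect_lt(abs(est - tr$gamma_il6r[j] * tr$delta_il6_to_crp), 3.5 * se)
  }
})

test_that("latent liability pair reproduces the residual correlation", {
  # the latent construction used by the generator, at 1e6 draws
  set.seed(5)
  rho <- 0.9
  n <- 1e6
  z1 <- rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  expect_equal(cor(z1, z2), rho, tolerance = 0.01)
})

test_that("selection with intercept-only coefficients is independent", {
  sim <- generate_cohort(sim_config(n_participants = 30000, seed = 9))
  tr <- sim$truth
  tr$selection_coefs <- c(intercept = -0.4, dep_score = 0, anx_score = 0,
                          age = 0, sexF = 0, tdi = 0)
  ch <- apply_selection(sim$cohort, tr)
  expect_equal(mean(ch$selected), plogis(-0.4), tolerance = 0.01)
  expect_lt(abs(mean(ch$dep_score[ch$selected == 1]) -
                  mean(ch$dep_score)), 0.1)
})

test_that("negative score coefficient selects lower-scoring participants", {
  sim <- small_sim()
  ch <- sim$cohort  # default coefficients are negative on dep_score
  expect_lt(mean(ch$dep_score[ch$selected == 1]), mean(ch$dep_score))
  expect_error(apply_selection(ch, list(seed = 1)), "selection_coefs")
})

test_that("score-link slope matches its Monte-Carlo estimate", {
  lk <- default_score_link()$dep
  k <- score_link_slope(lk)
  set.seed(31)
  z <- rnorm(4e5)
  s <- pmin(rnbinom(4e5, size = lk$size, mu = exp(lk$intercept +
                                                    lk$slope * z)), lk$max)
  expect_equal(k, coef(lm(log1p(s) ~ z))[[2]], tolerance = 0.02)
})
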