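aligned_table <- function(bx, by, sy, sx = rep(0.01, length(bx))) {
  data.frame(snp = paste0("rs", seq_along(bx)), beta_x = bx, se_x = sx,
             beta_y = by, se_y = sy)
}

test_that("Wald ratio arithmetic and degeneracies", {
  expect_equal(wald_ratio(0.1, 0.01, 0.05, 0.01),
               list(theta = 0.5, se = 0.1))
  expect_equal(wald_ratio(1, 0.1, 0.3, 0.05),
               list(theta = 0.3, se = 0.05))
  expect_equal(wald_ratio(0.2, 0.01, 0, 0.02)$theta, 0)
  expect_error(wald_ratio(0, 0.01, 0.1, 0.02), "non-zero")
})

test_that("IVW on the 3-SNP fixture matches the precomputed WLS oracle", {
  al <- aligned_table(c(0.12, 0.08, 0.20), c(0.030, 0.028, 0.055),
                      c(0.010, 0.012, 0.015))
  res <- ivw(al)
  expect_equal(res$beta, 0.274271844660194, tolerance = 1e-10)
  expect_equal(res$se, 0.052254976071871, tolerance = 1e-10)
  expect_equal(res$Q, 0.339805825242718, tolerance = 1e-10)
  expect_equal(res$Q_df, 2L)
})

test_that("IVW equals the weighted mean of Wald ratios", {
  set.seed(19)
  for (rep in 1:25) {
    J <- sample(2:12, 1)
    al <- aligned_table(runif(J, 0.03, 0.3) * sample(c(-1, 1), J, TRUE),
                        rnorm(J, 0, 0.05), runif(J, 0.005, 0.05))
    res <- ivw(al)
    w <- al$beta_x^2 / al$se_y^2
    expect_equal(res$beta, sum(w * (al$beta_y / al$beta_x)) / sum(w),
                 tolerance = 1e-12)
  }
})

test_that("single instrument reduces to the Wald ratio, no Q", {
  al <- aligned_table(0.15, 0.045, 0.02)
  res <- ivw(al)
  wr <- wald_ratio(0.15, 0.01, 0.045, 0.02)
  expect_equal(res$beta, wr$theta)
  expect_equal(res$se, wr$se)
  expect_true(is.na(res$Q))
  expect_equal(res$Q_df, 0L)
})

test_that("equal Wald ratios give the common value and Q = 0", {
  bx <- c(0.1, 0.2, 0.05)
  al <- aligned_table(bx, bx * 0.4, c(0.01, 0.02, 0.03))
  res <- ivw(al)
  expect_equal(res$beta, 0.4, tolerance = 1e-12)
  expect_equal(res$Q, 0, tolerance = 1e-12)
  expect_equal(res$Q_p, 1)
})

test_that("an outlying instrument dominates Q and leave-one-out removes it", {
  set.seed(29)
  bx <- runif(5, 0.08, 0.2)
  sy <- rep(0.01, 5)
  by <- bx * 0.3
  by[3] <- by[3] + 10 * sy[3]
  al <- aligned_table(bx, by, sy)
  res <- ivw(al)
  w <- bx^2 / sy^2
  contrib <- w * (by / bx - res$beta)^2
  expect_gt(contrib[3] / res$Q, 0.5)
  res_loo <- ivw(al[-3, ])
  expect_lt(res_loo$Q, qchisq(0.95, df = 3))
})

test_that("multiplicative random effects inflate the SE under heterogeneity", {
  al <- aligned_table(c(0.1, 0.1, 0.1, 0.1), c(0.01, 0.05, 0.02, 0.08),
                      rep(0.01, 4))
  fe <- ivw(al)
  re <- ivw(al, random_effects = TRUE)
  expect_equal(re$beta, fe$beta)
  expect_equal(re$se, fe$se * sqrt(re$Q / 3))
})

test_that("harmonisation aligns, flips and drops per the allele rules", {
  ex <- data.frame(snp = c("rs1", "rs2", "rs3", "rs4", "rs5"),
                   effect_allele = c("A", "A", "A", "A", "A"),
                   other_allele = c("G", "G", "T", "T", "G"),
                   eaf = c(0.3, 0.3, 0.10, 0.50, 0.2),
                   beta = c(0.1, 0.1, 0.1, 0.1, 0.1),
                   se = rep(0.01, 5))
  ou <- data.frame(snp = c("rs1", "rs2", "rs3", "rs4", "rs5"),
                   effect_allele = c("A", "G", "A", "A", "A"),
                   other_allele = c("G", "A", "T", "T", "C"),
                   eaf = c(0.3, 0.7, 0.91, 0.50, 0.2),
                   beta = c(0.05, 0.05, 0.05, 0.05, 0.05),
                   se = rep(0.02, 5))
  al <- harmonize(ex, ou)
  expect_equal(al$beta_y[al$snp == "rs1"], 0.05)     # identical alleles
  expect_equal(al$beta_y[al$snp == "rs2"], -0.05)    # swapped alleles
  expect_equal(al$eaf_y[al$snp == "rs2"], 0.3)
  expect_equal(al$beta_y[al$snp == "rs3"], -0.05)    # palindromic, EAF flip
  expect_false("rs4" %in% al$snp)                    # ambiguous EAF
  expect_false("rs5" %in% al$snp)                    # allele mismatch
  dropped <- attr(al, "dropped")
  expect_equal(dropped$rs4, "palindromic_ambiguous_eaf")
  expect_equal(dropped$rs5, "allele_mismatch")
})

test_that("allele recoding of the exposure leaves the IVW unchanged", {
  set.seed(37)
  ex <- data.frame(snp = paste0("rs", 1:4),
                   effect_allele = c("A", "C", "A", "G"),
                   other_allele = c("G", "T", "C", "A"),
                   eaf = runif(4, 0.1, 0.4),
                   beta = runif(4, 0.05, 0.2), se = rep(0.01, 4))
  ou <- ex
  ou$beta <- ex$beta * 0.3 + rnorm(4, 0, 0.01)
  ou$se <- rep(0.02, 4)
  base <- ivw(harmonize(ex, ou))
  flipped <- ex
  flipped$effect_allele <- ex$other_allele
  flipped$other_allele <- ex$effect_allele
  flipped$eaf <- 1 - ex$eaf
  flipped$beta <- -ex$beta
  recoded <- ivw(harmonize(flipped, ou))
  expect_equal(recoded$beta, base$beta, tolerance = 1e-12)
  expect_equal(recoded$se, base$se, tolerance = 1e-12)
})

test_that("per-SNP regressions recover a known dosage effect", {
  sim <- generate_cohort(sim_config(n_participants = 60000, seed = 41))
  tr <- sim$truth
  assoc <- estimate_snp_associations(sim$cohort, "log_crp",
                                     snps = paste0("g_CRP_", 1:4))
  for (j in 1:4) {
    expect_lt(abs(assoc$beta[j] - tr$alpha_crp[j]), 3.5 * assoc$se[j])
  }
  # permuted dosages are null
  ch <- sim$cohort
  set.seed(1)
  ch$g_CRP_1 <- sample(ch$g_CRP_1)
  null <- estimate_snp_associations(ch, "log_crp", snps = "g_CRP_1")
  expect_lt(abs(null$beta[1]), 4 * null$se[1])
})

test_that("constant IPW weights reproduce the unweighted estimates", {
  ch <- small_sim()$cohort
  plain <- estimate_snp_associations(ch, "dep_score",
                                     snps = "g_IL6R_1")
  w <- rep(1, nrow(ch))
  wted <- estimate_snp_associations(ch, "dep_score", snps = "g_IL6R_1",
                                    weights = w)
  expect_equal(wted$beta, plain$beta, tolerance = 1e-10)
})

test_that("one- and two-sample designs agree given the same instruments", {
  sim <- generate_cohort(sim_config(n_participants = 50000, seed = 43,
                                    theta_il6_dep = 0.3))
  ch <- sim$cohort
  one <- run_mr("one_sample", "il6", "dep_score", cohort = ch)
  # external table carrying the cohort's own exposure-side estimates
  inst <- estimate_snp_associations(ch, "log_crp",
                                    snps = paste0("g_IL6R_", 1:3))
  two <- run_mr("two_sample", "il6", "dep_score", cohort = ch,
                instruments = inst)
  expect_equal(two$beta, one$beta, tolerance = 1e-10)
  expect_lt(abs(one$beta - 0.3), 3 * one$se)
})

test_that("monomorphic SNPs are dropped with a log entry", {
  ch <- small_sim()$cohort
  ch$g_CRP_1 <- 0
  assoc <- estimate_snp_associations(ch, "log_crp",
                                     snps = c("g_CRP_1", "g_CRP_2"))
  expect_equal(attr(assoc, "dropped"), "g_CRP_1")
  expect_equal(nrow(assoc), 1L)
})
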