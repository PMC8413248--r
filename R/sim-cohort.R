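# Stage-specific substream seeds: enabling/disabling one stage must not
# perturb another stage's draws.
stage_seed <- function(seed, stage) {
  offs <- c(genotypes = 11L, covariates = 23L, il6 = 37L, crp = 47L,
            liability = 59L, scores = 71L, selection = 83L)
  (as.integer(seed) %% 1000000L) * 1000L + offs[[stage]]
}

#' Generate a synthetic biobank-style cohort
#'
#' Draws a cohort under the generative chain genotypes -> IL-6 activity ->
#' log-CRP -> symptom liabilities -> integer PHQ-9/GAD-7 scores ->
#' survey-selection flag. Genotypes are Hardy-Weinberg biallelic dosages in
#' two independent gene regions (CRP and IL6R); CRP is log-normal with IL-6
#' activity as an upstream driver; liabilities load on a shared latent
#' confounder and on the observed covariates; scores are right-truncated
#' negative-binomial draws; selection is outcome-dependent (a collider when
#' conditioned on).
#'
#' @param config a [sim_config()] object.
#' @return list with elements `cohort` (data frame, one row per
#'   participant) and `truth` (list recording every true parameter, the
#'   realised allele frequencies, the analysis-scale MR estimands and the
#'   seed).
#' @examples
#' sim <- generate_cohort(sim_config(n_participants = 500, seed = 7))
#' head(sim$cohort)
#' sim$truth$estimand["il6_dep"]
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  n <- config$n_participants

  # genotypes under Hardy-Weinberg equilibrium, SNPs independent (no LD)
  set.seed(stage_seed(config$seed, "genotypes"))
  j_crp <- config$n_snps_crp
  j_il6 <- config$n_snps_il6r
  eaf <- stats::runif(j_crp + j_il6, config$eaf_range[1], config$eaf_range[2])
  G <- vapply(eaf, function(p) stats::rbinom(n, 2L, p), numeric(n))
  g_crp <- G[, seq_len(j_crp), drop = FALSE]
  g_il6 <- G[, j_crp + seq_len(j_il6), drop = FALSE]

  # observed covariates and the shared latent confounder
  set.seed(stage_seed(config$seed, "covariates"))
  age <- pmin(pmax(stats::rnorm(n, 56.5, 7.8), 40), 70)
  sex <- ifelse(stats::runif(n) < 0.564, "female", "male")
  bmi <- pmax(stats::rnorm(n, 27, 4.5), 15)
  smoking <- sample(c("never", "current", "ex"), n, TRUE,
                    prob = c(0.570, 0.074, 0.356))
  alcohol <- sample(c("never_ex", "occasional", "regular"), n, TRUE,
                    prob = c(0.056, 0.450, 0.494))
  activity <- sample(1:4, n, TRUE, prob = c(0.79, 0.06, 0.123, 0.027))
  ethnicity <- ifelse(stats::runif(n) < 0.968, "white", "other")
  tdi <- stats::rnorm(n, -1.7, 2.8)
  diabetes <- stats::rbinom(n, 1L, 0.033)
  cvd <- stats::rbinom(n, 1L, 0.036)
  u <- stats::rnorm(n)

  covmat <- cbind(
    u = u, bmi = bmi - 27, age = age - 56.5, sexF = as.numeric(sex == "female"),
    smoking_current = as.numeric(smoking == "current"),
    smoking_ex = as.numeric(smoking == "ex"),
    alcohol_occasional = as.numeric(alcohol == "occasional"),
    alcohol_regular = as.numeric(alcohol == "regular"),
    activity = activity - 1, tdi = tdi - (-1.7), diabetes = diabetes,
    cvd = cvd, ethnicity_white = as.numeric(ethnicity == "white"))
  cov_term <- function(effects) {
    b <- effects[colnames(covmat)]
    b[is.na(b)] <- 0
    v <- drop(covmat %*% b)
    v - mean(v)
  }

  # latent IL-6 activity: genetic part plus residual, unit variance overall
  set.seed(stage_seed(config$seed, "il6"))
  gen_il6 <- drop(g_il6 %*% config$gamma_il6r)
  var_gen_il6 <- sum(config$gamma_il6r^2 * 2 * eaf[j_crp + seq_len(j_il6)] *
                       (1 - eaf[j_crp + seq_len(j_il6)]))
  il6 <- gen_il6 - mean(gen_il6) +
    stats::rnorm(n, 0, sqrt(max(1 - var_gen_il6, 0.05)))

  # log-CRP: genetics + IL-6 + confounders + noise; median ~= 1.15 mg/L
  set.seed(stage_seed(config$seed, "crp"))
  gen_crp <- drop(g_crp %*% config$alpha_crp)
  log_crp <- log(1.15) + gen_crp - mean(gen_crp) +
    config$delta_il6_to_crp * il6 +
    cov_term(config$confounder_effects$on_crp) +
    stats::rnorm(n, 0, 0.692)
  crp <- exp(log_crp)

  # symptom liabilities: causal terms + confounders + correlated residuals
  set.seed(stage_seed(config$seed, "liability"))
  mult <- ifelse(sex == "female",
                 config$sex_effect_multipliers[["female"]],
                 config$sex_effect_multipliers[["male"]])
  lc <- log_crp - mean(log_crp)
  eta_dep <- mult * (config$theta_il6_dep * il6 + config$theta_crp_dep * lc) +
    cov_term(config$confounder_effects$on_dep)
  eta_anx <- mult * (config$theta_il6_anx * il6 + config$theta_crp_anx * lc) +
    cov_term(config$confounder_effects$on_anx)
  eta_dep <- eta_dep - mean(eta_dep)
  eta_anx <- eta_anx - mean(eta_anx)
  s_dep <- sqrt(max(1 - stats::var(eta_dep), 0.05))
  s_anx <- sqrt(max(1 - stats::var(eta_anx), 0.05))
  rho <- config$liability_correlation
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  liab_dep <- eta_dep + s_dep * z1
  liab_anx <- eta_anx + s_anx * z2

  # right-truncated negative-binomial score link
  set.seed(stage_seed(config$seed, "scores"))
  draw_score <- function(link, liab) {
    s <- stats::rnbinom(n, size = link$size,
                        mu = exp(link$intercept + link$slope * liab))
    pmin(s, link$max)
  }
  dep_score <- draw_score(config$score_link$dep, liab_dep)
  anx_score <- draw_score(config$score_link$anx, liab_anx)

  cohort <- data.frame(participant_id = seq_len(n))
  for (j in seq_len(j_crp)) cohort[[paste0("g_CRP_", j)]] <- g_crp[, j]
  for (j in seq_len(j_il6)) cohort[[paste0("g_IL6R_", j)]] <- g_il6[, j]
  cohort$age <- age; cohort$sex <- sex; cohort$bmi <- bmi
  cohort$smoking <- smoking; cohort$alcohol <- alcohol
  cohort$activity <- activity; cohort$ethnicity <- ethnicity
  cohort$tdi <- tdi; cohort$diabetes <- diabetes; cohort$cvd <- cvd
  cohort$crp <- crp
  cohort$dep_score <- as.integer(dep_score)
  cohort$anx_score <- as.integer(anx_score)

  k_dep <- score_link_slope(config$score_link$dep)
  k_anx <- score_link_slope(config$score_link$anx)
  truth <- list(
    seed = config$seed,
    eaf = eaf,
    snp_names = c(paste0("g_CRP_", seq_len(j_crp)),
                  paste0("g_IL6R_", seq_len(j_il6))),
    alpha_crp = config$alpha_crp,
    gamma_il6r = config$gamma_il6r,
    delta_il6_to_crp = config$delta_il6_to_crp,
    theta = c(il6_dep = config$theta_il6_dep, crp_dep = config$theta_crp_dep,
              il6_anx = config$theta_il6_anx, crp_anx = config$theta_crp_anx),
    link_slope = c(dep = k_dep, anx = k_anx),
    # MR estimands on the log(score+1) analysis scale, per unit of
    # genetically-predicted log-CRP
    estimand = c(
      il6_dep = config$theta_il6_dep * k_dep / config$delta_il6_to_crp,
      il6_anx = config$theta_il6_anx * k_anx / config$delta_il6_to_crp,
      crp_dep = config$theta_crp_dep * k_dep,
      crp_anx = config$theta_crp_anx * k_anx),
    selection_coefs = config$selection_coefs,
    sex_effect_multipliers = config$sex_effect_multipliers,
    liability_correlation = config$liability_correlation)

  sim <- list(cohort = apply_selection_impl(cohort, truth, config$seed),
              truth = truth)
  sim
}

apply_selection_impl <- function(cohort, truth, seed) {
  set.seed(stage_seed(seed, "selection"))
  sc <- truth$selection_coefs
  lp <- sc[["intercept"]] +
    sc[["dep_score"]] * cohort$dep_score +
    sc[["anx_score"]] * cohort$anx_score +
    sc[["age"]] * (cohort$age - 56.5) +
    sc[["sexF"]] * as.numeric(cohort$sex == "female") +
    sc[["tdi"]] * cohort$tdi
  p <- stats::plogis(lp)
  cohort$selected <- stats::rbinom(nrow(cohort), 1L, p)
  attr(cohort, "selection_fraction") <- mean(cohort$selected)
  cohort
}

#' Redraw the survey-selection flag of a cohort
#'
#' Applies (or re-applies) the outcome-dependent participation model: the
#' logistic linear predictor includes the symptom scores, so conditioning
#' on `selected == 1` opens a collider path between CRP and the outcomes.
#'
#' @param cohort a cohort data frame from [generate_cohort()].
#' @param truth the matching truth record (its `selection_coefs` are used).
#' @return the cohort with a fresh `selected` column; the marginal
#'   selection fraction is attached as attribute `selection_fraction`.
#' @export
apply_selection <- function(cohort, truth) {
  if (is.null(truth$selection_coefs))
    stop("truth record carries no selection_coefs")
  apply_selection_impl(cohort, truth, truth$seed)
}
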