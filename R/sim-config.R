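#' Simulation configuration for a synthetic biobank-style cohort
#'
#' Builds the parameter set of the cohort generator. The generative chain is
#' genotypes -> latent IL-6 activity -> log-CRP -> symptom liabilities ->
#' integer PHQ-9/GAD-7 scores -> survey-selection flag, i.e. the causal
#' structure under which CRP is a downstream readout of classic IL-6
#' signalling while retaining a possible direct CRP pathway. Defaults are
#' calibrated so that, at biobank scale, the cohort marginals match a large
#' UK population cohort: median CRP about 1.15 mg/L, mean depression score
#' about 2.76, mean anxiety score about 2.15, score correlation about 0.68,
#' probable-depression prevalence about 5.5% and probable-GAD prevalence
#' about 4.4%.
#'
#' @param n_participants number of cohort rows to generate.
#' @param n_snps_crp number of biallelic instruments in the CRP gene region.
#' @param n_snps_il6r number of biallelic instruments in the IL6R gene region.
#' @param eaf_range range of effect-allele frequencies, inside (0, 1).
#' @param alpha_crp per-allele additive effects of the CRP-region SNPs on
#'   log-CRP (log mg/L per allele); recycled/truncated to `n_snps_crp`.
#' @param gamma_il6r per-allele additive effects of the IL6R-region SNPs on
#'   latent IL-6 activity (SD units per allele).
#' @param delta_il6_to_crp effect of one SD of IL-6 activity on log-CRP.
#'   The default equals the liability-to-analysis-scale slope of the
#'   depression score link, a normalisation that makes the IL-6 MR estimand
#'   on the `log(score + 1)` scale equal to `theta_il6_dep`.
#' @param theta_il6_dep,theta_crp_dep,theta_il6_anx,theta_crp_anx causal
#'   effects (liability SD per SD of IL-6 activity, and per unit log-CRP)
#'   of IL-6 activity and of CRP directly on the two symptom liabilities.
#' @param confounder_effects list with numeric vectors `on_crp`, `on_dep`,
#'   `on_anx`: loadings of the shared latent confounder `u` and of the
#'   observed covariates on log-CRP and on the two liabilities. See
#'   `default_confounder_effects()` for the recognised names.
#' @param liability_correlation residual correlation of the depression and
#'   anxiety liabilities, in (-1, 1).
#' @param score_link list with components `dep` and `anx`, each
#'   `list(intercept, slope, size, max)`: the symptom score is a negative
#'   binomial draw with log-mean `intercept + slope * liability` and
#'   dispersion `size`, right-truncated at `max` (27 for PHQ-9, 21 for
#'   GAD-7).
#' @param selection_coefs named vector of logistic coefficients of the
#'   survey-participation model: `intercept`, `dep_score`, `anx_score`,
#'   `age` (centred at 56.5), `sexF`, `tdi`. Outcome-dependent selection
#'   makes participation a collider.
#' @param sex_effect_multipliers named vector `c(female =, male =)` scaling
#'   the four theta parameters per sex.
#' @param seed integer seed; every draw is reproducible from it.
#' @return an object of class `sim_config` (a validated list).
#' @seealso [generate_cohort()], [apply_selection()]
#' @export
sim_config <- function(n_participants = 20000,
                       n_snps_crp = 4,
                       n_snps_il6r = 3,
                       eaf_range = c(0.1, 0.5),
                       alpha_crp = c(0.20, 0.15, 0.12, 0.10),
                       gamma_il6r = c(0.12, 0.10, 0.08),
                       delta_il6_to_crp = 0.619,
                       theta_il6_dep = 0.10,
                       theta_crp_dep = -0.03,
                       theta_il6_anx = 0.05,
                       theta_crp_anx = -0.04,
                       confounder_effects = default_confounder_effects(),
                       liability_correlation = 0.90,
                       score_link = default_score_link(),
                       selection_coefs = default_selection_coefs(),
                       sex_effect_multipliers = c(female = 1, male = 1),
                       seed = 1L) {
  cfg <- list(
    n_participants = as.integer(n_participants),
    n_snps_crp = as.integer(n_snps_crp),
    n_snps_il6r = as.integer(n_snps_il6r),
    eaf_range = as.numeric(eaf_range),
    alpha_crp = rep_len(as.numeric(alpha_crp), n_snps_crp),
    gamma_il6r = rep_len(as.numeric(gamma_il6r), n_snps_il6r),
    delta_il6_to_crp = as.numeric(delta_il6_to_crp),
    theta_il6_dep = as.numeric(theta_il6_dep),
    theta_crp_dep = as.numeric(theta_crp_dep),
    theta_il6_anx = as.numeric(theta_il6_anx),
    theta_crp_anx = as.numeric(theta_crp_anx),
    confounder_effects = confounder_effects,
    liability_correlation = as.numeric(liability_correlation),
    score_link = score_link,
    selection_coefs = selection_coefs,
    sex_effect_multipliers = sex_effect_multipliers,
    seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @export
default_confounder_effects <- function() {
  list(
    on_crp = c(u = 0.20, bmi = 0.08, age = 0.004, sexF = 0.10,
               smoking_current = 0.35, smoking_ex = 0.08,
               alcohol_occasional = -0.05, alcohol_regular = -0.12,
               activity = -0.05, tdi = 0.02, diabetes = 0.30, cvd = 0.20,
               ethnicity_white = 0),
    on_dep = c(u = 0.25, bmi = 0.020, age = -0.010, sexF = 0.15,
               smoking_current = 0.25, smoking_ex = 0.05,
               alcohol_occasional = 0, alcohol_regular = -0.05,
               activity = -0.06, tdi = 0.06, diabetes = 0.20, cvd = 0.20,
               ethnicity_white = 0),
    on_anx = c(u = 0.25, bmi = 0.010, age = -0.015, sexF = 0.20,
               smoking_current = 0.20, smoking_ex = 0.03,
               alcohol_occasional = 0, alcohol_regular = -0.04,
               activity = -0.04, tdi = 0.05, diabetes = 0.10, cvd = 0.15,
               ethnicity_white = 0))
}

#' @rdname sim_config
#' @export
default_score_link <- function() {
  list(dep = list(intercept = 0.4924, slope = 1.0409, size = 20, max = 27),
       anx = list(intercept = 0.0649, slope = 1.2266, size = 20, max = 21))
}

#' @rdname sim_config
#' @export
default_selection_coefs <- function() {
  c(intercept = 0.45, dep_score = -0.12, anx_score = -0.05,
    age = 0.02, sexF = 0.15, tdi = -0.05)
}

validate_sim_config <- function(cfg) {
  fail <- function(field, msg)
    stop(sprintf("invalid sim_config field '%s': %s", field, msg),
         call. = FALSE)
  if (is.na(cfg$n_participants) || cfg$n_participants < 1)
    fail("n_participants", "must be a positive integer")
  if (cfg$n_snps_crp < 0 || cfg$n_snps_il6r < 0)
    fail("n_snps_crp/n_snps_il6r", "must be non-negative")
  if (length(cfg$eaf_range) != 2 || any(cfg$eaf_range <= 0) ||
      any(cfg$eaf_range >= 1) || cfg$eaf_range[1] > cfg$eaf_range[2])
    fail("eaf_range", "must be an increasing pair inside (0, 1)")
  if (abs(cfg$liability_correlation) >= 1)
    fail("liability_correlation", "must lie in (-1, 1)")
  for (nm in c("dep", "anx")) {
    lk <- cfg$score_link[[nm]]
    if (!all(c("intercept", "slope", "size", "max") %in% names(lk)))
      fail("score_link", paste0("component '", nm,
                                "' needs intercept, slope, size, max"))
    if (lk$size <= 0) fail("score_link", "size must be positive")
  }
  if (cfg$score_link$dep$max != 27 || cfg$score_link$anx$max != 21)
    fail("score_link", "score caps must be 27 (PHQ-9) and 21 (GAD-7)")
  need <- c("intercept", "dep_score", "anx_score", "age", "sexF", "tdi")
  if (!all(need %in% names(cfg$selection_coefs)))
    fail("selection_coefs", paste("must name", paste(need, collapse = ", ")))
  if (!all(c("female", "male") %in% names(cfg$sex_effect_multipliers)))
    fail("sex_effect_multipliers", "must name female and male")
  for (nm in c("on_crp", "on_dep", "on_anx"))
    if (is.null(cfg$confounder_effects[[nm]]))
      fail("confounder_effects", paste("missing component", nm))
  invisible(cfg)
}

#' Analysis-scale slope of a score link
#'
#' Derivative of `E[log(score + 1)]` with respect to the liability for a
#' truncated negative-binomial score link, evaluated for a standard-normal
#' liability by the Stein identity `E[L * g(L)]` with Gauss-Hermite
#' quadrature. This constant converts liability-scale causal effects into
#' effects on the `log(score + 1)` analysis scale, and hence defines the MR
#' estimand of the simulator.
#'
#' @param link one component of `score_link`, e.g.
#'   `default_score_link()$dep`.
#' @param n_nodes number of Gauss-Hermite nodes.
#' @return numeric scalar slope.
#' @export
score_link_slope <- function(link, n_nodes = 64) {
  gh <- .gauss_hermite(n_nodes)
  z <- gh$nodes * sqrt(2)
  w <- gh$weights / sqrt(pi)
  mu <- exp(link$intercept + link$slope * z)
  smax <- link$max
  g <- vapply(mu, function(m) {
    s <- 0:(smax - 1)
    pr <- stats::dnbinom(s, size = link$size, mu = m)
    sum(log1p(s) * pr) + log1p(smax) * (1 - sum(pr))
  }, numeric(1))
  sum(w * z * g)  # Stein: E[Z g(Z)] = E[g'(Z)] for Z ~ N(0,1)
}

# Golub-Welsch Gauss-Hermite rule (physicists' weight exp(-x^2)).
.gauss_hermite <- function(n) {
  i <- seq_len(n - 1)
  b <- sqrt(i / 2)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  idx <- order(e$values)
  list(nodes = e$values[idx],
       weights = sqrt(pi) * e$vectors[1, idx]^2)
}
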