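#' @title Covariate sets of the four adjustment models
#' @description Model 1 is unadjusted; model 2 adds age, sex and BMI;
#' model 3 adds smoking, alcohol, physical activity, ethnicity and
#' Townsend deprivation index; model 4 adds diabetes and cardiovascular
#' disease.
#' @param model integer 1-4.
#' @param stratified drop `sex` (used inside sex strata).
#' @return character vector of covariate names (possibly empty).
#' @export
model_covariates <- function(model, stratified = FALSE) {
  model <- as.integer(model)
  if (!model %in% 1:4) stop("model must be 1, 2, 3 or 4")
  covs <- character(0)
  if (model >= 2) covs <- c(covs, "age", "sex", "bmi")
  if (model >= 3) covs <- c(covs, "smoking", "alcohol", "activity",
                            "ethnicity", "tdi")
  if (model >= 4) covs <- c(covs, "diabetes", "cvd")
  if (stratified) covs <- setdiff(covs, "sex")
  covs
}

.outcome_spec <- function(outcome) {
  switch(outcome,
    dep_score = list(binary = FALSE, col = "dep_score"),
    anx_score = list(binary = FALSE, col = "anx_score"),
    dep_dx    = list(binary = TRUE,  col = "dep_score", cut = 10L),
    gad_dx    = list(binary = TRUE,  col = "anx_score", cut = 10L),
    stop("unknown outcome: ", outcome))
}

# Assemble the analysis data: response, covariates, complete cases only.
.analysis_data <- function(cohort, outcome, model, sex_stratum,
                           weights = NULL) {
  spec <- .outcome_spec(outcome)
  if (!spec$col %in% names(cohort))
    stop("cohort lacks column ", spec$col)
  if (!sex_stratum %in% c("all", "women", "men"))
    stop("sex_stratum must be all, women or men")
  d <- cohort
  if (!is.null(weights)) d$.w <- weights
  if (sex_stratum != "all") {
    keep <- d$sex == if (sex_stratum == "women") "female" else "male"
    d <- d[keep, , drop = FALSE]
    if (nrow(d) == 0) stop("empty sex stratum: ", sex_stratum)
  }
  covs <- model_covariates(model, stratified = sex_stratum != "all")
  d$.y <- if (spec$binary) as.integer(d[[spec$col]] >= spec$cut)
          else transform_outcome(d[[spec$col]])
  use <- stats::complete.cases(d[, c(".y", "crp", covs), drop = FALSE])
  d <- d[use, , drop = FALSE]
  for (f in intersect(c("sex", "smoking", "alcohol", "ethnicity"), covs))
    d[[f]] <- factor(d[[f]])
  list(data = d, covs = covs, binary = spec$binary)
}

.fit_one <- function(formula, d, binary, weighted) {
  if (binary) {
    if (weighted)
      fit <- stats::glm(formula, data = d, family = stats::quasibinomial(),
                        weights = .w)
    else
      fit <- stats::glm(formula, data = d, family = stats::binomial())
    if (!fit$converged) stop("logistic fit did not converge")
    cf <- stats::coef(fit)
    if (any(abs(cf[-1]) > 15, na.rm = TRUE))
      stop("quasi-separation detected in logistic fit")
  } else {
    fit <- if (weighted) stats::lm(formula, data = d, weights = .w)
           else stats::lm(formula, data = d)
  }
  fit
}

.vcov_of <- function(fit, weighted) {
  if (weighted) sandwich::vcovHC(fit, type = "HC0") else stats::vcov(fit)
}

#' Quantile dose-response association of CRP with a symptom outcome
#'
#' Divides CRP into `K` quantile groups on the analysis sample and
#' regresses the outcome on the group factor plus the covariates of the
#' chosen adjustment model. Symptom-score outcomes use linear regression on
#' `log(score + 1)` with exponentiated coefficients reported as OR-style
#' ratios; probable diagnoses (scores >= 10) use logistic regression.
#' Per-group CIs come from floating absolute risks, so the reference group
#' receives its own CI; the trend OR uses the quantile index as a
#' continuous predictor; a quadratic term in log-CRP tests linearity and,
#' in the full sample, a sex-by-log-CRP product term tests effect
#' modification.
#'
#' @param cohort cohort data frame (see [generate_cohort()] or
#'   [read_cohort()]).
#' @param outcome one of `"dep_score"`, `"anx_score"`, `"dep_dx"`,
#'   `"gad_dx"`.
#' @param K number of quantile groups (5 or 10, say).
#' @param model adjustment model 1-4, see [model_covariates()].
#' @param sex_stratum `"all"`, `"women"` or `"men"`.
#' @param weights optional per-row inverse-probability weights (length
#'   `nrow(cohort)`); robust (sandwich) standard errors are used when
#'   weights are supplied.
#' @param floated_method passed to [floated_variances()].
#' @return object of class `doseresponse`: per-group table (`group`, `n`,
#'   `median_crp`, `beta`, `var_beta`, `lambda`, `or`, `lo`, `hi`), trend
#'   OR/CI/p, quadratic p, sex-interaction p (full sample only), model tag
#'   and n used.
#' @export
fit_doseresponse <- function(cohort, outcome, K = 5, model = 1,
                             sex_stratum = "all", weights = NULL,
                             floated_method = "mean") {
  ad <- .analysis_data(cohort, outcome, model, sex_stratum, weights)
  d <- ad$data
  weighted <- !is.null(weights)
  qa <- assign_quantiles(d$crp, K)
  d$.qgroup <- factor(qa$group_index, levels = seq_len(K))
  d$.qindex <- qa$group_index
  rhs <- function(x) paste(c(x, ad$covs), collapse = " + ")

  fit_q <- .fit_one(stats::as.formula(paste(".y ~", rhs(".qgroup"))),
                    d, ad$binary, weighted)
  cf <- stats::coef(fit_q)
  qnames <- paste0(".qgroup", 2:K)
  beta <- unname(cf[qnames])
  Vfull <- .vcov_of(fit_q, weighted)
  V <- Vfull[qnames, qnames, drop = FALSE]
  fl <- floated_variances(V, method = floated_method)
  beta_all <- c(0, beta)
  ci <- floated_ci(beta_all, fl$lambda)
  groups <- data.frame(
    group = seq_len(K),
    n = qa$group_n,
    median_crp = qa$group_medians,
    beta = beta_all,
    var_beta = c(NA_real_, diag(V)),
    lambda = fl$lambda,
    or = ci[, "or"], lo = ci[, "lo"], hi = ci[, "hi"])

  fit_t <- .fit_one(stats::as.formula(paste(".y ~", rhs(".qindex"))),
                    d, ad$binary, weighted)
  bt <- stats::coef(fit_t)[".qindex"]
  set <- sqrt(.vcov_of(fit_t, weighted)[".qindex", ".qindex"])
  trend <- c(or = exp(bt), lo = exp(bt - 1.96 * set),
             hi = exp(bt + 1.96 * set),
             p = 2 * stats::pnorm(-abs(bt / set)))
  names(trend) <- c("or", "lo", "hi", "p")

  quad <- .quadratic_term(d, ad, weighted)
  sexint <- if (sex_stratum == "all" && length(unique(d$sex)) > 1)
    .sex_interaction_term(d, ad, weighted) else NULL

  structure(list(
    outcome = outcome, K = K, model = model, sex_stratum = sex_stratum,
    binary = ad$binary, weighted = weighted, n = nrow(d),
    cut_points = qa$cut_points, groups = groups, trend = trend,
    quadratic_p = quad[["p"]],
    sex_interaction_p = if (is.null(sexint)) NA_real_ else sexint[["p"]],
    floated = fl), class = "doseresponse")
}

.quadratic_term <- function(d, ad, weighted) {
  d$.lc <- log(d$crp)
  d$.lc2 <- d$.lc^2
  f <- stats::as.formula(paste(".y ~",
        paste(c(".lc", ".lc2", ad$covs), collapse = " + ")))
  fit <- .fit_one(f, d, ad$binary, weighted)
  b <- unname(stats::coef(fit)[".lc2"])
  se <- sqrt(.vcov_of(fit, weighted)[".lc2", ".lc2"])
  c(coef = b, se = se, p = 2 * stats::pnorm(-abs(b / se)))
}

.sex_interaction_term <- function(d, ad, weighted) {
  d$.lc <- log(d$crp)
  d$sex <- factor(d$sex)
  extra <- setdiff(ad$covs, "sex")
  f <- stats::as.formula(paste(c(".y ~ .lc * sex", extra),
                               collapse = " + "))
  fit <- .fit_one(f, d, ad$binary, weighted)
  cf <- stats::coef(fit)
  nm <- grep("^\\.lc:sex", names(cf), value = TRUE)[1]
  b <- unname(cf[nm])
  se <- sqrt(.vcov_of(fit, weighted)[nm, nm])
  c(coef = b, se = se, p = 2 * stats::pnorm(-abs(b / se)))
}

#' Continuous log-CRP association
#'
#' Regression of an outcome on natural-log CRP plus the covariates of an
#' adjustment model, mirroring the "log CRP as continuous variable" column
#' of a quantile dose-response table.
#'
#' @inheritParams fit_doseresponse
#' @return list with `or`, `lo`, `hi`, `p`, `beta`, `se`, `n`.
#' @export
fit_log_crp <- function(cohort, outcome, model = 1, sex_stratum = "all",
                        weights = NULL) {
  ad <- .analysis_data(cohort, outcome, model, sex_stratum, weights)
  d <- ad$data
  weighted <- !is.null(weights)
  d$.lc <- log(d$crp)
  f <- stats::as.formula(paste(".y ~",
        paste(c(".lc", ad$covs), collapse = " + ")))
  fit <- .fit_one(f, d, ad$binary, weighted)
  b <- stats::coef(fit)[".lc"]
  se <- sqrt(.vcov_of(fit, weighted)[".lc", ".lc"])
  list(or = exp(unname(b)), lo = exp(unname(b - 1.96 * se)),
       hi = exp(unname(b + 1.96 * se)),
       p = unname(2 * stats::pnorm(-abs(b / se))),
       beta = unname(b), se = unname(se), n = nrow(d))
}

#' Test linearity of the CRP dose-response
#'
#' Augments the continuous log-CRP model with a squared term and returns
#' the Wald test of the quadratic coefficient.
#'
#' @inheritParams fit_doseresponse
#' @return list with `coef`, `se`, `p` for the squared log-CRP term.
#' @export
test_linearity <- function(cohort, outcome, model = 1, sex_stratum = "all",
                           weights = NULL) {
  ad <- .analysis_data(cohort, outcome, model, sex_stratum, weights)
  q <- .quadratic_term(ad$data, ad, !is.null(weights))
  list(coef = unname(q[["coef"]]), se = unname(q[["se"]]),
       p = unname(q[["p"]]))
}

#' Test sex interaction of the CRP association
#'
#' Adds a sex-by-log-CRP product term to the adjusted model and also
#' returns sex-stratified continuous log-CRP estimates.
#'
#' @inheritParams fit_doseresponse
#' @return list with `coef`, `se`, `p` for the product term, and
#'   `stratified` (list of [fit_log_crp()] results for women and men).
#' @export
test_sex_interaction <- function(cohort, outcome, model = 1,
                                 weights = NULL) {
  if (length(unique(cohort$sex)) < 2)
    stop("both sexes must be present to test a sex interaction")
  ad <- .analysis_data(cohort, outcome, model, "all", weights)
  s <- .sex_interaction_term(ad$data, ad, !is.null(weights))
  list(coef = s[["coef"]], se = s[["se"]], p = s[["p"]],
       stratified = list(
         women = fit_log_crp(cohort, outcome, model, "women", weights),
         men = fit_log_crp(cohort, outcome, model, "men", weights)))
}

#' @export
print.doseresponse <- function(x, ...) {
  cat(sprintf(
    "CRP %s-quantile dose-response for %s (model %d, %s, n = %d%s)\n",
    x$K, x$outcome, x$model, x$sex_stratum, x$n,
    if (x$weighted) ", IPW" else ""))
  g <- x$groups
  g[, c("median_crp", "or", "lo", "hi")] <-
    round(g[, c("median_crp", "or", "lo", "hi")], 2)
  print(g[, c("group", "n", "median_crp", "or", "lo", "hi")],
        row.names = FALSE)
  cat(sprintf("trend OR %.2f (%.2f-%.2f), p = %.3g\n",
              x$trend[["or"]], x$trend[["lo"]], x$trend[["hi"]],
              x$trend[["p"]]))
  cat(sprintf("quadratic p = %.3g; sex-interaction p = %.3g\n",
              x$quadratic_p, x$sex_interaction_p))
  invisible(x)
}
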