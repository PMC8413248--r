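#' Fit the survey-participation model and derive inverse-probability weights
#'
#' Logistic regression of the selection flag on a covariate set that
#' includes the symptom scores (selection is outcome-dependent). Weights
#' `1 / p_hat` for the selected rows re-weight the selected subsample back
#' to the full cohort, correcting the collider bias induced by
#' conditioning on participation. Weighted analyses should use robust
#' (sandwich) standard errors, which [fit_doseresponse()] and
#' [estimate_snp_associations()] do automatically when given weights.
#'
#' @param cohort cohort data frame containing a binary `selected` column
#'   with both selected and unselected rows.
#' @param covariates covariate names of the participation model; the
#'   default matches the simulator's selection mechanism.
#' @param stabilized multiply the weights by the marginal selection
#'   fraction, so they sum approximately to the number selected.
#' @param p_floor probabilities below this floor are truncated; the count
#'   of truncations is recorded.
#' @return object of class `ipw_weights`: list with `p_hat` (all rows),
#'   `weights` (all rows; `NA` for unselected), `coefficients`,
#'   `n_truncated`, `stabilized`, `selection_fraction`.
#' @export
fit_selection_model <- function(cohort,
                                covariates = c("dep_score", "anx_score",
                                               "age", "sex", "tdi"),
                                stabilized = FALSE, p_floor = 1e-3) {
  if (!"selected" %in% names(cohort))
    stop("cohort lacks a 'selected' column")
  if (length(unique(cohort$selected)) < 2)
    stop("cohort must contain both selected and unselected rows")
  miss <- setdiff(covariates, names(cohort))
  if (length(miss))
    stop("selection-model covariates missing from cohort: ",
         paste(miss, collapse = ", "))
  d <- cohort[, c("selected", covariates), drop = FALSE]
  for (f in intersect(c("sex", "smoking", "alcohol", "ethnicity"),
                      covariates))
    d[[f]] <- factor(d[[f]])
  fit <- stats::glm(stats::as.formula(
    paste("selected ~", paste(covariates, collapse = " + "))),
    data = d, family = stats::binomial())
  p_hat <- stats::fitted(fit)
  n_trunc <- sum(p_hat < p_floor & cohort$selected == 1)
  p_hat <- pmax(p_hat, p_floor)
  w <- ifelse(cohort$selected == 1, 1 / p_hat, NA_real_)
  frac <- mean(cohort$selected)
  if (stabilized) w <- w * frac
  structure(list(p_hat = as.numeric(p_hat), weights = as.numeric(w),
                 coefficients = stats::coef(fit), n_truncated = n_trunc,
                 stabilized = stabilized, selection_fraction = frac),
            class = "ipw_weights")
}
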