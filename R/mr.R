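#' Per-SNP association estimation in an individual-level cohort
#'
#' One regression per SNP of a (transformed) variable on the genotype
#' dosage plus covariates: linear for log-CRP and the transformed symptom
#' scores, logistic for the probable diagnoses. Supplying
#' inverse-probability weights restricts the fit to the selected rows,
#' weights it by `1 / p_hat` and switches to robust (sandwich) standard
#' errors, reproducing SNP-outcome associations corrected for
#' outcome-dependent survey participation.
#'
#' @param cohort cohort data frame with genotype dosage columns.
#' @param variable one of `"log_crp"`, `"dep_score"`, `"anx_score"`,
#'   `"dep_dx"`, `"gad_dx"`.
#' @param snps genotype column names; default: every column starting with
#'   `g_`.
#' @param covariates adjustment covariates (default age and sex; sex is
#'   dropped automatically inside sex strata).
#' @param stratum `"all"`, `"women"` or `"men"`.
#' @param weights optional `ipw_weights` object from
#'   [fit_selection_model()], or a numeric vector of per-row weights.
#' @return data frame of class `snp_associations` with columns `snp`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `n`; monomorphic
#'   SNPs are dropped and listed in attribute `dropped`.
#' @export
estimate_snp_associations <- function(cohort, variable,
                                      snps = grep("^g_", names(cohort),
                                                  value = TRUE),
                                      covariates = c("age", "sex"),
                                      stratum = "all", weights = NULL) {
  if (!length(snps)) stop("no genotype columns found")
  if (inherits(weights, "ipw_weights")) weights <- weights$weights
  d <- cohort
  if (!is.null(weights)) {
    if (length(weights) != nrow(cohort))
      stop("weights must have one entry per cohort row")
    d$.w <- weights
    d <- d[!is.na(d$.w), , drop = FALSE]
  }
  if (stratum != "all") {
    d <- d[d$sex == if (stratum == "women") "female" else "male", ,
           drop = FALSE]
    covariates <- setdiff(covariates, "sex")
    if (nrow(d) == 0) stop("empty sex stratum: ", stratum)
  }
  binary <- variable %in% c("dep_dx", "gad_dx")
  d$.y <- switch(variable,
    log_crp = log(d$crp),
    dep_score = transform_outcome(d$dep_score),
    anx_score = transform_outcome(d$anx_score),
    dep_dx = as.integer(d$dep_score >= 10),
    gad_dx = as.integer(d$anx_score >= 10),
    stop("unknown variable: ", variable))
  for (f in intersect("sex", covariates)) d[[f]] <- factor(d[[f]])

  weighted <- !is.null(weights)
  res <- vector("list", length(snps))
  dropped <- character(0)
  for (i in seq_along(snps)) {
    s <- snps[i]
    if (stats::var(d[[s]]) == 0) {
      dropped <- c(dropped, s)
      next
    }
    d$.g <- d[[s]]
    f <- stats::as.formula(paste(".y ~",
      paste(c(".g", covariates), collapse = " + ")))
    fit <- .fit_one(f, d, binary, weighted)
    b <- stats::coef(fit)[".g"]
    se <- sqrt(.vcov_of(fit, weighted)[".g", ".g"])
    res[[i]] <- data.frame(
      snp = s, effect_allele = "A", other_allele = "G",
      eaf = mean(d[[s]]) / 2, beta = unname(b), se = unname(se),
      n = nrow(d))
  }
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out)) stop("all SNPs monomorphic")
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  attr(out, "variable") <- variable
  attr(out, "stratum") <- stratum
  attr(out, "ipw") <- weighted
  class(out) <- c("snp_associations", "data.frame")
  out
}

.complement_allele <- function(a)
  c(A = "T", T = "A", C = "G", G = "C")[a]

.is_palindromic <- function(a1, a2)
  paste0(a1, a2) %in% c("AT", "TA", "CG", "GC")

#' Harmonise exposure and outcome summary statistics
#'
#' Aligns the outcome associations to the exposure's effect alleles. Where
#' the outcome's effect allele equals the exposure's other allele, the
#' outcome beta is negated and its frequency complemented; strand flips
#' (A<->T, C<->G relabelling) are resolved by complementing before
#' matching. Palindromic SNPs (A/T or C/G pairs) cannot be resolved by
#' allele labels: they are aligned by effect-allele frequency when both
#' frequencies are available and lie outside `(0.42, 0.58)`, otherwise
#' dropped. SNPs whose allele pairs cannot be reconciled are dropped with
#' a reason.
#'
#' @param exposure instrument table: columns `snp`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se` (and optionally `n`).
#' @param outcome outcome-association table with the same columns.
#' @param eaf_bounds frequency window treated as ambiguous for palindromic
#'   SNPs.
#' @return data frame with one row per retained SNP: `snp`, `beta_x`,
#'   `se_x`, `beta_y`, `se_y`, `eaf_x`, `eaf_y`, `flipped`, `palindromic`;
#'   counts of flipped and dropped SNPs (with reasons) in attributes
#'   `n_flipped` and `dropped`.
#' @export
harmonize <- function(exposure, outcome, eaf_bounds = c(0.42, 0.58)) {
  shared <- intersect(exposure$snp, outcome$snp)
  if (!length(shared)) stop("no shared variant ids")
  ex <- exposure[match(shared, exposure$snp), ]
  ou <- outcome[match(shared, outcome$snp), ]
  rows <- vector("list", length(shared))
  dropped <- list()
  n_flipped <- 0L
  for (i in seq_along(shared)) {
    ea_x <- toupper(ex$effect_allele[i]); oa_x <- toupper(ex$other_allele[i])
    ea_y <- toupper(ou$effect_allele[i]); oa_y <- toupper(ou$other_allele[i])
    by <- ou$beta[i]; fy <- ou$eaf[i]
    pal <- .is_palindromic(ea_x, oa_x)
    status <- NULL
    if (pal) {
      fx <- ex$eaf[i]
      ok <- !is.na(fx) && !is.na(fy) &&
        (fx < eaf_bounds[1] || fx > eaf_bounds[2]) &&
        (fy < eaf_bounds[1] || fy > eaf_bounds[2])
      if (!ok) {
        dropped[[shared[i]]] <- "palindromic_ambiguous_eaf"
        next
      }
      if ((fx < 0.5) != (fy < 0.5)) {
        by <- -by; fy <- 1 - fy; n_flipped <- n_flipped + 1L
        status <- "flipped_by_eaf"
      } else status <- "aligned_by_eaf"
    } else if (ea_y == ea_x && oa_y == oa_x) {
      status <- "aligned"
    } else if (ea_y == oa_x && oa_y == ea_x) {
      by <- -by; fy <- 1 - fy; n_flipped <- n_flipped + 1L
      status <- "flipped"
    } else {
      ce <- .complement_allele(ea_y); co <- .complement_allele(oa_y)
      if (identical(unname(ce), ea_x) && identical(unname(co), oa_x)) {
        status <- "strand_flipped"
      } else if (identical(unname(ce), oa_x) &&
                 identical(unname(co), ea_x)) {
        by <- -by; fy <- 1 - fy; n_flipped <- n_flipped + 1L
        status <- "strand_and_effect_flipped"
      } else {
        dropped[[shared[i]]] <- "allele_mismatch"
        next
      }
    }
    rows[[i]] <- data.frame(
      snp = shared[i], beta_x = ex$beta[i], se_x = ex$se[i],
      beta_y = by, se_y = ou$se[i], eaf_x = ex$eaf[i], eaf_y = fy,
      flipped = grepl("flip", status) & !grepl("strand_flipped", status),
      palindromic = pal)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) stop("no SNPs survived harmonisation")
  rownames(out) <- NULL
  attr(out, "n_flipped") <- n_flipped
  attr(out, "dropped") <- dropped
  out
}

#' Per-SNP Wald ratio
#'
#' The building block of the IVW estimator: `theta = beta_Y / beta_X`,
#' with the first-order standard error `se_Y / |beta_X|` (uncertainty in
#' the SNP-exposure association is ignored, appropriate for strong
#' instruments).
#'
#' @param beta_x,se_x SNP-exposure association and its SE.
#' @param beta_y,se_y SNP-outcome association and its SE.
#' @return list with `theta` and `se`.
#' @export
wald_ratio <- function(beta_x, se_x, beta_y, se_y) {
  if (any(beta_x == 0))
    stop("beta_x must be non-zero (degenerate weak instrument)")
  list(theta = beta_y / beta_x, se = se_y / abs(beta_x))
}

#' Inverse-variance weighted MR estimate
#'
#' Weighted regression of the SNP-outcome associations on the
#' SNP-exposure associations through the origin with weights
#' `1 / se_Y^2`, algebraically the `beta_X^2 / se_Y^2`-weighted mean of
#' the per-SNP Wald ratios. The fixed-effect standard error is
#' `(sum beta_X^2 / se_Y^2)^(-1/2)`; the multiplicative random-effects
#' option inflates it by `max(1, sqrt(Q / (J - 1)))`. Cochran's Q
#' (heterogeneity across Wald ratios, a signal of horizontal pleiotropy)
#' is attached whenever at least two instruments are available.
#'
#' @param aligned harmonised table from [harmonize()] (columns `beta_x`,
#'   `se_x`, `beta_y`, `se_y`), or any data frame with those columns.
#' @param random_effects use the multiplicative random-effects SE.
#' @return object of class `mr_result`: per-SNP Wald ratios, `beta`,
#'   `se`, `or` with 95% CI, normal `p`, `Q`, `Q_df`, `Q_p`, model tag and
#'   `J`.
#' @export
ivw <- function(aligned, random_effects = FALSE) {
  J <- nrow(aligned)
  if (is.null(J) || J < 1) stop("no instruments")
  bx <- aligned$beta_x; by <- aligned$beta_y; sy <- aligned$se_y
  wr <- wald_ratio(bx, aligned$se_x, by, sy)
  w <- bx^2 / sy^2
  beta <- sum(bx * by / sy^2) / sum(bx^2 / sy^2)
  se_fe <- 1 / sqrt(sum(bx^2 / sy^2))
  qq <- if (J >= 2) cochran_q(aligned, beta) else
    list(Q = NA_real_, df = 0L, p = NA_real_)
  se <- se_fe
  if (random_effects && J >= 2)
    se <- se_fe * max(1, sqrt(qq$Q / (J - 1)))
  z <- beta / se
  structure(list(
    theta = wr$theta, theta_se = wr$se, weights = w,
    beta = beta, se = se,
    or = exp(beta), lo = exp(beta - 1.96 * se), hi = exp(beta + 1.96 * se),
    p = 2 * stats::pnorm(-abs(z)),
    Q = qq$Q, Q_df = qq$df, Q_p = qq$p,
    model = if (random_effects) "multiplicative_re" else "fixed",
    J = J), class = "mr_result")
}

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum_j w_j (theta_j - beta_IVW)^2` over the per-SNP Wald ratios
#' with first-order weights `w_j = beta_X_j^2 / se_Y_j^2`, referred to
#' chi-squared with `J - 1` degrees of freedom. Excess heterogeneity
#' flags potential horizontal pleiotropy.
#'
#' @param aligned harmonised table (see [ivw()]).
#' @param beta_ivw the pooled IVW estimate.
#' @return list with `Q`, `df`, `p` (`Q` is `NA` with `df = 0` when fewer
#'   than two instruments are supplied).
#' @export
cochran_q <- function(aligned, beta_ivw) {
  J <- nrow(aligned)
  if (J < 2) return(list(Q = NA_real_, df = 0L, p = NA_real_))
  theta <- aligned$beta_y / aligned$beta_x
  w <- aligned$beta_x^2 / aligned$se_y^2
  Q <- sum(w * (theta - beta_ivw)^2)
  list(Q = Q, df = J - 1L,
       p = stats::pchisq(Q, df = J - 1, lower.tail = FALSE))
}

#' Run a full MR analysis
#'
#' Orchestrates per-SNP estimation, harmonisation, IVW pooling and
#' Cochran's Q for one design/exposure/outcome cell. The IL-6 exposure
#' uses the IL6R-region instruments with log-CRP as the downstream
#' exposure readout (classic IL-6 signalling); the CRP exposure uses the
#' CRP-region instruments. In the one-sample design both SNP-exposure and
#' SNP-outcome associations are estimated in the cohort; in the
#' two-sample design the SNP-exposure side comes from an external
#' instrument table.
#'
#' @param design `"one_sample"` or `"two_sample"`.
#' @param exposure `"crp"` or `"il6"`.
#' @param outcome one of `"dep_score"`, `"anx_score"`, `"dep_dx"`,
#'   `"gad_dx"`.
#' @param cohort cohort data frame (always required: SNP-outcome
#'   associations are estimated in it).
#' @param instruments external instrument table (required for
#'   `two_sample`), as from [read_instruments()].
#' @param stratum `"all"`, `"women"` or `"men"`.
#' @param ipw optional `ipw_weights` (or numeric weights) applied to the
#'   SNP-outcome regressions.
#' @param covariates covariates of the per-SNP regressions.
#' @param random_effects passed to [ivw()].
#' @return an `mr_result` (see [ivw()]) with the harmonised table in
#'   attribute `aligned`.
#' @export
run_mr <- function(design = c("one_sample", "two_sample"),
                   exposure = c("crp", "il6"), outcome = "dep_score",
                   cohort, instruments = NULL, stratum = "all",
                   ipw = NULL, covariates = c("age", "sex"),
                   random_effects = FALSE) {
  design <- match.arg(design)
  exposure <- match.arg(exposure)
  snps <- grep(if (exposure == "crp") "^g_CRP_" else "^g_IL6R_",
               names(cohort), value = TRUE)
  if (!length(snps)) stop("no genotype columns for exposure ", exposure)
  if (design == "two_sample") {
    if (is.null(instruments))
      stop("two_sample design requires an instrument table")
    expo <- instruments[instruments$snp %in% snps, , drop = FALSE]
    if (!nrow(expo)) stop("instrument table shares no SNPs with cohort")
  } else {
    expo <- estimate_snp_associations(cohort, "log_crp", snps = snps,
                                      covariates = covariates,
                                      stratum = stratum)
  }
  outc <- estimate_snp_associations(cohort, outcome, snps = snps,
                                    covariates = covariates,
                                    stratum = stratum, weights = ipw)
  aligned <- harmonize(expo, outc)
  res <- ivw(aligned, random_effects = random_effects)
  res$design <- design
  res$exposure <- exposure
  res$outcome <- outcome
  res$stratum <- stratum
  res$ipw <- !is.null(ipw)
  attr(res, "aligned") <- aligned
  res
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf(
    "IVW MR (%s): OR %.2f (%.2f-%.2f), p = %.3g [J = %d, %s]\n",
    paste(c(x$design, x$exposure, x$outcome, x$stratum), collapse = " / "),
    x$or, x$lo, x$hi, x$p, x$J, x$model))
  if (!is.na(x$Q))
    cat(sprintf("Cochran's Q = %.2f on %d df, p = %.3g\n",
                x$Q, x$Q_df, x$Q_p))
  invisible(x)
}
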