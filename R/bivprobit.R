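# Design matrix for the joint models: intercept, log-CRP, then covariates.
.joint_design <- function(cohort, model, sex_stratum = "all") {
  covs <- model_covariates(model, stratified = sex_stratum != "all")
  d <- cohort
  for (f in intersect(c("sex", "smoking", "alcohol", "ethnicity"), covs))
    d[[f]] <- factor(d[[f]])
  d$.lc <- log(d$crp)
  f <- if (length(covs))
    stats::as.formula(paste("~ .lc +", paste(covs, collapse = " + ")))
  else stats::as.formula("~ .lc")
  X <- stats::model.matrix(f, d)
  colnames(X)[colnames(X) == ".lc"] <- "log_crp"
  X
}

#' Bivariate probit regression of two binary outcomes on CRP
#'
#' Maximises the exact bivariate-probit log-likelihood: each observation
#' contributes the orthant probability of a bivariate standard normal with
#' latent correlation `rho`, evaluated by the high-accuracy quadrature of
#' [pbvnorm()]. Optimisation is quasi-Newton (BFGS) with analytic
#' gradients, started at the two univariate probit fits and `rho = 0`.
#' With `constrain_equal = TRUE` the coefficient of the exposure column is
#' shared across the two equations (all other coefficients remain free),
#' giving the null model of the disorder-specificity likelihood-ratio
#' test.
#'
#' @param y1,y2 binary outcome vectors (depression, anxiety).
#' @param X design matrix including an intercept; the shared/exposure
#'   column is named by `exposure_col`.
#' @param exposure_col name of the exposure column of `X` (default
#'   `"log_crp"`).
#' @param constrain_equal share the exposure coefficient across equations.
#' @param max_iter maximum BFGS iterations.
#' @return object of class `bivariate_probit`: coefficient vectors
#'   `b_dep`, `b_anx`, correlation `rho`, `logLik`, `vcov` (observed
#'   information inverse, parameter order `c(b_dep, b_anx, atanh_rho)` or
#'   the constrained analogue), `convergence` diagnostics and `n`.
#' @export
fit_bivariate_probit <- function(y1, y2, X, exposure_col = "log_crp",
                                 constrain_equal = FALSE, max_iter = 200) {
  y1 <- as.integer(y1); y2 <- as.integer(y2)
  X <- as.matrix(X)
  stopifnot(length(y1) == nrow(X), length(y2) == nrow(X))
  if (!all(y1 %in% 0:1) || !all(y2 %in% 0:1))
    stop("outcomes must be binary 0/1")
  p <- ncol(X)
  if (nrow(X) <= 2 * p + 1) stop("more parameters than observations")
  xi <- match(exposure_col, colnames(X))
  if (constrain_equal && is.na(xi))
    stop("exposure column '", exposure_col, "' not found in X")

  start1 <- stats::glm.fit(X, y1,
    family = stats::binomial("probit"))$coefficients
  start2 <- stats::glm.fit(X, y2,
    family = stats::binomial("probit"))$coefficients
  if (any(abs(c(start1, start2)) > 15))
    stop("quasi-separation detected in univariate probit start")

  q1 <- 2 * y1 - 1
  q2 <- 2 * y2 - 1
  par2coef <- function(par) {
    if (!constrain_equal) {
      list(b1 = par[seq_len(p)], b2 = par[p + seq_len(p)],
           w = par[2 * p + 1])
    } else {
      bx <- par[1]
      rest <- matrix(par[1 + seq_len(2 * (p - 1))], ncol = 2)
      b1 <- numeric(p); b2 <- numeric(p)
      b1[xi] <- bx; b2[xi] <- bx
      b1[-xi] <- rest[, 1]; b2[-xi] <- rest[, 2]
      list(b1 = b1, b2 = b2, w = par[2 * p])
    }
  }
  # rho = rho_max * tanh(w): smooth everywhere, and bounded away from the
  # |rho| = 1 boundary so perfectly concordant outcomes cannot drive the
  # optimiser into degenerate orthant probabilities
  rho_max <- 0.999
  cell <- function(par) {
    cf <- par2coef(par)
    rho <- rho_max * tanh(cf$w)
    h <- q1 * drop(X %*% cf$b1)
    k <- q2 * drop(X %*% cf$b2)
    r <- q1 * q2 * rho
    P <- pmax(pbvnorm(h, k, r), 1e-300)
    list(cf = cf, rho = rho, h = h, k = k, r = r, P = P)
  }
  nll <- function(par) -sum(log(cell(par)$P))
  ngr <- function(par) {
    cl <- cell(par)
    omr <- sqrt(1 - cl$r^2)
    d1 <- q1 * stats::dnorm(cl$h) *
      stats::pnorm((cl$k - cl$r * cl$h) / omr) / cl$P
    d2 <- q2 * stats::dnorm(cl$k) *
      stats::pnorm((cl$h - cl$r * cl$k) / omr) / cl$P
    dr <- q1 * q2 * .dbvnorm(cl$h, cl$k, cl$r) / cl$P
    g1 <- drop(crossprod(X, d1))
    g2 <- drop(crossprod(X, d2))
    gw <- sum(dr) * rho_max * (1 - tanh(cl$cf$w)^2)
    if (!constrain_equal) -c(g1, g2, gw)
    else -c(g1[xi] + g2[xi], g1[-xi], g2[-xi], gw)
  }
  start <- if (!constrain_equal) c(start1, start2, 0)
  else c(mean(c(start1[xi], start2[xi])), start1[-xi], start2[-xi], 0)

  opt <- stats::optim(start, nll, ngr, method = "BFGS", hessian = TRUE,
                      control = list(maxit = max_iter, reltol = 1e-12))
  gnorm <- max(abs(ngr(opt$par)))
  if (gnorm > 1e-5 * max(1, abs(opt$value))) {
    opt2 <- stats::optim(opt$par, nll, ngr, method = "BFGS",
                         hessian = TRUE,
                         control = list(maxit = max_iter, reltol = 1e-12))
    if (opt2$value <= opt$value) opt <- opt2
    gnorm <- max(abs(ngr(opt$par)))
  }
  if (gnorm > 1e-3 * max(1, abs(opt$value)))
    stop(sprintf(paste0("bivariate probit did not converge: ",
                        "gradient max-norm %.3g after %d iterations"),
                 gnorm, max_iter))
  cf <- par2coef(opt$par)
  vc <- tryCatch(solve(opt$hessian), error = function(e) NULL)
  names(cf$b1) <- names(cf$b2) <- colnames(X)
  structure(list(
    b_dep = cf$b1, b_anx = cf$b2, rho = rho_max * tanh(cf$w),
    logLik = -opt$value, vcov = vc, constrain_equal = constrain_equal,
    exposure_col = exposure_col, n = nrow(X),
    data_id = c(n = nrow(X), s1 = sum(y1), s2 = sum(y2),
                sx = sum(X[, min(xi, p, na.rm = TRUE)])),
    convergence = list(grad_norm = gnorm, counts = opt$counts,
                       code = opt$convergence)),
    class = "bivariate_probit")
}

# standard error of the exposure coefficient(s) from the information matrix
.bp_exposure_se <- function(fit) {
  p <- length(fit$b_dep)
  xi <- match(fit$exposure_col, names(fit$b_dep))
  if (is.null(fit$vcov)) return(c(NA_real_, NA_real_))
  if (fit$constrain_equal) {
    se <- sqrt(fit$vcov[1, 1])
    c(se, se)
  } else {
    c(sqrt(fit$vcov[xi, xi]), sqrt(fit$vcov[p + xi, p + xi]))
  }
}

#' Likelihood-ratio test of disorder specificity
#'
#' Compares a joint model in which the exposure coefficient differs
#' between the depression and anxiety equations with a nested model in
#' which it is constrained equal. The statistic `2 * (ll_free -
#' ll_constrained)` is referred to a chi-squared distribution with 1
#' degree of freedom; small negative values (optimiser tolerance) are
#' clipped to zero.
#'
#' @param free,constrained fits from [fit_bivariate_probit()] (or
#'   [fit_bivariate_gaussian()]) on the same data, without and with
#'   `constrain_equal`.
#' @return object of class `specificity_result`: `LR`, `df`, `p`, the
#'   per-outcome exposure coefficients with standard errors, and
#'   probit-scale ORs via [probit_to_or()] when applicable.
#' @export
lrt_specificity <- function(free, constrained) {
  if (!isTRUE(all.equal(free$data_id, constrained$data_id)))
    stop("free and constrained fits are not from the same data")
  if (constrained$logLik > free$logLik + 1e-6)
    warning("constrained log-likelihood exceeds free log-likelihood")
  LR <- max(0, 2 * (free$logLik - constrained$logLik))
  pval <- stats::pchisq(LR, df = 1, lower.tail = FALSE)
  xi <- match(free$exposure_col, names(free$b_dep))
  b <- c(dep = unname(free$b_dep[xi]), anx = unname(free$b_anx[xi]))
  se <- .bp_exposure_se(free)
  or <- if (inherits(free, "bivariate_probit"))
    list(dep = probit_to_or(b[["dep"]], se[1]),
         anx = probit_to_or(b[["anx"]], se[2]))
  else NULL
  structure(list(LR = LR, df = 1L, p = pval, coef = b, se = se,
                 or = or, rho = free$rho,
                 analysis = if (inherits(free, "bivariate_probit"))
                   "categorical" else "continuous"),
            class = "specificity_result")
}

#' Convert a probit coefficient to an odds ratio
#'
#' Multiplies the probit parameter by 1.6 (the logit/probit scale factor)
#' and exponentiates; the 95% CI applies the same transformation to
#' `b +- 1.96 se`.
#'
#' @param b probit coefficient.
#' @param se its standard error (`>= 0`).
#' @return named vector `or`, `lo`, `hi`.
#' @export
probit_to_or <- function(b, se) {
  if (any(se < 0, na.rm = TRUE)) stop("se must be non-negative")
  c(or = exp(1.6 * b), lo = exp(1.6 * (b - 1.96 * se)),
    hi = exp(1.6 * (b + 1.96 * se)))
}

#' Bivariate Gaussian (seemingly-unrelated) regression on transformed scores
#'
#' Continuous-outcome analogue of [fit_bivariate_probit()]: the two
#' transformed symptom scores are modelled jointly as bivariate normal
#' with a common design matrix. The free fit is equation-wise OLS with the
#' MLE residual covariance; the constrained fit (shared exposure
#' coefficient) is obtained by iterated feasible GLS, which converges to
#' the constrained MLE. Log-likelihoods are exact Gaussian, so the same
#' [lrt_specificity()] machinery applies.
#'
#' @inheritParams fit_bivariate_probit
#' @param y1,y2 continuous outcome vectors (e.g. `log(score + 1)`).
#' @return object of class `bivariate_gaussian` with the same essential
#'   fields as [fit_bivariate_probit()].
#' @export
fit_bivariate_gaussian <- function(y1, y2, X, exposure_col = "log_crp",
                                   constrain_equal = FALSE,
                                   max_iter = 50) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  xi <- match(exposure_col, colnames(X))
  if (is.na(xi)) stop("exposure column '", exposure_col, "' not found")
  loglik <- function(r1, r2, S) {
    Si <- solve(S)
    q <- Si[1, 1] * r1^2 + 2 * Si[1, 2] * r1 * r2 + Si[2, 2] * r2^2
    -n * log(2 * pi) - n / 2 * log(det(S)) - sum(q) / 2
  }
  if (!constrain_equal) {
    f1 <- stats::lm.fit(X, y1)
    f2 <- stats::lm.fit(X, y2)
    b1 <- f1$coefficients; b2 <- f2$coefficients
    r1 <- f1$residuals; r2 <- f2$residuals
    S <- crossprod(cbind(r1, r2)) / n
  } else {
    b1 <- stats::lm.fit(X, y1)$coefficients
    b2 <- stats::lm.fit(X, y2)$coefficients
    bx <- mean(c(b1[xi], b2[xi]))
    S <- diag(2)
    Z <- X[, -xi, drop = FALSE]
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      b1[xi] <- bx; b2[xi] <- bx
      r1 <- y1 - drop(X %*% b1)
      r2 <- y2 - drop(X %*% b2)
      S <- crossprod(cbind(r1, r2)) / n
      C <- chol(solve(S))
      ystar <- c(C[1, 1] * y1 + C[1, 2] * y2, C[2, 2] * y2)
      xcol <- c((C[1, 1] + C[1, 2]) * X[, xi], C[2, 2] * X[, xi])
      Zblk <- rbind(cbind(C[1, 1] * Z, C[1, 2] * Z),
                    cbind(0 * Z, C[2, 2] * Z))
      fit <- stats::lm.fit(cbind(xcol, Zblk), ystar)
      cf <- fit$coefficients
      bx <- cf[1]
      b1[-xi] <- cf[1 + seq_len(p - 1)]
      b2[-xi] <- cf[p + seq_len(p - 1)]
      b1[xi] <- bx; b2[xi] <- bx
      r1 <- y1 - drop(X %*% b1)
      r2 <- y2 - drop(X %*% b2)
      S <- crossprod(cbind(r1, r2)) / n
      ll_new <- loglik(r1, r2, S)
      if (abs(ll_new - ll_old) < 1e-10 * max(1, abs(ll_new))) break
      ll_old <- ll_new
    }
  }
  ll <- loglik(y1 - drop(X %*% b1), y2 - drop(X %*% b2), S)
  # large-sample SE of the exposure coefficients (free fit: SUR = OLS)
  XtXi <- solve(crossprod(X))
  se <- sqrt(c(S[1, 1], S[2, 2]) * XtXi[xi, xi])
  names(b1) <- names(b2) <- colnames(X)
  structure(list(
    b_dep = b1, b_anx = b2,
    rho = S[1, 2] / sqrt(S[1, 1] * S[2, 2]), sigma = S,
    logLik = ll, exposure_se = se, constrain_equal = constrain_equal,
    exposure_col = exposure_col, n = n,
    data_id = c(n = n, s1 = sum(y1), s2 = sum(y2), sx = sum(X[, xi])),
    convergence = list(grad_norm = 0, counts = NA, code = 0L)),
    class = "bivariate_gaussian")
}

#' Disorder-specificity test of the CRP association
#'
#' High-level wrapper: builds the joint design for the requested
#' adjustment model, fits the free and exposure-constrained joint models
#' (bivariate probit for probable diagnoses, bivariate Gaussian for
#' transformed symptom scores) and returns the likelihood-ratio test of
#' equality of the CRP coefficients.
#'
#' @param cohort cohort data frame.
#' @param outcomes `"categorical"` (probable diagnoses, PHQ-9 >= 10 and
#'   GAD-7 >= 10) or `"continuous"` (log-transformed scores).
#' @param model adjustment model 1-4.
#' @return a `specificity_result` (see [lrt_specificity()]) with the two
#'   fits attached as attributes `free` and `constrained`.
#' @export
specificity_test <- function(cohort, outcomes = c("categorical",
                                                  "continuous"),
                             model = 4) {
  outcomes <- match.arg(outcomes)
  X <- .joint_design(cohort, model)
  if (outcomes == "categorical") {
    y1 <- as.integer(cohort$dep_score >= 10)
    y2 <- as.integer(cohort$anx_score >= 10)
    free <- fit_bivariate_probit(y1, y2, X)
    con <- fit_bivariate_probit(y1, y2, X, constrain_equal = TRUE)
  } else {
    y1 <- transform_outcome(cohort$dep_score)
    y2 <- transform_outcome(cohort$anx_score)
    free <- fit_bivariate_gaussian(y1, y2, X)
    con <- fit_bivariate_gaussian(y1, y2, X, constrain_equal = TRUE)
  }
  res <- lrt_specificity(free, con)
  attr(res, "free") <- free
  attr(res, "constrained") <- con
  res
}

.bg_exposure_se <- function(fit) fit$exposure_se

#' Mutual adjustment of the depression and anxiety models
#'
#' Re-fits the CRP association for each outcome additionally adjusting for
#' the other disorder's symptom score, a complementary test of disorder
#' specificity: a specific association survives adjustment for the
#' comorbid score, a shared one does not.
#'
#' @param cohort cohort data frame.
#' @param model adjustment model 1-4.
#' @param outcomes `"continuous"` (transformed scores, linear model) or
#'   `"categorical"` (probable diagnoses, logistic model).
#' @return list with elements `dep` and `anx`, each `or`, `lo`, `hi`, `p`
#'   for the log-CRP coefficient after mutual adjustment.
#' @export
mutual_adjustment <- function(cohort, model = 4,
                              outcomes = c("continuous", "categorical")) {
  outcomes <- match.arg(outcomes)
  one <- function(out, other_col) {
    d <- cohort
    d$.other <- d[[other_col]]
    covs <- model_covariates(model)
    for (f in intersect(c("sex", "smoking", "alcohol", "ethnicity"), covs))
      d[[f]] <- factor(d[[f]])
    d$.lc <- log(d$crp)
    spec <- .outcome_spec(out)
    d$.y <- if (outcomes == "categorical")
      as.integer(d[[spec$col]] >= 10) else transform_outcome(d[[spec$col]])
    other_term <- if (stats::var(d$.other) > 0) ".other" else NULL
    f <- stats::as.formula(paste(".y ~",
      paste(c(".lc", other_term, covs), collapse = " + ")))
    fit <- if (outcomes == "categorical")
      stats::glm(f, data = d, family = stats::binomial())
    else stats::lm(f, data = d)
    b <- stats::coef(fit)[".lc"]
    se <- sqrt(stats::vcov(fit)[".lc", ".lc"])
    list(or = exp(unname(b)), lo = exp(unname(b - 1.96 * se)),
         hi = exp(unname(b + 1.96 * se)),
         p = unname(2 * stats::pnorm(-abs(b / se))))
  }
  list(dep = one("dep_score", "anx_score"),
       anx = one("anx_score", "dep_score"))
}
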