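# Shared fixtures, all generated in code.

# small default cohort reused by several tests
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_cohort(sim_config(n_participants = 30000,
                                           seed = 42))
    cache
  }
})

# independent oracle for the bivariate normal CDF: conditional-probability
# reduction evaluated by adaptive 1-D quadrature
pbvnorm_oracle <- function(x, y, rho) {
  stats::integrate(function(t)
    stats::dnorm(t) * stats::pnorm((y - rho * t) / sqrt(1 - rho^2)),
    -Inf, x, rel.tol = 1e-12, abs.tol = 1e-14)$value
}

# genuinely 2-D quadrature of the bivariate normal density over
# (-inf, x] x (-inf, y]: outer integral of an inner integral
pbvnorm_oracle_2d <- function(x, y, rho) {
  inner <- function(t, y)
    vapply(t, function(ti) stats::integrate(function(s)
      inflamr:::.dbvnorm(ti, s, rho), -8.5, y,
      rel.tol = 1e-11)$value, numeric(1))
  stats::integrate(inner, -8.5, x, y = y, rel.tol = 1e-10)$value
}

# minimal cohort data frame for regression-level tests that do not need
# the full generator
toy_cohort <- function(n, crp, dep_score = NULL, anx_score = NULL,
                       sex = NULL, seed = 1) {
  set.seed(seed)
  data.frame(
    participant_id = seq_len(n),
    age = stats::rnorm(n, 56, 8),
    sex = if (is.null(sex)) sample(c("female", "male"), n, TRUE) else sex,
    bmi = stats::rnorm(n, 27, 4),
    smoking = sample(c("never", "current", "ex"), n, TRUE),
    alcohol = sample(c("never_ex", "occasional", "regular"), n, TRUE),
    activity = sample(1:4, n, TRUE),
    ethnicity = sample(c("white", "other"), n, TRUE, prob = c(0.97, 0.03)),
    tdi = stats::rnorm(n, -1.7, 2.8),
    diabetes = stats::rbinom(n, 1, 0.03),
    cvd = stats::rbinom(n, 1, 0.04),
    crp = crp,
    dep_score = if (is.null(dep_score))
      pmin(stats::rpois(n, 2.7), 27L) else dep_score,
    anx_score = if (is.null(anx_score))
      pmin(stats::rpois(n, 2.1), 21L) else anx_score)
}
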