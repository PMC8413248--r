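#' Floating absolute risks from a covariance matrix of log-ORs
#'
#' Assigns a "floated" variance to every exposure group, including the
#' reference, such that `Var(beta_i - beta_j) ~ lambda_i + lambda_j` for
#' all pairs. Confidence intervals built from the floated variances no
#' longer share the reference group's uncertainty, so any two groups can
#' be compared directly on a dose-response plot.
#'
#' Two estimators are available. `"mean"` (default) is the
#' compound-symmetry heuristic: `lambda_0` is the mean of the off-diagonal
#' elements of `V` (the variance component shared through the reference)
#' and `lambda_k = V[k, k] - lambda_0`. For an exactly compound-symmetric
#' `V` (constant off-diagonal `c`) this recovers `lambda_0 = c`,
#' `lambda_k = V[k, k] - c` exactly. `"ls"` refines the assignment by
#' unweighted least squares over all pairs (reference included),
#' minimising `sum_{i<j} [(lambda_i + lambda_j) - Var(beta_i - beta_j)]^2`.
#'
#' @param V covariance matrix (dimension `K - 1`) of the non-reference
#'   log-OR contrasts, or a scalar variance when `K = 2` (in which case
#'   `lambda_0 = 0` and the conventional CI is reproduced).
#' @param method `"mean"` or `"ls"`.
#' @param eps floor applied to each floated variance.
#' @return list with `lambda` (length `K`, first element = reference),
#'   `lambda0`, `n_floored` (count of variances raised to `eps`, a
#'   recorded warning condition) and `method`.
#' @export
floated_variances <- function(V, method = c("mean", "ls"), eps = 1e-12) {
  method <- match.arg(method)
  V <- as.matrix(V)
  if (nrow(V) != ncol(V) || any(abs(V - t(V)) > 1e-8 * (1 + max(abs(V)))))
    stop("V must be a symmetric matrix")
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    stop("V must be positive semi-definite")
  m <- nrow(V)
  if (m == 1L || method == "mean") {
    lambda0 <- if (m == 1L) 0 else mean(V[upper.tri(V)])
    lambda <- c(lambda0, diag(V) - lambda0)
  } else {
    # unknowns lambda_0..lambda_m; rows: one per pair (i, j), i < j,
    # including the reference (index 0), target Var(beta_i - beta_j)
    idx <- utils::combn(0:m, 2)
    A <- matrix(0, ncol(idx), m + 1)
    d <- numeric(ncol(idx))
    for (r in seq_len(ncol(idx))) {
      i <- idx[1, r]; j <- idx[2, r]
      A[r, i + 1] <- 1; A[r, j + 1] <- 1
      d[r] <- if (i == 0) V[j, j] else V[i, i] + V[j, j] - 2 * V[i, j]
    }
    lambda <- drop(solve(crossprod(A), crossprod(A, d)))
  }
  n_floored <- sum(lambda < eps)
  lambda <- pmax(lambda, eps)
  list(lambda = unname(lambda), lambda0 = lambda[1],
       n_floored = n_floored, method = method)
}

floated_ci <- function(beta, lambda, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  cbind(or = exp(beta),
        lo = exp(beta - z * sqrt(lambda)),
        hi = exp(beta + z * sqrt(lambda)))
}
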