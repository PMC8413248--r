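#' Divide CRP concentrations into quantile groups
#'
#' Computes empirical quantile cut points (quintiles, deciles, ...) of the
#' analysis sample and assigns every value to a group. Group `k` holds the
#' values in `(cut[k-1], cut[k]]`: ties at a cut point go to the lower
#' group. Cut points are type-1 empirical quantiles, so for `1:10` with
#' `K = 5` the cut points are exactly 2, 4, 6, 8.
#'
#' @param crp vector of positive CRP concentrations (mg/L).
#' @param K number of groups (5 for quintiles, 10 for deciles).
#' @return object of class `quantile_assignment`: list with `K`,
#'   `cut_points` (length `K - 1`, strictly increasing), `group_index`
#'   (integer 1..K per value), `group_medians` (mg/L) and `group_n`.
#' @examples
#' qa <- assign_quantiles(c(0.3, 0.8, 1.4, 2.4, 5.5, 0.5, 1.1, 2.0), K = 4)
#' qa$cut_points
#' @export
assign_quantiles <- function(crp, K) {
  crp <- as.numeric(crp)
  if (anyNA(crp) || any(crp <= 0)) stop("all crp values must be positive")
  K <- as.integer(K)
  if (K < 2) stop("K must be at least 2")
  if (K > length(unique(crp)))
    stop("K exceeds the number of distinct CRP values")
  cut_points <- unname(stats::quantile(crp, probs = seq_len(K - 1) / K,
                                       type = 1))
  if (any(diff(cut_points) <= 0))
    stop("quantile cut points are not strictly increasing (too many ties)")
  idx <- quantile_group(crp, cut_points)
  structure(list(
    K = K,
    cut_points = cut_points,
    group_index = idx,
    group_medians = as.numeric(tapply(crp, idx, stats::median)),
    group_n = as.integer(tabulate(idx, nbins = K))),
    class = "quantile_assignment")
}

#' Classify values against existing quantile cut points
#'
#' @param x positive values to classify.
#' @param cut_points strictly increasing cut points, or a
#'   `quantile_assignment` object.
#' @return integer group index 1..K; ties at a cut point fall in the lower
#'   group.
#' @export
quantile_group <- function(x, cut_points) {
  if (inherits(cut_points, "quantile_assignment"))
    cut_points <- cut_points$cut_points
  findInterval(x, cut_points, left.open = TRUE) + 1L
}

#' Log transform of a symptom sum-score
#'
#' Returns `log(score + 1)`; regression coefficients for this outcome are
#' exponentiated and reported as OR-style ratios, matching the convention
#' of anti-logging coefficients from linear models of symptom scores.
#'
#' @param score non-negative integer score(s).
#' @return numeric vector `log(score + 1)`.
#' @export
transform_outcome <- function(score) {
  if (any(score < 0, na.rm = TRUE)) stop("scores must be non-negative")
  log1p(score)
}
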