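# 20-point Gauss-Legendre nodes/weights on (-1, 1), upper half.
.gl20_x <- c(
  0.9931285991850949, 0.9639719272779138, 0.9122344282513259,
  0.8391169718222188, 0.7463319064601508, 0.6360536807265150,
  0.5108670019508271, 0.3737060887154195, 0.2277858511416451,
  0.07652652113349734)
.gl20_w <- c(
  0.01761400713915212, 0.04060142980038694, 0.06267204833410907,
  0.08327674157670475, 0.10193011981724040, 0.11819453196151840,
  0.13168863844917660, 0.14209610931838200, 0.14917298647260370,
  0.15275338713072580)

#' Bivariate standard normal distribution function
#'
#' Computes `P(Z1 <= x, Z2 <= y)` for a standard bivariate normal vector with
#' correlation `rho`, vectorised over all three arguments. Uses the
#' Gauss-Legendre quadrature scheme of Genz (2004), accurate to about
#' `1e-15` for moderate correlations and better than `1e-10` for
#' `|rho|` close to 1, which makes it suitable as the cell-probability
#' engine of a bivariate probit likelihood.
#'
#' @param x,y numeric vectors of upper limits.
#' @param rho numeric vector of correlations in `(-1, 1)`; values of
#'   exactly `+-1` are handled as the degenerate comonotone limits.
#' @return numeric vector of probabilities.
#' @examples
#' pbvnorm(0, 0, 0.5)        # 1/4 + asin(0.5) / (2 * pi)
#' pbvnorm(1.96, 1.96, 0)    # pnorm(1.96)^2
#' @export
pbvnorm <- function(x, y, rho) {
  n <- max(length(x), length(y), length(rho))
  x <- rep_len(as.numeric(x), n)
  y <- rep_len(as.numeric(y), n)
  rho <- rep_len(as.numeric(rho), n)
  if (any(!is.finite(rho)) || any(abs(rho) > 1))
    stop("rho must lie in [-1, 1]")
  p <- numeric(n)
  deg <- abs(rho) == 1
  if (any(deg)) {
    up <- deg & rho == 1
    dn <- deg & rho == -1
    p[up] <- stats::pnorm(pmin(x[up], y[up]))
    p[dn] <- pmax(0, stats::pnorm(x[dn]) + stats::pnorm(y[dn]) - 1)
  }
  i <- which(!deg)
  if (length(i)) p[i] <- .bvnd(-x[i], -y[i], rho[i])
  pmin(pmax(p, 0), 1)
}

# Genz (2004) BVND: P(Z1 > h, Z2 > k); vectorised port of the TVPACK
# reference algorithm. Called with h = -x, k = -y to give the lower orthant.
.bvnd <- function(h, k, r) {
  n <- length(h)
  bvn <- numeric(n)
  lo <- abs(r) < 0.925
  if (any(lo)) {
    hh <- h[lo]; kk <- k[lo]; rr <- r[lo]
    hk <- hh * kk
    hs <- (hh * hh + kk * kk) / 2
    asr <- asin(rr)
    acc <- 0
    for (j in seq_along(.gl20_x)) {
      for (s in c(-1, 1)) {
        sn <- sin(asr * (s * .gl20_x[j] + 1) / 2)
        acc <- acc + .gl20_w[j] * exp((sn * hk - hs) / (1 - sn * sn))
      }
    }
    bvn[lo] <- acc * asr / (4 * pi) +
      stats::pnorm(-hh) * stats::pnorm(-kk)
  }
  hi <- !lo
  if (any(hi)) {
    hh <- h[hi]; kk <- k[hi]; rr <- r[hi]
    neg <- rr < 0
    kk[neg] <- -kk[neg]
    hk <- hh * kk
    as_ <- (1 - rr) * (1 + rr)
    a <- sqrt(as_)
    bs <- (hh - kk)^2
    cc <- (4 - hk) / 8
    dd <- (12 - hk) / 16
    asr <- -(bs / as_ + hk) / 2
    b0 <- ifelse(asr > -100,
      a * exp(asr) * (1 - cc * (bs - as_) * (1 - dd * bs / 5) / 3 +
                        cc * dd * as_ * as_ / 5),
      0)
    b <- sqrt(bs)
    b0 <- b0 - ifelse(-hk < 100,
      exp(-hk / 2) * sqrt(2 * pi) * stats::pnorm(-b / a) * b *
        (1 - cc * bs * (1 - dd * bs / 5) / 3),
      0)
    a2 <- a / 2
    for (j in seq_along(.gl20_x)) {
      for (s in c(-1, 1)) {
        xs <- (a2 * (s * .gl20_x[j] + 1))^2
        rs <- sqrt(1 - xs)
        asr1 <- -(bs / xs + hk) / 2
        term <- ifelse(asr1 > -100,
          a2 * .gl20_w[j] * exp(asr1) *
            (exp(-hk * (1 - rs) / (2 * (1 + rs))) / rs -
               (1 + cc * xs * (1 + dd * xs))),
          0)
        b0 <- b0 + term
      }
    }
    b0 <- -b0 / (2 * pi)
    pos <- !neg
    b0[pos] <- b0[pos] + stats::pnorm(-pmax(hh[pos], kk[pos]))
    if (any(neg)) {
      bn <- -b0[neg]
      hn <- hh[neg]; kn <- kk[neg]
      add <- kn > hn
      if (any(add)) {
        hi_ <- hn[add]; ki_ <- kn[add]
        bn[add] <- bn[add] + ifelse(hi_ < 0,
          stats::pnorm(ki_) - stats::pnorm(hi_),
          stats::pnorm(-hi_) - stats::pnorm(-ki_))
      }
      b0[neg] <- bn
    }
    bvn[hi] <- b0
  }
  bvn
}

# Bivariate standard normal density at (x, y) with correlation rho.
.dbvnorm <- function(x, y, rho) {
  omr <- 1 - rho^2
  exp(-(x^2 - 2 * rho * x * y + y^2) / (2 * omr)) / (2 * pi * sqrt(omr))
}
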