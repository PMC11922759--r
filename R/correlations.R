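# Latent-correlation estimators for mixed-type exposure pairs:
# Pearson (continuous-continuous), polyserial (continuous-ordinal) and
# polychoric/tetrachoric (ordinal-ordinal, incl. binary) correlations,
# all on the two-step maximum-likelihood scheme: thresholds fixed from the
# marginal frequencies, rho maximized on the profile likelihood.

# Standard bivariate normal upper-orthant probability P(X > h, Y > k),
# Gauss-Legendre quadrature with a series branch for |rho| near 1
# (Drezner-Wesolowsky / Genz). Scalar in (h, k), accurate to ~1e-14.
bvnu <- function(h, k, rho) {
  if (is.infinite(h) && h > 0) return(0)
  if (is.infinite(k) && k > 0) return(0)
  if (is.infinite(h)) return(if (is.infinite(k)) 1 else stats::pnorm(-k))
  if (is.infinite(k)) return(stats::pnorm(-h))
  if (rho == 0) return(stats::pnorm(-h) * stats::pnorm(-k))
  twopi <- 2 * pi
  ar <- abs(rho)
  if (ar < 0.3) {
    w <- c(0.1713244923791705, 0.3607615730481384, 0.4679139345726904)
    x <- c(0.9324695142031522, 0.6612093864662647, 0.2386191860831970)
  } else if (ar < 0.75) {
    w <- c(0.04717533638651177, 0.1069393259953183, 0.1600783285433464,
           0.2031674267230659, 0.2334925365383547, 0.2491470458134029)
    x <- c(0.9815606342467191, 0.9041172563704750, 0.7699026741943050,
           0.5873179542866171, 0.3678314989981802, 0.1252334085114692)
  } else {
    w <- c(0.01761400713915212, 0.04060142980038694, 0.06267204833410906,
           0.08327674157670475, 0.1019301198172404, 0.1181945319615184,
           0.1316886384491766, 0.1420961093183821, 0.1491729864726037,
           0.1527533871307259)
    x <- c(0.9931285991850949, 0.9639719272779138, 0.9122344282513259,
           0.8391169718222188, 0.7463319064601508, 0.6360536807265150,
           0.5108670019508271, 0.3737060887154196, 0.2277858511416451,
           0.07652652113349733)
  }
  hk <- h * k
  bvn <- 0
  if (ar < 0.925) {
    hs <- (h * h + k * k) / 2
    asr <- asin(rho)
    sn1 <- sin(asr * (1 - x) / 2)
    sn2 <- sin(asr * (1 + x) / 2)
    bvn <- sum(w * exp((sn1 * hk - hs) / (1 - sn1^2))) +
      sum(w * exp((sn2 * hk - hs) / (1 - sn2^2)))
    bvn <- bvn * asr / (2 * twopi) + stats::pnorm(-h) * stats::pnorm(-k)
  } else {
    if (rho < 0) {
      k <- -k
      hk <- -hk
    }
    if (ar < 1) {
      as_ <- (1 - rho) * (1 + rho)
      a <- sqrt(as_)
      bs <- (h - k)^2
      cc <- (4 - hk) / 8
      d <- (12 - hk) / 16
      asr <- -(bs / as_ + hk) / 2
      if (asr > -100) {
        bvn <- a * exp(asr) *
          (1 - cc * (bs - as_) * (1 - d * bs / 5) / 3 + cc * d * as_^2 / 5)
      }
      if (-hk < 100) {
        b <- sqrt(bs)
        sp <- sqrt(twopi) * stats::pnorm(-b / a)
        bvn <- bvn - exp(-hk / 2) * sp * b * (1 - cc * bs * (1 - d * bs / 5) / 3)
      }
      a <- a / 2
      for (i in seq_along(x)) {
        for (is in c(-1, 1)) {
          xs <- (a * (is * x[i] + 1))^2
          rs <- sqrt(1 - xs)
          asr <- -(bs / xs + hk) / 2
          if (asr > -100) {
            sp <- 1 + cc * xs * (1 + d * xs)
            ep <- exp(-hk * (1 - rs) / (2 * (1 + rs))) / rs
            bvn <- bvn + a * w[i] * exp(asr) * (ep - sp)
          }
        }
      }
      bvn <- -bvn / twopi
    }
    if (rho > 0) bvn <- bvn + stats::pnorm(-max(h, k))
    if (rho < 0) bvn <- -bvn + max(0, stats::pnorm(-h) - stats::pnorm(-k))
  }
  max(0, min(1, bvn))
}

# P(X <= h, Y <= k) for standard bivariate normal with correlation rho.
pbvnorm <- function(h, k, rho) bvnu(-h, -k, rho)

# Thresholds from marginal category frequencies of an ordinal vector.
ordinal_thresholds <- function(x) {
  x <- x[!is.na(x)]
  tab <- table(x)
  if (length(tab) < 2) {
    stop_("ordinal column with a single observed level: ",
          deparse(substitute(x)))
  }
  stats::qnorm(cumsum(tab / sum(tab)))[-length(tab)]
}

# Rectangle probabilities for all cells given row/col thresholds and rho.
cell_probs <- function(rt, ct, rho) {
  ra <- c(-Inf, rt, Inf)
  ca <- c(-Inf, ct, Inf)
  fr <- outer(ra, ca, Vectorize(function(a, b) pbvnorm(a, b, rho)))
  nr <- length(ra) - 1
  nc <- length(ca) - 1
  fr[2:(nr + 1), 2:(nc + 1), drop = FALSE] -
    fr[1:nr, 2:(nc + 1), drop = FALSE] -
    fr[2:(nr + 1), 1:nc, drop = FALSE] +
    fr[1:nr, 1:nc, drop = FALSE]
}

#' Polychoric correlation of two ordinal variables
#'
#' Two-step maximum-likelihood estimate of the latent bivariate-normal
#' correlation underlying a pair of ordered categorical variables (the
#' tetrachoric correlation when both are binary). Thresholds are fixed at
#' the normal quantiles of the marginal category frequencies; the
#' correlation maximizes the resulting multinomial profile likelihood.
#'
#' @param x,y ordinal vectors (integer codes or factors); pairwise-complete
#'   rows are used.
#' @return the estimated latent correlation, a single number in (-1, 1).
#' @examples
#' z1 <- rnorm(500); z2 <- 0.5 * z1 + sqrt(0.75) * rnorm(500)
#' polychoric(z1 > 0, z2 > 0)
#' @export
polychoric <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    stop_("polychoric needs at least two observed levels in each variable")
  }
  tab <- table(x, y)
  rt <- stats::qnorm(cumsum(rowSums(tab)) / sum(tab))[-nrow(tab)]
  ct <- stats::qnorm(cumsum(colSums(tab)) / sum(tab))[-ncol(tab)]
  nll <- function(rho) {
    p <- cell_probs(rt, ct, rho)
    -sum(tab * log(pmax(p, 1e-12)))
  }
  stats::optimize(nll, c(-0.999, 0.999))$minimum
}

#' Polyserial correlation of a continuous and an ordinal variable
#'
#' Two-step maximum-likelihood estimate of the latent correlation between a
#' continuous variable and the normal variable assumed to underlie an
#' ordered categorical one. The continuous margin is standardized, ordinal
#' thresholds are fixed from the marginal frequencies, and the correlation
#' maximizes the conditional profile likelihood.
#'
#' @param x continuous vector.
#' @param y ordinal vector (integer codes or factor).
#' @return the estimated latent correlation in (-1, 1).
#' @export
polyserial <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  if (length(unique(y)) < 2) {
    stop_("polyserial needs at least two observed levels in the ordinal variable")
  }
  z <- standardize(x)
  yf <- as.integer(factor(y))
  tau <- c(-Inf, ordinal_thresholds(yf), Inf)
  lo <- tau[yf]
  hi <- tau[yf + 1L]
  nll <- function(rho) {
    s <- sqrt(1 - rho^2)
    p <- stats::pnorm((hi - rho * z) / s) - stats::pnorm((lo - rho * z) / s)
    -sum(log(pmax(p, 1e-12)))
  }
  stats::optimize(nll, c(-0.999, 0.999))$minimum
}
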