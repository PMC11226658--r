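#' Aspect-ratio distributions
#'
#' Two one-parameter laws describe rescaled cell aspect ratios in confluent
#' monolayers. The k-gamma law is a gamma distribution constrained to unit
#' mean,
#' \deqn{P(x; k) = \frac{k^k}{\Gamma(k)} x^{k-1} e^{-kx},}
#' with variance 1/k. The mean-field law for the raw aspect ratio AR >= 1 of
#' closed-loop cells in a confluent tiling is
#' \deqn{P(AR; \alpha) = \frac{1}{\mathcal{N}(\alpha)}
#'   \left(AR + \frac{1}{AR}\right)^{3/2}
#'   \left(1 - \frac{1}{AR^2}\right) e^{-\alpha (AR + 1/AR)},}
#' with a single system-specific parameter alpha and normalization
#' \eqn{\mathcal{N}(\alpha)} computed by adaptive quadrature.
#'
#' @name ar-distributions
NULL

#' k-gamma density
#'
#' @param x quantile(s), >= 0.
#' @param k shape parameter, > 0; the variance of the law is 1/k.
#' @param log return log-density.
#' @return density values.
#' @export
dkgamma <- function(x, k, log = FALSE) {
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k <= 0) {
    stop("parameter-domain error: k must be a positive scalar")
  }
  stats::dgamma(x, shape = k, rate = k, log = log)
}

#' Draw from the k-gamma law
#'
#' @param n sample size.
#' @param k shape parameter, > 0.
#' @param seed optional integer seed for reproducibility.
#' @return numeric vector of n unit-mean gamma draws.
#' @export
sample_kgamma <- function(n, k, seed = NULL) {
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k <= 0) {
    stop("parameter-domain error: k must be a positive scalar")
  }
  stopifnot(n >= 1L)
  if (!is.null(seed)) set.seed(seed)
  stats::rgamma(n, shape = k, rate = k)
}

.mf_h <- function(ar) ar + 1 / ar

## unnormalized mean-field density on [1, Inf), with the exponent minimum
## (h = 2 at AR = 1) factored out so large alpha does not underflow; every
## internal ratio (density, moments, likelihood) uses this scaled form
## consistently, and the true normalization is recovered as z * exp(-2 alpha)
.mf_unnorm <- function(ar, alpha) {
  ifelse(ar < 1, 0,
         (ar + 1 / ar)^1.5 * (1 - 1 / ar^2) *
           exp(-alpha * (ar + 1 / ar - 2)))
}

## upper integration limit such that the neglected tail mass is < tail_mass
## (relative). The tail of the unnormalized density is bounded by
## C * ar^1.5 * exp(-alpha * ar); we grow the limit until the bound is met.
.mf_upper <- function(alpha, tail_mass = 1e-10) {
  u <- 1 + max(10, 30 / alpha)
  repeat {
    ## bound on int_u^Inf t^1.5 exp(-alpha t) dt via gamma tail
    tail <- (2^1.5) * stats::pgamma(u, shape = 2.5, rate = alpha,
                                    lower.tail = FALSE) *
      gamma(2.5) / alpha^2.5
    core <- .mf_unnorm(1 + 1 / alpha, alpha)  # scale of the bulk
    if (tail <= tail_mass * max(core / alpha, .Machine$double.xmin)) break
    u <- u * 1.5
    if (u > 1e6 / alpha + 1e6) break
  }
  u
}

.mf_quad <- function(f, alpha, lower = 1, upper = NULL) {
  if (is.null(upper)) upper <- .mf_upper(alpha)
  r <- stats::integrate(f, lower, upper, rel.tol = 1e-11, abs.tol = 1e-13,
                        subdivisions = 400L)
  if (r$message != "OK") {
    stop("numerical error: quadrature failed (", r$message, ")")
  }
  r$value
}

#' Normalization constant of the mean-field aspect-ratio law
#'
#' @param alpha system-specific parameter, > 0.
#' @return \eqn{\mathcal{N}(\alpha)}, the integral of the unnormalized
#'   density over AR in \[1, Inf).
#' @export
meanfield_norm <- function(alpha) {
  .check_alpha(alpha)
  .mf_z(alpha) * exp(-2 * alpha)
}

## scaled normalization (exponent minimum factored out)
.mf_z <- function(alpha) {
  .mf_quad(function(a) .mf_unnorm(a, alpha), alpha)
}

.check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0) {
    stop("parameter-domain error: alpha must be a positive scalar")
  }
}

#' Mean-field aspect-ratio density
#'
#' @param ar aspect ratio(s), >= 1.
#' @param alpha system-specific parameter, > 0.
#' @param log return log-density.
#' @return density values; 0 at ar = 1 (the law vanishes for circular cells).
#' @export
dmeanfield <- function(ar, alpha, log = FALSE) {
  .check_alpha(alpha)
  if (any(ar < 1, na.rm = TRUE)) {
    stop("parameter-domain error: aspect ratios must be >= 1")
  }
  z <- .mf_z(alpha)
  d <- .mf_unnorm(ar, alpha) / z
  if (log) base::log(d) else d
}

#' Mean and standard deviation of the mean-field aspect-ratio law
#'
#' Both moments are functions of alpha alone; computed by adaptive quadrature
#' on \[1, AR_max(alpha)\] with AR_max chosen so the truncated tail mass is
#' below 1e-10.
#'
#' @param alpha system-specific parameter, > 0.
#' @return named numeric vector `c(mean_ar, sd_ar)`.
#' @export
meanfield_moments <- function(alpha) {
  .check_alpha(alpha)
  upper <- .mf_upper(alpha)
  z <- .mf_quad(function(a) .mf_unnorm(a, alpha), alpha, upper = upper)
  m1 <- .mf_quad(function(a) a * .mf_unnorm(a, alpha), alpha, upper = upper) / z
  v <- .mf_quad(function(a) (a - m1)^2 * .mf_unnorm(a, alpha), alpha,
                upper = upper) / z
  c(mean_ar = m1, sd_ar = sqrt(v))
}

#' Expected value of AR + 1/AR under the mean-field law
#'
#' The sufficient statistic of the exponential family; strictly decreasing in
#' alpha, which makes the maximum-likelihood equation for alpha monotone.
#'
#' @inheritParams meanfield_moments
#' @return scalar expectation.
#' @export
meanfield_mean_h <- function(alpha) {
  .check_alpha(alpha)
  upper <- .mf_upper(alpha)
  z <- .mf_quad(function(a) .mf_unnorm(a, alpha), alpha, upper = upper)
  .mf_quad(function(a) .mf_h(a) * .mf_unnorm(a, alpha), alpha,
           upper = upper) / z
}

#' Draw from the mean-field aspect-ratio law
#'
#' Rejection sampling in the sufficient-statistic variable
#' w = AR + 1/AR - 2 (the exponent of the law), where the transformed
#' density is a slowly varying prefactor times exp(-alpha w): bounded near
#' w = 0 and growing like w^{3/2} in the tail. An equal-weight mixture of
#' gamma(1, alpha) and gamma(5/2, 0.95 alpha) dominates it for every alpha
#' after a constant, which is maximized numerically on a log grid and
#' padded. Draws map back through AR = 1 + t, t = (w + sqrt(w^2 + 4w))/2.
#'
#' @param n sample size.
#' @param alpha system-specific parameter, > 0.
#' @param seed optional integer seed.
#' @return numeric vector of n draws, all > 1, with attribute
#'   `acceptance_rate`.
#' @export
sample_meanfield <- function(n, alpha, seed = NULL) {
  .check_alpha(alpha)
  stopifnot(n >= 1L)
  if (!is.null(seed)) set.seed(seed)
  rate2 <- alpha * 0.95   # tail component: slightly heavier than the target
  env_dens_w <- function(w) {
    0.5 * stats::dexp(w, rate = alpha) +
      0.5 * stats::dgamma(w, shape = 2.5, rate = rate2)
  }
  env_draw_w <- function(k) {
    tail <- stats::runif(k) < 0.5
    w <- numeric(k)
    w[!tail] <- stats::rexp(sum(!tail), rate = alpha)
    w[tail] <- stats::rgamma(sum(tail), shape = 2.5, rate = rate2)
    w
  }
  w_to_ar <- function(w) 1 + (w + sqrt(w^2 + 4 * w)) / 2
  ## transformed target in w: .mf_unnorm(ar) / (dw/dt), dw/dt = t(t+2)/(1+t)^2
  target_w <- function(w) {
    t <- (w + sqrt(w^2 + 4 * w)) / 2
    .mf_unnorm(1 + t, alpha) * (1 + t)^2 / (t * (t + 2))
  }
  ## envelope constant: maximize ratio of target to envelope on a fine grid
  ## of w (log-spaced over the retained tail mass), then pad by 10%
  up <- .mf_upper(alpha)
  w_hi <- up + 1 / up - 2
  grid <- exp(seq(log(w_hi * 1e-8), log(w_hi), length.out = 512L))
  m <- 1.1 * max(target_w(grid) / env_dens_w(grid), na.rm = TRUE)
  if (!is.finite(m)) stop("numerical error: envelope failure (alpha = ",
                          alpha, ")")
  out <- numeric(0L)
  tries <- 0L
  while (length(out) < n) {
    todo <- n - length(out)
    w <- env_draw_w(ceiling(todo * 1.5) + 16L)
    u <- stats::runif(length(w))
    acc <- u < target_w(w) / (m * env_dens_w(w))
    tries <- tries + length(w)
    out <- c(out, w_to_ar(w[acc]))
    if (tries > 100L * n + 1000L && length(out) / tries < 0.01) {
      stop("numerical error: rejection acceptance rate below 1% (alpha = ",
           alpha, ")")
    }
  }
  out <- out[seq_len(n)]
  attr(out, "acceptance_rate") <- length(out) / tries
  out
}
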