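#' Rescale aspect ratios to the universal variable x
#'
#' Maps aspect ratios to x = (AR - 1) / (ARbar - 1), so the rescaled sample
#' starts at the origin and has mean exactly 1. This is the variable in which
#' aspect-ratio PDFs from different conditions collapse.
#'
#' @param values numeric vector of aspect ratios, all >= 1.
#' @return object of class `ar_sample`: list with `values`, `mean_ar`,
#'   `sd_ar`, `rescaled`.
#' @export
rescale_ar <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("degenerate-sample error: empty sample")
  if (any(!is.finite(values))) stop("non-finite aspect ratio in sample")
  if (any(values < 1)) stop("domain error: aspect ratios must be >= 1")
  m <- mean(values)
  if (m <= 1 + .Machine$double.eps * 4) {
    stop("degenerate-sample error: mean aspect ratio is 1 (all cells circular)")
  }
  x <- (values - 1) / (m - 1)
  structure(list(values = values, mean_ar = m, sd_ar = stats::sd(values),
                 rescaled = x),
            class = "ar_sample")
}

#' @export
print.ar_sample <- function(x, ...) {
  cat(sprintf("ar_sample: n = %d, mean AR = %.4f, SD(AR) = %.4f\n",
              length(x$values), x$mean_ar, x$sd_ar))
  invisible(x)
}

#' Maximum-likelihood fit of the k-gamma law
#'
#' The sample is renormalized to unit mean (the k-gamma law fixes the mean at
#' 1 by construction of the rescaled variable), after which the likelihood has
#' a single parameter k solving the monotone score equation
#' log k - digamma(k) = -mean(log x). Solved by bracketed root finding on
#' \[1e-3, 1e3\].
#'
#' @param values nonnegative rescaled aspect ratios (or any unit-scale
#'   positive sample); n >= 10. Exact zeros carry no likelihood information
#'   for k > 1 and are dropped with a warning.
#' @return object of class `kgamma_fit` with elements `k`, `loglik`, `n`.
#' @export
fit_kgamma <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 10L) stop("need at least 10 values to fit k")
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("domain error: values must be finite and >= 0")
  }
  if (stats::sd(values) == 0) {
    stop("degenerate-sample error: zero-variance sample")
  }
  nzero <- sum(values == 0)
  if (nzero > 0L) {
    warning(nzero, " zero value(s) dropped before k-gamma fit")
    values <- values[values > 0]
  }
  x <- values / mean(values)
  s <- -mean(log(x))  # = log(mean) - mean(log), >= 0 by Jensen
  score <- function(k) log(k) - digamma(k) - s
  k_hat <- stats::uniroot(score, c(1e-3, 1e3), tol = 1e-10)$root
  ll <- sum(dkgamma(x, k_hat, log = TRUE))
  structure(list(k = k_hat, loglik = ll, n = length(x)),
            class = "kgamma_fit")
}

#' @export
print.kgamma_fit <- function(x, ...) {
  cat(sprintf("k-gamma fit: k = %.4f (n = %d, logLik = %.2f)\n",
              x$k, x$n, x$loglik))
  invisible(x)
}

#' @export
coef.kgamma_fit <- function(object, ...) c(k = object$k)

#' @export
logLik.kgamma_fit <- function(object, ...) {
  structure(object$loglik, df = 1L, nobs = object$n, class = "logLik")
}

#' Maximum-likelihood fit of the mean-field aspect-ratio law
#'
#' The law is an exponential family in h(AR) = AR + 1/AR, so the MLE for
#' alpha solves the monotone moment-matching equation
#' E_alpha\[AR + 1/AR\] = mean(AR + 1/AR). Solved by bracketed root finding
#' on alpha in \[1e-3, 1e3\].
#'
#' @param values aspect ratios, all > 1; n >= 10.
#' @return object of class `meanfield_fit` with elements `alpha`, `norm`
#'   (the normalization constant at the MLE), `loglik`, `n`.
#' @export
fit_meanfield <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 10L) stop("need at least 10 values to fit alpha")
  if (any(!is.finite(values))) stop("non-finite value in sample")
  if (any(values <= 1)) {
    stop("domain error: the mean-field law is supported on AR > 1")
  }
  target <- mean(.mf_h(values))
  score <- function(la) meanfield_mean_h(exp(la)) - target
  lo <- log(1e-3); hi <- log(1e3)
  slo <- score(lo); shi <- score(hi)
  if (slo * shi > 0) {
    stop("numerical error: bracket failure solving for alpha (sample mean of ",
         "AR + 1/AR = ", signif(target, 6), ")")
  }
  la_hat <- stats::uniroot(score, c(lo, hi), tol = 1e-10)$root
  alpha_hat <- exp(la_hat)
  zs <- .mf_z(alpha_hat)  # scaled normalization; log N = log zs - 2 alpha
  ll <- sum(log(.mf_unnorm(values, alpha_hat))) - length(values) * log(zs)
  structure(list(alpha = alpha_hat, norm = zs * exp(-2 * alpha_hat),
                 loglik = ll,
                 n = length(values)),
            class = "meanfield_fit")
}

#' @export
print.meanfield_fit <- function(x, ...) {
  cat(sprintf("mean-field AR fit: alpha = %.4f (n = %d, logLik = %.2f)\n",
              x$alpha, x$n, x$loglik))
  invisible(x)
}

#' @export
coef.meanfield_fit <- function(object, ...) c(alpha = object$alpha)

#' @export
logLik.meanfield_fit <- function(object, ...) {
  structure(object$loglik, df = 1L, nobs = object$n, class = "logLik")
}
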