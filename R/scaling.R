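#' The universal shape-variability scaling line
#'
#' Because both the mean and the standard deviation of the aspect ratio under
#' the mean-field law are functions of the single parameter alpha, eliminating
#' alpha yields a near-linear relation SD(AR) vs mean AR that is independent
#' of system details. This function traces the parametric curve
#' (mean AR(alpha), SD(alpha)) on a dense alpha grid by quadrature and fits an
#' unweighted least-squares line over a stated window of mean AR.
#'
#' @param alpha_grid decreasing persistence of shape fluctuations is a larger
#'   alpha; defaults to a log-spaced grid over \[0.8, 40\] dense enough that
#'   consecutive mean-AR values differ by < 0.02.
#' @param fit_range window of mean AR over which the line is fitted
#'   (default c(1.15, 2.5), the span covered by confluent-monolayer data).
#' @param n_grid number of grid points when `alpha_grid` is NULL.
#' @return object of class `scaling_curve`: list with the grid
#'   (`alpha`, `mean_ar`, `sd_ar`), `slope`, `intercept`, `fit_range`, and a
#'   `sensitivity` table of coefficients refitted over perturbed windows.
#' @examples
#' \donttest{
#' sc <- universal_line()
#' sc$slope      # ~ 0.71
#' sc$intercept  # ~ -0.75
#' }
#' @export
universal_line <- function(alpha_grid = NULL, fit_range = c(1.15, 2.5),
                           n_grid = 400L) {
  if (is.null(alpha_grid)) {
    alpha_grid <- exp(seq(log(0.8), log(40), length.out = n_grid))
  }
  alpha_grid <- sort(as.numeric(alpha_grid))
  mm <- t(vapply(alpha_grid, meanfield_moments, numeric(2L)))
  mean_ar <- mm[, 1L]; sd_ar <- mm[, 2L]
  if (any(diff(mean_ar) >= 0)) {
    stop("mean AR must be strictly decreasing in alpha; degenerate grid?")
  }
  gaps <- abs(diff(mean_ar))
  in_rng <- mean_ar >= min(fit_range) & mean_ar <= max(fit_range)
  if (max(gaps[in_rng[-length(in_rng)] | in_rng[-1L]], 0) > 0.02) {
    warning("alpha grid coarser than 0.02 in mean AR inside the fit range")
  }
  fit_one <- function(rng) {
    sel <- mean_ar >= min(rng) & mean_ar <= max(rng)
    if (sum(sel) < 5L) {
      stop("insufficient-grid error: fewer than 5 grid points in fit range")
    }
    stats::coef(stats::lm(sd_ar[sel] ~ mean_ar[sel]))
  }
  co <- fit_one(fit_range)
  ## range-sensitivity diagnostics: shrink/stretch the window by 10%
  half <- diff(range(fit_range)) / 2; mid <- mean(fit_range)
  windows <- list(nominal = fit_range,
                  narrower = mid + c(-0.9, 0.9) * half,
                  wider = mid + c(-1.1, 1.1) * half)
  sens <- do.call(rbind, lapply(windows, function(w) {
    cc <- tryCatch(fit_one(w), error = function(e) c(NA_real_, NA_real_))
    data.frame(lo = min(w), hi = max(w), intercept = cc[1L], slope = cc[2L])
  }))
  structure(list(alpha = alpha_grid, mean_ar = mean_ar, sd_ar = sd_ar,
                 slope = unname(co[2L]), intercept = unname(co[1L]),
                 fit_range = fit_range, sensitivity = sens),
            class = "scaling_curve")
}

#' @export
print.scaling_curve <- function(x, ...) {
  cat(sprintf(
    "universal scaling line: SD(AR) = %.3f * mean(AR) %+.3f  (fit on mean AR in [%.2f, %.2f])\n",
    x$slope, x$intercept, x$fit_range[1L], x$fit_range[2L]))
  invisible(x)
}

#' @export
plot.scaling_curve <- function(x, ...) {
  graphics::plot(x$mean_ar, x$sd_ar, type = "l", xlab = "mean AR",
                 ylab = "SD(AR)", ...)
  graphics::abline(x$intercept, x$slope, lty = 2)
  invisible(x)
}

#' Collapse of rescaled aspect-ratio PDFs
#'
#' Rescales each sample to x = (AR - 1)/(ARbar - 1), builds density-normalized
#' histograms on shared bins and scores the collapse as the mean pairwise L1
#' distance between the histograms (0 = perfect collapse).
#'
#' @param samples list of numeric aspect-ratio vectors (each with mean > 1).
#' @param breaks shared histogram breaks for x; default 40 equal-width bins
#'   on \[0, 5\].
#' @return list with `breaks`, `density` (matrix, one row per sample) and
#'   `score`.
#' @export
collapse_pdfs <- function(samples, breaks = seq(0, 5, length.out = 41L)) {
  if (!is.list(samples) || length(samples) == 0L) {
    stop("input error: 'samples' must be a nonempty list of AR vectors")
  }
  dens <- t(vapply(samples, function(v) {
    x <- rescale_ar(v)$rescaled
    x <- pmin(x, max(breaks) - 1e-12)  # clamp far-tail mass into last bin
    h <- graphics::hist(x, breaks = breaks, plot = FALSE)
    h$density
  }, numeric(length(breaks) - 1L)))
  k <- nrow(dens)
  score <- 0
  if (k > 1L) {
    w <- diff(breaks)
    pairs <- utils::combn(k, 2L)
    d <- apply(pairs, 2L, function(ij) {
      sum(abs(dens[ij[1L], ] - dens[ij[2L], ]) * w)
    })
    score <- mean(d)
  }
  list(breaks = breaks, density = dens, score = score)
}

#' Deviation of (mean AR, SD) points from the universal line
#'
#' Computes residuals of observed points from a fitted scaling line and a
#' one-sided t-test of whether the points lie significantly below it, the
#' signature of mobility-selected (fast) cell subsets.
#'
#' @param points data.frame (or matrix) with columns `mean_ar` and `sd_ar`;
#'   at least 3 points.
#' @param curve a [universal_line()] result, or any list with `slope` and
#'   `intercept`.
#' @param level significance level for the one-sided test (default 0.05).
#' @return list with `residuals`, `mean_residual`, `se`, `statistic`,
#'   `p_value` (H1: mean residual < 0), `below` (logical decision at `level`).
#' @export
assess_scaling_deviation <- function(points, curve, level = 0.05) {
  pts <- as.data.frame(points)
  if (ncol(pts) < 2L) {
    stop("input error: need a two-column (mean_ar, sd_ar) point set")
  }
  if (!all(c("mean_ar", "sd_ar") %in% names(pts))) {
    names(pts)[1:2] <- c("mean_ar", "sd_ar")
  }
  if (nrow(pts) < 3L) stop("input error: need at least 3 points")
  r <- pts$sd_ar - (curve$slope * pts$mean_ar + curve$intercept)
  if (stats::sd(r) == 0) {
    ## exactly on (or parallel to) the line: no test possible
    return(list(residuals = r, mean_residual = mean(r), se = 0,
                statistic = NA_real_, p_value = NA_real_,
                below = FALSE))
  }
  tt <- stats::t.test(r, alternative = "less", mu = 0)
  list(residuals = r, mean_residual = mean(r),
       se = stats::sd(r) / sqrt(length(r)),
       statistic = unname(tt$statistic), p_value = tt$p.value,
       below = tt$p.value < level)
}
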