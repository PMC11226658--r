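#' Cell-center trajectories
#'
#' A `trajectory` stores per-frame 2D positions of all cells, the frame time
#' step, the box geometry (periodic rectangle or circular wall) and the
#' nominal area fraction.
#'
#' @param positions numeric array \[n_frames, n_cells, 2\].
#' @param dt time per frame.
#' @param box list: `list(type = "periodic", Lx =, Ly =)` or
#'   `list(type = "circular", R =)`.
#' @param phi nominal area fraction in (0, 1\].
#' @param cell_ids optional cell identifiers (default 1..n_cells).
#' @return object of class `trajectory`.
#' @export
trajectory <- function(positions, dt, box, phi = NA_real_, cell_ids = NULL) {
  stopifnot(is.array(positions), length(dim(positions)) == 3L,
            dim(positions)[3L] == 2L, dt > 0)
  if (!all(is.finite(positions))) stop("non-finite position in trajectory")
  if (!is.list(box) || is.null(box$type)) stop("box must be a typed list")
  if (box$type == "periodic") {
    stopifnot(is.numeric(box$Lx), is.numeric(box$Ly), box$Lx > 0, box$Ly > 0)
  } else if (box$type == "circular") {
    stopifnot(is.numeric(box$R), box$R > 0)
  } else stop("box$type must be 'periodic' or 'circular'")
  if (is.null(cell_ids)) cell_ids <- seq_len(dim(positions)[2L])
  stopifnot(length(cell_ids) == dim(positions)[2L])
  structure(list(positions = positions, dt = dt, box = box, phi = phi,
                 cell_ids = cell_ids),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  d <- dim(x$positions)
  cat(sprintf("trajectory: %d frames x %d cells, dt = %g, box = %s\n",
              d[1L], d[2L], x$dt, x$box$type))
  invisible(x)
}

#' Unwrapped positions
#'
#' For periodic boxes, per-frame steps are taken modulo the box (minimum
#' image) and accumulated, which assumes no cell moves more than half a box
#' length per frame (checked). Returns positions in an unbounded frame.
#' @noRd
.unwrap <- function(traj) {
  p <- traj$positions
  if (traj$box$type != "periodic") return(p)
  L <- c(traj$box$Lx, traj$box$Ly)
  nf <- dim(p)[1L]
  if (nf < 2L) return(p)
  nc <- dim(p)[2L]
  for (k in 1:2) {
    st <- p[-1L, , k, drop = FALSE] - p[-nf, , k, drop = FALSE]
    dim(st) <- c(nf - 1L, nc)
    wr <- .wrap_disp(st, L[k])
    if (any(abs(wr) > L[k] / 2 - 1e-12)) {
      stop("unwrapping assumption violated: step larger than half the box")
    }
    cum <- apply(wr, 2L, cumsum)
    dim(cum) <- c(nf - 1L, nc)
    p[, , k] <- rbind(p[1L, , k],
                      matrix(p[1L, , k], nf - 1L, nc, byrow = TRUE) + cum)
  }
  p
}

## lag-l displacement components from an unwrapped position array
.lag_disp <- function(u, l) {
  nf <- dim(u)[1L]
  dx <- u[(1L + l):nf, , 1L, drop = FALSE] - u[1:(nf - l), , 1L, drop = FALSE]
  dy <- u[(1L + l):nf, , 2L, drop = FALSE] - u[1:(nf - l), , 2L, drop = FALSE]
  list(dx = dx, dy = dy)
}

#' Mean-squared displacement
#'
#' Time-origin-averaged MSD on unwrapped coordinates.
#'
#' @param traj a [trajectory()].
#' @param max_lag largest lag in frames (< number of frames); default half
#'   the trajectory length.
#' @param lags optional explicit integer lags (overrides `max_lag`).
#' @return data.frame with columns `lag` (frames), `time`, `msd`.
#' @export
msd <- function(traj, max_lag = NULL, lags = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  nf <- dim(traj$positions)[1L]
  if (nf < 2L) stop("input error: need at least 2 frames")
  if (is.null(lags)) {
    if (is.null(max_lag)) max_lag <- nf %/% 2L
    if (max_lag >= nf) stop("input error: max_lag must be < number of frames")
    lags <- seq_len(max_lag)
  }
  lags <- sort(unique(as.integer(lags)))
  if (any(lags < 1L) || any(lags >= nf)) {
    stop("input error: lags must lie in [1, n_frames - 1]")
  }
  u <- .unwrap(traj)
  ms <- vapply(lags, function(l) {
    d <- .lag_disp(u, l)
    mean(d$dx^2 + d$dy^2)
  }, numeric(1L))
  data.frame(lag = lags, time = lags * traj$dt, msd = ms)
}

#' Persistence time from the ballistic-to-diffusive MSD crossover
#'
#' Estimates the local log-log slope of the MSD on (near) log-spaced lags
#' with centered differences and 3-point smoothing; the persistence time is
#' the lag at which the smoothed slope first crosses 1.5 (midpoint between
#' the ballistic slope 2 and the diffusive slope 1). The early-lag speed
#' estimate v = sqrt(MSD(t1))/t1 gives the persistence length l_p = v tau_p.
#'
#' @param msd_curve data.frame from [msd()] (columns `time`, `msd`).
#' @param slope_hi,slope_lo required early/late smoothed slopes for a
#'   crossover to be declared (defaults 1.8 and 1.2).
#' @return list with `tau_p`, `v`, `l_p` and the smoothed `slopes` table.
#' @export
persistence_time <- function(msd_curve, slope_hi = 1.8, slope_lo = 1.2) {
  stopifnot(all(c("time", "msd") %in% names(msd_curve)))
  cv <- msd_curve[msd_curve$msd > 0 & msd_curve$time > 0, ]
  ## thin to approximately log-spaced lags
  lt <- log(cv$time)
  keep <- !duplicated(round((lt - min(lt)) / (diff(range(lt)) + 1e-12) * 60))
  cv <- cv[keep, ]
  if (nrow(cv) < 5L) stop("input error: too few usable MSD points")
  lt <- log(cv$time); lm_ <- log(cv$msd)
  n <- length(lt)
  sl <- (lm_[c(2:n, n)] - lm_[c(1L, 1:(n - 1L))]) /
    (lt[c(2:n, n)] - lt[c(1L, 1:(n - 1L))])
  sl <- stats::filter(sl, rep(1 / 3, 3L), sides = 2L)
  sl[1L] <- sl[2L]; sl[n] <- sl[n - 1L]
  sl <- as.numeric(sl)
  early <- max(sl[seq_len(max(2L, n %/% 4L))])
  late <- min(sl[(n - max(2L, n %/% 4L)):n])
  if (early < slope_hi || late > slope_lo) {
    stop("no-crossover error: MSD does not span ballistic (slope >= ",
         slope_hi, ") to diffusive (slope <= ", slope_lo, ") regimes")
  }
  i0 <- which(sl >= slope_hi)[1L]
  idx <- which(sl[i0:n] < 1.5)[1L]
  if (is.na(idx)) stop("no-crossover error: slope never crosses 1.5")
  j <- i0 + idx - 1L
  f <- (1.5 - sl[j - 1L]) / (sl[j] - sl[j - 1L])
  tau_p <- exp(lt[j - 1L] + f * (lt[j] - lt[j - 1L]))
  v <- sqrt(cv$msd[1L]) / cv$time[1L]
  list(tau_p = tau_p, v = v, l_p = v * tau_p,
       slopes = data.frame(time = cv$time, slope = sl))
}

#' Self-intermediate scattering function
#'
#' Isotropic 2D form F_s(q, t) = < J0(q |dr_j(t)|) >, averaged over particles
#' and time origins; F_s(q, 0) = 1 exactly.
#'
#' @param traj a [trajectory()].
#' @param q wavevector magnitude (> 0); the convention q = 2 pi / sigma with
#'   sigma the mean cell diameter probes relaxation on the cell scale.
#' @param lags integer lags (default 0..n_frames/2).
#' @return data.frame with columns `lag`, `time`, `fs`.
#' @export
self_intermediate_scattering <- function(traj, q, lags = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  if (!is.numeric(q) || length(q) != 1L || q <= 0) {
    stop("parameter-domain error: q must be a positive scalar")
  }
  nf <- dim(traj$positions)[1L]
  if (is.null(lags)) lags <- 0:(nf %/% 2L)
  lags <- sort(unique(as.integer(lags)))
  if (any(lags < 0L) || any(lags >= nf)) stop("input error: bad lag")
  u <- .unwrap(traj)
  fs <- vapply(lags, function(l) {
    if (l == 0L) return(1)
    d <- .lag_disp(u, l)
    mean(besselJ(q * sqrt(d$dx^2 + d$dy^2), 0))
  }, numeric(1L))
  data.frame(lag = lags, time = lags * traj$dt, fs = fs)
}

#' Structural relaxation time
#'
#' The time at which F_s(q, t) decays to 1/e, by linear interpolation between
#' the bracketing lags. When the curve never crosses 1/e the result is
#' censored with a lower bound at the largest lag.
#'
#' @param fs_curve data.frame from [self_intermediate_scattering()].
#' @return list with `tau_alpha`, `censored` (logical) and, when censored,
#'   `lower_bound`.
#' @export
relaxation_time <- function(fs_curve) {
  stopifnot(all(c("time", "fs") %in% names(fs_curve)))
  thr <- exp(-1)
  below <- which(fs_curve$fs < thr)
  if (length(below) == 0L) {
    return(list(tau_alpha = NA_real_, censored = TRUE,
                lower_bound = max(fs_curve$time)))
  }
  j <- below[1L]
  if (j == 1L) return(list(tau_alpha = fs_curve$time[1L], censored = FALSE))
  f <- (thr - fs_curve$fs[j - 1L]) / (fs_curve$fs[j] - fs_curve$fs[j - 1L])
  tau <- fs_curve$time[j - 1L] + f * (fs_curve$time[j] - fs_curve$time[j - 1L])
  list(tau_alpha = tau, censored = FALSE)
}

#' Non-Gaussian parameter and cage-rearrangement time
#'
#' The 2D non-Gaussian parameter alpha2(t) = <dr^4> / (2 <dr^2>^2) - 1 peaks
#' at the cage-rearrangement time t*, the lag of maximal dynamical
#' heterogeneity. A peak at the boundary of the lag range (as for purely
#' Gaussian displacements, where alpha2 is flat) triggers a warning.
#'
#' @param traj a [trajectory()].
#' @param lags integer lags (default 1..n_frames/2).
#' @return list with `t_star` (time units), `t_star_lag` (frames),
#'   `alpha2` (data.frame lag/time/alpha2) and `boundary` flag.
#' @export
cage_time <- function(traj, lags = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  nf <- dim(traj$positions)[1L]
  if (is.null(lags)) lags <- seq_len(nf %/% 2L)
  lags <- sort(unique(as.integer(lags)))
  if (any(lags < 1L) || any(lags >= nf)) stop("input error: bad lag")
  u <- .unwrap(traj)
  a2 <- vapply(lags, function(l) {
    d <- .lag_disp(u, l)
    r2 <- d$dx^2 + d$dy^2
    mean(r2^2) / (2 * mean(r2)^2) - 1
  }, numeric(1L))
  i <- which.max(a2)
  boundary <- i == 1L || i == length(lags)
  if (boundary) {
    warning("boundary-peak warning: alpha2 is maximal at the edge of the ",
            "lag range; t* is unreliable")
  }
  list(t_star = lags[i] * traj$dt, t_star_lag = lags[i],
       alpha2 = data.frame(lag = lags, time = lags * traj$dt, alpha2 = a2),
       boundary = boundary)
}

#' Fast and slow mobility subsets over the cage time
#'
#' Ranks cells by their time-origin-averaged displacement magnitude over the
#' lag t* and selects the top and bottom quantiles. Ties are broken by cell
#' order for determinism; an all-equal displacement field is flagged
#' degenerate.
#'
#' @param traj a [trajectory()].
#' @param t_star_lag cage-rearrangement lag in frames (e.g. from
#'   [cage_time()]).
#' @param fraction mobility quantile in (0, 0.5\] (default 0.10).
#' @return object of class `dh_result`: list with `t_star`, `fast_ids`,
#'   `slow_ids`, `fraction`, `displacement` (per cell), `degenerate`.
#' @export
mobility_subsets <- function(traj, t_star_lag, fraction = 0.10) {
  stopifnot(inherits(traj, "trajectory"))
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 0.5) {
    stop("parameter error: fraction must be in (0, 0.5]")
  }
  nf <- dim(traj$positions)[1L]
  l <- as.integer(t_star_lag)
  if (l < 1L || l >= nf) stop("input error: t_star_lag out of range")
  u <- .unwrap(traj)
  d <- .lag_disp(u, l)
  disp <- colMeans(sqrt(d$dx^2 + d$dy^2))
  n <- length(disp)
  k <- max(1L, round(fraction * n))
  ord <- order(disp, seq_len(n))  # stable tie-break by cell index
  slow <- sort(ord[seq_len(k)])
  fast <- sort(ord[(n - k + 1L):n])
  structure(list(t_star = l * traj$dt, t_star_lag = l,
                 fast_ids = traj$cell_ids[fast],
                 slow_ids = traj$cell_ids[slow],
                 fraction = fraction,
                 displacement = stats::setNames(disp, traj$cell_ids),
                 degenerate = stats::sd(disp) == 0),
            class = "dh_result")
}

#' @export
print.dh_result <- function(x, ...) {
  cat(sprintf(
    "mobility subsets: t* = %g, %d fast / %d slow cells (fraction %.2f)%s\n",
    x$t_star, length(x$fast_ids), length(x$slow_ids), x$fraction,
    if (x$degenerate) " [degenerate: all displacements equal]" else ""))
  invisible(x)
}

#' Shape statistics of the fast and slow subsets
#'
#' Pools aspect ratios of the subset cells over the frames of a polygon
#' ensemble covering the displacement window and reports (mean AR, SD(AR))
#' per subset.
#'
#' @param dh a [mobility_subsets()] result.
#' @param polygons a [polygon_ensemble()] whose frames cover the window and
#'   whose cell ids match the trajectory's.
#' @return list with `fast` and `slow`, each c(mean_ar, sd_ar), plus the
#'   pooled per-subset AR vectors `fast_ar`, `slow_ar`.
#' @export
subset_shape_stats <- function(dh, polygons) {
  stopifnot(inherits(dh, "dh_result"), inherits(polygons, "polygon_ensemble"))
  present <- unique(unlist(lapply(polygons$frames, names)))
  one <- function(ids) {
    ids <- as.character(ids)
    if (!all(ids %in% present)) {
      stop("coverage error: polygons missing for subset cells ",
           paste(utils::head(setdiff(ids, present), 5L), collapse = ", "))
    }
    ar <- ensemble_aspect_ratios(polygons, cell_ids = ids)$ar
    list(stats = c(mean_ar = mean(ar), sd_ar = stats::sd(ar)), ar = ar)
  }
  f <- one(dh$fast_ids); s <- one(dh$slow_ids)
  list(fast = f$stats, slow = s$stats, fast_ar = f$ar, slow_ar = s$ar)
}

#' Spatial clustering of mobility subsets
#'
#' Builds Voronoi (shared-edge) adjacency for one frame of positions and
#' returns the connected components of the fast and slow subsets.
#'
#' @param dh a [mobility_subsets()] result.
#' @param positions n x 2 matrix of cell positions for the frame analyzed,
#'   rows matching the trajectory's cell order.
#' @param box length-2 c(Lx, Ly) for periodic data.
#' @param cell_ids ids matching rows of `positions` (default the dh result's
#'   full id set, in order).
#' @return list with elements `fast` and `slow`; each holds `membership`
#'   (component index per subset cell) and `sizes`.
#' @export
cluster_subsets <- function(dh, positions, box, cell_ids = NULL) {
  stopifnot(inherits(dh, "dh_result"))
  pts <- as.matrix(positions)
  if (is.null(cell_ids)) cell_ids <- names(dh$displacement)
  stopifnot(length(cell_ids) == nrow(pts))
  vor <- periodic_voronoi(pts, box)
  comp_of <- function(ids) {
    idx <- match(as.character(ids), as.character(cell_ids))
    if (any(is.na(idx))) stop("ids missing from the position frame")
    sub <- vor$adjacency[vor$adjacency[, 1L] %in% idx &
                           vor$adjacency[, 2L] %in% idx, , drop = FALSE]
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(sub[, 1L]),
                 to = as.character(sub[, 2L])),
      directed = FALSE,
      vertices = data.frame(name = as.character(idx)))
    cmp <- igraph::components(g)
    membership <- stats::setNames(
      as.integer(cmp$membership),
      cell_ids[as.integer(names(cmp$membership))])
    list(membership = membership, sizes = as.integer(cmp$csize))
  }
  list(fast = comp_of(dh$fast_ids), slow = comp_of(dh$slow_ids))
}
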