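#' Synthetic generators
#'
#' Seeded generators emulating the statistical structure of cell-mimic
#' experiments: chiral active Brownian trajectories whose persistence is
#' tuned by an interior-chirality parameter, samplers for the aspect-ratio
#' laws, and polygon ensembles with prescribed aspect ratios.
#'
#' @name synthetic-data
NULL

#' Map interior chirality to angular drift and rotational diffusion
#'
#' A cell with a racemic interior (chi_cell = 0) performs persistent runs;
#' increasing |chi_cell| adds an angular drift omega = omega_max * chi_cell
#' (sign = handedness) that winds the heading and shortens the effective
#' persistence time of the velocity autocorrelation
#' exp(-D_r t) cos(omega t). D_r is held fixed, so persistence decreases
#' monotonically with |chi_cell|.
#'
#' @param chi_cell interior chirality in \[-1, 1\].
#' @param omega_max angular drift at |chi_cell| = 1 (radians/time).
#' @param D_r rotational diffusivity (1/time).
#' @return list with `omega` and `D_r`.
#' @export
map_chirality <- function(chi_cell, omega_max = 1.0, D_r = 0.1) {
  if (!is.numeric(chi_cell) || any(abs(chi_cell) > 1)) {
    stop("domain error: |chi_cell| must be <= 1")
  }
  list(omega = omega_max * chi_cell, D_r = D_r)
}

#' Parameters of a chiral active Brownian cell
#'
#' @param v0 self-propulsion speed (length/time).
#' @param chi_cell interior chirality in \[-1, 1\]; mapped to the angular
#'   drift via [map_chirality()].
#' @param omega_max,D_r see [map_chirality()].
#' @param D_t translational diffusivity (length^2/time, default 0).
#' @return list of kinetic parameters (class `chiral_cell_params`).
#' @export
chiral_cell_params <- function(v0 = 1, chi_cell = 0, omega_max = 1.0,
                               D_r = 0.1, D_t = 0) {
  stopifnot(v0 >= 0, D_r >= 0, D_t >= 0)
  m <- map_chirality(chi_cell, omega_max, D_r)
  structure(list(v0 = v0, chi_cell = chi_cell, omega = m$omega,
                 D_r = m$D_r, D_t = D_t),
            class = "chiral_cell_params")
}

#' Simulate non-interacting chiral active Brownian cells
#'
#' Each cell carries a heading advanced by omega dt plus rotational noise and
#' moves at speed v0 along it (plus optional translational noise); this is
#' the isolated-cell (dilute) regime. With an ensemble chirality chi_sys the
#' clockwise/counterclockwise handedness counts are imbalanced accordingly;
#' the default chi_sys = 0 uses equal counts (n_cells must then be even).
#'
#' @param params a [chiral_cell_params()].
#' @param n_cells number of cells.
#' @param n_frames number of recorded frames.
#' @param dt time per frame; must satisfy dt * max(|omega|, D_r) < 0.1.
#' @param box length-2 c(Lx, Ly), periodic.
#' @param seed integer seed.
#' @param chi_sys ensemble chirality |N_cw - N_ccw| / N in \[0, 1\].
#' @return a [trajectory()]; attribute `handedness` records the per-cell
#'   sign of omega.
#' @export
chiral_abp_trajectory <- function(params, n_cells, n_frames, dt, box,
                                  seed = 1L, chi_sys = 0) {
  stopifnot(inherits(params, "chiral_cell_params"), n_cells >= 1L,
            n_frames >= 2L, dt > 0, length(box) == 2L)
  if (dt * max(abs(params$omega), params$D_r) >= 0.1) {
    stop("parameter error: dt * max(|omega|, D_r) must be < 0.1")
  }
  if (chi_sys < 0 || chi_sys > 1) stop("chi_sys must be in [0, 1]")
  n_cw <- round(n_cells * (1 + chi_sys) / 2)
  if (chi_sys == 0 && n_cells %% 2L == 1L) {
    stop("chi_sys = 0 requires an even number of cells")
  }
  hand <- c(rep(1, n_cw), rep(-1, n_cells - n_cw))
  set.seed(seed)
  theta <- stats::runif(n_cells, 0, 2 * pi)
  pos <- cbind(stats::runif(n_cells, 0, box[1L]),
               stats::runif(n_cells, 0, box[2L]))
  out <- array(NA_real_, c(n_frames, n_cells, 2L))
  out[1L, , ] <- pos
  sdr <- sqrt(2 * params$D_r * dt)
  sdt <- sqrt(2 * params$D_t * dt)
  for (f in 2:n_frames) {
    theta <- theta + hand * params$omega * dt +
      sdr * stats::rnorm(n_cells)
    pos <- pos + params$v0 * cbind(cos(theta), sin(theta)) * dt
    if (params$D_t > 0) {
      pos <- pos + sdt * matrix(stats::rnorm(2L * n_cells), n_cells, 2L)
    }
    pos[, 1L] <- pos[, 1L] %% box[1L]
    pos[, 2L] <- pos[, 2L] %% box[2L]
    out[f, , ] <- pos
  }
  tr <- trajectory(out, dt = dt,
                   box = list(type = "periodic", Lx = box[1L], Ly = box[2L]),
                   phi = NA_real_)
  attr(tr, "handedness") <- hand
  tr
}

#' Theoretical MSD of a chiral active Brownian particle
#'
#' MSD(t) = 2 int_0^t (t - s) v0^2 exp(-D_r s) cos(omega s) ds + 4 D_t t,
#' the Green-Kubo integral of the velocity autocorrelation, evaluated in
#' closed form through the complex antiderivative with mu = D_r - i omega:
#' int_0^t (t - s) e^(-mu s) ds = t/mu - (1 - e^(-mu t))/mu^2. Used as an
#' independent oracle for the simulator.
#'
#' @param t time(s).
#' @param params a [chiral_cell_params()].
#' @return numeric vector of MSD values.
#' @export
chiral_abp_msd_theory <- function(t, params) {
  mu <- complex(real = params$D_r, imaginary = -params$omega)
  vapply(t, function(tt) {
    if (tt == 0) return(0)
    i_val <- if (Mod(mu) * tt < 1e-6) {
      tt^2 / 2  # ballistic limit D_r = omega = 0
    } else {
      Re(tt / mu - (1 - exp(-mu * tt)) / mu^2)
    }
    2 * params$v0^2 * i_val + 4 * params$D_t * tt
  }, numeric(1L))
}

#' Polygon ensembles with prescribed aspect ratios
#'
#' Each polygon is an n-gon inscribed in an ellipse whose axis ratio is
#' root-found so that the measured second-moment aspect ratio matches the
#' requested value within tolerance; each polygon gets an independent random
#' rotation and is scaled to unit area.
#'
#' @param ar_values requested aspect ratios, all >= 1.
#' @param n_vertices vertices per polygon (>= 12).
#' @param seed integer seed for the random rotations.
#' @param tol aspect-ratio matching tolerance (default 1e-3).
#' @return a single-frame [polygon_ensemble()]; cell ids "1", "2", ...
#' @export
polygons_with_ar <- function(ar_values, n_vertices = 24L, seed = 1L,
                             tol = 1e-3) {
  ar_values <- as.numeric(ar_values)
  if (any(ar_values < 1)) stop("domain error: aspect ratios must be >= 1")
  stopifnot(n_vertices >= 12L)
  set.seed(seed)
  phis <- 2 * pi * (seq_len(n_vertices) - 1L) / n_vertices
  make_one <- function(target) {
    shape_at <- function(r) cbind(r * cos(phis), sin(phis))
    if (target == 1) {
      r_hat <- 1
    } else {
      f <- function(r) aspect_ratio(shape_at(r)) - target
      r_hat <- stats::uniroot(f, c(1, 4 * target + 1), tol = tol / 10)$root
    }
    p <- shape_at(r_hat)
    if (abs(aspect_ratio(p) - target) > tol) {
      stop("root-find failed to match requested aspect ratio")
    }
    th <- stats::runif(1L, 0, 2 * pi)
    rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
    p <- p %*% t(rot)
    p / sqrt(abs(polygon_area(p)))
  }
  frame <- lapply(ar_values, make_one)
  names(frame) <- as.character(seq_along(frame))
  polygon_ensemble(list(frame), validate = FALSE)
}
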