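#' Thermal vertex model of a confluent monolayer
#'
#' The tissue is a degree-3 polygonal tiling of a periodic rectangle:
#' `vertices` is a V x 2 matrix of positions, `cells` a list of
#' counterclockwise vertex-index cycles, every edge shared by exactly two
#' cells. The mechanical energy is the standard two-term form
#' \deqn{E = \sum_i K_A (A_i - A_0)^2 + K_P (P_i - P_0)^2,}
#' and the dynamics are overdamped Langevin at temperature T on the mobile
#' vertices, interleaved with T1 neighbor-exchange moves on edges shorter
#' than a threshold.
#'
#' @name vertex-model
NULL

.vm_default_params <- function(A0 = 1, p0 = 3.72, temperature = 0.009) {
  list(K_A = 1, A0 = A0, K_P = 1, P0 = p0 * sqrt(A0),
       temperature = temperature, gamma = 1, dt = 0.01,
       l_t1 = 0.04 * sqrt(A0))
}

#' Construct a vertex-model state
#'
#' @param vertices V x 2 matrix of vertex positions (wrapped into the box).
#' @param cells list of integer vertex cycles, counterclockwise.
#' @param box length-2 c(Lx, Ly).
#' @param params mechanical/dynamical parameters; see
#'   [vm_params()] for defaults.
#' @param mobile logical per-vertex mobility mask (default all TRUE).
#' @param validate run full topology validation.
#' @return object of class `vm_state`.
#' @export
vm_state <- function(vertices, cells, box, params = vm_params(),
                     mobile = NULL, validate = TRUE) {
  vertices <- as.matrix(vertices)
  stopifnot(ncol(vertices) == 2L, is.list(cells), length(box) == 2L)
  if (is.null(mobile)) mobile <- rep(TRUE, nrow(vertices))
  stopifnot(length(mobile) == nrow(vertices))
  st <- structure(list(vertices = vertices, cells = cells,
                       box = as.numeric(box), params = params,
                       mobile = mobile, flat = NULL),
                  class = "vm_state")
  st$flat <- .vm_flat(cells, nrow(vertices))
  if (validate) validate_vm_state(st)
  st
}

#' Vertex-model parameters
#'
#' Area stiffness K_A, target area A0, perimeter stiffness K_P, target
#' perimeter P0 = p0 sqrt(A0) (the target shape index p0 defaults to 3.72,
#' between the solid and fluid regimes; the regular hexagon has shape index
#' 3.722), temperature in energy units, friction gamma, time step dt, and
#' the T1 edge-length threshold l_t1 = 0.04 sqrt(A0).
#'
#' @param A0 target cell area.
#' @param p0 target shape index P0 / sqrt(A0).
#' @param temperature Langevin temperature in energy units.
#' @param ... overrides for any of K_A, K_P, gamma, dt, l_t1, P0.
#' @return named list of parameters.
#' @export
vm_params <- function(A0 = 1, p0 = 3.72, temperature = 0.009, ...) {
  p <- .vm_default_params(A0, p0, temperature)
  dots <- list(...)
  bad <- setdiff(names(dots), names(p))
  if (length(bad)) stop("unknown vertex-model parameter(s): ",
                        paste(bad, collapse = ", "))
  p[names(dots)] <- dots
  with(p, stopifnot(K_A > 0, A0 > 0, K_P > 0, P0 > 0, temperature >= 0,
                    gamma > 0, dt > 0, l_t1 > 0))
  p
}

## flat half-edge representation: one slot per (cell, position) pair
.vm_flat <- function(cells, n_vertices) {
  len <- lengths(cells)
  if (any(len < 3L)) stop("invalid topology: cell with fewer than 3 vertices")
  cell <- rep.int(seq_along(cells), len)
  v <- unlist(cells, use.names = FALSE)
  start <- cumsum(c(1L, len[-length(len)]))
  end <- cumsum(len)
  idx <- seq_along(v)
  nxt <- idx + 1L; nxt[end] <- start
  prv <- idx - 1L; prv[start] <- end
  list(cell = cell, v = v, vn = v[nxt], next_slot = nxt, prev_slot = prv,
       start = start, len = len, n_vertices = n_vertices)
}

## per-slot minimum-image edge vectors and per-cell geometry
.vm_geometry <- function(st) {
  fl <- st$flat
  r <- st$vertices
  dx <- .wrap_disp(r[fl$vn, 1L] - r[fl$v, 1L], st$box[1L])
  dy <- .wrap_disp(r[fl$vn, 2L] - r[fl$v, 2L], st$box[2L])
  ## positions relative to each cell's first vertex (unwrapped)
  csx <- cumsum(dx); csy <- cumsum(dy)
  prex <- c(0, csx[-length(csx)]); prey <- c(0, csy[-length(csy)])
  bx <- prex[fl$start][fl$cell]; by <- prey[fl$start][fl$cell]
  px <- prex - bx; py <- prey - by
  area <- as.numeric(rowsum(px * dy - py * dx, fl$cell)) / 2
  elen <- sqrt(dx^2 + dy^2)
  perim <- as.numeric(rowsum(elen, fl$cell))
  list(dx = dx, dy = dy, px = px, py = py, elen = elen,
       area = area, perim = perim)
}

#' Total mechanical energy of a vertex-model state
#'
#' Sum over cells of K_A (A - A0)^2 + K_P (P - P0)^2; nonnegative, and zero
#' iff every cell sits exactly at its target area and perimeter.
#'
#' @param st a [vm_state()].
#' @return scalar energy.
#' @export
vm_energy <- function(st) {
  stopifnot(inherits(st, "vm_state"))
  g <- .vm_geometry(st)
  p <- st$params
  sum(p$K_A * (g$area - p$A0)^2 + p$K_P * (g$perim - p$P0)^2)
}

#' Per-vertex forces (analytic energy gradient)
#'
#' F_v = -dE/dr_v from the shoelace-area and perimeter gradients. Forces are
#' reported for every vertex, including immobile ones (the mask is applied
#' by the integrator, not here).
#'
#' @param st a [vm_state()].
#' @return V x 2 matrix of forces.
#' @export
vm_forces <- function(st) {
  stopifnot(inherits(st, "vm_state"))
  g <- .vm_geometry(st)
  fl <- st$flat
  p <- st$params
  dpx <- g$dx[fl$prev_slot]; dpy <- g$dy[fl$prev_slot]
  lp <- g$elen[fl$prev_slot]; ln <- g$elen
  ## dA/dr_v = 0.5 * (d_next + d_prev) rotated by -90 deg
  dA_dx <- 0.5 * (g$dy + dpy)
  dA_dy <- -0.5 * (g$dx + dpx)
  ## dP/dr_v = unit(prev edge) - unit(next edge)
  eps <- 1e-300
  dP_dx <- dpx / pmax(lp, eps) - g$dx / pmax(ln, eps)
  dP_dy <- dpy / pmax(lp, eps) - g$dy / pmax(ln, eps)
  ca <- 2 * p$K_A * (g$area - p$A0)[fl$cell]
  cp <- 2 * p$K_P * (g$perim - p$P0)[fl$cell]
  fx <- rowsum(ca * dA_dx + cp * dP_dx, fl$v)  # sorted by vertex id
  fy <- rowsum(ca * dA_dy + cp * dP_dy, fl$v)
  f <- matrix(0, nrow(st$vertices), 2L)
  vid <- as.integer(rownames(fx))
  f[vid, 1L] <- -as.numeric(fx)
  f[vid, 2L] <- -as.numeric(fy)
  f
}

#' One overdamped Langevin step
#'
#' Mobile vertices move by dt/gamma * F plus Gaussian noise of variance
#' 2 T dt / gamma per coordinate; frozen vertices do not move. If the
#' deterministic (force) displacement of any mobile vertex would exceed
#' 0.1 l_t1 the step is taken as two half steps with recomputed forces
#' (recursively, with a warning).
#'
#' @param st a [vm_state()].
#' @param depth internal recursion counter for adaptive halving.
#' @return the advanced `vm_state`.
#' @export
vm_step <- function(st, depth = 0L) {
  p <- st$params
  f <- vm_forces(st)
  move <- f * (p$dt / p$gamma)
  mob <- st$mobile
  if (any(mob)) {
    mm <- max(abs(move[mob, ]))
    if (mm >= 0.1 * p$l_t1 && depth < 6L) {
      warning("step-size violation: halving dt for this step",
              call. = FALSE)
      st2 <- st; st2$params$dt <- p$dt / 2
      st2 <- vm_step(st2, depth + 1L)
      st2 <- vm_step(st2, depth + 1L)
      st2$params$dt <- p$dt
      return(st2)
    }
    nmob <- sum(mob)
    noise <- matrix(stats::rnorm(2L * nmob), nmob, 2L) *
      sqrt(2 * p$temperature * p$dt / p$gamma)
    st$vertices[mob, ] <- st$vertices[mob, , drop = FALSE] +
      move[mob, , drop = FALSE] + noise
    st$vertices[, 1L] <- st$vertices[, 1L] %% st$box[1L]
    st$vertices[, 2L] <- st$vertices[, 2L] %% st$box[2L]
  }
  st
}

## incidence: list of cell indices containing each vertex
.vm_cells_at_vertex <- function(st) {
  split(st$flat$cell, st$flat$v)
}

#' Attempt a T1 neighbor exchange on an edge
#'
#' The edge (a, b) is rotated 90 degrees about its midpoint and reconnected
#' so that the two cells sharing it separate and the two cells meeting it
#' only at an endpoint become neighbors; the new edge length is set to
#' 1.02 l_t1. The move is rejected (returning the state unchanged, with
#' attribute `accepted = FALSE`) when an endpoint is immobile, when either
#' losing cell is a triangle (the flip would create a 2-sided cell), or when
#' the surrounding cell quad is degenerate.
#'
#' @param st a [vm_state()].
#' @param a,b vertex indices of the edge endpoints.
#' @return updated `vm_state` with attribute `accepted`.
#' @export
vm_t1 <- function(st, a, b) {
  reject <- function(st) { attr(st, "accepted") <- FALSE; st }
  if (!(st$mobile[a] && st$mobile[b])) return(reject(st))
  cav <- .vm_cells_at_vertex(st)
  ca <- cav[[as.character(a)]]; cb <- cav[[as.character(b)]]
  if (length(ca) != 3L || length(cb) != 3L) return(reject(st))
  shared <- intersect(ca, cb)
  if (length(shared) != 2L) return(reject(st))
  Rc <- setdiff(ca, shared); Sc <- setdiff(cb, shared)
  if (length(Rc) != 1L || length(Sc) != 1L || Rc == Sc) return(reject(st))
  ## P contains a followed by b; Q contains b followed by a
  nxt_in <- function(cell, v) {
    cyc <- st$cells[[cell]]
    cyc[(match(v, cyc) %% length(cyc)) + 1L]
  }
  P <- if (nxt_in(shared[1L], a) == b) shared[1L] else shared[2L]
  Q <- setdiff(shared, P)
  if (nxt_in(P, a) != b || nxt_in(Q, b) != a) return(reject(st))
  if (length(st$cells[[P]]) <= 3L || length(st$cells[[Q]]) <= 3L) {
    return(reject(st))
  }
  ## geometry: rotate the edge about its midpoint
  ra <- st$vertices[a, ]; rb <- st$vertices[b, ]
  u <- c(.wrap_disp(rb[1L] - ra[1L], st$box[1L]),
         .wrap_disp(rb[2L] - ra[2L], st$box[2L]))
  len <- sqrt(sum(u^2))
  if (len == 0) return(reject(st))
  m <- ra + u / 2
  nvec <- c(-u[2L], u[1L]) / len         # left normal of a -> b (P side)
  delta <- 1.02 * st$params$l_t1 / 2
  st$vertices[a, ] <- (m + delta * nvec) %% st$box
  st$vertices[b, ] <- (m - delta * nvec) %% st$box
  ## topology: P drops b, Q drops a, R gains b before a, S gains a before b
  st$cells[[P]] <- setdiff(st$cells[[P]], b)
  st$cells[[Q]] <- setdiff(st$cells[[Q]], a)
  ins_before <- function(cyc, newv, at) {
    i <- match(at, cyc)
    append(cyc, newv, after = i - 1L)
  }
  st$cells[[Rc]] <- ins_before(st$cells[[Rc]], b, a)
  st$cells[[Sc]] <- ins_before(st$cells[[Sc]], a, b)
  st$flat <- .vm_flat(st$cells, nrow(st$vertices))
  attr(st, "accepted") <- TRUE
  st
}

## one sweep over all eligible short edges, in random order
.vm_t1_sweep <- function(st) {
  n_flips <- 0L
  fl <- st$flat
  sel <- fl$v < fl$vn
  ea <- fl$v[sel]; eb <- fl$vn[sel]
  dx <- .wrap_disp(st$vertices[eb, 1L] - st$vertices[ea, 1L], st$box[1L])
  dy <- .wrap_disp(st$vertices[eb, 2L] - st$vertices[ea, 2L], st$box[2L])
  short <- which(sqrt(dx^2 + dy^2) < st$params$l_t1 &
                   st$mobile[ea] & st$mobile[eb])
  if (length(short) == 0L) return(list(state = st, n_flips = 0L))
  for (i in sample(short)) {
    a <- ea[i]; b <- eb[i]
    ## re-check current length (earlier flips may have moved things)
    d <- c(.wrap_disp(st$vertices[b, 1L] - st$vertices[a, 1L], st$box[1L]),
           .wrap_disp(st$vertices[b, 2L] - st$vertices[a, 2L], st$box[2L]))
    if (sqrt(sum(d^2)) >= st$params$l_t1) next
    st2 <- vm_t1(st, a, b)
    if (isTRUE(attr(st2, "accepted"))) {
      st <- st2
      n_flips <- n_flips + 1L
    }
  }
  list(state = st, n_flips = n_flips)
}

#' Validate vertex-model invariants
#'
#' Degree-3 vertices, every edge shared by exactly two cells in opposite
#' orientations, Euler characteristic 0 on the torus, positive simple cell
#' areas summing to the box area.
#'
#' @param st a [vm_state()].
#' @return TRUE invisibly; errors on violation.
#' @export
validate_vm_state <- function(st) {
  fl <- st$flat
  deg <- tabulate(fl$v, nbins = nrow(st$vertices))
  if (any(deg != 3L)) {
    stop("invariant violation: vertex degree != 3 (vertices ",
         paste(utils::head(which(deg != 3L), 5L), collapse = ", "), ")")
  }
  ekey <- paste(pmin(fl$v, fl$vn), pmax(fl$v, fl$vn))
  cnt <- table(ekey)
  if (any(cnt != 2L)) stop("invariant violation: edge not shared by 2 cells")
  dkey <- paste(fl$v, fl$vn)
  if (anyDuplicated(dkey)) {
    stop("invariant violation: edge traversed twice in the same orientation")
  }
  V <- nrow(st$vertices); E <- length(ekey) / 2; F <- length(st$cells)
  if (V - E + F != 0) stop("invariant violation: Euler characteristic != 0")
  g <- .vm_geometry(st)
  if (any(g$area <= 0)) stop("invariant violation: non-positive cell area")
  if (abs(sum(g$area) - prod(st$box)) > 1e-8 * prod(st$box)) {
    stop("invariant violation: cell areas do not tile the box")
  }
  invisible(TRUE)
}

#' @export
print.vm_state <- function(x, ...) {
  cat(sprintf(
    "vm_state: %d cells, %d vertices, box %.3g x %.3g, T = %g, p0 = %.3f, %d mobile vertices\n",
    length(x$cells), nrow(x$vertices), x$box[1L], x$box[2L],
    x$params$temperature, x$params$P0 / sqrt(x$params$A0), sum(x$mobile)))
  invisible(x)
}

#' Initialize a confluent tissue
#'
#' Voronoi tessellation of a perturbed triangular lattice on a periodic
#' rectangle sized so the mean cell area equals A0. Disorder 0 gives the
#' regular hexagonal tiling. Degenerate tessellations (non-degree-3
#' vertices) are retried with an incremented seed.
#'
#' @param n_cells number of cells; must factor as nx * ny with ny even.
#' @param box_aspect target Lx / Ly ratio used to pick the lattice factors.
#' @param disorder seed-perturbation amplitude in units of the lattice
#'   spacing, in \[0, 0.5\].
#' @param seed integer seed.
#' @param params vertex-model parameters, see [vm_params()].
#' @return a [vm_state()] with all vertices mobile.
#' @export
init_tissue <- function(n_cells, box_aspect = 1, disorder = 0.3, seed = 1L,
                        params = vm_params()) {
  stopifnot(n_cells >= 4L, disorder >= 0, disorder <= 0.5)
  a <- sqrt(2 * params$A0 / sqrt(3))
  ## factor n_cells = nx * ny, ny even, aspect closest to box_aspect
  divs <- which(n_cells %% seq_len(n_cells) == 0L)
  cand <- data.frame(ny = divs, nx = n_cells / divs)
  cand <- cand[cand$ny %% 2L == 0L & cand$nx >= 2L & cand$ny >= 2L, ]
  if (nrow(cand) == 0L) {
    stop("n_cells must factor as nx * ny with ny even and nx, ny >= 2")
  }
  asp <- (cand$nx * a) / (cand$ny * a * sqrt(3) / 2)
  pick <- cand[which.min(abs(log(asp / box_aspect))), ]
  nx <- pick$nx; ny <- pick$ny
  box <- c(nx * a, ny * a * sqrt(3) / 2)
  ix <- rep(0:(nx - 1L), times = ny)
  iy <- rep(0:(ny - 1L), each = nx)
  sx <- (ix + 0.5 * (iy %% 2L)) * a
  sy <- iy * a * sqrt(3) / 2
  for (attempt in 0:9) {
    set.seed(seed + attempt)
    px <- (sx + stats::runif(n_cells, -1, 1) * disorder * a) %% box[1L]
    py <- (sy + stats::runif(n_cells, -1, 1) * disorder * a) %% box[2L]
    st <- tryCatch({
      vor <- periodic_voronoi(cbind(px, py), box)
      vm_state(vor$centers, vor$cells, box, params = params)
    }, error = function(e) e)
    if (inherits(st, "vm_state")) {
      if (attempt > 0L) {
        message("init_tissue: degenerate tessellation, re-perturbed with seed ",
                seed + attempt)
      }
      return(st)
    }
  }
  stop("init_tissue: could not build a valid tessellation: ",
       conditionMessage(st))
}

#' Freeze all but a compact cluster of n cells
#'
#' The mobile cluster is grown by breadth-first search over cell adjacency
#' from the cell nearest the box center (ties by cell index). A vertex is
#' mobile iff all of its incident cells are in the cluster, so n = 1 leaves
#' no mobile vertex and the single interior cell cannot change shape. T1
#' moves are automatically restricted to fully mobile edges.
#'
#' @param st a [vm_state()].
#' @param n cluster size, 1 <= n <= number of cells.
#' @return the state with `mobile` mask and `cluster` (cell indices) set.
#' @export
freeze_exterior <- function(st, n) {
  stopifnot(inherits(st, "vm_state"))
  nc <- length(st$cells)
  if (n < 1L || n > nc) stop("parameter error: n must be in [1, n_cells]")
  ## cell adjacency from shared edges
  fl <- st$flat
  ekey <- paste(pmin(fl$v, fl$vn), pmax(fl$v, fl$vn))
  pair <- split(fl$cell, ekey)
  adj <- do.call(rbind, pair)  # each edge: the two incident cells
  ## centroids to find the central cell
  cen <- vm_centroids(st)
  d2 <- (.wrap_disp(cen[, 1L] - st$box[1L] / 2, st$box[1L]))^2 +
    (.wrap_disp(cen[, 2L] - st$box[2L] / 2, st$box[2L]))^2
  root <- which.min(d2)
  nb <- split(c(adj[, 2L], adj[, 1L]), c(adj[, 1L], adj[, 2L]))
  cluster <- root
  frontier <- root
  while (length(cluster) < n) {
    cand <- sort(unique(unlist(nb[as.character(frontier)])))
    cand <- setdiff(cand, cluster)
    if (length(cand) == 0L) break
    take <- utils::head(cand, n - length(cluster))
    cluster <- c(cluster, take)
    frontier <- take
  }
  inc <- rep(FALSE, nc); inc[cluster] <- TRUE
  cav <- .vm_cells_at_vertex(st)
  mob <- vapply(seq_len(nrow(st$vertices)), function(v) {
    all(inc[cav[[as.character(v)]]])
  }, logical(1L))
  st$mobile <- mob
  st$cluster <- sort(cluster)
  st
}

#' Cell centroids of a vertex-model state
#'
#' Area-weighted polygon centroids, wrapped into the box.
#'
#' @param st a [vm_state()].
#' @return n_cells x 2 matrix.
#' @export
vm_centroids <- function(st) {
  g <- .vm_geometry(st)
  fl <- st$flat
  dx <- g$dx; dy <- g$dy; px <- g$px; py <- g$py
  ## shoelace centroid on the cell-relative unwrapped coordinates
  cr <- px * dy - py * dx  # cross(p_k, p_{k+1}) since p_{k+1} = p_k + d_k
  cx <- as.numeric(rowsum((2 * px + dx) * cr, fl$cell)) / (6 * g$area)
  cy <- as.numeric(rowsum((2 * py + dy) * cr, fl$cell)) / (6 * g$area)
  base <- st$vertices[fl$v[fl$start], , drop = FALSE]
  cbind((base[, 1L] + cx) %% st$box[1L],
        (base[, 2L] + cy) %% st$box[2L])
}

#' Cell polygons of a vertex-model state
#'
#' Per-cell outlines as coordinate matrices, each unwrapped around its own
#' first vertex (so polygons straddling the periodic boundary are contiguous).
#'
#' @param st a [vm_state()].
#' @return named list of n x 2 matrices ("1", "2", ...).
#' @export
vm_polygons <- function(st) {
  g <- .vm_geometry(st)
  fl <- st$flat
  base <- st$vertices[fl$v[fl$start], , drop = FALSE]
  xs <- g$px + base[fl$cell, 1L]
  ys <- g$py + base[fl$cell, 2L]
  out <- lapply(seq_along(st$cells), function(i) {
    sel <- fl$cell == i
    cbind(xs[sel], ys[sel])
  })
  names(out) <- as.character(seq_along(st$cells))
  out
}

#' Run the thermal vertex model
#'
#' Alternates overdamped Langevin steps with T1 sweeps over all
#' sub-threshold eligible edges (random order), emitting snapshots at a
#' fixed stride. Deterministic given the seed.
#'
#' @param st a [vm_state()].
#' @param n_steps number of time steps.
#' @param snapshot_stride record a snapshot every this many steps.
#' @param seed integer seed.
#' @param validate_every topology invariants asserted every this many steps
#'   (0 disables interior checks; a final check always runs).
#' @return object of class `vm_trajectory`: list with `snapshots` (each
#'   holding `step`, `vertices`, `cells`, `mobile`), `box`, `params`,
#'   `dt`, `t1_count`, `final_state`.
#' @export
vm_run <- function(st, n_steps, snapshot_stride = 10L, seed = 1L,
                   validate_every = 1000L) {
  stopifnot(inherits(st, "vm_state"), n_steps >= 1L)
  set.seed(seed)
  snaps <- list()
  t1_count <- 0L
  take_snap <- function(step) {
    list(step = step, vertices = st$vertices, cells = st$cells,
         mobile = st$mobile)
  }
  snaps[[1L]] <- take_snap(0L)
  n_halved <- 0L
  for (s in seq_len(n_steps)) {
    ## collect per-step size-violation warnings into one summary at the end
    st <- withCallingHandlers(
      vm_step(st),
      warning = function(w) {
        if (grepl("step-size violation", conditionMessage(w))) {
          n_halved <<- n_halved + 1L
          invokeRestart("muffleWarning")
        }
      })
    sw <- .vm_t1_sweep(st)
    st <- sw$state
    t1_count <- t1_count + sw$n_flips
    if (validate_every > 0L && s %% validate_every == 0L) {
      validate_vm_state(st)
    }
    if (s %% snapshot_stride == 0L) snaps[[length(snaps) + 1L]] <- take_snap(s)
  }
  validate_vm_state(st)
  if (n_halved > 0L) {
    warning("step-size violation: dt halved ", n_halved, " time(s) over ",
            n_steps, " steps", call. = FALSE)
  }
  structure(list(snapshots = snaps, box = st$box, params = st$params,
                 dt = st$params$dt * snapshot_stride, t1_count = t1_count,
                 final_state = st),
            class = "vm_trajectory")
}

#' @export
print.vm_trajectory <- function(x, ...) {
  cat(sprintf(
    "vm_trajectory: %d snapshots, %d cells, %d T1 event(s)\n",
    length(x$snapshots), length(x$snapshots[[1L]]$cells), x$t1_count))
  invisible(x)
}

#' Centroid trajectory view of a vertex-model run
#'
#' @param vt a [vm_run()] result.
#' @return a [trajectory()] of cell centroids (periodic box, phi = 1).
#' @export
vm_as_trajectory <- function(vt) {
  stopifnot(inherits(vt, "vm_trajectory"))
  nf <- length(vt$snapshots)
  nc <- length(vt$snapshots[[1L]]$cells)
  pos <- array(NA_real_, c(nf, nc, 2L))
  for (i in seq_len(nf)) {
    sn <- vt$snapshots[[i]]
    sti <- vm_state(sn$vertices, sn$cells, vt$box, params = vt$params,
                    mobile = sn$mobile, validate = FALSE)
    pos[i, , ] <- vm_centroids(sti)
  }
  trajectory(pos, dt = vt$dt,
             box = list(type = "periodic", Lx = vt$box[1L], Ly = vt$box[2L]),
             phi = 1)
}

#' Polygon-ensemble view of a vertex-model run
#'
#' @param vt a [vm_run()] result.
#' @param cells optional subset of cell indices.
#' @return a [polygon_ensemble()].
#' @export
vm_as_polygon_ensemble <- function(vt, cells = NULL) {
  stopifnot(inherits(vt, "vm_trajectory"))
  frames <- lapply(vt$snapshots, function(sn) {
    sti <- vm_state(sn$vertices, sn$cells, vt$box, params = vt$params,
                    mobile = sn$mobile, validate = FALSE)
    pg <- vm_polygons(sti)
    if (!is.null(cells)) pg <- pg[as.character(cells)]
    pg
  })
  polygon_ensemble(frames, validate = FALSE)
}
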