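#' Periodic Voronoi tessellation via image copies
#'
#' Delaunay/Voronoi duality on the torus is obtained by tiling the point set
#' with its 8 periodic images, triangulating the tiling (deldir), and keeping
#' exactly one representative per torus triangle: the one whose circumcenter
#' falls inside the fundamental domain. Voronoi vertices of the torus are the
#' circumcenters of the kept triangles; each point's Voronoi cell is the
#' polygon of its incident circumcenters ordered by angle.
#'
#' @param points n x 2 matrix of positions inside the box (n >= 4).
#' @param box length-2 numeric c(Lx, Ly).
#' @return list with `points` (wrapped into the box), `box`,
#'   `triangles` (m x 3 matrix of point indices per kept triangle),
#'   `centers` (m x 2 circumcenters in the fundamental domain),
#'   `cells` (per point, incident triangle indices in counterclockwise
#'   order), `areas` (per-point Voronoi areas), and `adjacency`
#'   (two-column matrix of neighboring point index pairs, i < j).
#' @export
periodic_voronoi <- function(points, box) {
  pts <- as.matrix(points)
  stopifnot(ncol(pts) == 2L, is.numeric(box), length(box) == 2L,
            all(box > 0))
  n <- nrow(pts)
  if (n < 4L) stop("need at least 4 points for a tessellation")
  if (!all(is.finite(pts))) stop("geometry error: non-finite position")
  pts[, 1L] <- pts[, 1L] %% box[1L]
  pts[, 2L] <- pts[, 2L] %% box[2L]
  ## duplicate points break the tessellation
  key <- paste(signif(pts[, 1L], 12), signif(pts[, 2L], 12))
  if (anyDuplicated(key)) stop("geometry error: duplicate (co-located) points")

  offs <- as.matrix(expand.grid(ox = c(0, -1, 1), oy = c(0, -1, 1)))
  allx <- rep(pts[, 1L], nrow(offs)) + rep(offs[, 1L], each = n) * box[1L]
  ally <- rep(pts[, 2L], nrow(offs)) + rep(offs[, 2L], each = n) * box[2L]
  orig <- rep.int(seq_len(n), nrow(offs))

  dd <- deldir::deldir(allx, ally, suppressMsge = TRUE)
  tm <- deldir::triMat(dd)

  ## circumcenters of all triangles
  ax <- allx[tm[, 1L]]; ay <- ally[tm[, 1L]]
  bx <- allx[tm[, 2L]]; by <- ally[tm[, 2L]]
  cx <- allx[tm[, 3L]]; cy <- ally[tm[, 3L]]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
  ## Keep one representative per torus triangle. The half-open test on the
  ## circumcenter is exact for generic points, but when a circumcenter lands
  ## on the domain boundary (regular lattices), rounding can keep both
  ## periodic copies or neither. So: accept within a small tolerance of the
  ## box, then deduplicate by a translation-invariant triangle key (sorted
  ## original indices + the circumcenter's minimum-image offset from the
  ## first vertex).
  eps <- 1e-9 * max(box)
  keep <- is.finite(ux) & is.finite(uy) &
    ux >= -eps & ux < box[1L] + eps & uy >= -eps & uy < box[2L] + eps
  tri <- cbind(orig[tm[keep, 1L]], orig[tm[keep, 2L]], orig[tm[keep, 3L]])
  cen <- cbind(ux[keep] %% box[1L], uy[keep] %% box[2L])
  tri_sorted <- t(apply(tri, 1L, sort))
  rx <- .wrap_disp(cen[, 1L] - pts[tri_sorted[, 1L], 1L], box[1L])
  ry <- .wrap_disp(cen[, 2L] - pts[tri_sorted[, 1L], 2L], box[2L])
  tkey <- paste(tri_sorted[, 1L], tri_sorted[, 2L], tri_sorted[, 3L],
                round(rx, 6L), round(ry, 6L))
  first <- !duplicated(tkey)
  tri <- tri[first, , drop = FALSE]
  cen <- cen[first, , drop = FALSE]
  m <- nrow(tri)
  if (m == 0L) stop("geometry error: degenerate tessellation")

  ## incident triangles per point, ordered counterclockwise around the seed
  inc <- split(rep(seq_len(m), 3L), as.vector(tri))
  if (length(inc) != n || any(lengths(inc) < 3L)) {
    stop("geometry error: degenerate tessellation (incomplete Voronoi cells)")
  }
  inc <- inc[as.character(seq_len(n))]
  cells <- vector("list", n)
  areas <- numeric(n)
  for (i in seq_len(n)) {
    ti <- inc[[i]]
    dx <- .wrap_disp(cen[ti, 1L] - pts[i, 1L], box[1L])
    dy <- .wrap_disp(cen[ti, 2L] - pts[i, 2L], box[2L])
    o <- order(atan2(dy, dx))
    cells[[i]] <- ti[o]
    px <- dx[o]; py <- dy[o]
    j <- c(seq_along(px)[-1L], 1L)
    areas[i] <- sum(px * py[j] - px[j] * py) / 2
  }
  if (any(areas <= 0)) {
    stop("geometry error: non-positive Voronoi cell area")
  }

  e <- rbind(tri[, c(1L, 2L)], tri[, c(2L, 3L)], tri[, c(3L, 1L)])
  e <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  e <- unique(e)
  e <- e[e[, 1L] != e[, 2L], , drop = FALSE]

  list(points = pts, box = box, triangles = tri, centers = cen,
       cells = cells, areas = areas, adjacency = e)
}

## signed minimum-image displacement on a periodic interval of length L
.wrap_disp <- function(d, L) d - L * round(d / L)

#' Per-cell Voronoi areas
#'
#' For periodic boxes the tessellation is built from image copies and the
#' areas sum exactly to the box area; for non-periodic (walled) data the
#' plane tessellation is clipped to the bounding window, which distorts the
#' cells touching the wall (exclude them upstream if needed).
#'
#' @param points n x 2 matrix of cell-center positions.
#' @param box for periodic data, length-2 c(Lx, Ly); for walled data, a
#'   list `list(type = "none")` or `NULL` to use the bounding rectangle.
#' @param breaks histogram breaks (default 30 bins spanning the areas).
#' @return list with `areas` (per input point) and `histogram`
#'   (density-normalized, from [graphics::hist()]).
#' @export
voronoi_areas <- function(points, box, breaks = 30L) {
  pts <- as.matrix(points)
  if (nrow(pts) < 4L) stop("need at least 4 points")
  if (is.numeric(box) && length(box) == 2L) {
    vor <- periodic_voronoi(pts, box)
    areas <- vor$areas
  } else {
    key <- paste(signif(pts[, 1L], 12), signif(pts[, 2L], 12))
    if (anyDuplicated(key)) stop("geometry error: duplicate points")
    dd <- deldir::deldir(pts[, 1L], pts[, 2L], suppressMsge = TRUE)
    areas <- dd$summary$dir.area
  }
  h <- graphics::hist(areas, breaks = breaks, plot = FALSE)
  list(areas = areas, histogram = h)
}
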