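#' Polygon geometry for cell outlines
#'
#' Cells are represented as closed simple polygons: an n x 2 numeric matrix of
#' vertex coordinates, the last vertex implicitly connected to the first.
#' Counterclockwise orientation gives positive shoelace area.
#'
#' @name polygon-geometry
NULL

## shoelace cross terms x_i*y_{i+1} - x_{i+1}*y_i for a closed polygon
.poly_cross <- function(p) {
  i2 <- c(2:nrow(p), 1L)
  p[, 1L] * p[i2, 2L] - p[i2, 1L] * p[, 2L]
}

#' Signed polygon area (shoelace formula)
#'
#' @param p numeric matrix with two columns (x, y); vertices in order,
#'   closed implicitly.
#' @return signed area; positive for counterclockwise orientation.
#' @export
polygon_area <- function(p) {
  p <- validate_polygon(p, check_area = FALSE)
  sum(.poly_cross(p)) / 2
}

#' Polygon centroid (area-weighted)
#'
#' @inheritParams polygon_area
#' @return length-2 numeric vector (x, y).
#' @export
polygon_centroid <- function(p) {
  p <- validate_polygon(p)
  cr <- .poly_cross(p)
  a <- sum(cr) / 2
  i2 <- c(2:nrow(p), 1L)
  cx <- sum((p[, 1L] + p[i2, 1L]) * cr) / (6 * a)
  cy <- sum((p[, 2L] + p[i2, 2L]) * cr) / (6 * a)
  c(cx, cy)
}

#' Area-normalized second-moment (covariance) tensor of a polygon interior
#'
#' The integral of the outer product of position about the centroid over the
#' polygon interior, divided by the area. For an ellipse with semi-axes a, b
#' the eigenvalues are a^2/4 and b^2/4.
#'
#' @inheritParams polygon_area
#' @return 2 x 2 symmetric matrix.
#' @export
polygon_moment_tensor <- function(p) {
  p <- validate_polygon(p)
  cr <- .poly_cross(p)
  a <- sum(cr) / 2
  i2 <- c(2:nrow(p), 1L)
  x1 <- p[, 1L]; y1 <- p[, 2L]; x2 <- p[i2, 1L]; y2 <- p[i2, 2L]
  cx <- sum((x1 + x2) * cr) / (6 * a)
  cy <- sum((y1 + y2) * cr) / (6 * a)
  ixx <- sum((x1^2 + x1 * x2 + x2^2) * cr) / 12
  iyy <- sum((y1^2 + y1 * y2 + y2^2) * cr) / 12
  ixy <- sum((x1 * y2 + 2 * x1 * y1 + 2 * x2 * y2 + x2 * y1) * cr) / 24
  m <- matrix(c(ixx / a - cx^2, ixy / a - cx * cy,
                ixy / a - cx * cy, iyy / a - cy^2), 2L, 2L)
  m
}

#' Aspect ratio of a cell outline
#'
#' The elongation estimator used throughout the package: the square root of
#' the eigenvalue ratio of the area-weighted second-moment tensor of the
#' polygon interior (the best-fit-ellipse convention of the shape-variability
#' literature). Equals 1 for any shape with a symmetry forcing equal
#' eigenvalues (circle, regular polygon) and the axis ratio a/b for an
#' ellipse. Invariant under rotation, translation and uniform scaling.
#'
#' @inheritParams polygon_area
#' @return aspect ratio, a dimensionless number >= 1.
#' @examples
#' hexagon <- cbind(cos(2 * pi * (0:5) / 6), sin(2 * pi * (0:5) / 6))
#' aspect_ratio(hexagon)  # 1 up to machine precision
#' @export
aspect_ratio <- function(p) {
  m <- polygon_moment_tensor(p)
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (ev[2L] <= 0) {
    stop("invalid geometry: degenerate polygon (singular moment tensor)")
  }
  sqrt(ev[1L] / ev[2L])
}

#' Validate a polygon
#'
#' Checks vertex count, finiteness and non-degenerate area; optionally checks
#' simplicity (no self-intersections) by exhaustive segment-pair testing.
#'
#' @inheritParams polygon_area
#' @param check_area error when the shoelace area is (numerically) zero.
#' @param check_simple also test for self-intersection (O(n^2); off by
#'   default, intended for data validation, not hot loops).
#' @return the polygon as a numeric matrix, invisibly usable.
#' @export
validate_polygon <- function(p, check_area = TRUE, check_simple = FALSE) {
  p <- as.matrix(p)
  if (ncol(p) != 2L || !is.numeric(p)) {
    stop("invalid geometry: polygon must be an n x 2 numeric matrix")
  }
  if (nrow(p) < 3L) stop("invalid geometry: polygon needs >= 3 vertices")
  if (!all(is.finite(p))) stop("invalid geometry: non-finite vertex coordinate")
  if (check_area) {
    a <- sum(.poly_cross(p)) / 2
    scale2 <- max(apply(p, 2L, function(z) diff(range(z))))^2
    if (abs(a) <= max(scale2, 1) * 1e-12) {
      stop("invalid geometry: polygon has zero area")
    }
  }
  if (check_simple && .poly_self_intersects(p)) {
    stop("invalid geometry: polygon is self-intersecting")
  }
  p
}

.segments_cross <- function(p1, p2, q1, q2) {
  d <- function(a, b, c) (b[1L] - a[1L]) * (c[2L] - a[2L]) -
    (b[2L] - a[2L]) * (c[1L] - a[1L])
  d1 <- d(q1, q2, p1); d2 <- d(q1, q2, p2)
  d3 <- d(p1, p2, q1); d4 <- d(p1, p2, q2)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

.poly_self_intersects <- function(p) {
  n <- nrow(p)
  i2 <- c(2:n, 1L)
  for (i in seq_len(n - 2L)) {
    for (j in (i + 2L):n) {
      if (i == 1L && j == n) next  # adjacent through closure
      if (.segments_cross(p[i, ], p[i2[i], ], p[j, ], p[i2[j], ])) return(TRUE)
    }
  }
  FALSE
}

#' Polygon ensembles
#'
#' A `polygon_ensemble` holds per-frame, per-cell closed outlines: a list of
#' frames, each frame a named list mapping cell id to an n x 2 coordinate
#' matrix.
#'
#' @param frames list of frames; each frame a named list of polygons.
#' @param validate check every polygon (vertex count, area).
#' @return an object of class `polygon_ensemble`.
#' @export
polygon_ensemble <- function(frames, validate = TRUE) {
  stopifnot(is.list(frames), length(frames) >= 1L)
  if (validate) {
    for (f in frames) {
      if (is.null(names(f)) || any(!nzchar(names(f)))) {
        stop("every polygon in a frame must be named by its cell id")
      }
      lapply(f, validate_polygon)
    }
  }
  structure(list(frames = frames), class = "polygon_ensemble")
}

#' @export
print.polygon_ensemble <- function(x, ...) {
  nf <- length(x$frames)
  nc <- length(x$frames[[1L]])
  cat("polygon_ensemble:", nf, "frame(s),", nc, "cell(s) in frame 1\n")
  invisible(x)
}

#' Aspect ratios of every polygon in an ensemble
#'
#' @param ensemble a [polygon_ensemble()].
#' @param cell_ids optional character vector restricting to a cell subset.
#' @return data.frame with columns `frame`, `cell_id`, `ar`.
#' @export
ensemble_aspect_ratios <- function(ensemble, cell_ids = NULL) {
  stopifnot(inherits(ensemble, "polygon_ensemble"))
  out <- lapply(seq_along(ensemble$frames), function(i) {
    fr <- ensemble$frames[[i]]
    ids <- names(fr)
    if (!is.null(cell_ids)) ids <- intersect(ids, as.character(cell_ids))
    if (length(ids) == 0L) return(NULL)
    data.frame(frame = i, cell_id = ids,
               ar = vapply(fr[ids], aspect_ratio, numeric(1L)),
               row.names = NULL)
  })
  do.call(rbind, out)
}
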