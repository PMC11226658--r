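#' File formats
#'
#' Plain-text columnar formats with JSON sidecars, chosen for
#' inspectability at desk scale.
#'
#' Trajectories: whitespace/comma-separated columns `frame`, `cell_id`,
#' `x`, `y` (frame 0-based) plus a JSON sidecar `<path>.json` holding
#' `dt`, `box_type` ("periodic" or "circular"), `Lx`/`Ly` or `R`, and `phi`.
#'
#' Polygon outlines: columns `frame_index` (0-based), `cell_id`,
#' `vertex_index`, `x`, `y`, with a header line.
#'
#' @name file-formats
NULL

#' Write a trajectory to disk
#'
#' @param traj a [trajectory()].
#' @param path output file; the sidecar goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  d <- dim(traj$positions)
  df <- data.frame(
    frame = rep(0:(d[1L] - 1L), times = d[2L]),
    cell_id = rep(traj$cell_ids, each = d[1L]),
    x = as.vector(traj$positions[, , 1L]),
    y = as.vector(traj$positions[, , 2L]))
  df <- df[order(df$frame, df$cell_id), ]
  utils::write.table(df, path, row.names = FALSE, quote = FALSE, sep = "\t")
  side <- list(dt = traj$dt, box_type = traj$box$type, phi = traj$phi)
  if (traj$box$type == "periodic") {
    side$Lx <- traj$box$Lx; side$Ly <- traj$box$Ly
  } else side$R <- traj$box$R
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a trajectory from disk
#'
#' Frames are sorted, cell ids checked for consistency across frames, and
#' non-finite coordinates rejected with the offending row named.
#'
#' @param path trajectory file written by [write_trajectory()] (sidecar at
#'   `<path>.json`).
#' @return a [trajectory()].
#' @export
read_trajectory <- function(path) {
  side_path <- paste0(path, ".json")
  if (!file.exists(side_path)) {
    stop("schema error: missing JSON sidecar ", side_path)
  }
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("frame", "cell_id", "x", "y")
  if (!all(need %in% names(df))) {
    stop("schema error: expected columns ", paste(need, collapse = ", "))
  }
  bad <- which(!is.finite(df$x) | !is.finite(df$y))
  if (length(bad)) {
    stop("schema error: non-finite coordinate at row ", bad[1L])
  }
  df <- df[order(df$frame, df$cell_id), ]
  frames <- sort(unique(df$frame))
  if (!identical(frames, seq(min(frames), max(frames)))) {
    stop("schema error: non-contiguous frame indices")
  }
  ids <- sort(unique(df$cell_id))
  nf <- length(frames); nc <- length(ids)
  if (nrow(df) != nf * nc) {
    stop("schema error: frames do not all contain the same cells")
  }
  pos <- array(NA_real_, c(nf, nc, 2L))
  pos[, , 1L] <- matrix(df$x, nf, nc, byrow = TRUE)
  pos[, , 2L] <- matrix(df$y, nf, nc, byrow = TRUE)
  box <- if (identical(side$box_type, "periodic")) {
    list(type = "periodic", Lx = side$Lx, Ly = side$Ly)
  } else if (identical(side$box_type, "circular")) {
    list(type = "circular", R = side$R)
  } else stop("schema error: unknown box_type in sidecar")
  trajectory(pos, dt = side$dt, box = box,
             phi = if (is.null(side$phi)) NA_real_ else side$phi,
             cell_ids = ids)
}

#' Write a polygon ensemble to disk
#'
#' @param ensemble a [polygon_ensemble()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_polygons <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "polygon_ensemble"))
  rows <- list()
  for (fi in seq_along(ensemble$frames)) {
    fr <- ensemble$frames[[fi]]
    for (id in names(fr)) {
      p <- fr[[id]]
      rows[[length(rows) + 1L]] <- data.frame(
        frame_index = fi - 1L, cell_id = id,
        vertex_index = seq_len(nrow(p)) - 1L,
        x = p[, 1L], y = p[, 2L])
    }
  }
  utils::write.table(do.call(rbind, rows), path, row.names = FALSE,
                     quote = FALSE, sep = "\t")
  invisible(path)
}

#' Read a polygon ensemble from disk
#'
#' @param path file written by [write_polygons()].
#' @param validate run polygon validation on every outline.
#' @return a [polygon_ensemble()].
#' @export
read_polygons <- function(path, validate = TRUE) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("frame_index", "cell_id", "vertex_index", "x", "y")
  if (!all(need %in% names(df))) {
    stop("schema error: expected columns ", paste(need, collapse = ", "))
  }
  bad <- which(!is.finite(df$x) | !is.finite(df$y))
  if (length(bad)) stop("schema error: non-finite coordinate at row ", bad[1L])
  df <- df[order(df$frame_index, df$cell_id, df$vertex_index), ]
  frames <- lapply(split(df, df$frame_index), function(d) {
    polys <- lapply(split(d, d$cell_id), function(pd) {
      cbind(pd$x, pd$y)
    })
    polys
  })
  polygon_ensemble(unname(frames), validate = validate)
}

#' Serialize a distribution fit as JSON
#'
#' @param fit a `kgamma_fit` or `meanfield_fit`.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  out <- if (inherits(fit, "kgamma_fit")) {
    list(distribution = "kgamma", parameter = fit$k, loglik = fit$loglik,
         n = fit$n)
  } else if (inherits(fit, "meanfield_fit")) {
    list(distribution = "meanfield", parameter = fit$alpha, norm = fit$norm,
         loglik = fit$loglik, n = fit$n)
  } else stop("unsupported fit object")
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and validate a run configuration
#'
#' JSON run configurations are schema-versioned, reject unknown keys, and
#' require an explicit seed for every stochastic stage.
#'
#' @param path JSON file.
#' @param known_stages stage names allowed in the config.
#' @return named list of stage parameter blocks (class `run_config`).
#' @export
read_run_config <- function(path,
                            known_stages = c("schema_version", "simulate",
                                             "shapes", "dynamics", "fits",
                                             "frozen_cluster")) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(cfg), known_stages)
  if (length(unknown)) {
    stop("schema error: unknown config key(s): ",
         paste(unknown, collapse = ", "))
  }
  if (is.null(cfg$schema_version)) {
    stop("schema error: config must declare schema_version")
  }
  for (stage in setdiff(names(cfg), "schema_version")) {
    blk <- cfg[[stage]]
    if (isTRUE(blk$stochastic) && is.null(blk$seed)) {
      stop("schema error: stochastic stage '", stage,
           "' must declare an explicit seed")
    }
  }
  structure(cfg, class = "run_config")
}
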