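#' Shape-scaling pipeline
#'
#' Chains the shape-statistics stages for a set of conditions: for each
#' condition (an aspect-ratio sample, typically drawn from the mean-field
#' law at a condition-specific alpha), computes mean AR, SD(AR), the
#' k-gamma fit of the rescaled sample and the mean-field fit of the raw
#' sample, overlays the points on the universal scaling line and scores the
#' PDF collapse across conditions.
#'
#' @param samples named list of aspect-ratio vectors, one per condition.
#' @param curve optional precomputed [universal_line()] (computed if NULL).
#' @param out_dir optional directory; when given, writes `summary.csv`,
#'   `summary.json` and a reproducibility manifest.
#' @param seeds optional named list/vector recorded in the manifest.
#' @return list with `table` (per-condition data.frame: condition, n,
#'   mean_ar, sd_ar, k_hat, alpha_hat, line_residual), `collapse_score`,
#'   `curve`.
#' @export
pipeline_shape_scaling <- function(samples, curve = NULL, out_dir = NULL,
                                   seeds = NULL) {
  if (!is.list(samples) || length(samples) == 0L) {
    stop("input error: 'samples' must be a nonempty named list")
  }
  if (is.null(names(samples)) || any(!nzchar(names(samples)))) {
    stop("input error: every condition must be named")
  }
  if (is.null(curve)) curve <- universal_line()
  rows <- lapply(names(samples), function(nm) {
    v <- samples[[nm]]
    rs <- rescale_ar(v)
    kf <- fit_kgamma(rs$rescaled)
    mf <- fit_meanfield(v[v > 1])
    data.frame(condition = nm, n = length(v), mean_ar = rs$mean_ar,
               sd_ar = rs$sd_ar, k_hat = kf$k, alpha_hat = mf$alpha,
               line_residual = rs$sd_ar -
                 (curve$slope * rs$mean_ar + curve$intercept))
  })
  tab <- do.call(rbind, rows)
  cs <- collapse_pdfs(unname(samples))$score
  res <- list(table = tab, collapse_score = cs, curve = curve)
  if (!is.null(out_dir)) {
    .write_report(out_dir, tab,
                  list(collapse_score = cs, slope = curve$slope,
                       intercept = curve$intercept),
                  seeds)
  }
  res
}

#' Dynamical-heterogeneity pipeline
#'
#' Runs the heterogeneity analysis on a vertex-model trajectory: cage time
#' t* from the non-Gaussian parameter, top/bottom mobility subsets, their
#' shape statistics and residuals from the universal line, and (optionally)
#' a frozen-cluster table with line residuals.
#'
#' @param vt a [vm_run()] trajectory (equilibrated, fluid enough that cells
#'   rearrange).
#' @param fraction mobility quantile (default 0.10).
#' @param curve optional [universal_line()] (computed if NULL).
#' @param frozen_table optional [frozen_cluster_experiment()] output to
#'   annotate with line residuals.
#' @param out_dir optional directory for CSV/JSON output + manifest.
#' @param seeds optional seeds recorded in the manifest.
#' @return list with `t_star`, `dh` (subsets), `subset_stats`,
#'   `fast_stats`, `slow_stats`, `fast_residual`, `slow_residual`, and
#'   `frozen` (annotated table or NULL).
#' @export
pipeline_heterogeneity <- function(vt, fraction = 0.10, curve = NULL,
                                   frozen_table = NULL, out_dir = NULL,
                                   seeds = NULL) {
  stopifnot(inherits(vt, "vm_trajectory"))
  if (is.null(curve)) curve <- universal_line()
  traj <- vm_as_trajectory(vt)
  ct <- cage_time(traj)
  dh <- mobility_subsets(traj, ct$t_star_lag, fraction = fraction)
  pe <- vm_as_polygon_ensemble(vt)
  ss <- subset_shape_stats(dh, pe)
  resid_of <- function(stats_) {
    unname(stats_["sd_ar"] -
             (curve$slope * stats_["mean_ar"] + curve$intercept))
  }
  frozen <- NULL
  if (!is.null(frozen_table)) {
    frozen <- frozen_table
    frozen$line_residual <- frozen$sd_ar -
      (curve$slope * frozen$mean_ar + curve$intercept)
  }
  res <- list(t_star = ct$t_star, dh = dh, subset_stats = ss,
              fast_stats = ss$fast, slow_stats = ss$slow,
              fast_residual = resid_of(ss$fast),
              slow_residual = resid_of(ss$slow),
              frozen = frozen)
  if (!is.null(out_dir)) {
    tab <- data.frame(subset = c("fast", "slow"),
                      mean_ar = c(ss$fast["mean_ar"], ss$slow["mean_ar"]),
                      sd_ar = c(ss$fast["sd_ar"], ss$slow["sd_ar"]),
                      line_residual = c(res$fast_residual,
                                        res$slow_residual))
    .write_report(out_dir, tab, list(t_star = ct$t_star), seeds)
    if (!is.null(frozen)) {
      utils::write.csv(frozen, file.path(out_dir, "frozen_cluster.csv"),
                       row.names = FALSE)
    }
  }
  res
}

## write summary.csv, summary.json and a reproducibility manifest
.write_report <- function(out_dir, table, scalars, seeds) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(table, file.path(out_dir, "summary.csv"),
                   row.names = FALSE)
  jsonlite::write_json(scalars, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package_version = as.character(utils::packageVersion("shapejam")),
    r_version = R.version.string,
    seeds = seeds,
    written = format(Sys.time(), tz = "UTC", usetz = TRUE))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
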