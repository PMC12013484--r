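#' Pipeline configuration
#'
#' `procv_config()` returns the reference parameter set of the matching
#' pipeline in normalized units (coordinates jointly scaled by the
#' reciprocal of the scene bounding-box diagonal before matching):
#' uniform-sampling voxel edges for ligand/pocket and protein clouds,
#' reference-frame / descriptor / normal support radii, the Hough
#' cluster bin size and vote threshold, and the hypothesis-verification
#' parameters. These defaults suit densely sampled surface clouds;
#' for atomic point clouds use [atomic_config()].
#'
#' Additional knobs: `max_descr_dist` (squared descriptor-distance
#' acceptance threshold), `corr_k` and `corr_rank` (candidate matches
#' per pocket keypoint handed to Hough grouping, and their ordering -
#' see [match_descriptors()]), `min_inlier_fraction`
#' (verification cut),
#' `similarity_threshold` (strong/weak correspondence-count cut, strict
#' `>`), `delta_metric` (the matching threshold delta, in Angstrom, used
#' by the evaluation metrics), `normalize`, `verify`, `centroid`
#' (keypoint centroid mode, see [component_centroid()]) and `seed`.
#'
#' @param ... named overrides of any default.
#' @return a named list of class `procv_config`.
#' @export
procv_config <- function(...) {
  cfg <- list(
    ligand_ss_ = 0.005,
    protein_ss_ = 0.01,
    rf_rad_ = 0.015,
    descr_rad_ = 0.02,
    cg_size_ = 0.05,
    cg_thresh_ = 5.0,
    hv_resolution_ = 0.005,
    hv_occupancy_grid_resolution_ = 0.01,
    hv_clutter_reg_ = 5.0,
    hv_inlier_th_ = 0.005,
    hv_occlusion_th_ = 0.01,
    hv_rad_clutter_ = 0.03,
    hv_regularizer_ = 3.0,
    hv_rad_normals_ = 0.05,
    hv_detect_clutter_ = TRUE,
    max_descr_dist = 0.25,
    corr_k = 10L,
    corr_rank = "containment",
    min_inlier_fraction = 0.5,
    similarity_threshold = 10L,
    delta_metric = 2.0,
    normalize = TRUE,
    verify = TRUE,
    centroid = "points",
    seed = NULL)
  override_config(cfg, list(...))
}

#' Atomic-scale pipeline configuration
#'
#' Parameters in Angstrom for clouds whose points are atoms (typical
#' nearest-neighbour spacing 1.5-4 A), used as the working default of
#' [match_pocket()]. Sampling voxel edges sit below the minimum
#' interatomic distance, so uniform sampling preserves atomic detail
#' (one keypoint per isolated atom). The descriptor support is short
#' range (3 A, roughly the covalently bonded shell): a pocket is a
#' partial view of its protein, and only the short-range context of a
#' pocket atom is the same in the excised pocket cloud and in the full
#' structure, so short-range descriptors stay comparable across the
#' two views while long-range ones are systematically contaminated.
#' Reference frames and normals use a 4 A support (enough neighbours
#' for stable covariance estimates). The Hough bin is 2 A with a
#' 5-vote threshold; verification uses a 1 A inlier threshold at 0.8
#' minimum fraction, strict enough that a misplaced pocket inside a
#' dense atom cloud is rejected.
#'
#' @param ... named overrides of any default.
#' @return a named list of class `procv_config`.
#' @export
atomic_config <- function(...) {
  cfg <- procv_config(
    ligand_ss_ = 0.4,
    protein_ss_ = 0.5,
    rf_rad_ = 4.0,
    descr_rad_ = 3.0,
    cg_size_ = 2.0,
    hv_rad_normals_ = 4.0,
    hv_inlier_th_ = 1.0,
    min_inlier_fraction = 0.8,
    normalize = FALSE)
  override_config(cfg, list(...))
}

override_config <- function(cfg, dots) {
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad))
      stop("unknown configuration parameter(s): ",
           paste(bad, collapse = ", "))
    for (nm in names(dots)) cfg[nm] <- list(dots[[nm]])  # NULL-safe
  }
  len_pos <- c("ligand_ss_", "protein_ss_", "rf_rad_", "descr_rad_",
               "cg_size_", "hv_rad_normals_", "hv_inlier_th_",
               "delta_metric")
  for (p in len_pos)
    if (!is.numeric(cfg[[p]]) || cfg[[p]] <= 0)
      stop("`", p, "` must be a positive length")
  structure(cfg, class = "procv_config")
}

#' @export
print.procv_config <- function(x, ...) {
  cat("<procv_config>\n")
  for (nm in names(x))
    cat(sprintf("  %-30s %s\n", nm,
                if (is.null(x[[nm]])) "NULL" else format(x[[nm]])))
  invisible(x)
}

#' Read / write a pipeline configuration file
#'
#' Configurations round-trip losslessly through YAML; unknown keys are
#' rejected, missing keys keep their defaults.
#'
#' @param path configuration file path.
#' @param config a [procv_config()] to write.
#' @param base defaults that `path` overrides (default
#'   [atomic_config()]).
#' @return `read_config` returns a `procv_config`; `write_config`
#'   returns `path` invisibly.
#' @export
read_config <- function(path, base = atomic_config()) {
  vals <- yaml::read_yaml(path)
  if (!is.list(vals)) stop("configuration file must be a YAML mapping")
  do.call(override_config, list(unclass(base), vals))
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "procv_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
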