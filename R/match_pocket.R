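#' Match a pocket against a protein point cloud
#'
#' The end-to-end recognition pipeline. Both clouds are (optionally)
#' jointly rescaled by the reciprocal of the protein's bounding-box
#' diagonal; keypoints are sampled from each cloud by grid-centroid
#' uniform sampling (pocket at `ligand_ss_`, protein at `protein_ss_`
#' voxel edge); per-point normals, per-keypoint local reference frames
#' and angular-histogram descriptors are computed; each pocket
#' descriptor is matched to its `corr_k` nearest protein descriptors
#' (a pocket is a partial view of its protein, so its boundary
#' descriptors are context-contaminated and the single nearest
#' neighbour is unreliable - geometric consistency is enforced by the
#' next stage instead); candidate correspondences are grouped by 3D
#' Hough voting (bin `cg_size_`, threshold `cg_thresh_`); each group
#' gets a least-squares rigid transform robustified by reprojection
#' inlier refinement ([refine_group()]); and, when `config$verify` is
#' on, groups are filtered by the inlier-fraction hypothesis test.
#' All reported transforms are de-normalized back to input units.
#'
#' The headline similarity readout is the total number of
#' correspondences across retained groups; an empty group list is a
#' valid "no match" outcome.
#'
#' @param pocket model cloud (the pocket), a [mol_cloud()] or matrix.
#' @param protein scene cloud, a [mol_cloud()] or matrix.
#' @param config a [procv_config()]; default [atomic_config()].
#' @return an object of class `pocket_match`: list with `groups`
#'   (transform-carrying `match_group`s in descending vote order),
#'   `n_correspondences` (summed over retained groups), `n_groups`,
#'   `correspondences` (the raw descriptor matches), `n_skipped`
#'   (degenerate-frame correspondences), `scale` (normalization factor
#'   applied) and `config`.
#' @export
match_pocket <- function(pocket, protein, config = atomic_config()) {
  stopifnot(inherits(config, "procv_config"))
  M <- as_points(pocket)
  S <- as_points(protein)
  if (nrow(M) == 0L || nrow(S) == 0L)
    stop("pocket and protein clouds must be nonempty")
  scale <- 1
  if (isTRUE(config$normalize)) {
    diag_len <- sqrt(sum((apply(S, 2L, max) - apply(S, 2L, min))^2))
    if (diag_len > 0) scale <- 1 / diag_len
  }
  Mn <- M * scale
  Sn <- S * scale

  kp_m <- sample_keypoints(Mn, mode = "voxel-size",
                           parameter = config$ligand_ss_,
                           centroid = config$centroid)
  kp_s <- sample_keypoints(Sn, mode = "voxel-size",
                           parameter = config$protein_ss_,
                           centroid = config$centroid)
  empty <- function(corrs = NULL, skipped = 0L) {
    structure(list(groups = list(), n_correspondences = 0L,
                   n_groups = 0L, correspondences = corrs,
                   n_skipped = skipped, scale = scale, config = config),
              class = "pocket_match")
  }
  if (nrow(kp_m$keypoints) == 0L || nrow(kp_s$keypoints) == 0L)
    return(empty())

  cm <- estimate_normals(mol_cloud(Mn), config$hv_rad_normals_)
  cs <- estimate_normals(mol_cloud(Sn), config$hv_rad_normals_)
  dm <- compute_descriptors(cm, kp_m, config$descr_rad_)
  ds <- compute_descriptors(cs, kp_s, config$descr_rad_)
  corrs <- match_descriptors(dm, ds, max_distance = config$max_descr_dist,
                             k = config$corr_k, rank = config$corr_rank)
  if (nrow(corrs$pairs) == 0L) return(empty(corrs))

  lrf_m <- compute_lrf(Mn, kp_m, config$rf_rad_)
  lrf_s <- compute_lrf(Sn, kp_s, config$rf_rad_)
  ref <- colMeans(Mn)
  vt <- cast_votes(corrs, kp_m, lrf_m, kp_s, lrf_s, ref)
  if (nrow(vt$votes) == 0L) return(empty(corrs, vt$n_skipped))

  voted_pairs <- corrs$pairs[vt$corr_index, , drop = FALSE]
  groups <- extract_groups(vt$votes, voted_pairs,
                           bin_size = config$cg_size_,
                           threshold = config$cg_thresh_)
  # re-admission spans every descriptor candidate: correspondences
  # that could not vote (degenerate frames) can still support a
  # geometrically consistent hypothesis
  groups <- Filter(Negate(is.null), lapply(groups, function(g)
    refine_group(g, kp_m, kp_s, tol = config$cg_size_ / 2,
                 candidates = corrs$pairs)))
  # distinct hypotheses only: clusters that converged to the same
  # correspondence set are one match
  sig <- vapply(groups, function(g)
    paste(sort(paste(g$correspondences$query, g$correspondences$match)),
          collapse = ";"), character(1))
  groups <- groups[!duplicated(sig)]
  groups <- groups[order(vapply(groups, `[[`, numeric(1), "vote_count"),
                         decreasing = TRUE)]
  if (isTRUE(config$verify))
    groups <- verify_hypotheses(groups, Mn, Sn,
                                inlier_threshold = config$hv_inlier_th_,
                                min_fraction = config$min_inlier_fraction)

  # de-normalize: scaled fit (R, t') maps s*m to s*p, so t = t'/s
  groups <- lapply(groups, function(g) {
    g$translation_input_units <- g$translation / scale
    g
  })
  structure(list(
    groups = groups,
    n_correspondences = sum(vapply(groups, `[[`, numeric(1), "vote_count")),
    n_groups = length(groups),
    correspondences = corrs,
    n_skipped = vt$n_skipped,
    scale = scale,
    config = config),
    class = "pocket_match")
}

#' @export
print.pocket_match <- function(x, ...) {
  cat(sprintf("<pocket_match> %d group(s), %d correspondence(s)%s\n",
              x$n_groups, x$n_correspondences,
              if (x$n_skipped > 0)
                sprintf(" (%d skipped: degenerate frames)", x$n_skipped)
              else ""))
  if (x$n_groups > 0) {
    g <- x$groups[[1L]]
    cat(sprintf("  top group: %d votes, rmsd %.4g%s\n", g$vote_count,
                g$rmsd,
                if (!is.null(g$inlier_fraction))
                  sprintf(", inlier fraction %.2f", g$inlier_fraction)
                else ""))
  }
  invisible(x)
}
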