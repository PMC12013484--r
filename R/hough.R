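#' Hesse-normal-form plane parameters
#'
#' A plane through point `p` with unit normal `n` is parameterized in
#' 3D Hough space by the normal's elevation `phi = acos(n_z)` (angle
#' from the z axis), its azimuth in the xy plane
#' `theta = atan2(n_y, n_x)`, and the signed origin distance
#' `rho = p_x cos(theta) sin(phi) + p_y sin(theta) sin(phi) +
#' p_z cos(phi)`, which equals the inner product `p . n`.
#'
#' @param point length-3 point on the plane.
#' @param normal length-3 unit normal (length 1 within 1e-9).
#' @return `list(phi, theta, rho)` (angles in radians).
#' @export
plane_hough_params <- function(point, normal) {
  point <- as.numeric(point); normal <- as.numeric(normal)
  if (length(point) != 3L || length(normal) != 3L)
    stop("`point` and `normal` must be length-3 vectors")
  if (abs(sqrt(sum(normal^2)) - 1) > 1e-9)
    stop("`normal` must have unit length (tolerance 1e-9)")
  phi <- acos(max(-1, min(1, normal[3L])))
  theta <- atan2(normal[2L], normal[1L])
  rho <- point[1L] * cos(theta) * sin(phi) +
    point[2L] * sin(theta) * sin(phi) +
    point[3L] * cos(phi)
  list(phi = phi, theta = theta, rho = rho)
}

#' Reconstruct a unit normal from Hough angles
#'
#' Inverse of the angular part of [plane_hough_params()].
#'
#' @param phi elevation from the z axis, radians.
#' @param theta azimuth in the xy plane, radians.
#' @return length-3 unit normal.
#' @export
hough_normal <- function(phi, theta) {
  c(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
}

#' Cast Hough votes for correspondences
#'
#' Each correspondence (model keypoint i, scene keypoint j) votes for
#' the position of the model reference point in the scene: the vector
#' from keypoint i to the reference point is expressed in model frame
#' i's coordinates and re-emitted from scene keypoint j through scene
#' frame j. For a rigid model/scene pair with covariant frames all
#' votes coincide at the transformed reference point. Correspondences
#' whose model or scene frame is degenerate are skipped and counted.
#'
#' @param corrs a [match_descriptors()] result.
#' @param model_lrfs,scene_lrfs frames from [compute_lrf()] for the
#'   model and scene keypoints.
#' @param model_keypoints,scene_keypoints keypoint position matrices
#'   (or `keypoint_set`s).
#' @param reference_point length-3 model reference point (conventionally
#'   the model cloud centroid).
#' @return `list(votes, corr_index, n_skipped)`: vote positions (one row
#'   per retained correspondence), the retained rows of `corrs$pairs`,
#'   and the number of skipped correspondences.
#' @export
cast_votes <- function(corrs, model_keypoints, model_lrfs,
                       scene_keypoints, scene_lrfs, reference_point) {
  stopifnot(inherits(corrs, "correspondence_set"))
  M <- keypoint_matrix(model_keypoints)
  S <- keypoint_matrix(scene_keypoints)
  ref <- as.numeric(reference_point)
  pairs <- corrs$pairs
  votes <- matrix(numeric(0), 0L, 3L)
  keep <- integer(0)
  skipped <- 0L
  for (r in seq_len(nrow(pairs))) {
    i <- pairs$query[r]; j <- pairs$match[r]
    fm <- model_lrfs[[i]]; fs <- scene_lrfs[[j]]
    if (fm$degenerate || fs$degenerate) { skipped <- skipped + 1L; next }
    cv <- fm$axes %*% (ref - M[i, ])          # model-frame coordinates
    v <- S[j, ] + as.numeric(crossprod(fs$axes, cv))
    votes <- rbind(votes, v)
    keep <- c(keep, r)
  }
  rownames(votes) <- NULL
  list(votes = votes, corr_index = keep, n_skipped = skipped)
}

#' Group Hough votes into match groups
#'
#' Votes are binned on a cubic grid of edge `bin_size` anchored at the
#' componentwise vote minimum; face-adjacent occupied bins are merged
#' (which suppresses bin-edge splitting) and every merged cluster whose
#' total vote count reaches `threshold` becomes a match group. Groups
#' are returned in descending vote order. Only bins holding at least
#' two votes can bridge a merge; single-vote bins are attached to the
#' heaviest adjacent cluster (or stand alone), so sparse background
#' votes cannot chain unrelated clusters together.
#'
#' @param votes vote-position matrix from [cast_votes()].
#' @param corr_pairs the correspondence rows that produced the votes
#'   (data frame parallel to `votes`).
#' @param bin_size Hough bin edge length.
#' @param threshold minimum votes per group (counts are integral, so
#'   `ceiling(threshold)` members are required).
#' @return list of `match_group` objects: `list(correspondences,
#'   vote_count, rotation = NULL, translation = NULL)`.
#' @export
extract_groups <- function(votes, corr_pairs, bin_size, threshold = 5) {
  if (nrow(votes) == 0L) return(list())
  if (bin_size <= 0) stop("`bin_size` must be positive")
  origin <- apply(votes, 2L, min)
  bins <- matrix(as.integer(floor(sweep(votes, 2L, origin) / bin_size)),
                 ncol = 3L) + 1L
  bin_key <- paste(bins[, 1L], bins[, 2L], bins[, 3L])
  ub <- unique(bins)
  ub_key <- paste(ub[, 1L], ub[, 2L], ub[, 3L])
  bin_mass <- as.integer(table(bin_key)[ub_key])
  cluster_of <- integer(nrow(ub))          # 0 = unassigned
  heavy <- which(bin_mass >= 2L)
  if (length(heavy)) {
    comps <- components_int_triples(ub[heavy, , drop = FALSE])
    for (ci in seq_along(comps)) cluster_of[heavy[comps[[ci]]]] <- ci
  }
  n_clust <- max(cluster_of, 0L)
  # singleton bins join the heaviest adjacent cluster, else stand alone
  offs <- rbind(c(1L, 0L, 0L), c(-1L, 0L, 0L), c(0L, 1L, 0L),
                c(0L, -1L, 0L), c(0L, 0L, 1L), c(0L, 0L, -1L))
  clust_mass <- vapply(seq_len(n_clust), function(ci)
    sum(bin_mass[cluster_of == ci]), numeric(1))
  for (b in which(cluster_of == 0L)) {
    nb_keys <- paste(ub[b, 1L] + offs[, 1L], ub[b, 2L] + offs[, 2L],
                     ub[b, 3L] + offs[, 3L])
    adj <- unique(cluster_of[match(nb_keys, ub_key)])
    adj <- adj[!is.na(adj) & adj > 0L]
    if (length(adj)) {
      cluster_of[b] <- adj[which.max(clust_mass[adj])]
    } else {
      n_clust <- n_clust + 1L
      cluster_of[b] <- n_clust
      clust_mass <- c(clust_mass, bin_mass[b])
    }
  }
  need <- ceiling(threshold)
  vote_cluster <- cluster_of[match(bin_key, ub_key)]
  groups <- list()
  for (ci in seq_len(n_clust)) {
    members <- which(vote_cluster == ci)
    if (length(members) >= need) {
      # densest single bin of the cluster: the tightest consensus,
      # used downstream to seed the transform estimate
      mk <- bin_key[members]
      top_bin <- names(which.max(table(mk)))
      groups[[length(groups) + 1L]] <- structure(
        list(correspondences = corr_pairs[members, , drop = FALSE],
             vote_count = length(members),
             seed_members = which(mk == top_bin),
             rotation = NULL, translation = NULL),
        class = "match_group")
    }
  }
  groups[order(vapply(groups, `[[`, numeric(1), "vote_count"),
               decreasing = TRUE)]
}

#' Least-squares rigid transform of a match group
#'
#' Kabsch fit: the rotation/translation minimizing the summed squared
#' distance between transformed model keypoints and their matched scene
#' keypoints, with the SVD reflection guard ensuring a proper rotation.
#' Needs at least 3 non-collinear correspondences.
#'
#' @param group a `match_group` from [extract_groups()].
#' @param model_keypoints,scene_keypoints keypoint position matrices.
#' @return the group with `rotation` (3 x 3), `translation` (length 3)
#'   and `rmsd` (post-fit root-mean-square residual) filled in.
#' @export
estimate_transform <- function(group, model_keypoints, scene_keypoints) {
  stopifnot(inherits(group, "match_group"))
  M <- keypoint_matrix(model_keypoints)
  S <- keypoint_matrix(scene_keypoints)
  pairs <- group$correspondences
  if (nrow(pairs) < 3L)
    stop("need at least 3 correspondences to estimate a rigid transform")
  A <- M[pairs$query, , drop = FALSE]
  B <- S[pairs$match, , drop = FALSE]
  fit <- kabsch(A, B)
  if (is.null(fit))
    stop("correspondences are collinear; transform undefined")
  group$rotation <- fit$R
  group$translation <- fit$t
  res <- sweep(A %*% t(fit$R), 2L, fit$t, "+") - B
  group$rmsd <- sqrt(mean(rowSums(res^2)))
  group
}

# Kabsch/SVD rigid fit mapping A onto B; NULL when A is (near-)collinear.
kabsch <- function(A, B) {
  ca <- colMeans(A); cb <- colMeans(B)
  H <- crossprod(sweep(A, 2L, ca), sweep(B, 2L, cb))
  sv <- svd(H)
  if (sv$d[2L] <= max(sv$d[1L] * 1e-12, 1e-300)) return(NULL)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(R = R, t = as.numeric(cb - R %*% ca))
}

#' Refine a match group by reprojection error
#'
#' Robustifies a group's transform hypothesis. The transform is seeded
#' from the group's densest Hough bin (the tightest vote consensus)
#' and then alternates between (a) selecting, from the full candidate
#' correspondence set, the pairs whose scene keypoint lies within
#' `tol` of the transformed model keypoint - at most one pair per
#' model keypoint, the one with the smallest residual - and (b)
#' re-estimating the transform from that selection, until the
#' selection is stable. The candidate set is fixed, so this is a
#' trimmed least-squares consensus evaluation, not a new search; with
#' k-nearest-neighbour candidates it both removes pairs that voted
#' into the cluster by coincidence and recovers correct pairs whose
#' votes were scattered by boundary-contaminated reference frames.
#' Hypotheses left with fewer than 3 inliers are discarded (`NULL`).
#'
#' @param group a `match_group` from [extract_groups()] (the transform
#'   is seeded internally; a pre-filled transform is used as the
#'   starting hypothesis when the seed bin is too small).
#' @param model_keypoints,scene_keypoints keypoint position matrices.
#' @param tol inlier tolerance (conventionally half the Hough bin
#'   size, which also sits below typical interatomic spacing).
#' @param candidates optional data frame of all candidate pairs
#'   (`query`, `match`, `distance`) to re-admit from; defaults to the
#'   group's own members.
#' @param max_iter maximum refinement rounds (default 20).
#' @return the refined `match_group`, or `NULL` if degenerate.
#' @export
refine_group <- function(group, model_keypoints, scene_keypoints, tol,
                         candidates = NULL, max_iter = 20L) {
  stopifnot(inherits(group, "match_group"))
  M <- keypoint_matrix(model_keypoints)
  S <- keypoint_matrix(scene_keypoints)
  if (is.null(candidates)) candidates <- group$correspondences
  # seed the hypothesis from the densest bin when it can pin down a
  # transform, else from the whole cluster
  seed <- group
  if (!is.null(group$seed_members) && length(group$seed_members) >= 3L) {
    seed$correspondences <-
      group$correspondences[group$seed_members, , drop = FALSE]
    seed$vote_count <- nrow(seed$correspondences)
  }
  fit <- tryCatch(estimate_transform(seed, model_keypoints, scene_keypoints),
                  error = function(e) NULL)
  if (is.null(fit))
    fit <- tryCatch(estimate_transform(group, model_keypoints,
                                       scene_keypoints),
                    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  group$rotation <- fit$rotation
  group$translation <- fit$translation
  A <- M[candidates$query, , drop = FALSE]
  B <- S[candidates$match, , drop = FALSE]
  sel_prev <- integer(0)
  for (it in seq_len(max_iter)) {
    res <- sqrt(rowSums((sweep(A %*% t(group$rotation), 2L,
                               group$translation, "+") - B)^2))
    ok <- which(res <= tol)
    if (length(ok) < 3L) return(NULL)
    # best residual per model keypoint
    ok <- ok[order(candidates$query[ok], res[ok])]
    ok <- ok[!duplicated(candidates$query[ok])]
    if (identical(ok, sel_prev)) break
    sel_prev <- ok
    group$correspondences <- candidates[ok, , drop = FALSE]
    group$vote_count <- length(ok)
    group <- tryCatch(
      estimate_transform(group, model_keypoints, scene_keypoints),
      error = function(e) NULL)
    if (is.null(group)) return(NULL)
  }
  group$seed_members <- NULL
  group
}

#' @export
print.match_group <- function(x, ...) {
  cat(sprintf("<match_group> %d votes%s\n", x$vote_count,
              if (!is.null(x$rotation))
                sprintf(", rmsd %.4g", x$rmsd) else " (no transform)"))
  invisible(x)
}

#' Verify match-group hypotheses by inlier fraction
#'
#' A simplified hypothesis-verification stage: a group is kept iff the
#' fraction of transformed model points that have a scene point within
#' `inlier_threshold` exceeds `min_fraction`. An infinite threshold
#' retains everything.
#'
#' @param groups list of transform-carrying `match_group`s.
#' @param model_cloud,scene_cloud the full model and scene clouds.
#' @param inlier_threshold distance threshold for an inlier.
#' @param min_fraction minimum inlier fraction (default 0.5).
#' @return the retained groups, each with `inlier_fraction` recorded.
#' @export
verify_hypotheses <- function(groups, model_cloud, scene_cloud,
                              inlier_threshold, min_fraction = 0.5) {
  M <- as_points(model_cloud)
  S <- as_points(scene_cloud)
  kept <- list()
  for (g in groups) {
    if (is.null(g$rotation)) next
    TP <- sweep(M %*% t(g$rotation), 2L, g$translation, "+")
    if (is.infinite(inlier_threshold)) {
      g$inlier_fraction <- 1
    } else {
      mind2 <- apply(cross_dist2(TP, S), 1L, min)
      g$inlier_fraction <- mean(sqrt(mind2) <= inlier_threshold)
    }
    if (g$inlier_fraction > min_fraction)
      kept[[length(kept) + 1L]] <- g
  }
  kept
}
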