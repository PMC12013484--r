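#' Estimate per-point surface normals
#'
#' The normal at a point is the eigenvector of the smallest eigenvalue
#' of the covariance of its neighbourhood (all cloud points within
#' `radius`). Signs are disambiguated globally: each normal is oriented
#' away from the cloud's center of mass, which is a rigidly covariant
#' rule. Points with fewer than 3 neighbours get an undefined normal
#' (an all-`NA` row).
#'
#' @param cloud a [mol_cloud()] or coordinate matrix with >= 3 points.
#' @param radius neighbourhood radius (same units as the cloud).
#' @return the input as a [mol_cloud()] carrying `normals`; the logical
#'   attribute `"normal_defined"` flags points with a defined normal.
#' @export
estimate_normals <- function(cloud, radius) {
  P <- as_points(cloud)
  if (nrow(P) < 3L) stop("need at least 3 points to estimate normals")
  if (radius <= 0) stop("`radius` must be positive")
  atoms <- if (inherits(cloud, "mol_cloud")) cloud$atoms else NULL
  ctr <- colMeans(P)
  d2 <- cross_dist2(P, P)
  r2 <- radius^2
  N <- matrix(NA_real_, nrow(P), 3L)
  defined <- logical(nrow(P))
  for (i in seq_len(nrow(P))) {
    nb <- which(d2[i, ] <= r2)
    if (length(nb) < 3L) next
    n <- point_normal(P[nb, , drop = FALSE])
    if (is.null(n)) next
    # orient away from the center of mass (concavity-consistent)
    if (sum(n * (P[i, ] - ctr)) < 0) n <- -n
    N[i, ] <- n
    defined[i] <- TRUE
  }
  out <- mol_cloud(P, atoms = atoms, normals = N)
  attr(out, "normal_defined") <- defined
  out
}

# Unit normal of a neighbourhood: smallest-eigenvalue eigenvector of the
# point covariance. NULL when the neighbourhood is degenerate.
point_normal <- function(Q) {
  C <- stats::cov(Q)
  if (any(!is.finite(C))) return(NULL)
  ev <- eigen(C, symmetric = TRUE)
  n <- ev$vectors[, 3L]
  len <- sqrt(sum(n^2))
  if (!is.finite(len) || len == 0) return(NULL)
  n / len
}

#' Local reference frames at keypoints
#'
#' Each keypoint gets an orthonormal, right-handed frame from the
#' eigen-decomposition of the distance-weighted covariance of its
#' neighbourhood (support points within `rf_radius`; weights
#' `rf_radius - distance`). The first two axes (largest and middle
#' eigenvalue) are oriented so that the weighted majority of neighbour
#' displacement vectors has nonnegative projection; the third axis is
#' their cross product, so the frame is always proper. Frames with
#' fewer than 5 neighbours or a (near-)collinear neighbourhood are
#' flagged degenerate; frames whose first two eigenvalues are nearly
#' equal are flagged low-confidence.
#'
#' @param cloud support cloud (a [mol_cloud()] or matrix).
#' @param keypoints a `keypoint_set` ([sample_keypoints()]) or m x 3
#'   matrix of keypoint positions.
#' @param rf_radius support radius.
#' @return a list of frames, one per keypoint:
#'   `list(origin, axes, degenerate, low_confidence, eigenvalues)` with
#'   `axes` a 3 x 3 matrix whose rows are the x, y, z axes.
#' @export
compute_lrf <- function(cloud, keypoints, rf_radius) {
  P <- as_points(cloud)
  K <- keypoint_matrix(keypoints)
  if (nrow(K) == 0L) stop("`keypoints` is empty")
  if (rf_radius <= 0) stop("`rf_radius` must be positive")
  d2 <- cross_dist2(K, P)
  r2 <- rf_radius^2
  lapply(seq_len(nrow(K)), function(i) {
    p <- K[i, ]
    nb <- which(d2[i, ] <= r2)
    frame <- list(origin = p, axes = diag(3), degenerate = TRUE,
                  low_confidence = FALSE,
                  eigenvalues = rep(NA_real_, 3L))
    if (length(nb) < 5L) return(frame)
    V <- sweep(P[nb, , drop = FALSE], 2L, p)
    w <- rf_radius - sqrt(d2[i, nb])
    C <- crossprod(V * w, V) / sum(w)
    ev <- eigen(C, symmetric = TRUE)
    lam <- ev$values
    if (!all(is.finite(lam)) || lam[2L] <= lam[1L] * 1e-9)
      return(frame)                       # collinear neighbourhood
    ax <- ev$vectors[, 1L]
    ay <- ev$vectors[, 2L]
    # orient towards the weighted majority of the neighbourhood; the
    # weighted projection sum is continuous in the points, so the sign
    # is stable under rigid motion (an unweighted head count can tie)
    if (sum(w * (V %*% ax)) < 0) ax <- -ax
    if (sum(w * (V %*% ay)) < 0) ay <- -ay
    az <- cross3(ax, ay)
    frame$axes <- rbind(x = ax, y = ay, z = az)
    frame$degenerate <- FALSE
    frame$low_confidence <- lam[2L] / lam[1L] > 0.9
    frame$eigenvalues <- lam
    frame
  })
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

keypoint_matrix <- function(keypoints) {
  if (inherits(keypoints, "keypoint_set")) keypoints$keypoints
  else as_points(keypoints)
}

#' Local angular-histogram descriptors at keypoints
#'
#' A rotation-invariant descriptor in the spirit of fast point feature
#' histograms: for every keypoint, each support point within
#' `descr_radius` contributes one (keypoint, neighbour) pair, and the
#' full point-feature quadruplet of the pair - alpha, the cosine
#' between the neighbour normal and the frame's v axis; phi, the cosine
#' between the keypoint normal and the displacement direction; theta,
#' the signed angle `atan2(w . n_t, u . n_t)`; and d, the pair
#' distance - is histogrammed into 11 bins per feature and
#' concatenated into a 44-bin vector normalized to sum 1. The bin
#' layout is fixed: alpha and phi partition [-1, 1], theta partitions
#' (-pi, pi], and d partitions [0, `descr_radius`], uniformly into 11
#' bins each. All four features are rigid-invariant given covariant
#' normals.
#'
#' The keypoint normal is re-estimated from the support cloud within
#' `descr_radius` (keypoints are cell centroids, not cloud points);
#' neighbour normals must already be present on `cloud` (see
#' [estimate_normals()]). Keypoints with no usable neighbour get a zero
#' vector and are flagged unmatchable.
#'
#' @param cloud support cloud carrying normals.
#' @param keypoints a `keypoint_set` or m x 3 matrix.
#' @param descr_radius support radius.
#' @return an object of class `descriptor_set`: list with `descriptors`
#'   (m x 44 matrix, normalized), `counts` (the raw per-bin pair
#'   counts), `radius`, and logical `populated`.
#' @export
compute_descriptors <- function(cloud, keypoints, descr_radius) {
  if (!inherits(cloud, "mol_cloud") || is.null(cloud$normals))
    stop("`cloud` must carry normals; run estimate_normals() first")
  P <- cloud$points
  NRM <- cloud$normals
  K <- keypoint_matrix(keypoints)
  if (nrow(K) == 0L) stop("`keypoints` is empty")
  if (descr_radius <= 0) stop("`descr_radius` must be positive")
  d2 <- cross_dist2(K, P)
  r2 <- descr_radius^2
  ctr <- colMeans(P)
  nbins <- 11L
  D <- matrix(0, nrow(K), 4L * nbins)
  CNT <- matrix(0L, nrow(K), 4L * nbins)
  populated <- logical(nrow(K))
  for (i in seq_len(nrow(K))) {
    p <- K[i, ]
    nb <- which(d2[i, ] <= r2 & !is.na(NRM[, 1L]))
    sup <- which(d2[i, ] <= r2)
    if (length(sup) < 3L) next
    np <- point_normal(P[sup, , drop = FALSE])
    if (is.null(np)) next
    if (sum(np * (p - ctr)) < 0) np <- -np
    V <- sweep(P[nb, , drop = FALSE], 2L, p)
    dist <- sqrt(rowSums(V^2))
    nb <- nb[dist > 1e-9]          # drop the keypoint's own atom
    V <- V[dist > 1e-9, , drop = FALSE]
    dist <- dist[dist > 1e-9]
    if (length(nb) < 1L) next
    DU <- V / dist
    # Darboux frame per pair: u = keypoint normal, v = du x u, w = u x v
    VX <- cbind(DU[, 2L] * np[3L] - DU[, 3L] * np[2L],
                DU[, 3L] * np[1L] - DU[, 1L] * np[3L],
                DU[, 1L] * np[2L] - DU[, 2L] * np[1L])
    vlen <- sqrt(rowSums(VX^2))
    ok <- vlen > 1e-12
    if (!any(ok)) next
    VX <- VX[ok, , drop = FALSE] / vlen[ok]
    DUk <- DU[ok, , drop = FALSE]
    NQ <- NRM[nb[ok], , drop = FALSE]
    WX <- cbind(np[2L] * VX[, 3L] - np[3L] * VX[, 2L],
                np[3L] * VX[, 1L] - np[1L] * VX[, 3L],
                np[1L] * VX[, 2L] - np[2L] * VX[, 1L])
    alpha <- rowSums(VX * NQ)                    # in [-1, 1]
    phi <- DUk %*% np                            # in [-1, 1]
    theta <- atan2(rowSums(WX * NQ), NQ %*% np)  # in (-pi, pi]
    h <- c(tab_bins(alpha, -1, 1, nbins),
           tab_bins(phi, -1, 1, nbins),
           tab_bins(theta, -pi, pi, nbins),
           tab_bins(dist[ok], 0, descr_radius, nbins))
    D[i, ] <- h / sum(h)
    CNT[i, ] <- as.integer(h)
    populated[i] <- TRUE
  }
  structure(list(descriptors = D, counts = CNT, radius = descr_radius,
                 populated = populated),
            class = "descriptor_set")
}

# Histogram counts of `x` over `nbins` uniform bins on [lo, hi].
tab_bins <- function(x, lo, hi, nbins) {
  b <- floor((x - lo) / (hi - lo) * nbins) + 1
  b[b < 1] <- 1L; b[b > nbins] <- nbins
  tabulate(b, nbins)
}

#' @export
print.descriptor_set <- function(x, ...) {
  cat(sprintf("<descriptor_set> %d keypoints x %d bins (radius %g), %d populated\n",
              nrow(x$descriptors), ncol(x$descriptors), x$radius,
              sum(x$populated)))
  invisible(x)
}
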