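#' Partition a point cloud into an axis-aligned grid
#'
#' Divides each axis of the cloud's tight bounding box into `epsilon`
#' equal-length intervals that are closed at the front and open at the
#' back, with the global axis maximum assigned to the last interval, and
#' tallies per-cell masses (instance counts). An axis of zero extent
#' collapses to a single interval with a warning.
#'
#' @param cloud a [mol_cloud()] or coordinate matrix (nonempty).
#' @param epsilon intervals per axis: a single integer >= 1 or a
#'   length-3 integer vector.
#' @param edge alternatively, a cell edge length; per-axis interval
#'   counts are then derived as `ceiling(extent / edge)` (voxel-size
#'   mode). Exactly one of `epsilon`/`edge` must be given.
#' @return an object of class `grid_partition`: a list with `epsilon`
#'   (per-axis counts), `domain_min`, `domain_max`, `cell_index` (n x 3
#'   integer matrix mapping each point to its cell), `cells` (data frame
#'   of occupied cells: index triple `k1,k2,k3`, `mass`, geometric
#'   center `cx,cy,cz`, mass-weighted member-point mean `px,py,pz`),
#'   `n_points`, and `grid_num` (number of occupied cells).
#' @export
partition_grid <- function(cloud, epsilon = NULL, edge = NULL) {
  P <- as_points(cloud)
  if (nrow(P) == 0L) stop("`cloud` is empty")
  lo <- apply(P, 2L, min)
  hi <- apply(P, 2L, max)
  w <- hi - lo
  if (is.null(epsilon) == is.null(edge))
    stop("give exactly one of `epsilon` or `edge`")
  if (!is.null(edge)) {
    if (edge <= 0) stop("`edge` must be positive")
    eps <- pmax(1L, as.integer(ceiling(w / edge)))
  } else {
    eps <- as.integer(epsilon)
    if (any(is.na(eps)) || any(eps < 1L))
      stop("`epsilon` must be integer(s) >= 1")
    if (length(eps) == 1L) eps <- rep(eps, 3L)
    if (length(eps) != 3L) stop("`epsilon` must have length 1 or 3")
  }
  degen <- w == 0
  if (any(degen) && any(eps[degen] > 1L)) {
    warning("axis with zero extent collapsed to a single interval")
    eps[degen] <- 1L
  }
  idx <- matrix(1L, nrow(P), 3L)
  for (j in 1:3) {
    if (w[j] > 0) {
      k <- floor((P[, j] - lo[j]) / w[j] * eps[j]) + 1
      idx[, j] <- as.integer(pmin(k, eps[j]))   # domain max -> last cell
    }
  }
  key <- cell_key(idx, eps)
  agg <- rowsum(cbind(1, P), group = key, reorder = TRUE)
  ukey <- as.numeric(rownames(agg))
  kidx <- key_to_index(ukey, eps)
  mass <- agg[, 1L]
  pm <- agg[, 2:4, drop = FALSE] / mass
  centers <- sapply(1:3, function(j) {
    if (w[j] > 0) lo[j] + (kidx[, j] - 0.5) * w[j] / eps[j]
    else rep(lo[j], nrow(kidx))
  })
  if (is.null(dim(centers))) centers <- matrix(centers, ncol = 3L)
  cells <- data.frame(k1 = kidx[, 1L], k2 = kidx[, 2L], k3 = kidx[, 3L],
                      mass = as.integer(mass),
                      cx = centers[, 1L], cy = centers[, 2L],
                      cz = centers[, 3L],
                      px = pm[, 1L], py = pm[, 2L], pz = pm[, 3L])
  ord <- order(cells$k1, cells$k2, cells$k3)
  cells <- cells[ord, , drop = FALSE]
  rownames(cells) <- NULL
  structure(list(epsilon = eps, domain_min = lo, domain_max = hi,
                 cell_index = idx, cells = cells,
                 n_points = nrow(P), grid_num = nrow(cells)),
            class = "grid_partition")
}

# Linear encoding of an integer index triple, and its inverse.
cell_key <- function(idx, eps) {
  (idx[, 1L] - 1) + as.numeric(eps[1L]) *
    ((idx[, 2L] - 1) + as.numeric(eps[2L]) * (idx[, 3L] - 1))
}
key_to_index <- function(key, eps) {
  k1 <- key %% eps[1L]
  r <- (key - k1) / eps[1L]
  k2 <- r %% eps[2L]
  k3 <- (r - k2) / eps[2L]
  cbind(as.integer(k1) + 1L, as.integer(k2) + 1L, as.integer(k3) + 1L)
}

#' @export
print.grid_partition <- function(x, ...) {
  cat(sprintf(
    "<grid_partition> %d points, epsilon = (%s), %d occupied cells\n",
    x$n_points, paste(x$epsilon, collapse = ", "), x$grid_num))
  invisible(x)
}

#' Dense cells of a grid partition
#'
#' A cell is dense when its mass reaches half the mean occupied-cell
#' mass: `mass >= n / GridNum * 0.5` (boundary inclusive), where `n` is
#' the total point count and `GridNum` the number of occupied cells.
#'
#' @param partition a [partition_grid()] result.
#' @return the `cells` data frame restricted to dense cells.
#' @export
dense_cells <- function(partition) {
  stopifnot(inherits(partition, "grid_partition"))
  thr <- partition$n_points / partition$grid_num * 0.5
  out <- partition$cells[partition$cells$mass >= thr, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Connected components of integer index triples under face adjacency
# (two triples are neighbours iff they differ by 1 in exactly one
# coordinate). Returns a list of integer vectors of row indices into
# `idx`, each sorted; components ordered by their smallest member in
# lexicographic (k1, k2, k3) order.
components_int_triples <- function(idx) {
  m <- nrow(idx)
  if (m == 0L) return(list())
  ord <- order(idx[, 1L], idx[, 2L], idx[, 3L])
  lut <- new.env(hash = TRUE, parent = emptyenv())
  keyf <- function(a, b, c) paste(a, b, c, sep = ",")
  for (r in seq_len(m))
    assign(keyf(idx[r, 1L], idx[r, 2L], idx[r, 3L]), r, envir = lut)
  seen <- logical(m)
  offs <- rbind(c(1L, 0L, 0L), c(-1L, 0L, 0L), c(0L, 1L, 0L),
                c(0L, -1L, 0L), c(0L, 0L, 1L), c(0L, 0L, -1L))
  comps <- list()
  for (start in ord) {
    if (seen[start]) next
    queue <- start; seen[start] <- TRUE; members <- integer(0)
    while (length(queue)) {
      r <- queue[[1L]]; queue <- queue[-1L]
      members <- c(members, r)
      for (o in seq_len(6L)) {
        nb <- idx[r, ] + offs[o, ]
        hit <- lut[[keyf(nb[1L], nb[2L], nb[3L])]]
        if (!is.null(hit) && !seen[hit]) {
          seen[hit] <- TRUE
          queue <- c(queue, hit)
        }
      }
    }
    comps[[length(comps) + 1L]] <- sort(members)
  }
  comps
}

#' Connected components of dense cells
#'
#' Groups cells under face adjacency: two cells are neighbours iff their
#' index triples differ by exactly 1 in exactly one dimension (diagonal
#' contact does not connect). Components are ordered by their
#' lexicographically smallest member cell index.
#'
#' @param cells a data frame of cells as returned by [dense_cells()].
#' @return a list of data frames, one per component.
#' @export
connected_components <- function(cells) {
  if (nrow(cells) == 0L) return(list())
  idx <- as.matrix(cells[, c("k1", "k2", "k3")])
  comps <- components_int_triples(idx)
  lapply(comps, function(r) {
    out <- cells[r, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Mass and centroid of a cell component
#'
#' Total mass is the sum of member-cell masses; the centroid is the
#' mass-weighted mean of the member cells' representative points -
#' either the cells' geometric centers (`"cell-center"`, the
#' default) or the mass-weighted means of the member points
#' (`"points"`, which preserves rigid equivariance at sub-atomic cell
#' sizes and is what the matching pipeline uses).
#'
#' @param component a data frame of cells (one component).
#' @param centroid which per-cell representative point to weight.
#' @return `list(mass, center)` with `center` a length-3 vector.
#' @export
component_centroid <- function(component,
                               centroid = c("cell-center", "points")) {
  centroid <- match.arg(centroid)
  if (nrow(component) == 0L) stop("component is empty")
  m <- sum(component$mass)
  if (m <= 0) stop("component has zero total mass; centroid undefined")
  R <- if (centroid == "cell-center")
    as.matrix(component[, c("cx", "cy", "cz")])
  else
    as.matrix(component[, c("px", "py", "pz")])
  list(mass = m, center = as.numeric(colSums(R * component$mass) / m))
}

#' Grid-centroid keypoint sampling
#'
#' The full keypoint-detection pipeline: partition the cloud into a
#' grid, keep dense cells, connect face-adjacent dense cells into
#' components, and emit one mass-weighted component centroid per
#' component as a keypoint.
#'
#' @param cloud a [mol_cloud()] or coordinate matrix.
#' @param mode `"epsilon-grid"` (fixed interval count per axis) or
#'   `"voxel-size"` (fixed cell edge length; interval counts derived as
#'   `ceiling(extent / edge)`).
#' @param parameter epsilon (default 10) or the edge length, per `mode`.
#' @param centroid per-cell representative point used for centroids,
#'   see [component_centroid()].
#' @return an object of class `keypoint_set`: a list with `keypoints`
#'   (m x 3 matrix), `masses`, `provenance` (member cell index triples
#'   per component), and the underlying `partition`.
#' @export
sample_keypoints <- function(cloud,
                             mode = c("epsilon-grid", "voxel-size"),
                             parameter = 10,
                             centroid = c("cell-center", "points")) {
  mode <- match.arg(mode)
  centroid <- match.arg(centroid)
  part <- if (mode == "epsilon-grid")
    partition_grid(cloud, epsilon = parameter)
  else
    partition_grid(cloud, edge = parameter)
  dense <- dense_cells(part)
  comps <- connected_components(dense)
  cents <- lapply(comps, component_centroid, centroid = centroid)
  kp <- if (length(cents))
    do.call(rbind, lapply(cents, `[[`, "center"))
  else matrix(numeric(0), ncol = 3L)
  colnames(kp) <- c("x", "y", "z")
  structure(list(
    keypoints = kp,
    masses = vapply(cents, `[[`, numeric(1), "mass"),
    provenance = lapply(comps, function(d)
      as.matrix(d[, c("k1", "k2", "k3")])),
    partition = part),
    class = "keypoint_set")
}

#' @export
print.keypoint_set <- function(x, ...) {
  cat(sprintf("<keypoint_set> %d keypoints from %d points\n",
              nrow(x$keypoints), x$partition$n_points))
  invisible(x)
}
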