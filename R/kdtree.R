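#' Build a k-d tree
#'
#' A k-dimensional binary search tree over point rows. The splitting
#' dimension cycles with depth (`depth %% k`, the layer discriminator)
#' and each node splits at the median point of its subset along that
#' dimension; points smaller than the node's coordinate go left,
#' larger-or-equal go right. Nearest-neighbour answers are exactly
#' those of a brute-force linear scan, with distance ties broken
#' towards the lowest point index.
#'
#' @param X numeric matrix, one point per row (any dimension k >= 1).
#' @return an object of class `kd_tree`.
#' @export
build_kdtree <- function(X) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (nrow(X) == 0L) stop("cannot build a KD-tree from an empty set")
  if (any(!is.finite(X))) stop("KD-tree points must be finite")
  k <- ncol(X)
  build <- function(rows, depth) {
    if (length(rows) == 0L) return(NULL)
    dim <- depth %% k + 1L                 # layer discriminator
    ord <- rows[order(X[rows, dim], rows)]
    med <- (length(ord) + 1L) %/% 2L
    list(idx = ord[med], dim = dim,
         left = build(ord[seq_len(med - 1L)], depth + 1L),
         right = build(ord[seq(med + 1L, length.out = length(ord) - med)],
                       depth + 1L))
  }
  structure(list(root = build(seq_len(nrow(X)), 0L), points = X, k = k),
            class = "kd_tree")
}

#' @export
print.kd_tree <- function(x, ...) {
  cat(sprintf("<kd_tree> %d points in %d dimensions\n",
              nrow(x$points), x$k))
  invisible(x)
}

#' Nearest neighbour via a k-d tree
#'
#' @param tree a [build_kdtree()] result.
#' @param query numeric matrix of query points (rows), or a single
#'   point as a vector; dimensionality must match the tree.
#' @return a data frame with one row per query: `index` of the nearest
#'   stored point and `distance` (Euclidean).
#' @export
kdtree_nn <- function(tree, query) {
  stopifnot(inherits(tree, "kd_tree"))
  if (is.null(dim(query))) query <- matrix(query, nrow = 1L)
  query <- as.matrix(query)
  if (ncol(query) != tree$k)
    stop("query dimensionality (", ncol(query),
         ") does not match the tree (", tree$k, ")")
  X <- tree$points
  n_q <- nrow(query)
  best_i <- integer(n_q)
  best_d2 <- numeric(n_q)
  for (qi in seq_len(n_q)) {
    q <- query[qi, ]
    bi <- 0L; bd2 <- Inf
    search <- function(node) {
      if (is.null(node)) return(invisible())
      p <- X[node$idx, ]
      d2 <- sum((q - p)^2)
      if (d2 < bd2 || (d2 == bd2 && node$idx < bi)) {
        bd2 <<- d2; bi <<- node$idx
      }
      split <- q[node$dim] - p[node$dim]
      near <- if (split < 0) node$left else node$right
      far <- if (split < 0) node$right else node$left
      search(near)
      if (split^2 <= bd2) search(far)   # hypersphere may cross the plane
      invisible()
    }
    search(tree$root)
    best_i[qi] <- bi
    best_d2[qi] <- bd2
  }
  data.frame(index = best_i, distance = sqrt(best_d2))
}

#' Match descriptor sets by nearest neighbour
#'
#' For every populated query keypoint, finds its `k` nearest target
#' descriptors (KD-tree search for `k = 1`, the default and the
#' canonical single-nearest-neighbour rule) and keeps each pair iff
#' its squared descriptor distance is below `max_distance`. Distance
#' ties go to the lowest target index. `k > 1` emits one candidate
#' correspondence per neighbour (candidates tied with the k-th best
#' distance are all kept); downstream Hough grouping is then
#' responsible for rejecting the geometrically inconsistent ones,
#' which is the standard remedy when the query cloud is a partial
#' view whose descriptors are boundary-contaminated.
#'
#' @param query,target [compute_descriptors()] results of equal
#'   descriptor length.
#' When the query cloud is an excerpt of the target (a pocket inside
#' its protein), every (keypoint, neighbour) pair of a query keypoint
#' also exists - with identical geometry - around its true target
#' counterpart, so the query's raw bin counts are dominated by the
#' counterpart's. `rank = "containment"` exploits this: candidates are
#' ordered first by the containment violation
#' `sum(pmax(0, counts_query - counts_target))` (exactly 0 for the
#' true counterpart of an excerpt) and only then by Euclidean
#' distance. `rank = "euclidean"` (the default) is the plain
#' descriptor-space metric.
#'
#' @param max_distance acceptance threshold on the squared descriptor
#'   distance (default 0.25).
#' @param k candidate matches per query keypoint (default 1).
#' @param rank candidate ordering for `k > 1`, see above.
#' @return an object of class `correspondence_set`: list with `pairs`
#'   (data frame `query`, `match`, `distance` - the squared descriptor
#'   distance) and `max_distance`.
#' @export
match_descriptors <- function(query, target, max_distance = 0.25, k = 1L,
                              rank = c("euclidean", "containment")) {
  stopifnot(inherits(query, "descriptor_set"),
            inherits(target, "descriptor_set"))
  rank <- match.arg(rank)
  if (ncol(query$descriptors) != ncol(target$descriptors))
    stop("descriptor lengths differ between query and target")
  if (k < 1L) stop("`k` must be at least 1")
  q_ok <- which(query$populated)
  t_ok <- which(target$populated)
  pairs <- data.frame(query = integer(0), match = integer(0),
                      distance = numeric(0))
  if (length(q_ok) && length(t_ok)) {
    Tm <- target$descriptors[t_ok, , drop = FALSE]
    if (k == 1L && rank == "euclidean") {
      tree <- build_kdtree(Tm)
      nn <- kdtree_nn(tree, query$descriptors[q_ok, , drop = FALSE])
      pairs <- data.frame(query = q_ok, match = t_ok[nn$index],
                          distance = nn$distance^2)
    } else {
      kk <- min(k, nrow(Tm))
      Q <- query$descriptors[q_ok, , drop = FALSE]
      d2 <- outer(rowSums(Q^2), rowSums(Tm^2), "+") - 2 * tcrossprod(Q, Tm)
      d2[d2 < 0] <- 0
      viol <- NULL
      if (rank == "containment") {
        if (is.null(query$counts) || is.null(target$counts))
          stop("containment ranking needs raw bin counts on both sets")
        Cq <- query$counts[q_ok, , drop = FALSE]
        Ct <- target$counts[t_ok, , drop = FALSE]
        viol <- matrix(0, nrow(Cq), nrow(Ct))
        for (b in seq_len(ncol(Cq)))
          viol <- viol + pmax(0, outer(Cq[, b], Ct[, b], "-"))
      }
      pairs <- do.call(rbind, lapply(seq_along(q_ok), function(r) {
        if (is.null(viol)) {
          ord <- order(d2[r, ], seq_len(ncol(d2)))
          kk_r <- sum(d2[r, ] <= d2[r, ord[kk]] + 1e-15)
        } else {
          ord <- order(viol[r, ], d2[r, ], seq_len(ncol(d2)))
          kth <- ord[kk]
          kk_r <- sum(viol[r, ] < viol[r, kth] |
                      (viol[r, ] == viol[r, kth] &
                       d2[r, ] <= d2[r, kth] + 1e-15))
        }
        ord <- ord[seq_len(kk_r)]
        data.frame(query = q_ok[r], match = t_ok[ord],
                   distance = d2[r, ord])
      }))
    }
    pairs <- pairs[pairs$distance < max_distance, , drop = FALSE]
    rownames(pairs) <- NULL
  }
  structure(list(pairs = pairs, max_distance = max_distance),
            class = "correspondence_set")
}

#' @export
print.correspondence_set <- function(x, ...) {
  cat(sprintf("<correspondence_set> %d pairs (max squared distance %g)\n",
              nrow(x$pairs), x$max_distance))
  invisible(x)
}
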