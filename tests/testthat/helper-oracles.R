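# Independent brute-force oracles and small fixture builders shared by
# the test files. Oracles are deliberately written from first
# principles, with none of the package's internal code paths.

cross_dist2_test <- function(A, B) {
  d <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d[d < 0] <- 0
  d
}

rand_cloud <- function(n, scale = 20) {
  matrix(stats::runif(3 * n, -scale, scale), ncol = 3)
}

# nearest neighbour by linear scan; ties to the lowest index
bf_nn <- function(X, q) {
  d2 <- colSums((t(X) - q)^2)
  i <- which.min(d2)
  list(index = i, distance = sqrt(d2[i]))
}

# per-point grid binning straight from the interval definition
bf_bin_points <- function(P, epsilon) {
  lo <- apply(P, 2, min); hi <- apply(P, 2, max)
  w <- hi - lo
  eps <- rep(epsilon, length.out = 3)
  eps[w == 0] <- 1L
  idx <- sapply(1:3, function(j) {
    if (w[j] == 0) return(rep(1L, nrow(P)))
    k <- floor((P[, j] - lo[j]) / w[j] * eps[j]) + 1
    pmin(as.integer(k), eps[j])
  })
  if (is.null(dim(idx))) idx <- matrix(idx, ncol = 3)
  idx
}

# connected components of index triples via igraph (face adjacency)
bf_components <- function(idx) {
  m <- nrow(idx)
  if (m == 1L) return(list(1L))
  d <- as.matrix(dist(idx, method = "manhattan"))
  adj <- d == 1
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  unname(split(seq_len(m), comp))
}

# double-loop confusion counts per the point-classification rules
bf_confusion <- function(pred, true, delta) {
  lo <- apply(true, 2, min); hi <- apply(true, 2, max)
  tp <- 0L; fp <- 0L; tn <- 0L
  for (i in seq_len(nrow(pred))) {
    dmin <- Inf
    for (j in seq_len(nrow(true)))
      dmin <- min(dmin, sqrt(sum((pred[i, ] - true[j, ])^2)))
    if (dmin <= delta) tp <- tp + 1L
    else if (all(pred[i, ] >= lo) && all(pred[i, ] <= hi)) fp <- fp + 1L
    else tn <- tn + 1L
  }
  fn <- 0L
  for (j in seq_len(nrow(true))) {
    dmin <- Inf
    for (i in seq_len(nrow(pred)))
      dmin <- min(dmin, sqrt(sum((pred[i, ] - true[j, ])^2)))
    if (dmin > delta) fn <- fn + 1L
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

bf_pos <- function(pred, true, delta) {
  if (nrow(pred) == 0L) return(0)
  covered <- 0L
  for (j in seq_len(nrow(true))) {
    for (i in seq_len(nrow(pred))) {
      if (sqrt(sum((pred[i, ] - true[j, ])^2)) <= delta) {
        covered <- covered + 1L
        break
      }
    }
  }
  covered / nrow(true)
}

bf_rmse <- function(pred, true) {
  s <- 0
  for (i in seq_len(nrow(pred))) {
    dmin <- Inf
    for (j in seq_len(nrow(true)))
      dmin <- min(dmin, sum((pred[i, ] - true[j, ])^2))
    s <- s + dmin
  }
  sqrt(s / nrow(pred))
}

bf_mcc <- function(tp, fp, tn, fn) {
  f <- c(tp + fp, tp + fn, tn + fp, tn + fn)
  if (any(f == 0)) return(0)
  num <- prod(c(tp, tn)) - prod(c(fp, fn))
  num / sqrt(f[1]) / sqrt(f[2]) / sqrt(f[3]) / sqrt(f[4])
}

# one standard fixture shared across files (cheap to rebuild; cached)
std_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_structure(fixture_spec(seed = 7L))
    cache
  }
})

fixture_protein <- function(atoms = std_fixture()) {
  structure_to_pointcloud(atoms, function(a) !a$hetero)
}

fixture_pocket <- function(atoms = std_fixture()) {
  extract_pocket(atoms[!atoms$hetero, ], atoms[atoms$hetero, ], 5)
}
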