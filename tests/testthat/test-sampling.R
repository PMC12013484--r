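test_that("partition_grid bins points like the interval definition", {
  one <- matrix(c(1, 2, 3), ncol = 3)
  p1 <- partition_grid(one, epsilon = 1)
  expect_equal(p1$grid_num, 1L)
  expect_equal(p1$cells$mass, 1L)

  corners <- as.matrix(expand.grid(c(0, 1), c(0, 1), c(0, 1)))
  p2 <- partition_grid(corners, epsilon = 2)
  expect_equal(p2$grid_num, 8L)
  expect_equal(p2$cells$mass, rep(1L, 8))
  # hand-enumerated indices: 0 -> cell 1, 1 (the domain max) -> cell 2
  expect_setequal(
    paste(p2$cells$k1, p2$cells$k2, p2$cells$k3),
    paste(corners[, 1] + 1, corners[, 2] + 1, corners[, 3] + 1))

  set.seed(31)
  P <- rand_cloud(500)
  for (eps in c(2, 10)) {
    part <- partition_grid(P, epsilon = eps)
    idx <- bf_bin_points(P, eps)
    tab <- table(paste(idx[, 1], idx[, 2], idx[, 3]))
    got <- setNames(part$cells$mass,
                    paste(part$cells$k1, part$cells$k2, part$cells$k3))
    expect_equal(got[names(tab)], setNames(as.integer(tab), names(tab)))
    expect_equal(sum(part$cells$mass), part$n_points)
    expect_true(all(part$cells$k1 >= 1 & part$cells$k1 <= eps))
  }
})

test_that("degenerate axes collapse to one interval with a warning", {
  flat <- cbind(runif(20), runif(20), 0)
  expect_warning(p <- partition_grid(flat, epsilon = 4), "zero extent")
  expect_equal(p$epsilon[3], 1L)
  expect_equal(sum(p$cells$mass), 20L)
})

test_that("dense cells follow the half-mean-occupancy threshold", {
  # all points in one cell: always dense
  p <- partition_grid(matrix(rep(c(1, 1, 1), 5), ncol = 3, byrow = TRUE),
                      epsilon = 1)
  expect_equal(nrow(dense_cells(p)), 1L)
  # masses {5, 5}: threshold 10/2*0.5 = 2.5, both dense
  P <- rbind(matrix(rep(c(0, 0, 0), 5), ncol = 3, byrow = TRUE),
             matrix(rep(c(10, 0, 0), 5), ncol = 3, byrow = TRUE))
  expect_equal(nrow(dense_cells(suppressWarnings(partition_grid(P, epsilon = 2)))), 2L)
  # masses {9, 1}: threshold 2.5, only the mass-9 cell survives
  P2 <- rbind(matrix(rep(c(0, 0, 0), 9), ncol = 3, byrow = TRUE),
              matrix(c(10, 0, 0), ncol = 3))
  d2 <- dense_cells(suppressWarnings(partition_grid(P2, epsilon = 2)))
  expect_equal(d2$mass, 9L)
})

test_that("connected components use face adjacency only", {
  cells <- data.frame(k1 = c(1, 2), k2 = c(1, 1), k3 = c(1, 1),
                      mass = c(1L, 1L), cx = 0, cy = 0, cz = 0,
                      px = 0, py = 0, pz = 0)
  expect_length(connected_components(cells), 1L)
  diag2 <- transform(cells, k2 = c(1, 2))       # (1,1,1) vs (2,2,1)
  expect_length(connected_components(diag2), 2L)
})

test_that("components match an igraph flood-fill oracle on random grids", {
  skip_if_not_installed("igraph")
  set.seed(8)
  for (trial in 1:25) {
    m <- sample(3:40, 1)
    idx <- unique(matrix(sample.int(10, 3 * m, replace = TRUE), ncol = 3))
    cells <- data.frame(k1 = idx[, 1], k2 = idx[, 2], k3 = idx[, 3],
                        mass = 1L, cx = 0, cy = 0, cz = 0,
                        px = 0, py = 0, pz = 0)
    got <- connected_components(cells)
    want <- bf_components(idx)
    key <- function(comp) paste(sort(comp), collapse = "-")
    got_rows <- sapply(got, function(d)
      key(match(paste(d$k1, d$k2, d$k3),
                paste(cells$k1, cells$k2, cells$k3))))
    expect_setequal(got_rows, sapply(want, key))
  }
})

test_that("component centroids are mass-weighted means", {
  comp <- data.frame(k1 = 1:2, k2 = 1, k3 = 1, mass = c(2L, 2L),
                     cx = c(0, 4), cy = c(0, 0), cz = c(1, 3),
                     px = c(0, 4), py = c(0, 0), pz = c(1, 3))
  expect_equal(component_centroid(comp)$center, c(2, 0, 2))  # midpoint
  expect_equal(component_centroid(comp[1, ])$center, c(0, 0, 1))
  comp$mass <- c(1L, 3L)
  expect_equal(component_centroid(comp)$center, c(3, 0, 2.5))
  expect_equal(component_centroid(comp)$mass, 4L)
})

test_that("sample_keypoints runs the whole pipeline on planted clusters", {
  set.seed(13)
  c1 <- matrix(rep(c(0.5, 0.5, 0.5), 5), ncol = 3, byrow = TRUE) +
    matrix(runif(15, -0.2, 0.2), ncol = 3)
  c2 <- matrix(rep(c(9.5, 9.5, 9.5), 5), ncol = 3, byrow = TRUE) +
    matrix(runif(15, -0.2, 0.2), ncol = 3)
  ks <- sample_keypoints(rbind(c1, c2), mode = "epsilon-grid", parameter = 4)
  expect_equal(nrow(ks$keypoints), 2L)
  # each keypoint is its occupied cell's geometric center
  part <- ks$partition
  dense <- dense_cells(part)
  expect_equal(sort(ks$keypoints[, 1]),
               sort(sapply(connected_components(dense), function(d)
                 component_centroid(d)$center[1])))
  # a single cluster collapses to one keypoint (the grid spans the
  # data's own bounding box, so one interval per axis holds everything)
  ks1 <- sample_keypoints(c1, mode = "epsilon-grid", parameter = 1)
  expect_equal(nrow(ks1$keypoints), 1L)
  # keypoints can never outnumber dense cells
  P <- rand_cloud(200)
  ksr <- sample_keypoints(P, mode = "epsilon-grid", parameter = 5)
  expect_lte(nrow(ksr$keypoints),
             nrow(dense_cells(ksr$partition)))
})

test_that("keypoints are insensitive to point order and translate with the cloud", {
  set.seed(17)
  P <- rand_cloud(300)
  a <- sample_keypoints(P, mode = "epsilon-grid", parameter = 6)
  b <- sample_keypoints(P[sample(nrow(P)), ], mode = "epsilon-grid",
                        parameter = 6)
  expect_equal(a$keypoints, b$keypoints)
  expect_equal(a$masses, b$masses)
  v <- c(3.5, -1.25, 12)
  tr <- sample_keypoints(sweep(P, 2, -v), mode = "epsilon-grid",
                         parameter = 6)
  expect_equal(tr$keypoints, sweep(a$keypoints, 2, -v), tolerance = 1e-9)
})

test_that("the full sampling pipeline equals a brute-force oracle", {
  skip_if_not_installed("igraph")
  set.seed(23)
  for (trial in 1:20) {
    P <- rand_cloud(sample(20:400, 1))
    eps <- sample(c(2, 4, 10), 1)
    ks <- sample_keypoints(P, mode = "epsilon-grid", parameter = eps)

    idx <- bf_bin_points(P, eps)
    keys <- paste(idx[, 1], idx[, 2], idx[, 3])
    tab <- table(keys)
    thr <- nrow(P) / length(tab) * 0.5
    dense_keys <- names(tab)[tab >= thr]
    didx <- do.call(rbind, lapply(strsplit(dense_keys, " "), as.integer))
    comps <- bf_components(didx)
    lo <- apply(P, 2, min); hi <- apply(P, 2, max); w <- hi - lo
    centers <- sapply(1:3, function(j)
      if (w[j] > 0) lo[j] + (didx[, j] - 0.5) * w[j] / eps else rep(lo[j], nrow(didx)))
    if (is.null(dim(centers))) centers <- matrix(centers, ncol = 3)
    want <- t(sapply(comps, function(rows) {
      m <- as.numeric(tab[dense_keys[rows]])
      colSums(centers[rows, , drop = FALSE] * m) / sum(m)
    }))
    got <- ks$keypoints
    ord1 <- order(got[, 1], got[, 2], got[, 3])
    ord2 <- order(want[, 1], want[, 2], want[, 3])
    expect_equal(unname(got[ord1, , drop = FALSE]),
                 unname(want[ord2, , drop = FALSE]), tolerance = 1e-12)
  }
})
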