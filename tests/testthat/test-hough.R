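test_that("Hesse-normal-form parameters satisfy the defining identities", {
  h <- plane_hough_params(c(0, 0, 5), c(0, 0, 1))
  expect_equal(h$phi, 0)
  expect_equal(h$rho, 5)
  h2 <- plane_hough_params(c(3, 0, 0), c(1, 0, 0))
  expect_equal(h2$phi, pi / 2)
  expect_equal(h2$theta, 0)
  expect_equal(h2$rho, 3)
  expect_error(plane_hough_params(c(0, 0, 0), c(1, 1, 0)), "unit length")

  set.seed(61)
  for (i in 1:200) {
    p <- runif(3, -50, 50)
    n <- rnorm(3); n <- n / sqrt(sum(n^2))
    h <- plane_hough_params(p, n)
    expect_equal(h$rho, sum(p * n), tolerance = 1e-12)
    expect_lt(max(abs(hough_normal(h$phi, h$theta) - n)), 1e-12)
  }
})

test_that("votes from a rigid scene coincide at the moved reference point", {
  atoms <- std_fixture()
  P <- as_points(fixture_protein(atoms))
  kp <- sample_keypoints(P, mode = "voxel-size", parameter = 0.5,
                         centroid = "points")
  fr <- compute_lrf(P, kp, rf_radius = 4)
  n_kp <- nrow(kp$keypoints)
  corrs <- structure(list(
    pairs = data.frame(query = seq_len(n_kp), match = seq_len(n_kp),
                       distance = 0),
    max_distance = 0.25), class = "correspondence_set")
  ref <- colMeans(P)
  # identical scene: all votes at the reference point itself
  v0 <- cast_votes(corrs, kp, fr, kp, fr, ref)
  expect_lt(max(abs(sweep(v0$votes, 2, ref))), 1e-9)
  # rigid scene: all votes at the transformed reference point
  R0 <- random_rotation(8); tv <- c(4, 4, -4)
  P2 <- as_points(apply_rigid(P, R0, tv))
  kp2 <- sample_keypoints(P2, mode = "voxel-size", parameter = 0.5,
                          centroid = "points")
  TK <- sweep(kp$keypoints %*% t(R0), 2, tv, "+")
  perm <- apply(cross_dist2_test(TK, kp2$keypoints), 1, which.min)
  fr2 <- compute_lrf(P2, kp2, rf_radius = 4)
  corrs2 <- structure(list(
    pairs = data.frame(query = seq_len(n_kp), match = perm, distance = 0),
    max_distance = 0.25), class = "correspondence_set")
  v1 <- cast_votes(corrs2, kp, fr, kp2, fr2, ref)
  want <- as.numeric(R0 %*% ref + tv)
  expect_lt(max(abs(sweep(v1$votes, 2, want))), 1e-6)
  expect_equal(nrow(v1$votes) + v1$n_skipped, n_kp)
})

test_that("vote grouping respects the count threshold and separation", {
  ten <- matrix(rep(c(1, 2, 3), 10), ncol = 3, byrow = TRUE)
  pairs <- data.frame(query = 1:10, match = 1:10, distance = 0)
  g <- extract_groups(ten, pairs, bin_size = 0.5, threshold = 5)
  expect_length(g, 1L)
  expect_equal(g[[1]]$vote_count, 10L)

  four <- ten[1:4, ]
  expect_length(extract_groups(four, pairs[1:4, ], 0.5, 5), 0L)

  two <- rbind(ten[1:6, ], sweep(ten[1:6, ], 2, c(50, 0, 0), "+"))
  g2 <- extract_groups(two, data.frame(query = 1:12, match = 1:12,
                                       distance = 0), 0.5, 5)
  expect_length(g2, 2L)
  expect_equal(sapply(g2, `[[`, "vote_count"), c(6L, 6L))
})

test_that("rigid transforms are recovered by the Kabsch fit", {
  set.seed(71)
  M <- rand_cloud(30)
  grp <- structure(list(correspondences = data.frame(query = 1:30,
                                                     match = 1:30,
                                                     distance = 0),
                        vote_count = 30L, rotation = NULL,
                        translation = NULL), class = "match_group")
  # identical scene: identity transform
  g0 <- estimate_transform(grp, M, M)
  expect_lt(max(abs(g0$rotation - diag(3))), 1e-9)
  expect_lt(max(abs(g0$translation)), 1e-9)
  # planted motion, recovered to machine precision
  R0 <- random_rotation(10); tv <- c(-7, 2, 13)
  S <- as_points(apply_rigid(M, R0, tv))
  g1 <- estimate_transform(grp, M, S)
  expect_lt(norm(g1$rotation - R0, "F"), 1e-6)
  expect_lt(sqrt(sum((g1$translation - tv)^2)), 1e-6)
  expect_lt(g1$rmsd, 1e-9)
  # independent cross-check of the fit against bio3d's superposition
  xyz_fit <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.vector(t(S)), mobile = as.vector(t(M))))
  expect_lt(max(abs(matrix(xyz_fit, ncol = 3, byrow = TRUE) -
                    sweep(M %*% t(g1$rotation), 2, g1$translation, "+"))),
            1e-6)
  # scrambled correspondences leave a large residual
  grp_bad <- grp
  grp_bad$correspondences$match <- sample(30)
  g2 <- estimate_transform(grp_bad, M, S)
  expect_gt(g2$rmsd, 1)
  # collinear points cannot pin down a rotation
  line <- cbind(1:5, 0, 0)
  grp_l <- grp
  grp_l$correspondences <- data.frame(query = 1:5, match = 1:5, distance = 0)
  expect_error(estimate_transform(grp_l, line, line), "collinear")
})

test_that("hypothesis verification filters by inlier fraction", {
  set.seed(73)
  M <- rand_cloud(40)
  grp <- structure(list(correspondences = data.frame(query = 1:40,
                                                     match = 1:40,
                                                     distance = 0),
                        vote_count = 40L, rotation = diag(3),
                        translation = c(0, 0, 0)), class = "match_group")
  kept <- verify_hypotheses(list(grp), M, M, inlier_threshold = 0.1)
  expect_length(kept, 1L)
  expect_equal(kept[[1]]$inlier_fraction, 1)
  # unrelated scene: rejected
  kept2 <- verify_hypotheses(list(grp), M, rand_cloud(40) + 500,
                             inlier_threshold = 0.1)
  expect_length(kept2, 0L)
  # infinite threshold is a vacuous filter
  kept3 <- verify_hypotheses(list(grp), M, rand_cloud(40) + 500,
                             inlier_threshold = Inf)
  expect_length(kept3, 1L)
})

test_that("refine_group trims inconsistent members and keeps the fit exact", {
  set.seed(77)
  M <- rand_cloud(25)
  R0 <- random_rotation(12); tv <- c(1, -2, 3)
  S <- rbind(as_points(apply_rigid(M, R0, tv)), rand_cloud(10) + 30)
  pairs <- data.frame(query = c(1:25, sample(25, 8)),
                      match = c(1:25, 25 + sample(10, 8, replace = TRUE)),
                      distance = 0)
  grp <- structure(list(correspondences = pairs, vote_count = nrow(pairs),
                        seed_members = 1:25,
                        rotation = NULL, translation = NULL),
                   class = "match_group")
  out <- refine_group(grp, M, S, tol = 0.5, candidates = pairs)
  expect_equal(out$vote_count, 25L)
  expect_lt(norm(out$rotation - R0, "F"), 1e-9)
})

test_that("a pocket matches its own protein and not an unrelated cloud", {
  atoms <- std_fixture()
  pocket <- fixture_pocket(atoms)
  protein <- fixture_protein(atoms)
  res <- match_pocket(pocket, protein)
  expect_gte(res$n_groups, 1L)
  top <- res$groups[[1]]
  # the transformed pocket must lie on the protein
  TP <- sweep(as_points(pocket) %*% t(top$rotation), 2,
              top$translation_input_units, "+")
  nn <- sqrt(apply(cross_dist2_test(TP, as_points(protein)), 1, min))
  expect_gt(mean(nn <= 1), 0.8)
  # a random cloud of the same size yields nothing at default settings
  set.seed(83)
  res0 <- match_pocket(pocket, rand_cloud(n_points(protein), scale = 25))
  expect_equal(res0$n_groups, 0L)
})

test_that("a planted whole-protein motion is recovered end to end", {
  atoms <- make_structure(fixture_spec(seed = 19))
  protein <- fixture_protein(atoms)
  R0 <- random_rotation(20); tv <- c(6, -11, 2)
  moved <- apply_rigid(protein, R0, tv)
  res <- match_pocket(protein, moved)
  expect_gte(res$n_groups, 1L)
  g <- res$groups[[1]]
  expect_lt(norm(g$rotation - R0, "F"), 1e-6)
  expect_lt(sqrt(sum((g$translation_input_units - tv)^2)), 1e-6)
  # vote concentration: nearly every matchable keypoint is in the top group
  qs <- unique(res$correspondences$pairs$query)
  expect_gte(length(unique(g$correspondences$query)) / length(qs), 0.95)
  # pocket vs the moved parent: recovery at the looser pocket tolerance
  pocket <- fixture_pocket(atoms)
  resp <- match_pocket(pocket, moved)
  expect_gte(resp$n_groups, 1L)
  gp <- resp$groups[[1]]
  expect_lt(norm(gp$rotation - R0, "F"), 1e-4)
  expect_lt(sqrt(sum((gp$translation_input_units - tv)^2)), 1e-4)
})
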