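test_that("read_pdb parses fixed-column ATOM/HETATM records", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      2  CB  ALA A   1       2.500   2.000   3.000  1.00  0.00           C",
    "ATOM      3  CA  GLY A   2       4.800   2.000   3.000  1.00  0.00           C",
    "HETATM    4  C1  LIG B   1       1.000   6.000   3.000  1.00  0.00           C",
    "HETATM    5  C2  LIG B   1       2.400   6.000   3.000  1.00  0.00           C",
    "END"), pdb)
  atoms <- read_pdb(pdb)
  expect_equal(nrow(atoms), 5L)
  expect_equal(sum(atoms$hetero), 2L)
  expect_equal(unname(unlist(atoms[1, c("x", "y", "z")])), c(1, 2, 3))
  expect_equal(atoms$name[1], "CA")
  expect_equal(atoms$chain[4], "B")
  expect_error(read_pdb(file.path(tempdir(), "nope.pdb")), "not found")
})

test_that("PDB write/read round-trips fixture coordinates to column precision", {
  atoms <- std_fixture()
  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(atoms, pdb)
  back <- read_pdb(pdb)
  expect_equal(nrow(back), nrow(atoms))
  expect_equal(back$x, atoms$x, tolerance = 1e-3)
  expect_equal(back$y, atoms$y, tolerance = 1e-3)
  expect_equal(back$z, atoms$z, tolerance = 1e-3)
  expect_equal(back$hetero, atoms$hetero)
  expect_equal(back$resseq, atoms$resseq)
})

test_that("alternate locations resolve to the highest-occupancy conformer", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       1.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1       9.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CB AALA A   1       0.000   1.000   0.000  0.50  0.00           C",
    "ATOM      4  CB BALA A   1       0.000   9.000   0.000  0.50  0.00           C",
    "END"), pdb)
  atoms <- read_pdb(pdb)
  expect_equal(nrow(atoms), 2L)
  expect_equal(atoms$x[atoms$name == "CA"], 9)        # occupancy 0.6 wins
  expect_equal(atoms$y[atoms$name == "CB"], 1)        # tie -> altloc A
})

test_that("hydrogens are dropped by default and kept on request", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       1.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  HA  ALA A   1       1.500   0.500   0.000  1.00  0.00           H",
    "END"), pdb)
  expect_equal(nrow(read_pdb(pdb)), 1L)
  expect_equal(nrow(read_pdb(pdb, keep_hydrogens = TRUE)), 2L)
})

test_that("structure_to_pointcloud honours predicates and preserves order", {
  atoms <- std_fixture()
  all_cloud <- structure_to_pointcloud(atoms)
  expect_equal(n_points(all_cloud), nrow(atoms))
  het <- structure_to_pointcloud(atoms, function(a) a$hetero)
  expect_equal(n_points(het), sum(atoms$hetero))
  expect_true(all(het$atoms$hetero))
  # chain predicate against a brute-force filter
  manual <- atoms[atoms$chain == "A", ]
  byfun <- structure_to_pointcloud(atoms, function(a) a$chain == "A")
  expect_equal(as_points(byfun), unname(cbind(manual$x, manual$y, manual$z)),
               ignore_attr = TRUE)
  expect_error(structure_to_pointcloud(atoms, function(a) a$chain == "Z"),
               "no atoms")
})

test_that("extract_pocket keeps exactly the atoms within the shell", {
  lig <- data.frame(serial = 1L, name = "C1", resname = "LIG", chain = "B",
                    resseq = 1L, x = 0, y = 0, z = 0, hetero = TRUE,
                    occupancy = 1, altloc = "", element = "C")
  prot <- data.frame(serial = 1:2, name = "CA", resname = "ALA", chain = "A",
                     resseq = 1:2, x = c(4.9, 5.1), y = 0, z = 0,
                     hetero = FALSE, occupancy = 1, altloc = "", element = "C")
  pk <- extract_pocket(prot, lig, 5)
  expect_equal(n_points(pk), 1L)
  expect_equal(pk$atoms$x, 4.9)
  expect_warning(pk0 <- extract_pocket(prot, lig, 0), "empty")
  expect_equal(n_points(pk0), 0L)
})

test_that("extract_pocket matches a double-loop oracle and is rigid-invariant", {
  set.seed(11)
  prot <- data.frame(serial = 1:200, name = "CA", resname = "ALA",
                     chain = "A", resseq = 1:200,
                     x = runif(200, -15, 15), y = runif(200, -15, 15),
                     z = runif(200, -15, 15), hetero = FALSE,
                     occupancy = 1, altloc = "", element = "C")
  lig <- data.frame(serial = 1:5, name = "C1", resname = "LIG", chain = "B",
                    resseq = 1L, x = runif(5, -3, 3), y = runif(5, -3, 3),
                    z = runif(5, -3, 3), hetero = TRUE, occupancy = 1,
                    altloc = "", element = "C")
  pk <- extract_pocket(prot, lig, 5)
  keep <- sapply(seq_len(nrow(prot)), function(i) {
    any(sapply(seq_len(nrow(lig)), function(j)
      sqrt(sum((unlist(prot[i, c("x", "y", "z")]) -
                unlist(lig[j, c("x", "y", "z")]))^2)) <= 5))
  })
  expect_equal(pk$atoms$serial, prot$serial[keep])
  # common rigid motion of protein and ligand leaves the selection intact
  R0 <- random_rotation(3); tv <- c(4, -2, 9)
  rot <- function(df) {
    m <- as_points(apply_rigid(as.matrix(df[, c("x", "y", "z")]), R0, tv))
    df[, c("x", "y", "z")] <- m
    df
  }
  pk2 <- extract_pocket(rot(prot), rot(lig), 5)
  expect_equal(pk2$atoms$serial, pk$atoms$serial)
})

test_that("PCD write/read round-trips and records WIDTH correctly", {
  p3 <- matrix(c(0, 0, 0, 1.5, -2.25, 3, 10, 20, -30), ncol = 3, byrow = TRUE)
  f <- withr::local_tempfile(fileext = ".pcd")
  write_pcd(p3, f)
  lines <- readLines(f)
  expect_true("WIDTH 3" %in% lines)
  expect_true("FIELDS x y z" %in% lines)
  expect_equal(as_points(read_pcd(f)), p3, ignore_attr = TRUE)

  set.seed(2)
  big <- rand_cloud(1000, scale = 100)
  write_pcd(big, f)
  expect_lt(max(abs(as_points(read_pcd(f)) - big)), 1e-6)
})

test_that("malformed PCD headers are rejected with the offending line", {
  f <- withr::local_tempfile(fileext = ".pcd")
  writeLines(c("VERSION 0.7", "GARBAGE LINE", "DATA ascii"), f)
  expect_error(read_pcd(f), "GARBAGE")
  writeLines(c("VERSION 0.7", "FIELDS x y", "POINTS 1", "DATA ascii", "1 2"), f)
  expect_error(read_pcd(f), "FIELDS")
  writeLines(c("VERSION 0.7", "FIELDS x y z", "POINTS 2", "DATA ascii",
               "1 2 3"), f)
  expect_error(read_pcd(f), "promises")
})

test_that("perturb_cloud calibration hits the requested mean displacement", {
  set.seed(5)
  big <- rand_cloud(10000)
  for (distr in c("isotropic-gaussian", "uniform-sphere")) {
    pert <- perturb_cloud(big, noise_spec(1.0, distribution = distr,
                                          seed = 99))
    expect_equal(compute_delta(big, pert), 1.0, tolerance = 0.05)
  }
  # magnitude 0 is the identity; equal seeds give equal outputs
  expect_equal(as_points(perturb_cloud(big, noise_spec(0))), big,
               ignore_attr = TRUE, tolerance = 0)
  a <- perturb_cloud(big, noise_spec(0.7, seed = 4))
  b <- perturb_cloud(big, noise_spec(0.7, seed = 4))
  expect_identical(as_points(a), as_points(b))
  expect_error(noise_spec(-0.1), "nonnegative")
})

test_that("compute_delta is the mean per-point displacement", {
  cl <- rand_cloud(50)
  expect_identical(compute_delta(cl, cl), 0)
  shifted <- sweep(cl, 2, c(0, 0, -1.5))
  expect_equal(compute_delta(cl, shifted), 1.5, tolerance = 1e-12)
  one <- matrix(c(0, 0, 0), ncol = 3)
  expect_equal(compute_delta(one, matrix(c(1, 2, 2), ncol = 3)), 3)
  expect_error(compute_delta(cl, cl[-1, ]), "same number")
})
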