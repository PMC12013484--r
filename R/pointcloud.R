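#' Molecular point cloud
#'
#' A `mol_cloud` is an ordered set of 3D points (Angstrom), optionally
#' carrying the atom records the points came from and per-point unit
#' normals. Point order is stable under all operations and under
#' round-trip serialization to PCD/PDB.
#'
#' @param points numeric matrix with 3 columns (x, y, z) or a length-3
#'   vector for a single point.
#' @param atoms optional data frame of atom records parallel to `points`
#'   (one row per point), as returned by [read_pdb()].
#' @param normals optional numeric matrix of unit normals, same shape as
#'   `points`. Rows that are all-`NA` mark points whose normal is
#'   undefined; all defined rows must have unit Euclidean length.
#' @return an object of class `mol_cloud`.
#' @export
mol_cloud <- function(points, atoms = NULL, normals = NULL) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L)
  points <- as.matrix(points)
  if (ncol(points) != 3L)
    stop("`points` must have exactly 3 columns (x, y, z)")
  storage.mode(points) <- "double"
  if (nrow(points) > 0L && !all(is.finite(points)))
    stop("point coordinates must be finite")
  dimnames(points) <- list(NULL, c("x", "y", "z"))
  if (!is.null(atoms)) {
    atoms <- as.data.frame(atoms)
    if (nrow(atoms) != nrow(points))
      stop("`atoms` must have one row per point")
  }
  if (!is.null(normals)) {
    normals <- as.matrix(normals)
    storage.mode(normals) <- "double"
    if (!identical(dim(normals), dim(points)))
      stop("`normals` must have the same dimensions as `points`")
    def <- !is.na(normals[, 1L])
    if (any(def)) {
      len <- sqrt(rowSums(normals[def, , drop = FALSE]^2))
      if (any(abs(len - 1) > 1e-9))
        stop("defined normals must have unit length (tolerance 1e-9)")
    }
  }
  structure(list(points = points, atoms = atoms, normals = normals),
            class = "mol_cloud")
}

#' @export
print.mol_cloud <- function(x, ...) {
  cat(sprintf("<mol_cloud> %d points%s%s\n", nrow(x$points),
              if (!is.null(x$atoms)) ", with atom records" else "",
              if (!is.null(x$normals)) ", with normals" else ""))
  if (nrow(x$points) > 0L) {
    rng <- apply(x$points, 2L, range)
    cat(sprintf("  extent: x [%.2f, %.2f]  y [%.2f, %.2f]  z [%.2f, %.2f] A\n",
                rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  }
  invisible(x)
}

#' @export
length.mol_cloud <- function(x) nrow(x$points)

#' Number of points in a cloud
#' @param cloud a [mol_cloud()] or coordinate matrix.
#' @return integer point count.
#' @export
n_points <- function(cloud) nrow(as_points(cloud))

#' Coerce to a coordinate matrix
#'
#' Accepts a `mol_cloud` or a plain numeric matrix and returns the n x 3
#' coordinate matrix.
#' @param x a `mol_cloud` or matrix.
#' @return numeric matrix with columns x, y, z.
#' @export
as_points <- function(x) {
  if (inherits(x, "mol_cloud")) return(x$points)
  if (is.null(dim(x))) x <- matrix(x, ncol = 3L)
  x <- as.matrix(x)
  if (ncol(x) != 3L) stop("expected 3 columns")
  storage.mode(x) <- "double"
  x
}

# Squared Euclidean cross-distances between two coordinate matrices.
# Returns |A| x |B| matrix; clamped at 0 against negative round-off.
cross_dist2 <- function(A, B) {
  A <- as_points(A); B <- as_points(B)
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

# Run expr with a temporary RNG state seeded by `seed`; the caller's
# RNG stream is untouched. seed = NULL runs expr as-is.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
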