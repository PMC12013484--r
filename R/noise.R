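#' Specification of the coordinate-noise model
#'
#' Structural noise is quantified as the mean per-atom Euclidean
#' displacement delta between original and perturbed coordinates (see
#' [compute_delta()]). A `noise_spec` states a target delta and the shape
#' of the displacement distribution used to realize it.
#'
#' For `"isotropic-gaussian"` each coordinate receives independent
#' N(0, sigma^2) noise; the displacement magnitude then follows a chi
#' distribution with 3 degrees of freedom, whose mean is
#' `sigma * 2 * sqrt(2/pi)`, so `sigma = magnitude * sqrt(pi/8)` makes the
#' expected displacement equal the requested magnitude. For
#' `"uniform-sphere"` displacements are uniform in a solid ball; the mean
#' magnitude of such a draw is 3/4 of the ball radius, so the radius is
#' `4/3 * magnitude`.
#'
#' @param magnitude target mean displacement delta in Angstrom (>= 0;
#'   the study range is 0-1.5 A).
#' @param distribution `"isotropic-gaussian"` (default) or
#'   `"uniform-sphere"`.
#' @param seed optional integer seed making the perturbation
#'   reproducible.
#' @return an object of class `noise_spec`.
#' @export
noise_spec <- function(magnitude,
                       distribution = c("isotropic-gaussian",
                                        "uniform-sphere"),
                       seed = NULL) {
  if (!is.numeric(magnitude) || length(magnitude) != 1L || magnitude < 0)
    stop("`magnitude` must be a single nonnegative number")
  structure(list(magnitude = magnitude,
                 distribution = match.arg(distribution),
                 seed = seed),
            class = "noise_spec")
}

#' Perturb a point cloud with positional noise
#'
#' Displaces every point by an independent random vector drawn so that
#' the expected per-point displacement magnitude equals
#' `spec$magnitude` (see [noise_spec()] for the calibration). With a seed
#' the output is deterministic; with magnitude 0 the input is returned
#' unchanged.
#'
#' @param cloud a [mol_cloud()] or coordinate matrix (nonempty).
#' @param spec a [noise_spec()].
#' @return a perturbed [mol_cloud()] (atom records are carried over).
#' @export
perturb_cloud <- function(cloud, spec) {
  stopifnot(inherits(spec, "noise_spec"))
  P <- as_points(cloud)
  if (nrow(P) == 0L) stop("`cloud` is empty")
  atoms <- if (inherits(cloud, "mol_cloud")) cloud$atoms else NULL
  if (spec$magnitude == 0) return(mol_cloud(P, atoms = atoms))
  n <- nrow(P)
  D <- with_seed(spec$seed, {
    if (spec$distribution == "isotropic-gaussian") {
      sigma <- spec$magnitude * sqrt(pi / 8)
      matrix(stats::rnorm(3L * n, sd = sigma), ncol = 3L)
    } else {
      # uniform in a solid ball of radius 4/3 * magnitude
      u <- matrix(stats::rnorm(3L * n), ncol = 3L)
      u <- u / sqrt(rowSums(u^2))
      r <- (4 / 3) * spec$magnitude * stats::runif(n)^(1 / 3)
      u * r
    }
  })
  mol_cloud(P + D, atoms = atoms)
}

#' Mean per-atom displacement between two clouds
#'
#' The noise statistic delta: the arithmetic mean of the per-point
#' Euclidean distances between matched points of two equally sized,
#' identically ordered clouds. For a global translation v of a cloud,
#' `compute_delta` returns exactly `||v||`.
#'
#' @param original,perturbed clouds of equal cardinality and matching
#'   point order.
#' @return delta in Angstrom.
#' @export
compute_delta <- function(original, perturbed) {
  A <- as_points(original); B <- as_points(perturbed)
  if (!identical(dim(A), dim(B)))
    stop("clouds must have the same number of points")
  if (nrow(A) == 0L) stop("clouds are empty")
  mean(sqrt(rowSums((B - A)^2)))
}

#' Perturb a cloud at a series of noise levels
#'
#' Produces one perturbed copy of `cloud` per target delta in `levels`
#' (sorted ascending) and records the realized delta of each copy.
#'
#' @param cloud a [mol_cloud()] or coordinate matrix.
#' @param levels ascending nonnegative target deltas in Angstrom.
#' @param seed integer seed; level i uses `seed + i - 1` so levels are
#'   independently reproducible.
#' @param distribution noise shape, see [noise_spec()].
#' @return a list with one element per level:
#'   `list(level, cloud, delta)` where `delta` is the realized mean
#'   displacement.
#' @export
noise_series <- function(cloud, levels = c(0, 0.5, 1.0, 1.5), seed = 1L,
                         distribution = "isotropic-gaussian") {
  if (is.unsorted(levels)) stop("`levels` must be sorted ascending")
  if (any(levels < 0)) stop("noise levels must be nonnegative")
  lapply(seq_along(levels), function(i) {
    sp <- noise_spec(levels[i], distribution = distribution,
                     seed = seed + i - 1L)
    pc <- perturb_cloud(cloud, sp)
    list(level = levels[i], cloud = pc,
         delta = compute_delta(cloud, pc))
  })
}
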