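#' Pocket overlap score (POS)
#'
#' Fraction of the true pocket covered by the prediction: a true point
#' is covered when some predicted point lies within the matching
#' threshold delta, and POS is the number of covered true points over
#' the size of the true pocket, so POS always lies in [0, 1].
#'
#' @param pred predicted pocket cloud (may be empty).
#' @param true actual pocket cloud (nonempty).
#' @param delta matching threshold in Angstrom (default 2.0, a typical
#'   heavy-atom contact resolution).
#' @return POS in [0, 1].
#' @export
pocket_overlap_score <- function(pred, true, delta = 2.0) {
  TP <- as_points(true)
  if (nrow(TP) == 0L) stop("the true pocket is empty; POS undefined")
  if (delta < 0) stop("`delta` must be nonnegative")
  PP <- as_points(pred)
  if (nrow(PP) == 0L) return(0)
  covered <- sqrt(apply(exact_dist2(TP, PP), 1L, min)) <= delta
  sum(covered) / nrow(TP)
}

# Cancellation-free squared cross-distances (differences first, then
# squares), used by the evaluation metrics where exact zeros matter.
exact_dist2 <- function(A, B) {
  outer(A[, 1L], B[, 1L], "-")^2 + outer(A[, 2L], B[, 2L], "-")^2 +
    outer(A[, 3L], B[, 3L], "-")^2
}

#' Point-level confusion counts for pocket prediction
#'
#' Every predicted point is classified exactly once: a true positive if
#' some actual pocket point lies within delta; otherwise a true
#' negative if it falls outside the axis-aligned bounding box of the
#' actual pocket; otherwise (inside the box but farther than delta from
#' every actual point) a false positive. False negatives are the actual
#' pocket points with no predicted point within delta.
#'
#' @param pred predicted pocket cloud.
#' @param true actual pocket cloud (nonempty).
#' @param delta matching threshold in Angstrom.
#' @return an object of class `confusion_counts`:
#'   `list(tp, fp, tn, fn, delta)`.
#' @export
classify_points <- function(pred, true, delta = 2.0) {
  TPm <- as_points(true)
  if (nrow(TPm) == 0L) stop("the true pocket is empty")
  if (delta < 0) stop("`delta` must be nonnegative")
  PP <- as_points(pred)
  if (nrow(PP) == 0L) {
    counts <- list(tp = 0L, fp = 0L, tn = 0L, fn = nrow(TPm), delta = delta)
    return(structure(counts, class = "confusion_counts"))
  }
  d <- sqrt(exact_dist2(PP, TPm))
  near <- apply(d, 1L, min) <= delta
  lo <- apply(TPm, 2L, min); hi <- apply(TPm, 2L, max)
  in_box <- PP[, 1L] >= lo[1L] & PP[, 1L] <= hi[1L] &
            PP[, 2L] >= lo[2L] & PP[, 2L] <= hi[2L] &
            PP[, 3L] >= lo[3L] & PP[, 3L] <= hi[3L]
  tp <- sum(near)
  tn <- sum(!near & !in_box)
  fp <- sum(!near & in_box)
  fn <- sum(apply(d, 2L, min) > delta)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn, delta = delta),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP %d  FP %d  TN %d  FN %d (delta %g A)\n",
              x$tp, x$fp, x$tn, x$fn, x$delta))
  invisible(x)
}

#' Precision, recall and F1 from confusion counts
#'
#' `precision = tp / (tp + fp)`, `recall = tp / (tp + fn)`,
#' `f1 = 2 * precision * recall / (precision + recall)`; any zero
#' denominator yields 0 by convention.
#'
#' @param counts a [classify_points()] result (or any list with
#'   `tp`, `fp`, `fn`).
#' @return `list(precision, recall, f1)`.
#' @export
f1_score <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  list(precision = precision, recall = recall, f1 = f1)
}

#' Matthews correlation coefficient
#'
#' `(tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`, with 0 when
#' any denominator factor is zero, and the result clamped to [-1, 1]
#' to guard against floating-point overshoot.
#'
#' @param counts a [classify_points()] result.
#' @return MCC in [-1, 1].
#' @export
mcc <- function(counts) {
  tp <- as.numeric(counts$tp); fp <- as.numeric(counts$fp)
  tn <- as.numeric(counts$tn); fn <- as.numeric(counts$fn)
  fac <- c(tp + fp, tp + fn, tn + fp, tn + fn)
  if (any(fac == 0)) return(0)
  v <- (tp * tn - fp * fn) / sqrt(prod(fac))
  max(-1, min(1, v))
}

#' Nearest-neighbour RMSE between clouds
#'
#' The root of the mean squared nearest-neighbour distance from each
#' predicted point to the true set.
#'
#' @param pred predicted cloud (nonempty).
#' @param true reference cloud (nonempty).
#' @return RMSE in Angstrom.
#' @export
rmse <- function(pred, true) {
  PP <- as_points(pred); TPm <- as_points(true)
  if (nrow(PP) == 0L || nrow(TPm) == 0L)
    stop("both clouds must be nonempty; RMSE undefined")
  sqrt(mean(apply(exact_dist2(PP, TPm), 1L, min)))
}

#' Strong/weak similarity classification
#'
#' A pocket-protein pair is a strong match when its correspondence
#' count strictly exceeds the threshold (default 10), weak otherwise.
#'
#' @param correspondence_count nonnegative integer.
#' @param threshold integer cut (default 10).
#' @return `"strong"` or `"weak"`.
#' @export
classify_similarity <- function(correspondence_count, threshold = 10L) {
  if (correspondence_count < 0) stop("count must be nonnegative")
  if (correspondence_count > threshold) "strong" else "weak"
}

#' Full evaluation report for a predicted pocket
#'
#' Bundles POS, the confusion counts, precision/recall/F1, MCC, RMSE
#' and the similarity class into one row.
#'
#' @param pred predicted pocket cloud.
#' @param true actual pocket cloud.
#' @param delta matching threshold in Angstrom.
#' @param correspondence_count optional count for the similarity class.
#' @param similarity_threshold strong/weak cut (default 10).
#' @return a one-row data frame with columns `pos`, `tp`, `fp`, `tn`,
#'   `fn`, `precision`, `recall`, `f1`, `mcc`, `rmse`,
#'   `similarity_class`.
#' @export
metrics_report <- function(pred, true, delta = 2.0,
                           correspondence_count = NA_integer_,
                           similarity_threshold = 10L) {
  counts <- classify_points(pred, true, delta)
  pr <- f1_score(counts)
  data.frame(
    pos = pocket_overlap_score(pred, true, delta),
    tp = counts$tp, fp = counts$fp, tn = counts$tn, fn = counts$fn,
    precision = pr$precision, recall = pr$recall, f1 = pr$f1,
    mcc = mcc(counts),
    rmse = if (n_points(pred) > 0) rmse(pred, true) else NA_real_,
    similarity_class = if (is.na(correspondence_count)) NA_character_
      else classify_similarity(correspondence_count, similarity_threshold),
    stringsAsFactors = FALSE)
}

#' All-against-all similarity matrix
#'
#' Runs [match_pocket()] for every pocket against every protein and
#' tabulates the correspondence counts. Failures of individual pairs
#' are recorded as `NA` and the run continues.
#'
#' @param pockets named list of pocket clouds.
#' @param proteins named list of protein clouds.
#' @param config a [procv_config()].
#' @return integer matrix, rows = pockets, columns = proteins.
#' @export
similarity_matrix <- function(pockets, proteins, config = atomic_config()) {
  if (length(pockets) == 0L || length(proteins) == 0L)
    stop("`pockets` and `proteins` must be nonempty lists")
  m <- matrix(NA_integer_, length(pockets), length(proteins),
              dimnames = list(names(pockets), names(proteins)))
  for (i in seq_along(pockets)) {
    for (j in seq_along(proteins)) {
      m[i, j] <- tryCatch(
        as.integer(match_pocket(pockets[[i]], proteins[[j]],
                                config)$n_correspondences),
        error = function(e) {
          warning("pair (", i, ", ", j, ") failed: ",
                  conditionMessage(e))
          NA_integer_
        })
    }
  }
  m
}
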