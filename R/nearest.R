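#' Nearest-neighbour search between 3D point sets
#'
#' For every query point, finds the closest reference point (Euclidean) using
#' a k-d tree. Ties in distance resolve to the lowest reference index, so the
#' result is exactly reproducible and identical to [exhaustive_nearest()].
#'
#' @param query n x 3 numeric matrix of query points.
#' @param reference m x 3 numeric matrix of reference points.
#' @return list with `index` (1-based into `reference`) and `distance` (mm).
#' @export
nearest_points <- function(query, reference) {
  query <- as.matrix(query)
  reference <- as.matrix(reference)
  stopifnot(ncol(query) == 3L, ncol(reference) == 3L)
  if (nrow(query) == 0L) stop("query point set is empty")
  if (nrow(reference) == 0L) stop("reference point set is empty")
  .nn_kdtree(query, reference)
}

#' Brute-force nearest neighbour (oracle)
#'
#' Exhaustive O(n*m) search with the same tie rule (lowest reference index)
#' as [nearest_points()]. Kept as the independent check that the accelerated
#' tree search is exact; use [nearest_points()] for real workloads.
#'
#' @inheritParams nearest_points
#' @return list with `index` and `distance`, identical to [nearest_points()].
#' @export
exhaustive_nearest <- function(query, reference) {
  query <- as.matrix(query)
  reference <- as.matrix(reference)
  if (nrow(query) == 0L) stop("query point set is empty")
  if (nrow(reference) == 0L) stop("reference point set is empty")
  rx <- reference[, 1]; ry <- reference[, 2]; rz <- reference[, 3]
  idx <- integer(nrow(query))
  d <- numeric(nrow(query))
  for (i in seq_len(nrow(query))) {
    dx <- rx - query[i, 1]; dy <- ry - query[i, 2]; dz <- rz - query[i, 3]
    d2 <- dx * dx + dy * dy + dz * dz
    j <- which.min(d2)   # which.min returns the first (lowest) index on ties
    idx[i] <- j
    d[i] <- sqrt(d2[j])
  }
  list(index = idx, distance = d)
}
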