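# One-dimensional Lloyd's k-means with random initial centroids.
#
# Initial centroids are drawn uniformly without replacement from the distinct
# data values (using R's global RNG; seed at the caller for reproducibility).
# Assignment ties go to the lower-index centroid.  Clusters that empty out
# are dropped; because a valid k-clustering always exists for k <= #distinct
# values, the run is retried (bounded) if the solution degenerates.
lloyd_1d <- function(x, k, max_iter = 100L, retries = 20L) {
  ux <- unique(x)
  k <- min(k, length(ux))
  if (k == 1L)
    return(list(assign = rep(1L, length(x)), centers = mean(x), k = 1L))
  for (attempt in seq_len(retries)) {
    centers <- sort(sample(ux, k))
    assign <- integer(length(x))
    for (it in seq_len(max_iter)) {
      d <- abs(outer(x, centers, "-"))
      new_assign <- max.col(-d, ties.method = "first")
      keep <- sort(unique(new_assign))
      if (length(keep) < length(centers)) {
        centers <- centers[keep]
        new_assign <- match(new_assign, keep)
      }
      centers <- vapply(seq_along(centers),
                        function(j) mean(x[new_assign == j]), numeric(1))
      if (identical(new_assign, assign)) break
      assign <- new_assign
    }
    if (length(centers) == k)
      return(list(assign = assign, centers = centers, k = k))
  }
  # fall back to whatever non-degenerate clustering the last attempt reached
  list(assign = assign, centers = centers, k = length(centers))
}

check_binarizable <- function(x, min_len = 2L, what = "input") {
  x <- as.numeric(x)
  if (length(x) < min_len)
    stop_degenerate(sprintf("%s has fewer than %d values", what, min_len))
  if (length(unique(x)) < 2L)
    stop_degenerate(sprintf(
      "%s is constant (all values identical); it carries no Boolean signal",
      what))
  x
}

#' Two-cluster k-means binarization (KM-1)
#'
#' Clusters the values of one species into two groups by 1-D k-means (time
#' stamps are ignored); values in the higher-mean cluster become 1, the rest
#' 0.  Initial centroids are random, so repeated calls may differ on
#' ambiguous data; seed R's RNG for reproducibility.
#'
#' @param x numeric vector of one species' measurements (length >= 2, at
#'   least two distinct values).
#' @return integer 0/1 vector, same length as `x`.
#' @examples
#' set.seed(1)
#' binarize_km1(c(0.1, 0.9, 0.2, 0.8, 0.15))
#' @export
binarize_km1 <- function(x) {
  binarize_km3(x, depth = 1L)
}

#' Iterative k-means binarization (KM-3)
#'
#' Starts from `k = 2^depth` clusters; in each iteration the data are
#' clustered, every value is replaced by its cluster's mean, and the depth is
#' decremented (so `k` halves).  The final 2-cluster pass emits 1 for the
#' higher cluster and 0 for the lower.  The coarse-to-fine schedule preserves
#' late low-amplitude peaks of damped oscillations that direct 2-means (KM-1,
#' equivalent to `depth = 1`) flattens to 0.
#'
#' If `2^depth` exceeds the number of distinct values at some iteration, `k`
#' is clamped to that number for the iteration.
#'
#' @param x numeric vector of one species' measurements.
#' @param depth clustering depth `d >= 1`; the default 3 (initial `k = 8`)
#'   works well for oscillatory systems.
#' @return integer 0/1 vector, same length as `x`.
#' @examples
#' set.seed(1)
#' binarize_km3(c(0, 1, 0, 0.7, 0, 0.45, 0, 0.3), depth = 3)
#' @export
binarize_km3 <- function(x, depth = 3L) {
  x <- check_binarizable(x)
  depth <- as.integer(depth)
  if (depth < 1L) stop("depth must be >= 1")
  vals <- x
  for (d in depth:1) {
    if (length(unique(vals)) < 2L)
      stop_degenerate("values collapsed to a single cluster mean")
    cl <- lloyd_1d(vals, 2L^d)
    if (d == 1L) {
      if (cl$k < 2L)
        stop_degenerate("final 2-means pass degenerated to one cluster")
      return(as.integer(cl$centers[cl$assign] == max(cl$centers)))
    }
    vals <- cl$centers[cl$assign]
  }
}

#' Binarize a whole time series
#'
#' Applies the chosen per-species binarizer column-wise and assembles the
#' per-time-point bit vectors in time order.
#'
#' @param ts a [time_series()].
#' @param method `"km1"`, `"km3"` or `"basca"`.
#' @param depth clustering depth for `"km3"`.
#' @return a `binary_trajectory`: 0/1 integer matrix with one row per time
#'   point and the species names as columns, class `binary_trajectory`.
#' @export
binarize_timeseries <- function(ts, method = c("km3", "km1", "basca"),
                                depth = 3L) {
  stopifnot(inherits(ts, "time_series"))
  method <- match.arg(method)
  n <- ncol(ts$values)
  bits <- matrix(0L, nrow(ts$values), n, dimnames = list(NULL, ts$species))
  for (j in seq_len(n)) {
    bits[, j] <- tryCatch(
      switch(method,
             km1 = binarize_km1(ts$values[, j]),
             km3 = binarize_km3(ts$values[, j], depth = depth),
             basca = binarize_basca(ts$values[, j])),
      boolinfer_degenerate_error = function(e)
        stop_degenerate(sprintf("species '%s': %s",
                                ts$species[j], conditionMessage(e))))
  }
  binary_trajectory(bits)
}

#' Construct a binary trajectory
#'
#' @param states 0/1 matrix, one row per time point, one column per species.
#' @return the matrix with class `binary_trajectory`.
#' @export
binary_trajectory <- function(states) {
  states <- as.matrix(states)
  storage.mode(states) <- "integer"
  if (!all(states %in% c(0L, 1L))) stop("states must be 0/1")
  if (nrow(states) < 1L) stop("empty trajectory")
  structure(states, class = c("binary_trajectory", "matrix", "array"))
}

#' @export
print.binary_trajectory <- function(x, ...) {
  cat(sprintf("binary_trajectory: %d states x %d species\n",
              nrow(x), ncol(x)))
  cat(paste0("  ", apply(unclass(x), 1, paste, collapse = ""),
             collapse = "\n"), "\n")
  invisible(x)
}

#' Remove false steady-state redundancy from a binary trajectory
#'
#' Finely sampled data produce long runs of identical consecutive binary
#' states that falsely suggest steady states.  Every maximal run of identical
#' states is collapsed to a single state, except a run that ends at the final
#' time point: that one is collapsed to exactly two states, because only a
#' trailing pair of equal states is evidence of a true point attractor.
#' Idempotent.
#'
#' @param b a `binary_trajectory`.
#' @return a reduced `binary_trajectory` (a subsequence of the input rows).
#' @examples
#' b <- binary_trajectory(rbind(c(0, 0), c(0, 0), c(1, 0),
#'                              c(1, 1), c(1, 1), c(1, 1)))
#' remove_redundancy(b)
#' @export
remove_redundancy <- function(b) {
  stopifnot(inherits(b, "binary_trajectory"))
  key <- apply(unclass(b), 1, paste, collapse = "")
  r <- rle(key)
  first_idx <- cumsum(c(1L, head(r$lengths, -1L)))
  keep <- first_idx
  last_run_len <- r$lengths[length(r$lengths)]
  if (last_run_len >= 2L)  # retain the steady-state pair
    keep <- c(keep, first_idx[length(first_idx)] + 1L)
  binary_trajectory(b[sort(keep), , drop = FALSE])
}
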