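# Independent oracles used across the suite.  These deliberately use brute
# force / exhaustive enumeration and stay independent of the package's own
# algorithms.

# Optimal 1-D k-clustering by exhaustive search over contiguous partitions of
# the sorted values (the 1-D WSS optimum is always contiguous in sorted
# order).  Returns per-element cluster means.
oracle_kmeans_1d <- function(x, k) {
  ord <- order(x)
  v <- x[ord]
  N <- length(v)
  k <- min(k, length(unique(v)))
  if (k == 1L) return(rep(mean(x), N))
  best_wss <- Inf
  best_means <- NULL
  for (cuts in utils::combn(N - 1L, k - 1L, simplify = FALSE)) {
    bounds <- c(0L, cuts, N)
    means <- numeric(N)
    wss <- 0
    for (s in seq_len(k)) {
      seg <- (bounds[s] + 1L):bounds[s + 1L]
      m <- mean(v[seg])
      means[seg] <- m
      wss <- wss + sum((v[seg] - m)^2)
    }
    if (wss < best_wss - 1e-12) {
      best_wss <- wss
      best_means <- means
    }
  }
  out <- numeric(N)
  out[ord] <- best_means
  out
}

# Exhaustive-oracle KM-1: optimal 2-means, higher cluster -> 1.
oracle_km1 <- function(x) {
  m <- oracle_kmeans_1d(x, 2L)
  as.integer(m == max(m))
}

# Exhaustive-oracle KM-3: iterative replacement by optimal cluster means.
oracle_km3 <- function(x, depth) {
  vals <- x
  for (d in depth:1) {
    if (d == 1L) return(oracle_km1(vals))
    vals <- oracle_kmeans_1d(vals, 2L^d)
  }
}

# Exhaustive optimal ascending step function: minimum SSE over all break
# sets of the sorted vector, for a given discontinuity count.
oracle_step_sse <- function(v, n_disc) {
  N <- length(v)
  best <- Inf
  for (cuts in utils::combn(N - 1L, n_disc, simplify = FALSE)) {
    bounds <- c(0L, cuts, N)
    sse <- 0
    for (s in seq_len(n_disc + 1L)) {
      seg <- v[(bounds[s] + 1L):bounds[s + 1L]]
      sse <- sse + sum((seg - mean(seg))^2)
    }
    if (sse < best) best <- sse
  }
  best
}

# Reference R evaluator for synchronous simulation (oracle for the C++
# kernel): evaluates each truth table by direct bit indexing.
oracle_sync_step <- function(net, state) {
  vapply(net$functions, function(f) {
    k <- length(f$regulators)
    idx <- if (k == 0L) 0L else sum(state[f$regulators] * 2^((k - 1):0))
    f$truth_table[idx + 1L]
  }, integer(1))
}

oracle_sync_traj <- function(net, start, steps) {
  out <- matrix(0L, steps + 1L, net$n)
  out[1L, ] <- as.integer(start)
  for (t in seq_len(steps))
    out[t + 1L, ] <- oracle_sync_step(net, out[t, ])
  out
}

oracle_traj_error <- function(net, b) {
  sim <- oracle_sync_traj(net, b[1L, ], nrow(b) - 1L)
  sum(sim[-1L, ] != unclass(b)[-1L, ]) / (ncol(b) * (nrow(b) - 1L))
}

# Brute-force minimum pdBf error over all regulator subsets of exactly size
# k (weighted by observation counts).
oracle_min_pdbf_error <- function(b, target, k) {
  n <- ncol(b)
  src <- unclass(b)[-nrow(b), , drop = FALSE]
  y <- unclass(b)[-1L, target]
  subs <- if (k == 0L) list(integer(0)) else
    utils::combn(n, k, simplify = FALSE)
  min(vapply(subs, function(regs) {
    key <- apply(src[, regs, drop = FALSE], 1, paste, collapse = "")
    sum(vapply(unique(key), function(p) {
      yy <- y[key == p]
      min(sum(yy == 1L), sum(yy == 0L))
    }, numeric(1)))
  }, numeric(1)))
}

# random reduced binary trajectory fixture (consecutive duplicates removed)
random_btraj <- function(T_, n) {
  m <- matrix(sample(0:1, T_ * n, replace = TRUE), T_, n)
  remove_redundancy(binary_trajectory(m))
}

toy_spec_small <- function() toy_model_spec(n_points = 61L)
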