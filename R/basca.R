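# BASC A: binarization via optimal ascending step functions.
#
# The sorted measurement vector is itself an ascending step function with
# N - 1 discontinuities.  For every target count of discontinuities
# j = 1 .. N-2 a dynamic program finds the ascending step function (segment
# levels = segment means) minimizing the quadratic distance to the sorted
# vector.  Each optimal step function contributes its *strongest*
# discontinuity; the final binarization threshold is the median of those
# candidate thresholds.
#
# Strongest-discontinuity score at a break after sorted position p:
#   jump(p)  = mean(v[(p+1):N]) - mean(v[1:p])      (height of the split)
#   err(p)   = within-group SSE of the two sides    (approximation error)
#   score(p) = jump(p) / max(err(p), 1e-12)
# Ties are broken toward the larger jump, then the smaller index.  The
# candidate threshold at p is the midpoint (v[p] + v[p+1]) / 2.

# Segment SSE cost matrix and DP over break positions.  Returns, for each
# number of segments m = 1..N, the optimal total SSE and the break set.
basca_dp <- function(v) {
  N <- length(v)
  cs <- cumsum(v)
  cs2 <- cumsum(v^2)
  seg_cost <- function(i, j) {  # SSE of v[i..j] about its mean (vector in i)
    s <- cs[j] - c(0, cs)[i]
    s2 <- cs2[j] - c(0, cs2)[i]
    s2 - s^2 / (j - i + 1)
  }
  # E[m, j]: min SSE of splitting v[1..j] into m segments; P[m, j]: last break
  E <- matrix(Inf, N, N)
  P <- matrix(0L, N, N)
  E[1, ] <- vapply(seq_len(N), function(j) seg_cost(1L, j)[1], numeric(1))
  for (m in 2:N) {
    for (j in m:N) {
      cuts <- (m - 1):(j - 1)           # last segment is v[(cut+1)..j]
      tot <- E[m - 1, cuts] + seg_cost(cuts + 1L, j)
      best <- which.min(tot)
      E[m, j] <- tot[best]
      P[m, j] <- cuts[best]
    }
  }
  breaks_for <- function(m) {       # break positions (segment ends), sorted
    out <- integer(m - 1L)
    j <- N
    for (s in m:2) {
      out[s - 1L] <- P[s, j]
      j <- P[s, j]
    }
    out
  }
  list(E = E[, N], breaks_for = breaks_for)
}

basca_break_scores <- function(v) {
  N <- length(v)
  cs <- cumsum(v)
  cs2 <- cumsum(v^2)
  p <- seq_len(N - 1L)
  lo_n <- p
  hi_n <- N - p
  lo_mean <- cs[p] / lo_n
  hi_mean <- (cs[N] - cs[p]) / hi_n
  jump <- hi_mean - lo_mean
  err <- (cs2[p] - cs[p]^2 / lo_n) +
    ((cs2[N] - cs2[p]) - (cs[N] - cs[p])^2 / hi_n)
  list(score = jump / pmax(err, 1e-12), jump = jump,
       threshold = (v[p] + v[p + 1L]) / 2)
}

#' BASC A binarization
#'
#' Deterministic binarization of one species' measurements via optimal
#' ascending step functions: a dynamic program computes, for every
#' discontinuity count from 1 to `length(x) - 2`, the ascending step function
#' closest (in quadratic distance) to the sorted data; each contributes its
#' strongest discontinuity (largest jump-to-approximation-error ratio), and
#' the final threshold is the median of the candidate thresholds (midpoints
#' of the flanking sorted values).  A value is mapped to 1 iff it exceeds the
#' threshold.
#'
#' @param x numeric vector, length >= 3, at least two distinct values.
#' @return integer 0/1 vector, same length and order as `x`.
#' @examples
#' binarize_basca(c(1, 2, 3, 10, 11, 12))
#' @export
binarize_basca <- function(x) {
  x <- check_binarizable(x, min_len = 3L)
  v <- sort(x)
  N <- length(v)
  dp <- basca_dp(v)
  sc <- basca_break_scores(v)
  thresholds <- numeric(N - 2L)
  for (j in seq_len(N - 2L)) {            # j discontinuities = j+1 segments
    brk <- dp$breaks_for(j + 1L)
    ord <- order(-sc$score[brk], -sc$jump[brk], brk)
    thresholds[j] <- sc$threshold[brk[ord[1L]]]
  }
  thr <- median(thresholds)
  as.integer(x > thr)
}
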