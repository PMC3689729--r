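# Learning Boolean networks from reduced binary trajectories.
#
# All learners scan regulator subsets by increasing size (0, 1, ..., max_k;
# lexicographic within a size) and keep only subsets of the smallest size
# achieving the method's acceptance criterion.  REVEAL consumes the
# determinized transition table; Best-Fit and Full-Fit consume the raw
# consecutive state pairs, because their error size counts exactly the
# inconsistencies that determinization would hide.

# pool consecutive state pairs of one trajectory or a list of trajectories;
# never forms a pair spanning two trajectories
transition_pairs <- function(b) {
  if (inherits(b, "binary_trajectory")) b <- list(b)
  src <- list(); dst <- list()
  for (tr in b) {
    stopifnot(inherits(tr, "binary_trajectory"))
    Tn <- nrow(tr)
    if (Tn < 2L) next
    src[[length(src) + 1L]] <- unclass(tr)[-Tn, , drop = FALSE]
    dst[[length(dst) + 1L]] <- unclass(tr)[-1L, , drop = FALSE]
  }
  if (!length(src)) stop("need at least one trajectory with >= 2 states")
  list(src = do.call(rbind, src), dst = do.call(rbind, dst))
}

#' Build a deterministic transition table from binary trajectories
#'
#' Tallies all consecutive state pairs; when a source state was observed with
#' several distinct successors, only the most frequent successor is kept
#' (ties: the successor with the smallest integer encoding).  The result maps
#' each observed state to exactly one successor, as required by REVEAL.
#'
#' @param b a `binary_trajectory`, or a list of them (pairs are pooled, never
#'   spanning two trajectories).
#' @return a list of class `transition_table` with integer matrices `src` and
#'   `succ` (one row per distinct source state) and `counts`, the number of
#'   observations supporting each retained transition.
#' @export
build_transition_table <- function(b) {
  tp <- transition_pairs(b)
  n <- ncol(tp$src)
  src_key <- apply(tp$src, 1, paste, collapse = "")
  dst_key <- apply(tp$dst, 1, paste, collapse = "")
  pair_key <- paste(src_key, dst_key)
  cnt <- table(pair_key)
  first <- match(names(cnt), pair_key)
  ps <- src_key[first]
  pd <- dst_key[first]
  pc <- as.integer(cnt)
  keep <- integer(0)
  for (s in unique(ps)) {
    cand <- which(ps == s)
    best <- cand[pc[cand] == max(pc[cand])]
    if (length(best) > 1L) {
      enc <- vapply(pd[best],
                    function(k) encode_state(as.integer(strsplit(k, "")[[1]])),
                    numeric(1))
      best <- best[which.min(enc)]
    }
    keep <- c(keep, best)
  }
  key_to_mat <- function(keys)
    do.call(rbind, lapply(keys,
                          function(k) as.integer(strsplit(k, "")[[1]])))
  structure(list(src = key_to_mat(ps[keep]), succ = key_to_mat(pd[keep]),
                 counts = pc[keep], n = n),
            class = "transition_table")
}

#' Shannon entropy of a bit vector (base 2)
#'
#' @param x 0/1 vector.
#' @return entropy in bits; `0 * log(0)` is treated as 0.
#' @examples
#' entropy_bits(c(0, 1, 0, 1))  # 1
#' @export
entropy_bits <- function(x) {
  p <- tabulate(x + 1L, 2L) / length(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Mutual information between joint bit columns and a bit vector (base 2)
#'
#' `M(X; Y) = H(X) + H(Y) - H(X, Y)` on the empirical joint distribution.
#'
#' @param x_cols 0/1 matrix (columns are jointly considered variables) or a
#'   vector; zero columns give `M = 0` for non-degenerate `y` only when
#'   `H(y) = 0`.
#' @param y_col 0/1 vector with `nrow(x_cols)` entries.
#' @return mutual information in bits (>= 0 up to rounding).
#' @export
mutual_information <- function(x_cols, y_col) {
  x_cols <- as.matrix(x_cols)
  stopifnot(nrow(x_cols) == length(y_col))
  hx <- entropy_key(apply(x_cols, 1, paste, collapse = ""))
  hy <- entropy_bits(y_col)
  hxy <- entropy_key(paste(apply(x_cols, 1, paste, collapse = ""), y_col))
  hx + hy - hxy
}

entropy_key <- function(keys) {
  p <- as.numeric(table(keys)) / length(keys)
  -sum(p * log2(p))
}

# pattern index (0-based) of each row of `mat` projected on `regs`;
# MSB = first regulator
pattern_index <- function(mat, regs) {
  k <- length(regs)
  if (k == 0L) return(rep(0L, nrow(mat)))
  as.integer(mat[, regs, drop = FALSE] %*% 2^((k - 1):0))
}

subsets_of_size <- function(n, k) {
  if (k == 0L) return(list(integer(0)))
  if (k > n) return(list())
  cmb <- utils::combn(n, k)
  lapply(seq_len(ncol(cmb)), function(j) cmb[, j])
}

MAX_CANDIDATE_SUBSETS <- 1000L

cap_candidates <- function(cands, what) {
  if (length(cands) > MAX_CANDIDATE_SUBSETS) {
    warning(sprintf("%s: %d qualifying subsets; retaining the first %d",
                    what, length(cands), MAX_CANDIDATE_SUBSETS))
    cands <- cands[seq_len(MAX_CANDIDATE_SUBSETS)]
  }
  cands
}

#' Learn candidate functions for one species with REVEAL
#'
#' Scans regulator subsets by increasing size.  A subset qualifies when the
#' mutual information between its joint state columns and the target's
#' next-state column (over the determinized transition table) equals the
#' target's entropy, *and* the subset is complete: all `2^k` of its input
#' patterns occur among the table's source states.  All qualifying subsets of
#' the smallest qualifying size are returned, each with the unique consistent
#' truth table.  The empty list is a valid outcome.
#'
#' @param tt a [build_transition_table()] result.
#' @param target 1-based species index.
#' @param max_k maximum in-degree (default 3).
#' @return list of [boolean_function()] (possibly empty).
#' @export
learn_reveal <- function(tt, target, max_k = 3L) {
  stopifnot(inherits(tt, "transition_table"))
  y <- tt$succ[, target]
  hy <- entropy_bits(y)
  for (k in 0:min(max_k, tt$n)) {
    found <- list()
    for (regs in subsets_of_size(tt$n, k)) {
      idx <- pattern_index(tt$src, regs)
      if (length(unique(idx)) < 2^k) next      # incomplete: discard
      mi <- if (k == 0L) 0 else mutual_information(
        tt$src[, regs, drop = FALSE], y)
      if (abs(mi - hy) > 1e-9) next
      tab <- integer(2^k)
      tab[idx + 1L] <- y                        # deterministic since M = H
      found[[length(found) + 1L]] <-
        boolean_function(target, regs, tab)
    }
    if (length(found))
      return(cap_candidates(found, sprintf("REVEAL target %d", target)))
  }
  list()
}

#' Build a partially defined Boolean function (pdBf)
#'
#' Projects the source state of every consecutive pair onto the regulator
#' set; the pattern is added to the true (false) examples when the target's
#' bit in the successor state is 1 (0), with observation counts.  The error
#' size is the total weight of inconsistencies: for each pattern occurring in
#' both sets, the smaller of the two counts.
#'
#' @param b a `binary_trajectory` or list of them.
#' @param target 1-based species index.
#' @param regulators integer vector of regulator indices (possibly empty).
#' @param weighted if `FALSE`, each distinct (pattern, output) pair counts
#'   once regardless of multiplicity.
#' @return list of class `pdbf` with `true_counts` and `false_counts`
#'   (length `2^k` tallies by pattern index, MSB = first regulator) and
#'   `error_size`.
#' @export
build_pdbf <- function(b, target, regulators, weighted = TRUE) {
  tp <- transition_pairs(b)
  build_pdbf_pairs(tp, target, regulators, weighted)
}

build_pdbf_pairs <- function(tp, target, regulators, weighted = TRUE) {
  regulators <- as.integer(regulators)
  k <- length(regulators)
  idx <- pattern_index(tp$src, regulators)
  y <- tp$dst[, target]
  t1 <- tabulate(idx[y == 1L] + 1L, 2^k)
  t0 <- tabulate(idx[y == 0L] + 1L, 2^k)
  if (!weighted) {
    t1 <- pmin(t1, 1L)
    t0 <- pmin(t0, 1L)
  }
  structure(list(target = target, regulators = regulators,
                 true_counts = t1, false_counts = t0,
                 error_size = sum(pmin(t1, t0))),
            class = "pdbf")
}

pdbf_to_function <- function(p) {
  k <- length(p$regulators)
  tab <- integer(2^k)
  for (i in seq_len(2^k)) {
    n1 <- p$true_counts[i]; n0 <- p$false_counts[i]
    tab[i] <- if (n1 == 0L && n0 == 0L) {
      sample(0:1, 1L)                     # undefined entry: random fill
    } else if (n1 > n0) 1L else 0L        # majority; ties -> 0
  }
  boolean_function(p$target, p$regulators, tab)
}

learn_fit <- function(b, target, max_k, require_zero, weighted, what) {
  tp <- transition_pairs(b)
  n <- ncol(tp$src)
  best_err <- Inf
  best_size <- NA_integer_
  best <- list()
  for (k in 0:min(max_k, n)) {
    for (regs in subsets_of_size(n, k)) {
      p <- build_pdbf_pairs(tp, target, regs, weighted)
      if (require_zero && p$error_size > 0L) next
      if (p$error_size < best_err) {
        best_err <- p$error_size
        best_size <- k
        best <- list(p)
      } else if (p$error_size == best_err && k == best_size) {
        best[[length(best) + 1L]] <- p
      }
    }
  }
  if (!length(best)) return(list())
  best <- cap_candidates(best, what)
  lapply(best, pdbf_to_function)
}

#' Learn candidate functions for one species with the Best-Fit extension
#'
#' Computes the pdBf error size of every regulator subset up to `max_k`,
#' keeps the subsets attaining the minimum error at the smallest size where
#' that minimum is achieved, resolves conflicting patterns by the majority
#' class (ties to 0), and fills undefined truth-table entries with random
#' coin flips (R's global RNG).
#'
#' @inheritParams build_pdbf
#' @param max_k maximum in-degree (default 3).
#' @return list of [boolean_function()] (non-empty: some function always
#'   fits with finite error).
#' @export
learn_bestfit <- function(b, target, max_k = 3L, weighted = TRUE) {
  learn_fit(b, target, max_k, require_zero = FALSE, weighted = weighted,
            what = sprintf("BESTFIT target %d", target))
}

#' Learn candidate functions for one species with Full-Fit enumeration
#'
#' Identical scan to [learn_bestfit()], but only zero-error (fully
#' consistent) subsets are accepted; if every subset up to `max_k` has an
#' inconsistency the empty list is returned, in which case no network exists
#' for this binarization.
#'
#' @inheritParams learn_bestfit
#' @return list of [boolean_function()] (possibly empty).
#' @export
learn_fullfit <- function(b, target, max_k = 3L, weighted = TRUE) {
  learn_fit(b, target, max_k, require_zero = TRUE, weighted = weighted,
            what = sprintf("FULLFIT target %d", target))
}

#' Learn candidate function lists for every species
#'
#' With a single trajectory this simply applies the chosen learner per
#' species.  With a *list* of trajectories (independent experiments), the
#' fit-based learners consume all consecutive pairs pooled (no pair ever
#' spans two experiments), while REVEAL first uses the transition table of
#' the pooled pairs; any species left without a qualifying subset there
#' falls back to the union of its single-trajectory REVEAL candidates, since
#' determinizing across disagreeing experiments can destroy the exact
#' mutual-information identity REVEAL demands (see the methods vignette).
#'
#' @param b a `binary_trajectory` or list of them.
#' @param method `"reveal"`, `"bestfit"` or `"fullfit"`.
#' @param max_k maximum in-degree.
#' @return list (one element per species) of candidate-function lists.
#' @export
learn_candidates <- function(b, method = c("bestfit", "reveal", "fullfit"),
                             max_k = 3L) {
  method <- match.arg(method)
  multi <- !inherits(b, "binary_trajectory")
  n <- if (multi) ncol(b[[1]]) else ncol(b)
  if (method != "reveal")
    return(lapply(seq_len(n), function(i)
      switch(method,
             bestfit = learn_bestfit(b, i, max_k),
             fullfit = learn_fullfit(b, i, max_k))))
  tt <- build_transition_table(b)
  cands <- lapply(seq_len(n), function(i) learn_reveal(tt, i, max_k))
  if (multi && length(b) > 1L) {
    missing <- which(vapply(cands, length, integer(1)) == 0L)
    if (length(missing)) {
      per_set <- lapply(b, build_transition_table)
      for (i in missing) {
        pool <- list()
        for (pt in per_set)
          pool <- c(pool, learn_reveal(pt, i, max_k))
        cands[[i]] <- dedupe_functions(pool)
      }
    }
  }
  cands
}

dedupe_functions <- function(fs) {
  if (!length(fs)) return(fs)
  keys <- vapply(fs, function(f)
    paste(paste(f$regulators, collapse = ","),
          paste(f$truth_table, collapse = "")), character(1))
  fs[!duplicated(keys)]
}

#' Sample one Boolean network from per-species candidate pools
#'
#' Independently and uniformly selects one candidate function per species.
#'
#' @param candidates list of candidate-function lists, one per species (as
#'   returned by [learn_candidates()]).
#' @param species optional species names.
#' @return a [boolean_network()].
#' @export
sample_network <- function(candidates, species = NULL) {
  empty <- which(vapply(candidates, length, integer(1)) == 0L)
  if (length(empty))
    stop_no_network(sprintf(
      "no candidate function for species %s; no network can be formed",
      paste(empty, collapse = ", ")))
  funs <- lapply(candidates, function(fs) fs[[sample.int(length(fs), 1L)]])
  boolean_network(funs, species = species)
}
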