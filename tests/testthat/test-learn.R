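traj <- function(...) binary_trajectory(do.call(rbind, list(...)))

test_that("build_transition_table determinizes by count with encoding tie-break", {
  # 00 -> 01 twice, 00 -> 11 once: majority wins
  b <- traj(c(0, 0), c(0, 1), c(0, 0), c(0, 1), c(0, 0), c(1, 1))
  tt <- build_transition_table(b)
  row00 <- which(apply(tt$src, 1, paste, collapse = "") == "00")
  expect_identical(tt$succ[row00, ], c(0L, 1L))
  # tie: 00 -> 01 once, 00 -> 11 once; smaller integer encoding kept
  b2 <- traj(c(0, 0), c(0, 1), c(0, 0), c(1, 1))
  tt2 <- build_transition_table(b2)
  row00 <- which(apply(tt2$src, 1, paste, collapse = "") == "00")
  expect_identical(tt2$succ[row00, ], c(0L, 1L))
  # already deterministic trajectory: exactly its distinct pairs
  b3 <- traj(c(0, 0), c(1, 0), c(1, 1), c(0, 0), c(1, 0))
  tt3 <- build_transition_table(b3)
  expect_identical(nrow(tt3$src), 3L)
  # no duplicate source states, ever
  set.seed(201)
  for (i in 1:20) {
    tt4 <- build_transition_table(random_btraj(15, 3))
    expect_false(anyDuplicated(apply(tt4$src, 1, paste, collapse = "")) > 0)
  }
})

test_that("entropy and mutual information match closed forms", {
  expect_equal(entropy_bits(c(0, 1, 0, 1)), 1.0)
  expect_equal(entropy_bits(c(0, 0, 0, 0)), 0.0)
  expect_equal(entropy_bits(c(0, 0, 0, 1)),
               -0.75 * log2(0.75) - 0.25 * log2(0.25))
  expect_equal(mutual_information(cbind(c(0, 0, 1, 1)), c(0, 1, 0, 1)), 0.0)
  expect_equal(mutual_information(cbind(c(0, 0, 1, 1)), c(1, 1, 0, 0)), 1.0)
})

test_that("mutual information is bounded, symmetric and M(x;x) = H(x)", {
  set.seed(202)
  for (i in 1:50) {
    x <- sample(0:1, 12, replace = TRUE)
    y <- sample(0:1, 12, replace = TRUE)
    m <- mutual_information(cbind(x), y)
    expect_gte(m, -1e-9)
    expect_lte(m, min(entropy_bits(x), entropy_bits(y)) + 1e-9)
    expect_equal(m, mutual_information(cbind(y), x), tolerance = 1e-12)
    expect_equal(mutual_information(cbind(x), x), entropy_bits(x))
  }
})

test_that("learn_reveal recovers the 2-gene toggle from its full table", {
  # x1' = x2, x2' = NOT x1; full 4-row table from the 4-cycle
  b <- traj(c(0, 0), c(0, 1), c(1, 1), c(1, 0), c(0, 0))
  tt <- build_transition_table(b)
  for (target in 1:2) {
    fs <- learn_reveal(tt, target, max_k = 3)
    expect_length(fs, 1L)
    expect_length(fs[[1]]$regulators, 1L)
  }
  f1 <- learn_reveal(tt, 1, 3)[[1]]
  expect_identical(f1$regulators, 2L)
  expect_identical(f1$truth_table, c(0L, 1L))       # x1' = x2
  f2 <- learn_reveal(tt, 2, 3)[[1]]
  expect_identical(f2$regulators, 1L)
  expect_identical(f2$truth_table, c(1L, 0L))       # x2' = NOT x1
})

test_that("learn_reveal returns the constant function for zero-entropy targets", {
  b <- traj(c(0, 0), c(1, 0), c(0, 0), c(1, 0))
  tt <- build_transition_table(b)
  fs <- learn_reveal(tt, 2, 3)
  expect_length(fs, 1L)
  expect_length(fs[[1]]$regulators, 0L)
  expect_identical(fs[[1]]$truth_table, 0L)
})

test_that("learn_reveal discards incomplete subsets", {
  # target 3 = XOR of species 1,2 over only 3 of the 4 patterns; no single
  # species explains it, and the pair is incomplete -> empty result
  src <- rbind(c(0, 0, 0), c(0, 1, 0), c(1, 0, 1))
  succ <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 0, 1))
  blist <- lapply(1:3, function(i)
    binary_trajectory(rbind(src[i, ], succ[i, ])))
  tt <- build_transition_table(blist)
  expect_identical(nrow(tt$src), 3L)
  fs <- learn_reveal(tt, 3, max_k = 2)
  expect_length(fs, 0L)
})

test_that("build_pdbf counts true/false examples and the error size", {
  # source pattern 01 seen with target-2 successors 1, 0, 0: the pattern
  # lands in both example sets; the error contribution is the smaller count
  blist <- list(traj(c(0, 1), c(1, 1)), traj(c(0, 1), c(0, 0)),
                traj(c(0, 1), c(1, 0)))
  p <- build_pdbf(blist, target = 2, regulators = c(1L, 2L))
  expect_identical(p$true_counts[2L], 1L)   # pattern 01 -> index 2
  expect_identical(p$false_counts[2L], 2L)
  expect_identical(p$error_size, 1L)
  # unweighted variant counts distinct (pattern, output) pairs once
  pu <- build_pdbf(blist, 2, c(1L, 2L), weighted = FALSE)
  expect_identical(pu$error_size, 1L)
  expect_identical(pu$false_counts[2L], 1L)
  # fully consistent data: empty intersection
  b2 <- traj(c(0, 0), c(1, 1), c(0, 0), c(1, 1))
  p2 <- build_pdbf(b2, 1, 1L)
  expect_identical(p2$error_size, 0L)
  # empty regulator set, target always 1
  b3 <- traj(c(0, 1), c(1, 1), c(0, 1))
  p3 <- build_pdbf(b3, 2, integer(0))
  expect_identical(p3$true_counts, 2L)
  expect_identical(p3$false_counts, 0L)
})

test_that("learn_bestfit finds the exact function on consistent complete data", {
  # x3' = x1 AND x2, all 4 patterns covered
  src <- rbind(c(0, 0, 0), c(0, 1, 0), c(1, 0, 0), c(1, 1, 0))
  blist <- lapply(1:4, function(i) {
    s2 <- src[i, ]; s2[3] <- as.integer(src[i, 1] & src[i, 2])
    binary_trajectory(rbind(src[i, ], s2))
  })
  set.seed(203)
  fs <- learn_bestfit(blist, 3, max_k = 3)
  expect_length(fs, 1L)
  expect_identical(fs[[1]]$regulators, c(1L, 2L))
  expect_identical(fs[[1]]$truth_table, c(0L, 0L, 0L, 1L))
})

test_that("learn_bestfit resolves conflicts by majority and reports min error", {
  # pattern x1=0 seen twice -> 0, once -> 1 for target 2
  blist <- list(traj(c(0, 0), c(0, 0)), traj(c(0, 1), c(0, 0)),
                traj(c(0, 0), c(0, 1)))
  set.seed(204)
  fs <- learn_bestfit(blist, 2, max_k = 0)
  expect_length(fs, 1L)
  expect_identical(fs[[1]]$truth_table, 0L)   # majority class 0
  p <- build_pdbf(blist, 2, integer(0))
  expect_identical(p$error_size, 1L)
})

test_that("learn_bestfit error equals the brute-force subset minimum", {
  set.seed(205)
  for (i in 1:15) {
    b <- random_btraj(12, 4)
    if (nrow(b) < 3) next
    target <- sample(4, 1)
    fs <- learn_bestfit(b, target, max_k = 2)
    k <- length(fs[[1]]$regulators)
    err <- build_pdbf(b, target, fs[[1]]$regulators)$error_size
    # returned error equals the minimum over all subsets of size <= 2 ...
    best_all <- min(vapply(0:2, function(kk)
      oracle_min_pdbf_error(b, target, kk), numeric(1)))
    expect_identical(err, as.integer(best_all))
    # ... and no smaller subset achieves it (smallest-size rule)
    if (k > 0) {
      smaller <- min(vapply(0:(k - 1), function(kk)
        oracle_min_pdbf_error(b, target, kk), numeric(1)))
      expect_gt(smaller, best_all)
    }
  }
})

test_that("learn_fullfit accepts only zero-error subsets", {
  # constant target
  b <- traj(c(0, 0), c(1, 0), c(0, 0), c(1, 0))
  set.seed(206)
  fs <- learn_fullfit(b, 2, max_k = 3)
  expect_length(fs, 1L)
  expect_identical(fs[[1]]$truth_table, 0L)
  # engineered conflict on every subset: same full state to both outcomes
  blist <- list(traj(c(0, 1), c(1, 1)), traj(c(0, 1), c(0, 1)))
  expect_length(learn_fullfit(blist, 1, max_k = 3), 0L)
  # consistent data: fullfit and bestfit agree on accepted regulator sets
  set.seed(207)
  fx <- random_network_fixture(3, 2)
  btr <- fx$trajectories
  for (target in 1:3) {
    set.seed(300 + target); a <- learn_fullfit(btr, target, max_k = 3)
    set.seed(300 + target); c <- learn_bestfit(btr, target, max_k = 3)
    expect_identical(lapply(a, `[[`, "regulators"),
                     lapply(c, `[[`, "regulators"))
  }
})

test_that("sample_network samples candidates uniformly and errors on empty pools", {
  f1a <- boolean_function(1, integer(0), 0L)
  f1b <- boolean_function(1, integer(0), 1L)
  f2 <- boolean_function(2, 1L, c(0L, 1L))
  cands <- list(list(f1a, f1b), list(f2))
  set.seed(208)
  picks <- replicate(1000, sample_network(cands)$functions[[1]]$truth_table)
  expect_gt(mean(picks), 0.45)
  expect_lt(mean(picks), 0.55)
  expect_error(sample_network(list(list(f1a), list())),
               class = "boolinfer_no_network_error")
  one <- sample_network(list(list(f1a), list(f2)))
  expect_identical(one$functions[[2]]$regulators, 1L)
})

test_that("all three learners recover generators from complete transition data", {
  set.seed(209)
  for (i in 1:20) {
    fx <- random_network_fixture(sample(2:4, 1), 2)
    n <- fx$network$n
    for (method in c("reveal", "bestfit", "fullfit")) {
      cands <- learn_candidates(fx$trajectories, method, max_k = 3)
      expect_true(all(vapply(cands, length, integer(1)) > 0),
                  label = sprintf("%s candidates (net %d)", method, i))
      net <- sample_network(cands)
      for (b in fx$trajectories)
        expect_equal(trajectory_error(net, b), 0,
                     label = sprintf("%s recovery error (net %d)", method, i))
      # learned in-degree never exceeds the cap
      for (cl in cands) for (f in cl)
        expect_lte(length(f$regulators), 3L)
    }
  }
})
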