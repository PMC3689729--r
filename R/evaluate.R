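#' Normalized Hamming trajectory error of a network against binary data
#'
#' Synchronously simulates the network from the first state of the reduced
#' binary trajectory for `T - 1` steps and counts the bits that differ from
#' the data over states `2..T`, normalized by `n * (T - 1)`.  0 means the
#' network reproduces the reduced data exactly; 1 means every bit after the
#' first state is wrong.
#'
#' @param net a [boolean_network()].
#' @param b a redundancy-reduced `binary_trajectory` with >= 2 states.
#' @return error in \[0, 1\].
#' @export
trajectory_error <- function(net, b) {
  stopifnot(inherits(net, "boolean_network"),
            inherits(b, "binary_trajectory"))
  if (ncol(b) != net$n)
    stop("trajectory width does not match the network's species count")
  if (nrow(b) < 2L)
    stop("trajectory error needs at least 2 states")
  cp <- net_to_cpp(net)
  .traj_error_cpp(cp$regs, cp$tts, unclass(b))
}

#' Number of distinct synchronous trajectories among networks
#'
#' All networks are simulated from the same start state for the same number
#' of steps; the count of distinct trajectories is returned.  A value of 1
#' means every network captures the same dynamics (without necessarily being
#' the same network).
#'
#' @param nets non-empty list of [boolean_network()].
#' @param reference_start 0/1 start state.
#' @param steps synchronous steps.
#' @return integer count (<= `length(nets)`).
#' @export
uniqueness_count <- function(nets, reference_start, steps) {
  stopifnot(length(nets) >= 1L)
  keys <- vapply(nets, function(net) {
    tr <- simulate_sync(net, reference_start, steps)
    paste(unclass(tr), collapse = "")
  }, character(1))
  length(unique(keys))
}

# sample `samples` networks from candidate pools and score them against one
# or more reduced trajectories (mean error), caching repeated candidate
# combinations.  Returns the best network, its error, and the number of
# networks scored until the best was first reached.
sample_and_score <- function(candidates, bmats, samples, species = NULL) {
  cps <- lapply(candidates, function(fs) lapply(fs, function(f)
    list(reg = f$regulators - 1L, tt = f$truth_table)))
  sizes <- vapply(candidates, length, integer(1))
  raw <- lapply(bmats, unclass)
  cache <- new.env(parent = emptyenv(), hash = TRUE)
  best_err <- Inf; best_choice <- NULL; best_at <- NA_integer_
  for (j in seq_len(samples)) {
    choice <- vapply(sizes, function(m) sample.int(m, 1L), integer(1))
    key <- paste(choice, collapse = ".")
    err <- cache[[key]]
    if (is.null(err)) {
      regs <- lapply(seq_along(choice),
                     function(i) cps[[i]][[choice[i]]]$reg)
      tts <- lapply(seq_along(choice),
                    function(i) cps[[i]][[choice[i]]]$tt)
      err <- mean(vapply(raw, function(m)
        .traj_error_cpp(regs, tts, m), numeric(1)))
      cache[[key]] <- err
    }
    if (err < best_err) {
      best_err <- err
      best_choice <- choice
      best_at <- j
    }
    if (best_err == 0) break
  }
  net <- boolean_network(
    lapply(seq_along(best_choice),
           function(i) candidates[[i]][[best_choice[i]]]),
    species = species)
  list(network = net, error = best_err, scored = j, best_at = best_at)
}

#' Iterated search for minimum-error Boolean networks
#'
#' Implements the full inference loop: repeatedly binarize the time series,
#' remove redundancy, learn per-species candidate functions, sample
#' `samples` networks from the candidate pools and score each against the
#' binarized data with [trajectory_error()].  One scored network counts as
#' one iteration; a search ends after `max_iterations` iterations or as soon
#' as a zero-error network is found (0 is the best possible value).  The
#' whole procedure is repeated for `searches` independent searches.
#'
#' With a stochastic binarizer (`km1`, `km3`) every round re-binarizes the
#' data, so different rounds explore different binary trajectories; the
#' reported error of a network is always measured against the binarization
#' it was learned from.
#'
#' @param ts a [time_series()].
#' @param bin_method `"km1"`, `"km3"` or `"basca"`.
#' @param learn_method `"reveal"`, `"bestfit"` or `"fullfit"`.
#' @param searches number of independent searches (default 100).
#' @param max_iterations cap on scored networks per search (default 10000).
#' @param samples networks sampled per binarization round (default 100).
#' @param depth KM-3 clustering depth.
#' @param max_k maximum in-degree.
#' @param seed optional integer; per-search substreams are derived from it.
#' @return object of class `search_result`: list with `best_error`,
#'   `networks` (per-search winners attaining the global minimum, each with
#'   its binarized trajectory), `iterations_to_best` (per successful search),
#'   `convergence` (their mean), `uniqueness`, `searches` and `seed`.  When
#'   no search produced any network (a possibility for Full-Fit) the result
#'   has `best_error = NA` and a `reason` string.
#' @export
search_min_error <- function(ts, bin_method = "km3", learn_method = "bestfit",
                             searches = 100L, max_iterations = 10000L,
                             samples = 100L, depth = 3L, max_k = 3L,
                             seed = NULL) {
  stopifnot(inherits(ts, "time_series"), searches >= 1L,
            max_iterations >= 1L, samples >= 1L)
  bin_method <- match.arg(bin_method, c("km1", "km3", "basca"))
  learn_method <- match.arg(learn_method, c("reveal", "bestfit", "fullfit"))
  deterministic_bin <- bin_method == "basca"
  max_rounds <- max(1L, ceiling(max_iterations / samples))

  per_search <- vector("list", searches)
  for (s in seq_len(searches)) {
    if (!is.null(seed)) set.seed(derive_seed(seed, s))
    iters <- 0L
    best <- list(error = Inf, network = NULL, bmat = NULL,
                 at = NA_integer_)
    bmat <- NULL
    for (round in seq_len(max_rounds)) {
      if (is.null(bmat) || !deterministic_bin)
        bmat <- remove_redundancy(
          binarize_timeseries(ts, bin_method, depth = depth))
      cands <- learn_candidates(bmat, learn_method, max_k = max_k)
      if (any(vapply(cands, length, integer(1)) == 0L)) {
        if (deterministic_bin) break  # identical candidates every round
        next
      }
      budget <- min(samples, max_iterations - iters)
      sc <- sample_and_score(cands, list(bmat), budget,
                             species = colnames(bmat))
      if (sc$error < best$error)
        best <- list(error = sc$error, network = sc$network, bmat = bmat,
                     at = iters + sc$best_at)
      iters <- iters + sc$scored
      if (best$error == 0 || iters >= max_iterations) break
    }
    per_search[[s]] <- best
  }

  errs <- vapply(per_search, `[[`, numeric(1), "error")
  ok <- is.finite(errs)
  if (!any(ok)) {
    return(structure(list(best_error = NA_real_, networks = list(),
                          iterations_to_best = integer(0),
                          convergence = NA_real_, uniqueness = NA_integer_,
                          searches = searches, seed = seed,
                          reason = paste("no search produced a network",
                                         "(every candidate pool was empty)")),
                     class = "search_result"))
  }
  best_error <- min(errs[ok])
  winners <- per_search[ok][errs[ok] == best_error]
  traj_keys <- vapply(winners, function(w) {
    tr <- simulate_sync(w$network, w$bmat[1L, ], nrow(w$bmat) - 1L)
    paste(unclass(tr), collapse = "")
  }, character(1))
  structure(list(
    best_error = best_error,
    networks = winners,
    iterations_to_best = vapply(per_search[ok], `[[`, integer(1), "at"),
    convergence = mean(vapply(per_search[ok], `[[`, integer(1), "at")),
    uniqueness = length(unique(traj_keys)),
    searches = searches, seed = seed, reason = NULL),
    class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  if (is.na(x$best_error)) {
    cat("search_result: no network learned -", x$reason, "\n")
    return(invisible(x))
  }
  cat(sprintf(paste0("search_result: min error %.4g over %d searches ",
                     "(convergence %.1f, uniqueness %d, %d winner(s))\n"),
              x$best_error, x$searches, x$convergence, x$uniqueness,
              length(x$networks)))
  invisible(x)
}

#' Leave-one-out cross-validation of one-step predictive power
#'
#' For each fold, a minimum-error network is learned from all but one
#' dataset (their binarized, reduced trajectories pooled at the
#' transition-pair level); the held-out dataset is binarized and reduced,
#' and for every pair of consecutive states the network is executed
#' synchronously for one step from the earlier state; the fraction of
#' mismatched bits against the later state is recorded.  Errors are averaged
#' over pairs, folds and repeats.  Predictive power is `1 - error`.
#'
#' @param datasets list of >= 2 [time_series()] (same species).
#' @param bin_method,learn_method,depth,max_k as in [search_min_error()].
#' @param repeats number of repetitions of the whole protocol (re-binarizing
#'   each time when the binarizer is stochastic).
#' @param samples networks sampled per fold when picking the minimum-error
#'   network.
#' @param seed optional integer seed.
#' @return object of class `crossval_report`: list with `prediction_error`,
#'   `per_fold_errors` (folds x repeats matrix), `folds`, `repeats`, `seed`.
#'   Folds where no network could be learned are `NA` and excluded from the
#'   average.
#' @export
crossval_prediction_error <- function(datasets, bin_method = "km3",
                                      learn_method = "reveal",
                                      repeats = 100L, samples = 100L,
                                      depth = 3L, max_k = 3L, seed = NULL) {
  stopifnot(length(datasets) >= 2L, repeats >= 1L)
  bin_method <- match.arg(bin_method, c("km1", "km3", "basca"))
  learn_method <- match.arg(learn_method, c("reveal", "bestfit", "fullfit"))
  nfold <- length(datasets)
  fold_err <- matrix(NA_real_, nfold, repeats)
  for (r in seq_len(repeats)) {
    if (!is.null(seed)) set.seed(derive_seed(seed, r))
    btrajs <- lapply(datasets, function(d)
      remove_redundancy(binarize_timeseries(d, bin_method, depth = depth)))
    for (f in seq_len(nfold)) {
      train <- btrajs[-f]
      cands <- learn_candidates(train, learn_method, max_k = max_k)
      if (any(vapply(cands, length, integer(1)) == 0L)) next
      sc <- sample_and_score(cands, train, samples,
                             species = colnames(btrajs[[f]]))
      held <- unclass(btrajs[[f]])
      Tn <- nrow(held)
      if (Tn < 2L) next
      cp <- net_to_cpp(sc$network)
      pred <- .step_rows_cpp(cp$regs, cp$tts, held[-Tn, , drop = FALSE])
      fold_err[f, r] <- mean(pred != held[-1L, , drop = FALSE])
    }
  }
  structure(list(prediction_error = mean(fold_err, na.rm = TRUE),
                 per_fold_errors = fold_err,
                 folds = nfold, repeats = repeats, seed = seed),
            class = "crossval_report")
}

#' @export
print.crossval_report <- function(x, ...) {
  cat(sprintf(paste0("crossval_report: prediction error %.4f ",
                     "(predictive power %.1f%%) over %d folds x %d repeats\n"),
              x$prediction_error, 100 * (1 - x$prediction_error),
              x$folds, x$repeats))
  invisible(x)
}
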