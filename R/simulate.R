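#' Synchronous simulation of a Boolean network
#'
#' All species are updated simultaneously: state `t+1` is obtained by
#' evaluating every update function on state `t`.  Deterministic.
#'
#' @param net a [boolean_network()].
#' @param start 0/1 vector of length `net$n`.
#' @param steps number of update steps (>= 0).
#' @return a `binary_trajectory` with `steps + 1` states, the first being
#'   `start`.
#' @examples
#' toggle <- boolean_network(list(boolean_function(1, 2, c(0, 1)),
#'                                boolean_function(2, 1, c(1, 0))))
#' simulate_sync(toggle, c(0, 1), 4)
#' @export
simulate_sync <- function(net, start, steps) {
  stopifnot(inherits(net, "boolean_network"),
            length(start) == net$n, steps >= 0)
  cp <- net_to_cpp(net)
  m <- .sim_sync_cpp(cp$regs, cp$tts, as.integer(start), as.integer(steps))
  colnames(m) <- net$species
  binary_trajectory(m)
}

#' Asynchronous (SSA-style) simulation of a Boolean network
#'
#' In each run, every step picks one species uniformly at random, recomputes
#' its bit from the current state and updates it immediately; a step is a
#' single-species update, not a sweep.  The returned trace averages the
#' per-step states across runs, mimicking stochastic single-molecule
#' simulation with a uniform distribution over the update functions.
#'
#' @param net a [boolean_network()].
#' @param start 0/1 start state.
#' @param steps single-update steps per run (default `10 * net$n`).
#' @param runs number of independent executions to average (default 100).
#' @return object of class `async_trace`: list with `mean_activity`
#'   (`(steps+1) x n` matrix of activities in \[0, 1\]) and `runs`.
#' @export
simulate_async <- function(net, start, steps = 10L * net$n, runs = 100L) {
  stopifnot(inherits(net, "boolean_network"),
            length(start) == net$n, steps >= 0, runs >= 1)
  n <- net$n
  acc <- matrix(0, steps + 1L, n)
  for (r in seq_len(runs)) {
    s <- as.integer(start)
    acc[1L, ] <- acc[1L, ] + s
    if (steps > 0L) {
      picks <- sample.int(n, steps, replace = TRUE)
      for (t in seq_len(steps)) {
        i <- picks[t]
        s[i] <- eval_function(net$functions[[i]], s)
        acc[t + 1L, ] <- acc[t + 1L, ] + s
      }
    }
  }
  structure(list(mean_activity = acc / runs, runs = runs,
                 species = net$species),
            class = "async_trace")
}

#' @export
print.async_trace <- function(x, ...) {
  cat(sprintf("async_trace: %d steps x %d species, averaged over %d runs\n",
              nrow(x$mean_activity) - 1L, ncol(x$mean_activity), x$runs))
  invisible(x)
}

#' Find a synchronous point attractor reachable from a start state
#'
#' Iterates the synchronous dynamics and returns the first state that equals
#' its own successor (a steady state), or `NULL` if none is reached within
#' `max_steps`.
#'
#' @param net a [boolean_network()].
#' @param start 0/1 start state.
#' @param max_steps maximum number of synchronous steps to try.
#' @return 0/1 integer vector, or `NULL`.
#' @export
find_point_attractor <- function(net, start, max_steps = 100L) {
  stopifnot(max_steps >= 1)
  traj <- simulate_sync(net, start, max_steps)
  for (t in seq_len(nrow(traj) - 1L)) {
    if (all(traj[t, ] == traj[t + 1L, ]))
      return(as.integer(traj[t, ]))
  }
  NULL
}
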