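#' Specification of the synthetic four-gene oscillatory toy network
#'
#' The toy regulatory network couples four species A, B, C, D: gene A is
#' self-regulatory (its product activates its own expression), the protein
#' products of A and B form a heterodimer that activates the expression of C,
#' the product of C activates D, and the product of D inhibits the expression
#' of both A and B.  The A/B -> C -> D -| A/B negative feedback loop, together
#' with the positive self-loop on A, yields sustained relaxation oscillations.
#'
#' The kinetic realization is *synthetic*: Hill-type activation/inhibition
#' terms with first-order decay, with rate constants chosen once so that the
#' system oscillates with 4-6 peaks per species over a 24 h window from every
#' 0/1 corner initial condition (see the methods vignette).  All rates are in
#' 1/h, thresholds in the same arbitrary concentration unit as the state.
#'
#' @param params named list of positive kinetics constants; see defaults.
#' @param init numeric(4) non-negative initial concentrations of A, B, C, D.
#' @param t_span numeric(2) integration window in hours.
#' @param n_points number of equally spaced sampling times (includes both
#'   endpoints).
#' @return an object of class `toy_model_spec`.
#' @export
toy_model_spec <- function(params = NULL,
                           init = c(0.1, 0.1, 0.1, 0.1),
                           t_span = c(0, 24),
                           n_points = 241L) {
  default <- list(
    vA = 1.2, vB = 1.0, vC = 2.0, vD = 1.5,   # max synthesis rates [1/h]
    kA = 1.0, kB = 1.0, kC = 1.5, kD = 0.8,   # first-order decay [1/h]
    KA = 0.3,  # half-activation of A's positive self-loop
    KD = 0.25, # half-inhibition threshold of D on A and B
    KC = 0.2,  # half-activation of C by the A.B heterodimer
    KH = 0.4,  # half-activation of D by C
    h = 4,     # Hill coefficient (shared)
    basal = 0.2)  # basal fraction of A transcription (escape from A = 0)
  if (!is.null(params)) {
    unknown <- setdiff(names(params), names(default))
    if (length(unknown)) stop("unknown toy parameters: ",
                              paste(unknown, collapse = ", "))
    default[names(params)] <- params
  }
  if (any(unlist(default) <= 0)) stop("all toy parameters must be positive")
  if (length(init) != 4L || any(init < 0))
    stop("init must be 4 non-negative concentrations")
  if (length(t_span) != 2L || t_span[2] <= t_span[1])
    stop("t_span must be an increasing pair of times")
  n_points <- as.integer(n_points)
  if (n_points < 2L) stop("n_points must be at least 2")
  structure(list(params = default, init = as.numeric(init),
                 t_span = as.numeric(t_span), n_points = n_points),
            class = "toy_model_spec")
}

toy_rhs <- function(p) {
  hill_act <- function(x, K) {
    x <- max(x, 0)
    x^p$h / (K^p$h + x^p$h)
  }
  hill_inh <- function(x, K) {
    x <- max(x, 0)
    K^p$h / (K^p$h + x^p$h)
  }
  function(t, y) {
    A <- y[1]; B <- y[2]; C <- y[3]; D <- y[4]
    c(p$vA * (p$basal + (1 - p$basal) * hill_act(A, p$KA)) *
        hill_inh(D, p$KD) - p$kA * A,
      p$vB * hill_inh(D, p$KD) - p$kB * B,
      p$vC * hill_act(A * B, p$KC) - p$kC * C,
      p$vD * hill_act(C, p$KH) - p$kD * D)
  }
}

#' Generate the toy-network time series by numerical ODE integration
#'
#' Integrates the toy system of [toy_model_spec()] with an adaptive
#' Dormand-Prince RK45 scheme (rtol 1e-6, atol 1e-9) and samples it on the
#' spec's uniform grid.  Deterministic given the spec.
#'
#' @param spec a [toy_model_spec()].
#' @param rtol,atol solver tolerances.
#' @return a [time_series()] with species `A`, `B`, `C`, `D`.
#' @examples
#' ts <- generate_toy_series(toy_model_spec(n_points = 25))
#' ts
#' @export
generate_toy_series <- function(spec = toy_model_spec(),
                                rtol = 1e-6, atol = 1e-9) {
  stopifnot(inherits(spec, "toy_model_spec"))
  times <- seq(spec$t_span[1], spec$t_span[2], length.out = spec$n_points)
  y <- ode_rk45(toy_rhs(spec$params), spec$init, times,
                rtol = rtol, atol = atol)
  y[y < 0 & y > -1e-9] <- 0  # clip integrator round-off below zero
  time_series(times, y, c("A", "B", "C", "D"))
}

#' Generate the 16 corner-initial-condition toy datasets
#'
#' One dataset per assignment of the four initial concentrations to 0 or 1,
#' used by the cross-validation protocol.
#'
#' @param spec base [toy_model_spec()]; its `init` field is overridden.
#' @return a list of 16 [time_series()], named by the 4-bit corner
#'   (`"0000"` ... `"1111"`, order A, B, C, D).
#' @export
toy_corner_datasets <- function(spec = toy_model_spec()) {
  corners <- expand.grid(D = 0:1, C = 0:1, B = 0:1, A = 0:1)[, 4:1]
  out <- vector("list", 16L)
  names(out) <- apply(corners, 1, paste, collapse = "")
  for (i in seq_len(16L)) {
    s <- spec
    s$init <- as.numeric(corners[i, ])
    out[[i]] <- generate_toy_series(s)
  }
  out
}

#' Random Boolean network fixture with its full synchronous behavior
#'
#' Samples a Boolean network with per-species regulator sets of size at most
#' `max_k` and uniform random truth tables, and returns it together with the
#' synchronous trajectories started from every one of the `2^n` states.
#' Intended as an oracle fixture: learning from the full transition behavior
#' must recover functions with zero trajectory error.
#'
#' @param n number of species (1..6).
#' @param max_k maximum in-degree (<= n).
#' @param steps synchronous steps per trajectory.
#' @return a list with elements `network` (a [boolean_network()]) and
#'   `trajectories` (list of `binary_trajectory`, one per start state).
#' @export
random_network_fixture <- function(n, max_k, steps = 8L) {
  stopifnot(n >= 1L, n <= 6L, max_k >= 0L, max_k <= n)
  funs <- lapply(seq_len(n), function(i) {
    k <- sample.int(max_k + 1L, 1L) - 1L
    regs <- if (k > 0) sort(sample.int(n, k)) else integer(0)
    boolean_function(target = i, regulators = regs,
                     truth_table = sample(0:1, 2^k, replace = TRUE))
  })
  net <- boolean_network(funs, species = paste0("x", seq_len(n)))
  starts <- as.matrix(expand.grid(rep(list(0:1), n)))[, n:1, drop = FALSE]
  trajs <- lapply(seq_len(nrow(starts)), function(i)
    simulate_sync(net, starts[i, ], steps))
  list(network = net, trajectories = trajs)
}
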