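#' Boolean update function for one species
#'
#' A truth table over an ordered set of regulators.  Regulator indices are
#' 1-based species indices, sorted ascending.  Row `r` of the truth table
#' (1-based) corresponds to the regulator bit pattern whose most significant
#' bit is the *first* regulator: row index `1 + sum(bits * 2^((k-1):0))`.
#'
#' @param target 1-based index of the regulated species.
#' @param regulators integer vector of regulator indices (possibly empty).
#' @param truth_table 0/1 vector of length `2^length(regulators)`.
#' @return an object of class `boolean_function`.
#' @examples
#' # x3' <- x1 AND x2
#' boolean_function(3, c(1, 2), c(0, 0, 0, 1))
#' @export
boolean_function <- function(target, regulators, truth_table) {
  target <- as.integer(target)
  regulators <- as.integer(regulators)
  truth_table <- as.integer(truth_table)
  if (length(regulators) && is.unsorted(regulators, strictly = TRUE))
    stop("regulators must be strictly ascending")
  if (length(truth_table) != 2^length(regulators))
    stop("truth_table must have length 2^|regulators|")
  if (!all(truth_table %in% c(0L, 1L)))
    stop("truth_table entries must be 0 or 1")
  structure(list(target = target, regulators = regulators,
                 truth_table = truth_table),
            class = "boolean_function")
}

#' Evaluate a Boolean function on a system state
#'
#' @param f a [boolean_function()].
#' @param state 0/1 vector of the full system state.
#' @return 0 or 1.
#' @export
eval_function <- function(f, state) {
  k <- length(f$regulators)
  if (k == 0L) return(f$truth_table[1L])
  idx <- sum(state[f$regulators] * 2^((k - 1):0))
  f$truth_table[idx + 1L]
}

#' Boolean network: one update function per species
#'
#' @param functions list of [boolean_function()], one per species, in target
#'   order 1..n.
#' @param species character vector of species names.
#' @return an object of class `boolean_network`.
#' @export
boolean_network <- function(functions, species = NULL) {
  n <- length(functions)
  if (n < 1L) stop("a network needs at least one function")
  if (is.null(species)) species <- paste0("x", seq_len(n))
  if (length(species) != n) stop("one species name per function required")
  for (i in seq_len(n)) {
    f <- functions[[i]]
    if (!inherits(f, "boolean_function"))
      stop("functions must be boolean_function objects")
    if (f$target != i)
      stop(sprintf("function %d has target %d; expected one function per
 species in order", i, f$target))
    if (length(f$regulators) && max(f$regulators) > n)
      stop("regulator index exceeds species count")
  }
  structure(list(n = n, functions = functions, species = species),
            class = "boolean_network")
}

#' @export
print.boolean_network <- function(x, ...) {
  cat(sprintf("boolean_network on %d species\n", x$n))
  for (f in x$functions) {
    regs <- if (length(f$regulators))
      paste(x$species[f$regulators], collapse = ",") else "-"
    cat(sprintf("  %s' = f(%s)  tt=%s\n", x$species[f$target], regs,
                paste(f$truth_table, collapse = "")))
  }
  invisible(x)
}

#' Encode a 0/1 state vector as an integer
#'
#' Most significant bit = first species; the inverse of [decode_state()].
#' Used for transition-table keys and deterministic tie-breaking.
#'
#' @param state 0/1 vector.
#' @return a non-negative integer (double for n > 31).
#' @export
encode_state <- function(state) {
  n <- length(state)
  sum(state * 2^((n - 1):0))
}

#' Decode an integer to a 0/1 state vector
#'
#' @param code non-negative integer.
#' @param n number of species.
#' @return 0/1 integer vector of length `n`.
#' @export
decode_state <- function(code, n) {
  as.integer(intToBits(code))[n:1]
}

# internal: flatten a network for the C++ kernels (0-based regulators)
net_to_cpp <- function(net) {
  list(regs = lapply(net$functions, function(f) f$regulators - 1L),
       tts = lapply(net$functions, function(f) f$truth_table))
}

#' Serialize a Boolean network to JSON
#'
#' Schema: `{schema_version, species, functions: [{target, regulators,
#' truth_table}]}` with `truth_table` a bit string whose most significant bit
#' corresponds to the first regulator.  [network_from_json()] round-trips.
#'
#' @param net a [boolean_network()].
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly, if written to `path`).
#' @export
network_to_json <- function(net, path = NULL) {
  stopifnot(inherits(net, "boolean_network"))
  obj <- list(
    schema_version = "1.0",
    species = net$species,
    functions = lapply(net$functions, function(f)
      list(target = f$target,
           regulators = I(f$regulators),
           truth_table = paste(f$truth_table, collapse = ""))))
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(as.character(txt)))
  }
  as.character(txt)
}

#' Deserialize a Boolean network from JSON
#'
#' @param x JSON string or file path produced by [network_to_json()].
#' @return a [boolean_network()].
#' @export
network_from_json <- function(x) {
  obj <- jsonlite::fromJSON(x, simplifyVector = FALSE)
  funs <- lapply(obj$functions, function(f)
    boolean_function(f$target, unlist(f$regulators),
                     as.integer(strsplit(f$truth_table, "")[[1]])))
  funs <- funs[order(vapply(funs, `[[`, 1L, "target"))]
  boolean_network(funs, species = unlist(obj$species))
}
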