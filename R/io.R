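REPORT_SCHEMA_VERSION <- "1.0"

#' Pipeline run configuration
#'
#' Validated bundle of every knob of the inference pipeline; echoed into all
#' report files so any output is reproducible from (input, config, seed).
#'
#' @param bin_method `"km1"`, `"km3"` or `"basca"`.
#' @param learn_method `"reveal"`, `"bestfit"` or `"fullfit"`.
#' @param depth KM-3 clustering depth.
#' @param max_indegree maximum in-degree of learned functions.
#' @param searches number of independent searches.
#' @param max_iterations per-search cap on scored networks.
#' @param samples networks sampled per binarization round.
#' @param seed integer RNG seed.
#' @param async_runs executions averaged in asynchronous simulation.
#' @return a list of class `run_config`.
#' @export
run_config <- function(bin_method = "km3", learn_method = "bestfit",
                       depth = 3L, max_indegree = 3L, searches = 100L,
                       max_iterations = 10000L, samples = 100L,
                       seed = 1L, async_runs = 100L) {
  bin_method <- match.arg(bin_method, c("km1", "km3", "basca"))
  learn_method <- match.arg(learn_method, c("reveal", "bestfit", "fullfit"))
  num <- list(depth = depth, max_indegree = max_indegree,
              searches = searches, max_iterations = max_iterations,
              samples = samples, async_runs = async_runs)
  for (nm in names(num))
    if (!is.numeric(num[[nm]]) || length(num[[nm]]) != 1L || num[[nm]] < 1)
      stop(sprintf("config field '%s' must be a positive number", nm))
  structure(list(bin_method = bin_method, learn_method = learn_method,
                 depth = as.integer(depth),
                 max_indegree = as.integer(max_indegree),
                 searches = as.integer(searches),
                 max_iterations = as.integer(max_iterations),
                 samples = as.integer(samples),
                 seed = as.integer(seed),
                 async_runs = as.integer(async_runs)),
            class = "run_config")
}

#' Run the full inference pipeline on a CSV time series
#'
#' Reads the series, runs [search_min_error()] under the configuration, and
#' returns the search result (logging per-search progress when
#' `verbose = TRUE`).
#'
#' @param config a [run_config()].
#' @param input path to a time-series CSV (see [read_timeseries_csv()]).
#' @param verbose print progress.
#' @return a `search_result`.
#' @export
run_pipeline <- function(config, input, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  ts <- read_timeseries_csv(input)
  res <- search_min_error(ts,
                          bin_method = config$bin_method,
                          learn_method = config$learn_method,
                          searches = config$searches,
                          max_iterations = config$max_iterations,
                          samples = config$samples,
                          depth = config$depth,
                          max_k = config$max_indegree,
                          seed = config$seed)
  if (verbose) print(res)
  res
}

#' Write a search or cross-validation report as JSON
#'
#' The report embeds a schema version, the configuration echo and seed, the
#' headline numbers and (for search results) the winning networks in the
#' same JSON schema as [network_to_json()].  An empty result (no network
#' learned) is serialized with `networks = null` and a reason string.
#'
#' @param result a `search_result` or `crossval_report`.
#' @param path output file path.
#' @param config optional [run_config()] to echo.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path, config = NULL) {
  base <- list(schema_version = REPORT_SCHEMA_VERSION,
               config = if (is.null(config)) NULL else unclass(config))
  if (inherits(result, "search_result")) {
    obj <- c(base, list(
      kind = "search",
      seed = result$seed,
      best_error = result$best_error,
      convergence = result$convergence,
      uniqueness = result$uniqueness,
      searches = result$searches,
      iterations_to_best = I(result$iterations_to_best),
      reason = result$reason,
      networks = if (!length(result$networks)) NULL else
        lapply(result$networks, function(w)
          jsonlite::fromJSON(network_to_json(w$network),
                             simplifyVector = FALSE))))
  } else if (inherits(result, "crossval_report")) {
    obj <- c(base, list(
      kind = "crossval",
      seed = result$seed,
      prediction_error = result$prediction_error,
      predictive_power_percent = 100 * (1 - result$prediction_error),
      folds = result$folds,
      repeats = result$repeats,
      per_fold_errors = result$per_fold_errors))
  } else stop("unsupported result type")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Read a report written by [write_report()]
#'
#' @param path JSON report path.
#' @return the parsed report list (`kind` field distinguishes report types).
#' @export
read_report <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}
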