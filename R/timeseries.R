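#' Construct a time series of species concentrations
#'
#' A `time_series` holds non-negative real measurements of `n` molecular
#' species at strictly increasing time points.  It is the raw input of the
#' inference pipeline.
#'
#' @param times numeric vector of strictly increasing time stamps
#'   (arbitrary units; the toy model uses hours).
#' @param values numeric matrix, one row per time point, one column per
#'   species.
#' @param species character vector of species names; defaults to the column
#'   names of `values` or `"x1"`, `"x2"`, ...
#' @return an object of class `time_series` with fields `times`, `values`
#'   and `species`.
#' @examples
#' ts <- time_series(0:3, cbind(a = c(0, 1, 0, 1), b = c(1, 1, 0, 0)))
#' ts$species
#' @export
time_series <- function(times, values, species = NULL) {
  times <- as.numeric(times)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(species)) {
    species <- colnames(values)
    if (is.null(species)) species <- paste0("x", seq_len(ncol(values)))
  }
  if (length(times) != nrow(values))
    stop("length(times) must equal nrow(values)")
  if (length(times) < 2L)
    stop("a time series needs at least 2 time points")
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing")
  if (ncol(values) < 1L)
    stop("at least one species is required")
  if (length(species) != ncol(values))
    stop("species names must match the number of value columns")
  colnames(values) <- species
  structure(list(times = times, values = values, species = species),
            class = "time_series")
}

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf("time_series: %d time points x %d species (%s), t in [%g, %g]\n",
              length(x$times), length(x$species),
              paste(x$species, collapse = ", "),
              min(x$times), max(x$times)))
  invisible(x)
}

#' Min-max normalize each species to the unit interval
#'
#' @param ts a [time_series()].
#' @return a `time_series` with every column rescaled to span exactly
#'   \[0, 1\].
#' @examples
#' ts <- time_series(0:2, cbind(a = c(2, 4, 6)))
#' normalize_series(ts)$values[, 1]
#' @export
normalize_series <- function(ts) {
  stopifnot(inherits(ts, "time_series"))
  v <- ts$values
  for (j in seq_len(ncol(v))) {
    rng <- range(v[, j])
    if (diff(rng) <= 0)
      stop_degenerate(sprintf(
        "species '%s' is constant; cannot min-max normalize", ts$species[j]))
    v[, j] <- (v[, j] - rng[1]) / diff(rng)
  }
  time_series(ts$times, v, ts$species)
}

#' Subsample a time series at a coarser measurement grid
#'
#' Emulates sparse experimental sampling of a densely simulated trajectory.
#' `grid16` is the 16-point schedule 0, 5, 15, 30, 45 min, 1, 2, 3, 6, 8, 10,
#' 12, 15, 18, 21, 24 h; `grid8` is every other point of that schedule
#' (starting at 0).  `manual` takes the times from `at`.  Values are taken at
#' the nearest available source time, which must lie within half the local
#' source step.
#'
#' @param ts a [time_series()] with times in hours.
#' @param mode one of `"grid16"`, `"grid8"`, `"manual"`.
#' @param at numeric vector of requested times (hours) when `mode="manual"`.
#' @return a `time_series` at the requested times.
#' @export
subsample_timepoints <- function(ts, mode = c("grid16", "grid8", "manual"),
                                 at = NULL) {
  stopifnot(inherits(ts, "time_series"))
  mode <- match.arg(mode)
  grid16 <- c(0, 5 / 60, 15 / 60, 30 / 60, 45 / 60, 1, 2, 3, 6, 8, 10, 12,
              15, 18, 21, 24)
  req <- switch(mode,
                grid16 = grid16,
                grid8  = grid16[seq(1, 16, by = 2)],
                manual = as.numeric(at))
  if (mode == "manual" && (is.null(at) || length(at) < 2L))
    stop("mode='manual' requires at least two requested times in `at`")
  if (any(req < min(ts$times)) || any(req > max(ts$times)))
    stop("requested time outside the range of the series")
  step <- median(diff(ts$times))
  idx <- vapply(req, function(t0) which.min(abs(ts$times - t0)), integer(1))
  if (any(abs(ts$times[idx] - req) > step / 2 + 1e-9))
    stop("no source time point within half a step of a requested time")
  time_series(ts$times[idx], ts$values[idx, , drop = FALSE], ts$species)
}

#' Read a time series from CSV
#'
#' Expected layout: a header row `time,<species1>,<species2>,...` followed by
#' one row per time point; comma separator, `.` decimal mark, UTF-8.
#'
#' @param path CSV file path.
#' @return a [time_series()].
#' @export
read_timeseries_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, check.names = FALSE)
  if (ncol(df) < 2L || tolower(names(df)[1]) != "time")
    stop("malformed header: expected 'time' followed by species names, got: ",
         paste(names(df), collapse = ","))
  for (j in seq_along(df)) {
    if (!is.numeric(df[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[j]]))))[1]
      stop(sprintf("non-numeric value in column '%s' (row %d)",
                   names(df)[j], if (is.na(bad)) 1L else bad))
    }
  }
  tm <- df[[1]]
  if (anyDuplicated(tm) || any(diff(tm) <= 0))
    stop(sprintf("times must be strictly increasing (violated near row %d)",
                 which(diff(tm) <= 0)[1] + 1L))
  time_series(tm, as.matrix(df[, -1, drop = FALSE]), names(df)[-1])
}

#' Write a time series to CSV
#'
#' @param ts a [time_series()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_timeseries_csv <- function(ts, path) {
  stopifnot(inherits(ts, "time_series"))
  df <- data.frame(time = ts$times, check.names = FALSE)
  df[ts$species] <- ts$values
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
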