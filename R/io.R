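# Plain-text input/output: JSON configs, CSV time series, snapshot matrices.

#' Write / read a lattice snapshot as a plain-text integer matrix
#'
#' One grid row per line, states space-separated (0 = empty,
#' 1 = susceptible, 2 = infected).
#'
#' @param grid integer matrix over `GRID_STATES`.
#' @param file path.
#' @return `read_snapshot` returns the integer matrix.
#' @export
write_snapshot <- function(grid, file) {
  stopifnot(is.matrix(grid))
  writeLines(apply(grid, 1, paste, collapse = " "), file)
  invisible(file)
}

#' @rdname write_snapshot
#' @export
read_snapshot <- function(file) {
  rows <- strsplit(trimws(readLines(file)), "\\s+")
  rows <- rows[lengths(rows) > 0]
  g <- do.call(rbind, lapply(rows, as.integer))
  if (!all(g %in% GRID_STATES)) stop("invalid state codes in snapshot")
  g
}

#' Write the time series of a run as CSV
#'
#' Header `t,n_S,n_I,n_empty,boundary_contacted` for lattice runs;
#' `t,sum_S,sum_I` for metapopulation runs.
#'
#' @param run a `lattice_run` or `metapop_run`.
#' @param file path.
#' @export
write_timeseries_csv <- function(run, file) {
  ts <- run$ts
  if ("boundary_contacted" %in% names(ts))
    ts$boundary_contacted <- as.integer(ts$boundary_contacted)
  write.csv(ts, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read an observed infected-cell count series
#'
#' CSV with columns `day`, `count` and optionally `sd`.
#'
#' @param file path.
#' @return Data frame `day, count[, sd]`.
#' @export
read_observed_csv <- function(file) {
  d <- read.csv(file)
  if (!all(c("day", "count") %in% names(d)))
    stop("observed series must have columns day, count")
  d
}

#' Read a flat JSON configuration into a lattice run specification
#'
#' Keys: `R, D, B, A, N, max_steps, seed, record_every` and `init.scheme`,
#' `init.infected_side`, `init.susceptible_side` (either nested under
#' `init` or dotted at the top level).
#'
#' @param file path to the JSON config.
#' @return List with `params` ([lattice_params()]), `init`
#'   ([init_condition()]) and `record_every`.
#' @export
read_lattice_config <- function(file) {
  cfg <- jsonlite::read_json(file, simplifyVector = TRUE)
  get <- function(key, default = NULL) {
    if (!is.null(cfg[[key]])) return(cfg[[key]])
    if (!is.null(cfg$init) && startsWith(key, "init."))
      return(cfg$init[[sub("^init\\.", "", key)]])
    default
  }
  params <- lattice_params(
    R = get("R"), D = get("D", 0), B = get("B"), A = get("A"),
    N = get("N"), max_steps = get("max_steps", 1000),
    seed = get("seed", 1))
  init <- init_condition(
    scheme = tolower(get("init.scheme", "center_square_in_full")),
    infected_side = get("init.infected_side"),
    susceptible_side = get("init.susceptible_side"))
  list(params = params, init = init,
       record_every = get("record_every", 10))
}

#' Read a flat JSON configuration into metapopulation parameters
#'
#' Keys: `r, beta, a, d, k, m_S, m_I, n, h, t_max, seed`.
#'
#' @param file path to the JSON config.
#' @return A [metapop_params()] object.
#' @export
read_metapop_config <- function(file) {
  cfg <- jsonlite::read_json(file, simplifyVector = TRUE)
  val <- function(key, default) if (is.null(cfg[[key]])) default
                                else cfg[[key]]
  metapop_params(r = cfg$r, beta = cfg$beta, a = cfg$a,
                 d = val("d", 0), k = val("k", 100),
                 m_S = val("m_S", 1), m_I = val("m_I", val("m_S", 1)),
                 n = val("n", 100), h = val("h", 1),
                 t_max = val("t_max", 100), seed = val("seed", 1))
}

#' Write a JSON report
#'
#' Scalars are written unboxed at full precision.
#'
#' @param x named list.
#' @param file path.
#' @export
write_json_report <- function(x, file) {
  jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}
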