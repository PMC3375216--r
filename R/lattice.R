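# Agent-based lattice model of virus spread through a growing cell monolayer.
#
# Grid states: 0 = empty, 1 = susceptible (uninfected), 2 = infected.

#' Grid state codes
#'
#' Integer codes used in lattice matrices throughout the package.
#' @format Named integer vector: `EMPTY = 0`, `SUSCEPTIBLE = 1`, `INFECTED = 2`.
#' @export
GRID_STATES <- c(EMPTY = 0L, SUSCEPTIBLE = 1L, INFECTED = 2L)

#' Parameters of the agent-based lattice model
#'
#' The four event weights of the model: at each time step the grid is sampled
#' `N^2` times with replacement; a sampled uninfected cell divides into a
#' uniformly chosen Moore neighbor with probability `R` (succeeding only if
#' that spot is empty) and otherwise dies with probability `D`; a sampled
#' infected cell transmits the virus to a uniformly chosen Moore neighbor with
#' probability `B` (succeeding only if that spot holds a susceptible cell;
#' the source survives transmission) and otherwise dies with probability `A`.
#' Infected cells do not divide. Weights larger than one are mapped to
#' probabilities by dividing all four by `max(1, R, D, B, A)`, which preserves
#' every rate ratio; the emergent patterns depend only on the ratios.
#'
#' @param R division weight of uninfected cells (per sampling event).
#' @param D death weight of uninfected cells.
#' @param B transmission weight of infected cells.
#' @param A death weight of infected cells.
#' @param N side length of the square grid (spots), at least 3.
#' @param max_steps maximum number of time steps to simulate.
#' @param seed integer RNG seed recorded with the run.
#' @return An object of class `lattice_params`.
#' @examples
#' p <- lattice_params(R = 0.014, D = 0, B = 0.032, A = 0.008, N = 30)
#' @export
lattice_params <- function(R, D = 0, B, A, N, max_steps = 1000L, seed = 1L) {
  stopifnot(R >= 0, D >= 0, B >= 0, A >= 0)
  N <- as.integer(N)
  max_steps <- as.integer(max_steps)
  if (N < 3L) stop("N must be at least 3")
  if (max_steps < 0L) stop("max_steps must be non-negative")
  structure(
    list(R = R, D = D, B = B, A = A, N = N,
         max_steps = max_steps, seed = as.integer(seed)),
    class = "lattice_params")
}

#' @export
print.lattice_params <- function(x, ...) {
  cat(sprintf(
    "Lattice parameters: R = %g, D = %g, B = %g, A = %g on %d x %d grid\n",
    x$R, x$D, x$B, x$A, x$N, x$N))
  cat(sprintf("  max_steps = %d, seed = %d\n", x$max_steps, x$seed))
  invisible(x)
}

#' Initial conditions for the lattice model
#'
#' Two standard schemes plus a custom grid. `"center_square_in_full"` fills
#' the whole grid with susceptible cells and places a centered
#' `infected_side` x `infected_side` square of infected cells (the plaque
#' set-up: founder infection inside a confluent monolayer).
#' `"nested_squares"` starts from an empty grid holding a centered
#' `susceptible_side` square of uninfected cells whose centered
#' `infected_side` core is infected (the long-term outcome set-up, in which
#' both populations can expand into empty space). When the grid and square
#' parities differ, the square is shifted one spot toward the origin.
#'
#' @param scheme one of `"center_square_in_full"`, `"nested_squares"`,
#'   `"custom"`.
#' @param infected_side side of the central infected square.
#' @param susceptible_side side of the surrounding susceptible square
#'   (`"nested_squares"` only).
#' @param custom_grid integer matrix over `GRID_STATES` (`"custom"` only).
#' @return An object of class `init_condition`.
#' @examples
#' init_condition("nested_squares", infected_side = 5, susceptible_side = 13)
#' @export
init_condition <- function(scheme = c("center_square_in_full",
                                      "nested_squares", "custom"),
                           infected_side = NULL, susceptible_side = NULL,
                           custom_grid = NULL) {
  scheme <- match.arg(scheme)
  if (scheme != "custom") {
    stopifnot(!is.null(infected_side), infected_side >= 0)
    infected_side <- as.integer(infected_side)
  }
  if (scheme == "nested_squares") {
    stopifnot(!is.null(susceptible_side))
    susceptible_side <- as.integer(susceptible_side)
    if (infected_side > susceptible_side)
      stop("infected_side must not exceed susceptible_side")
  }
  if (scheme == "custom") {
    stopifnot(is.matrix(custom_grid),
              all(custom_grid %in% GRID_STATES))
    storage.mode(custom_grid) <- "integer"
  }
  structure(list(scheme = scheme, infected_side = infected_side,
                 susceptible_side = susceptible_side,
                 custom_grid = custom_grid),
            class = "init_condition")
}

# centered placement, shifted toward the origin on parity mismatch
centered_range <- function(N, side) {
  if (side == 0L) return(integer(0))
  start <- floor((N - side) / 2) + 1L
  seq.int(start, start + side - 1L)
}

#' Build the initial lattice state
#'
#' @param params a [lattice_params()] object.
#' @param init an [init_condition()] object.
#' @return An object of class `lattice_state`: list with the integer `grid`,
#'   time `t = 0` and the `boundary_contacted` flag (whether any occupied
#'   spot touches an edge row or column).
#' @examples
#' p <- lattice_params(R = 0.5, B = 0.6, A = 0.62, N = 30)
#' st <- init_lattice(p, init_condition("nested_squares", 5, 13))
#' table(st$grid)
#' @export
init_lattice <- function(params, init) {
  stopifnot(inherits(params, "lattice_params"),
            inherits(init, "init_condition"))
  N <- params$N
  if (init$scheme == "custom") {
    g <- init$custom_grid
    if (nrow(g) != N || ncol(g) != N)
      stop("custom grid must be N x N")
  } else if (init$scheme == "center_square_in_full") {
    if (init$infected_side > N)
      stop("infected_side exceeds grid side N")
    g <- matrix(GRID_STATES[["SUSCEPTIBLE"]], N, N)
    idx <- centered_range(N, init$infected_side)
    g[idx, idx] <- GRID_STATES[["INFECTED"]]
  } else {
    if (init$susceptible_side > N)
      stop("susceptible_side exceeds grid side N")
    g <- matrix(GRID_STATES[["EMPTY"]], N, N)
    idx <- centered_range(N, init$susceptible_side)
    g[idx, idx] <- GRID_STATES[["SUSCEPTIBLE"]]
    idx <- centered_range(N, init$infected_side)
    g[idx, idx] <- GRID_STATES[["INFECTED"]]
  }
  occupied <- g != GRID_STATES[["EMPTY"]]
  boundary <- any(occupied[1, ]) || any(occupied[N, ]) ||
    any(occupied[, 1]) || any(occupied[, N])
  structure(list(grid = g, t = 0L, boundary_contacted = boundary),
            class = "lattice_state")
}

#' Advance the lattice by one or more time steps
#'
#' Performs `n_steps` asynchronous update steps (each `N^2` sequential random
#' spot draws on the evolving grid) and returns the new state. Mostly useful
#' for fine-grained inspection; use [run_lattice()] for full trajectories.
#'
#' @param state a `lattice_state`.
#' @param params a [lattice_params()] object.
#' @param n_steps number of steps to advance.
#' @return The advanced `lattice_state`.
#' @export
lattice_step <- function(state, params, n_steps = 1L) {
  stopifnot(inherits(state, "lattice_state"))
  res <- lattice_run_cpp(state$grid, params$R, params$D, params$B, params$A,
                         as.integer(n_steps), as.integer(n_steps) + 1L,
                         FALSE, 1L)
  structure(list(grid = res$grid, t = state$t + as.integer(n_steps),
                 boundary_contacted = state$boundary_contacted ||
                   res$boundary),
            class = "lattice_state")
}

#' Run the agent-based lattice simulation
#'
#' Iterates the update rule until `max_steps` is reached, the virus is
#' extinct (`n_I = 0`), or all cells are extinct. Records the population
#' counts at every step and grid snapshots every `record_every` steps
#' (always including the initial and final grids). Identical
#' `(params, init, seed)` give bit-identical trajectories.
#'
#' @param params a [lattice_params()] object (its `seed` seeds the run).
#' @param init an [init_condition()] object.
#' @param record_every snapshot interval in steps (>= 1).
#' @param keep_snapshots set `FALSE` to skip snapshot storage.
#' @return An object of class `lattice_run`: list with
#'   \describe{
#'   \item{ts}{data frame `t, n_S, n_I, n_empty, boundary_contacted`, one row
#'     per step including `t = 0`.}
#'   \item{snapshots, snap_t}{list of grid matrices and their times.}
#'   \item{termination}{`"MAX_STEPS"`, `"VIRUS_EXTINCT"` or
#'     `"CELLS_EXTINCT"`.}
#'   \item{max_I}{largest infected count attained (invasion diagnostics).}
#'   \item{params, init}{the inputs, for provenance.}
#'   }
#' @examples
#' p <- lattice_params(R = 0.014, B = 0.032, A = 0.008, N = 30,
#'                     max_steps = 500, seed = 7)
#' run <- run_lattice(p, init_condition("nested_squares", 5, 13))
#' tail(run$ts)
#' @export
run_lattice <- function(params, init, record_every = 10L,
                        keep_snapshots = TRUE) {
  stopifnot(inherits(params, "lattice_params"))
  record_every <- as.integer(record_every)
  if (record_every < 1L) stop("record_every must be >= 1")
  state0 <- init_lattice(params, init)
  set.seed(params$seed)
  res <- lattice_run_cpp(state0$grid, params$R, params$D, params$B, params$A,
                         params$max_steps, record_every, keep_snapshots, 1L)
  n_empty <- params$N^2 - res$n_S - res$n_I
  ts <- data.frame(t = res$t, n_S = res$n_S, n_I = res$n_I,
                   n_empty = n_empty,
                   boundary_contacted = as.logical(res$boundary_contacted))
  structure(list(ts = ts,
                 snapshots = if (keep_snapshots) res$snapshots else list(),
                 snap_t = if (keep_snapshots) res$snap_t else integer(0),
                 termination = res$termination,
                 max_I = res$max_I,
                 final_grid = res$grid,
                 params = params, init = init, seed = params$seed),
            class = "lattice_run")
}

#' @export
print.lattice_run <- function(x, ...) {
  last <- x$ts[nrow(x$ts), ]
  cat(sprintf("Lattice run (%d x %d, seed %d): %d steps, %s\n",
              x$params$N, x$params$N, x$seed, last$t, x$termination))
  cat(sprintf("  final counts: S = %d, I = %d, empty = %d; boundary %s\n",
              last$n_S, last$n_I, last$n_empty,
              if (last$boundary_contacted) "contacted" else "not contacted"))
  invisible(x)
}

#' Population time series container
#'
#' Validates and assembles a `(t, S, I)` trajectory, the shared interchange
#' format between the simulators, the classifiers and the fitter.
#'
#' @param t time points (steps or days), strictly increasing.
#' @param S uninfected counts.
#' @param I infected counts.
#' @param sd_I optional per-point standard deviation of `I` (replicate
#'   spread).
#' @return A data frame of class `population_ts`.
#' @export
population_ts <- function(t, S, I, sd_I = NULL) {
  stopifnot(length(t) == length(S), length(t) == length(I),
            all(diff(t) > 0), all(S >= 0), all(I >= 0))
  out <- data.frame(t = t, S = S, I = I)
  if (!is.null(sd_I)) {
    stopifnot(length(sd_I) == length(t), all(sd_I >= 0))
    out$sd_I <- sd_I
  }
  class(out) <- c("population_ts", "data.frame")
  out
}

#' Extract the population time series of a lattice run
#'
#' @param run a `lattice_run`.
#' @return A [population_ts()] data frame.
#' @export
run_population_ts <- function(run) {
  stopifnot(inherits(run, "lattice_run"))
  population_ts(run$ts$t, run$ts$n_S, run$ts$n_I)
}
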