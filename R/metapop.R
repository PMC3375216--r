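# One-dimensional stochastic metapopulation model: local mass-action
# predator-prey dynamics in n patches coupled by nearest-neighbor migration,
# simulated exactly with the Gillespie direct method.

#' Parameters of the metapopulation model
#'
#' Local (per-patch) rates mirror the mass-action ODE model: susceptible
#' birth at rate `r*S*(1 - (S + I)/k)` (clipped at zero when the patch is
#' over capacity), infection at rate `beta*S*I/k`, infected death at rate
#' `a*I`, susceptible death at rate `d*S`. Cells migrate to each of the two
#' nearest patches at rate `m/2` per cell (total outflow `m`); the chain has
#' hard walls, so the off-chain channels of the end patches are absent.
#'
#' @param r local division rate of uninfected cells.
#' @param beta local infection rate.
#' @param a infected death rate.
#' @param d susceptible death rate (default 0).
#' @param k local carrying capacity (cells per patch).
#' @param m_S,m_I migration rates; equal by default (`m_I = m_S`), which
#'   introduces no asymmetry between the populations.
#' @param n number of patches (>= 3).
#' @param h patch spacing (length unit; sets the diffusion scale).
#' @param t_max simulation horizon.
#' @param seed integer RNG seed.
#' @return Object of class `metapop_params`.
#' @export
metapop_params <- function(r, beta, a, d = 0, k = 100, m_S = 1, m_I = m_S,
                           n = 100, h = 1, t_max = 100, seed = 1L) {
  stopifnot(r >= 0, beta >= 0, a >= 0, d >= 0, m_S >= 0, m_I >= 0,
            k >= 1, n >= 3, h > 0, t_max >= 0)
  structure(list(r = r, beta = beta, a = a, d = d, k = k,
                 m_S = m_S, m_I = m_I, n = as.integer(n), h = h,
                 t_max = t_max, seed = as.integer(seed)),
            class = "metapop_params")
}

#' Initial state of the metapopulation
#'
#' The default `"core"` scheme seeds the middle patch with 30 infected and
#' 70 uninfected cells and puts the uninfected population at carrying
#' capacity in the five patches on each side of it; all remaining patches
#' start empty. (With `k` other than 100 the middle patch holds `0.3*k`
#' infected and `0.7*k` uninfected cells, rounded.) `"custom"` takes
#' explicit `S` and `I` vectors.
#'
#' @param p a [metapop_params()] object.
#' @param scheme `"core"` or `"custom"`.
#' @param S,I integer vectors of length `n` (`"custom"` only).
#' @return Object of class `metapop_state` with integer vectors `S`, `I`
#'   and time `t = 0`.
#' @examples
#' st <- init_metapop(metapop_params(r = .1, beta = 1, a = .1))
#' c(sum(st$S), sum(st$I))  # 1070, 30
#' @export
init_metapop <- function(p, scheme = c("core", "custom"),
                         S = NULL, I = NULL) {
  scheme <- match.arg(scheme)
  n <- p$n
  if (scheme == "core") {
    if (n < 11) stop("the core scheme needs at least 11 patches")
    Sv <- integer(n); Iv <- integer(n)
    mid <- (n + 1L) %/% 2L
    Iv[mid] <- as.integer(round(0.3 * p$k))
    Sv[mid] <- as.integer(round(0.7 * p$k))
    side <- setdiff((mid - 5L):(mid + 5L), mid)
    Sv[side] <- as.integer(round(p$k))
  } else {
    stopifnot(length(S) == n, length(I) == n, all(S >= 0), all(I >= 0))
    Sv <- as.integer(S); Iv <- as.integer(I)
  }
  structure(list(S = Sv, I = Iv, t = 0), class = "metapop_state")
}

#' Simulate the stochastic metapopulation
#'
#' Exact continuous-time simulation (Gillespie direct method). Terminates at
#' `t_max`, at global extinction of the infected population, or when all
#' event rates vanish. Population totals are recorded on a uniform time grid
#' and full patch profiles at `profile_times`.
#'
#' @param p a [metapop_params()] object (its `seed` seeds the run).
#' @param state0 a [init_metapop()] state (default: the core scheme).
#' @param record_points number of points of the uniform recording grid.
#' @param profile_times times at which `(S_i, I_i)` patch profiles are
#'   stored; defaults to 21 evenly spaced times.
#' @return Object of class `metapop_run`: totals data frame `ts`
#'   (`t, sum_S, sum_I`), profile matrices `profile_S`, `profile_I` (one row
#'   per profile time), `termination`, `max_sum_I`, `boundary_contacted`
#'   (target cells ever present in an end patch), the final `S`, `I` and the
#'   internal
#'   rate bookkeeping discrepancy `rate_discrepancy` (should be at numerical
#'   round-off level).
#' @export
simulate_metapop <- function(p, state0 = init_metapop(p),
                             record_points = 201L, profile_times = NULL) {
  stopifnot(inherits(p, "metapop_params"), inherits(state0, "metapop_state"))
  if (is.null(profile_times))
    profile_times <- seq(0, p$t_max, length.out = 21L)
  record_times <- seq(0, p$t_max, length.out = record_points)
  set.seed(p$seed)
  res <- metapop_run_cpp(state0$S, state0$I, p$r, p$beta, p$a, p$d, p$k,
                         p$m_S, p$m_I, p$t_max, record_times, profile_times)
  structure(list(
    ts = data.frame(t = res$record_times, sum_S = res$sum_S,
                    sum_I = res$sum_I),
    profile_S = res$profile_S, profile_I = res$profile_I,
    profile_times = res$profile_times,
    S = res$S, I = res$I, t_end = res$t_end,
    termination = res$termination, max_sum_I = res$max_sum_I,
    boundary_contacted = res$boundary_contacted,
    n_events = res$n_events, rate_discrepancy = res$rate_discrepancy,
    params = p, seed = p$seed),
    class = "metapop_run")
}

#' @export
print.metapop_run <- function(x, ...) {
  cat(sprintf(
    "Metapopulation run (n = %d, k = %g, seed = %d): t_end = %.3g, %s\n",
    x$params$n, x$params$k, x$seed, x$t_end, x$termination))
  cat(sprintf("  final totals: S = %g, I = %g; %.0f events; boundary %s\n",
              sum(x$S), sum(x$I), x$n_events,
              if (x$boundary_contacted) "contacted" else "not contacted"))
  invisible(x)
}

#' Classify the outcome regime of a metapopulation run
#'
#' Maps a terminated run onto the outcome regimes of the metapopulation
#' phase diagram:
#' \describe{
#' \item{MA}{virus-mediated extinction: both populations extinct before the
#'   occupied region reached an end patch.}
#' \item{MB}{boundary-mediated extinction: both extinct at or after boundary
#'   contact (the co-traveling waves ran into the wall).}
#' \item{MB1}{persistence through repeatedly splitting traveling fronts:
#'   survival to `t_max` with only a small fraction of patches occupied.}
#' \item{MC}{true coexistence: survival to `t_max` with broad occupancy
#'   across the patches.}
#' \item{MD}{virus extinction after initial invasion (infected total grew at
#'   least `gamma`-fold), cells persist.}
#' \item{ME}{virus extinction without invasion.}
#' }
#'
#' @param run a `metapop_run`.
#' @param gamma invasion fold-change criterion (default 4).
#' @param occupancy_threshold fraction of patches that must hold cells at
#'   the end for the broad-occupancy (MC) call (default 0.4).
#' @return Character label with attribute `invaded`.
#' @export
classify_metapop_outcome <- function(run, gamma = 4,
                                     occupancy_threshold = 0.4) {
  stopifnot(inherits(run, "metapop_run"))
  I0 <- run$ts$sum_I[1]
  invaded <- I0 > 0 && run$max_sum_I >= gamma * I0
  totS <- sum(run$S); totI <- sum(run$I)
  label <-
    if (totS == 0) {
      # no target cells left: any remaining infected cells are doomed
      if (run$boundary_contacted) "MB" else "MA"
    } else if (totI == 0) {
      if (invaded) "MD" else "ME"
    } else {
      occ <- mean(run$S + run$I > 0)
      if (occ >= occupancy_threshold) "MC" else "MB1"
    }
  attr(label, "invaded") <- invaded
  label
}
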