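# Concordance between the local-neighborhood ODE prediction and the
# simulated long-run outcome of the lattice model: the central claim that
# global outcomes of the spatial system can be read off the local
# mass-action equilibria.

#' Local-theory vs lattice outcome concordance experiment
#'
#' Samples parameter points log-uniformly in the `(log10(R/B), log10(A/B))`
#' plane with `D = 0`, excluding bands around the loci `S1 = 1` and
#' `I1 = 1` (where neither call is expected to be clean), runs the lattice
#' model from the nested-squares initial condition at each point for several
#' seeds, and compares the majority simulated outcome with the three-way
#' local-ODE prediction. Simulated labels map onto predictions as: cell
#' extinction (pre or post boundary) to target-extinction-or-controlled,
#' coexistence to coexistence, virus extinction (with or without invasion)
#' to virus loss.
#'
#' @param n_points number of parameter points.
#' @param seeds_per_point lattice replicates per point (majority vote).
#' @param x_range,y_range sampling ranges of `log10(R/B)` and `log10(A/B)`.
#' @param B_ref reference transmission weight.
#' @param N,max_steps lattice side and step budget.
#' @param band_S1,band_I1 half-widths (in `log10` units of the equilibrium
#'   value) of the exclusion bands around `S1 = 1` and `I1 = 1`.
#' @param seed master seed.
#' @return List of class `concordance_result` with the per-point data frame
#'   `points` (coordinates, equilibria, prediction, majority simulated
#'   outcome, agreement) and the overall `concordance` fraction.
#' @export
local_theory_concordance <- function(n_points = 40L, seeds_per_point = 10L,
                                     x_range = c(-2, 1),
                                     y_range = c(-2.5, 0.5),
                                     B_ref = 0.5, N = 30L,
                                     max_steps = 4000L,
                                     band_S1 = 0.35, band_I1 = 0.25,
                                     seed = 101L) {
  set.seed(seed)
  K <- 9
  pts <- data.frame()
  while (nrow(pts) < n_points) {
    x <- runif(1, x_range[1], x_range[2])
    y <- runif(1, y_range[1], y_range[2])
    S1 <- 10^y * K
    xr <- 10^x
    I1 <- K * xr / (xr + 1) * (1 - 10^y)
    if (abs(log10(S1)) < band_S1) next
    if (I1 > 0 && abs(log10(I1)) < band_I1) next
    pts <- rbind(pts, data.frame(x = x, y = y, S1 = S1, I1 = I1))
  }
  map_label <- function(lab) switch(
    lab,
    CELL_EXTINCTION_PRE_BOUNDARY = ,
    CELL_EXTINCTION_POST_BOUNDARY = "TARGET_EXTINCTION_OR_CONTROLLED",
    COEXISTENCE = "COEXISTENCE_PREDICTED",
    "VIRUS_LOSS_PREDICTED")
  init <- init_condition("nested_squares", 5, 13)
  out <- lapply(seq_len(nrow(pts)), function(i) {
    x <- pts$x[i]; y <- pts$y[i]
    pred <- predict_outcome(ode_params(R = B_ref * 10^x, B = B_ref,
                                       A = B_ref * 10^y, K = K))$prediction
    labs <- vapply(seq_len(seeds_per_point), function(s) {
      p <- lattice_params(R = B_ref * 10^x, D = 0, B = B_ref,
                          A = B_ref * 10^y, N = N, max_steps = max_steps,
                          seed = derive_seed(seed, i, s))
      as.character(classify_outcome(run_lattice(p, init,
                                                keep_snapshots = FALSE)))
    }, character(1))
    majority <- names(sort(table(labs), decreasing = TRUE))[1]
    data.frame(prediction = pred, majority = majority,
               majority_mapped = map_label(majority),
               agree = map_label(majority) == pred)
  })
  points <- cbind(pts, do.call(rbind, out))
  structure(list(points = points, concordance = mean(points$agree),
                 n_points = n_points, seeds_per_point = seeds_per_point),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf(
    "Local-theory concordance: %.1f%% over %d points (%d seeds each)\n",
    100 * x$concordance, x$n_points, x$seeds_per_point))
  invisible(x)
}
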