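# Monte-Carlo mapping of long-run outcomes over parameter space, with the
# analytic overlay lines of the local theory (S1 = 1 white, I1 = 1 black,
# numeric invasion threshold yellow, H = 1 green).

#' Configuration of a phase-diagram scan
#'
#' The scan axes are the rate ratios `log10(R/B)` and `log10(A/B)` (lattice)
#' or `log10(r/beta)` and `log10(a/beta)` (metapopulation), with the
#' transmission rate held at a reference value: at `D = 0` all analytic loci
#' depend only on these ratios, and a common scaling of the rates changes
#' only the time scale.
#'
#' @param model `"lattice"` or `"metapop"`.
#' @param x_range,y_range axis ranges (`log10` of the ratios).
#' @param resolution points per axis (>= 2).
#' @param replicates stochastic replicates per grid point.
#' @param B_ref reference transmission rate (`beta` for the metapopulation).
#' @param N lattice side (lattice model).
#' @param max_steps lattice step budget per run.
#' @param infected_side,susceptible_side lattice initial squares (the
#'   nested-squares scheme).
#' @param n,k,t_max,m metapopulation geometry, capacity, horizon, migration.
#' @param gamma invasion fold-change used in outcome classification.
#' @param seed master seed; per-point, per-replicate seeds are derived
#'   deterministically from it.
#' @return Object of class `scan_config`.
#' @export
scan_config <- function(model = c("lattice", "metapop"),
                        x_range = c(-4, 4), y_range = c(-4, 4),
                        resolution = 12L, replicates = 10L,
                        B_ref = 0.5, N = 30L, max_steps = 5000L,
                        infected_side = 5L, susceptible_side = 13L,
                        n = 51L, k = 100, t_max = 150, m = 1,
                        gamma = 4, seed = 1L) {
  model <- match.arg(model)
  stopifnot(resolution >= 2, replicates >= 1,
            all(is.finite(c(x_range, y_range))), B_ref > 0)
  structure(list(model = model, x_range = x_range, y_range = y_range,
                 resolution = as.integer(resolution),
                 replicates = as.integer(replicates), B_ref = B_ref,
                 N = as.integer(N), max_steps = as.integer(max_steps),
                 infected_side = as.integer(infected_side),
                 susceptible_side = as.integer(susceptible_side),
                 n = as.integer(n), k = k, t_max = t_max, m = m,
                 gamma = gamma, seed = as.integer(seed)),
            class = "scan_config")
}

# deterministic per-point, per-replicate seed below 2^31
derive_seed <- function(master, point, rep) {
  as.integer((as.double(master) * 48271 + point * 1117 + rep * 7) %%
               2147483629)
}

# one simulation at a ratio point (x = log10(R/B), y = log10(A/B));
# returns the outcome label and the invasion flag
scan_point_label <- function(cfg, x, y, seed) {
  lab <- if (cfg$model == "lattice") {
    p <- lattice_params(R = cfg$B_ref * 10^x, D = 0, B = cfg$B_ref,
                        A = cfg$B_ref * 10^y, N = cfg$N,
                        max_steps = cfg$max_steps, seed = seed)
    run <- run_lattice(p, init_condition("nested_squares",
                                         cfg$infected_side,
                                         cfg$susceptible_side),
                       keep_snapshots = FALSE)
    classify_outcome(run, gamma = cfg$gamma)
  } else {
    p <- metapop_params(r = cfg$B_ref * 10^x, beta = cfg$B_ref,
                        a = cfg$B_ref * 10^y, k = cfg$k,
                        m_S = cfg$m, n = cfg$n, t_max = cfg$t_max,
                        seed = seed)
    run <- simulate_metapop(p)
    classify_metapop_outcome(run, gamma = cfg$gamma)
  }
  list(label = as.character(lab), invaded = isTRUE(attr(lab, "invaded")))
}

#' Run a Monte-Carlo phase-diagram scan
#'
#' For each point of the axis grid, runs `replicates` simulations of the
#' chosen model from its standard initial condition, classifies each
#' outcome, and tallies the labels. Deterministic given `cfg$seed`.
#'
#' @param cfg a [scan_config()] object.
#' @return Object of class `phase_diagram`: data frame `points` with the
#'   axis coordinates, per-label tallies and the `majority` label, plus the
#'   analytic `lines` sampled on the same axes (see [analytic_lines()]).
#' @export
phase_scan <- function(cfg) {
  stopifnot(inherits(cfg, "scan_config"))
  xs <- seq(cfg$x_range[1], cfg$x_range[2], length.out = cfg$resolution)
  ys <- seq(cfg$y_range[1], cfg$y_range[2], length.out = cfg$resolution)
  grid <- expand.grid(x = xs, y = ys)
  labels_at <- function(i) {
    vapply(seq_len(cfg$replicates), function(rep) {
      scan_point_label(cfg, grid$x[i], grid$y[i],
                       derive_seed(cfg$seed, i, rep))$label
    }, character(1))
  }
  all_levels <- if (cfg$model == "lattice")
    c("CELL_EXTINCTION_PRE_BOUNDARY", "CELL_EXTINCTION_POST_BOUNDARY",
      "COEXISTENCE", "VIRUS_EXTINCTION_AFTER_INVASION",
      "VIRUS_EXTINCTION_NO_INVASION")
  else c("MA", "MB", "MB1", "MC", "MD", "ME")
  tallies <- t(vapply(seq_len(nrow(grid)), function(i) {
    tab <- table(factor(labels_at(i), levels = all_levels))
    as.integer(tab)
  }, integer(length(all_levels))))
  colnames(tallies) <- all_levels
  majority <- all_levels[max.col(tallies, ties.method = "first")]
  points <- cbind(grid, as.data.frame(tallies), majority = majority,
                  stringsAsFactors = FALSE)
  K <- if (cfg$model == "lattice") 9 else cfg$k
  structure(list(points = points,
                 lines = analytic_lines(K, xs, model = cfg$model, p = cfg),
                 config = cfg),
            class = "phase_diagram")
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat(sprintf("Phase diagram (%s): %d points x %d replicates\n",
              x$config$model, nrow(x$points), x$config$replicates))
  print(table(x$points$majority))
  invisible(x)
}

#' Analytic overlay lines of the phase diagram
#'
#' Loci in the `(log10(R/B), log10(A/B))` plane, from the local-theory
#' closed forms at `D = 0`:
#' * white: `S1 = 1`, i.e. `A/B = 1/K` — a horizontal line;
#' * black: `I1 = 1`, i.e. `A/B = 1 - (R/B + 1)/(K * R/B)` (only where the
#'   right-hand side is positive);
#' * green (metapopulation only): `H = 1`, i.e. `a/beta = 1/k - r/beta`
#'   (symmetric migration).
#'
#' @param K neighborhood capacity (9 for the lattice) or patch capacity.
#' @param xs values of the first axis (`log10(R/B)`) to sample.
#' @param model `"lattice"` or `"metapop"` (adds the green line).
#' @param p optional config (unused placeholder for future asymmetric
#'   migration).
#' @return Data frame `x, white, black, green` of `log10(A/B)` values
#'   (`NA` where a locus does not exist).
#' @export
analytic_lines <- function(K, xs, model = c("lattice", "metapop"),
                           p = NULL) {
  model <- match.arg(model)
  safe_log10 <- function(v) {
    out <- rep(NA_real_, length(v))
    out[v > 0] <- log10(v[v > 0])
    out
  }
  white <- rep(log10(1 / K), length(xs))
  ratio_RB <- 10^xs
  black <- safe_log10(1 - (ratio_RB + 1) / (K * ratio_RB))
  green <- if (model == "metapop") safe_log10(1 / K - ratio_RB)
           else rep(NA_real_, length(xs))
  data.frame(x = xs, white = white, black = black, green = green)
}

#' Numeric invasion threshold (the yellow line)
#'
#' For each value of `log10(R/B)`, bisects along `log10(A/B)` for the
#' smallest ratio at which the invasion frequency (fraction of replicates in
#' which the infected population grows at least `gamma`-fold) drops below
#' `p_inv`. Stochastic extinction can only hurt the virus, so the numeric
#' threshold lies at or below the deterministic `A = B` locus.
#'
#' @param cfg a [scan_config()] object (`replicates` should be >= 20).
#' @param xs first-axis values to probe (defaults to the config grid).
#' @param p_inv invasion-frequency threshold (default 0.05).
#' @param y_lo,y_hi bisection bracket in `log10(A/B)`.
#' @param tol bisection tolerance on `log10(A/B)`.
#' @return Data frame `x, y` sampling the yellow line (`y` is `NA` for
#'   probe values where the bracket does not straddle the threshold).
#' @export
invasion_line <- function(cfg, xs = NULL, p_inv = 0.05,
                          y_lo = -3, y_hi = 1.5, tol = 0.05) {
  stopifnot(inherits(cfg, "scan_config"))
  if (is.null(xs))
    xs <- seq(cfg$x_range[1], cfg$x_range[2],
              length.out = cfg$resolution)
  inv_freq <- function(x, y, salt) {
    mean(vapply(seq_len(cfg$replicates), function(rep) {
      as.numeric(scan_point_label(cfg, x, y,
                                  derive_seed(cfg$seed, salt, rep))$invaded)
    }, numeric(1)))
  }
  ys <- vapply(seq_along(xs), function(i) {
    lo <- y_lo; hi <- y_hi
    f_lo <- inv_freq(xs[i], lo, 10000 + i)
    f_hi <- inv_freq(xs[i], hi, 20000 + i)
    if (!(f_lo >= p_inv && f_hi < p_inv)) return(NA_real_)
    it <- 0L
    while (hi - lo > tol && it < 20L) {
      mid <- (lo + hi) / 2
      f <- inv_freq(xs[i], mid, 30000 + i + 100L * it)
      if (f >= p_inv) lo <- mid else hi <- mid
      it <- it + 1L
    }
    (lo + hi) / 2
  }, numeric(1))
  data.frame(x = xs, y = ys)
}
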