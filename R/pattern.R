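# Quantification and classification of emergent spatial patterns and of the
# quadratic/linear growth laws of the infected-cell population.

#' Default thresholds of the pattern classifier
#'
#' `theta_detect`: minimum infected fraction for an annulus to count as part
#' of the infected region; `theta_hollow`: maximum core occupancy (S + I) for
#' a hollow ring; `theta_filled`: minimum core susceptible fraction for a
#' filled ring; `theta_sparse`: maximum core infected fraction for a filled
#' ring; `theta_mix`: minimum fraction of each population for the disperse
#' (interspersed) call; `width`: annulus width in spots.
#' @export
pattern_thresholds <- function(theta_detect = 0.05, theta_hollow = 0.2,
                               theta_filled = 0.5, theta_sparse = 0.2,
                               theta_mix = 0.15, width = 3L) {
  list(theta_detect = theta_detect, theta_hollow = theta_hollow,
       theta_filled = theta_filled, theta_sparse = theta_sparse,
       theta_mix = theta_mix, width = as.integer(width))
}

#' Radial occupancy profile of a lattice snapshot
#'
#' Bins the grid into concentric annuli of fixed width around `center` and
#' reports the fraction of empty, susceptible and infected spots in each
#' annulus (the three fractions sum to one). Also locates `r_out`, the outer
#' radius of the infected region: the outer edge of the farthest annulus
#' whose infected fraction exceeds `theta_detect` (`NA` when no annulus
#' qualifies).
#'
#' @param snapshot integer matrix over `GRID_STATES`.
#' @param center numeric `(row, col)`; defaults to the grid midpoint.
#' @param width annulus width in spots.
#' @param theta_detect detection threshold for the infected rim.
#' @return List with the per-annulus data frame `profile`
#'   (`r_in, r_out, n, f_empty, f_S, f_I`), `r_out` and `center`.
#' @examples
#' g <- matrix(1L, 41, 41)
#' prof <- radial_profile(g)
#' all(prof$profile$f_S == 1)
#' @export
radial_profile <- function(snapshot, center = NULL, width = 3L,
                           theta_detect = 0.05) {
  stopifnot(is.matrix(snapshot), length(snapshot) > 0)
  N <- nrow(snapshot); M <- ncol(snapshot)
  if (is.null(center)) center <- c((N + 1) / 2, (M + 1) / 2)
  if (center[1] < 1 || center[1] > N || center[2] < 1 || center[2] > M)
    stop("center must lie inside the grid")
  d <- sqrt(outer((seq_len(N) - center[1])^2,
                  (seq_len(M) - center[2])^2, "+"))
  band <- floor(d / width)
  st <- as.vector(snapshot)
  bandv <- as.vector(band)
  bands <- sort(unique(bandv))
  n <- tabulate(match(bandv, bands))
  frac <- function(code) {
    cnt <- tapply(st == code, bandv, sum)
    as.numeric(cnt) / n
  }
  profile <- data.frame(
    r_in = bands * width, r_out = (bands + 1) * width, n = n,
    f_empty = frac(GRID_STATES[["EMPTY"]]),
    f_S = frac(GRID_STATES[["SUSCEPTIBLE"]]),
    f_I = frac(GRID_STATES[["INFECTED"]]))
  inf_bands <- which(profile$f_I > theta_detect)
  r_out <- if (length(inf_bands)) profile$r_out[max(inf_bands)] else NA_real_
  list(profile = profile, r_out = r_out, center = center)
}

#' Centroid of the infected cells of a snapshot
#' @param snapshot integer matrix over `GRID_STATES`.
#' @return `(row, col)` centroid, or `NULL` if no infected cells.
#' @export
infected_centroid <- function(snapshot) {
  idx <- which(snapshot == GRID_STATES[["INFECTED"]], arr.ind = TRUE)
  if (nrow(idx) == 0) return(NULL)
  c(mean(idx[, 1]), mean(idx[, 2]))
}

#' Classify the spatial pattern of a snapshot sequence
#'
#' Applies decision rules to the radial profile of the final snapshot, with
#' the center held fixed at the infected centroid of the first snapshot (the
#' founder region). The labels follow the experimentally observed plaque
#' morphologies:
#' \describe{
#' \item{HOLLOW_RING}{an infected rim enclosing a core emptied of cells
#'   (occupancy below `theta_hollow`).}
#' \item{FILLED_RING}{an infected rim enclosing a core dominated by
#'   surviving uninfected cells.}
#' \item{CONCENTRIC_RINGS}{two or more disjoint infected annuli separated by
#'   a susceptible or empty annulus.}
#' \item{DISPERSE}{infected and uninfected cells interspersed throughout the
#'   infected region, with no rim/core contrast.}
#' \item{SOLID_MASS}{a filled, predominantly infected region (the early
#'   stage before a hollow ring forms).}
#' \item{EXTINCT}{no infected cells in the final snapshot.}
#' }
#'
#' @param snapshots list of grid matrices, ordered in time (a single matrix
#'   is accepted).
#' @param thresholds see [pattern_thresholds()].
#' @return List of class `pattern_label` with `label` and the `evidence`
#'   (radial summary statistics used for the call).
#' @export
classify_pattern <- function(snapshots, thresholds = pattern_thresholds()) {
  if (is.matrix(snapshots)) snapshots <- list(snapshots)
  if (length(snapshots) == 0) stop("at least one snapshot is required")
  th <- thresholds
  center <- NULL
  for (g in snapshots) {            # founder centroid: first snapshot with I
    center <- infected_centroid(g)
    if (!is.null(center)) break
  }
  final <- snapshots[[length(snapshots)]]
  if (is.null(center) ||
      !any(final == GRID_STATES[["INFECTED"]])) {
    return(structure(list(label = "EXTINCT", evidence = NULL),
                     class = "pattern_label"))
  }
  rp <- radial_profile(final, center = center, width = th$width,
                       theta_detect = th$theta_detect)
  prof <- rp$profile
  r_out <- rp$r_out
  if (is.na(r_out)) {
    # infected cells exist but are too sparse for any annulus to pass the
    # detection threshold: take the farthest annulus holding any infection
    r_out <- max(prof$r_out[prof$f_I > 0])
  }

  # interior annuli: everything inside the infected region
  inside <- prof$r_out <= r_out
  # core: inner half of the infected region (by radius), at least one annulus
  core <- prof$r_out <= max(r_out / 2, prof$r_out[1])
  # rim: outer quarter of the infected region (at least its last annulus)
  rim <- inside & prof$r_in >= 0.75 * r_out
  if (!any(rim)) rim <- inside & prof$r_out == r_out
  wcore <- prof$n[core]
  core_S <- sum(prof$f_S[core] * wcore) / sum(wcore)
  core_I <- sum(prof$f_I[core] * wcore) / sum(wcore)
  core_occ <- core_S + core_I
  win <- prof$n[inside]
  in_S <- sum(prof$f_S[inside] * win) / sum(win)
  in_I <- sum(prof$f_I[inside] * win) / sum(win)
  wrim <- prof$n[rim]
  rim_I <- sum(prof$f_I[rim] * wrim) / sum(wrim)
  # a genuine rim concentrates infection relative to the core
  has_rim <- rim_I > th$theta_detect && rim_I >= 2 * core_I

  # disjoint infected annuli (concentric rings): rings are separated only
  # by annuli whose infected fraction is well below the detection level (a
  # genuine susceptible/empty wake, not a noisy dip), and each ring must
  # carry a non-trivial share of the infected cells (stray cells must not
  # split a ring)
  fI_in <- prof$f_I[inside]
  gap <- fI_in < th$theta_detect / 2
  runs <- rle(!gap)
  ring_mass <- numeric(0)
  if (any(runs$values)) {
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    mass <- fI_in * prof$n[inside]
    keep_run <- which(runs$values)
    ring_mass <- vapply(keep_run, function(j) {
      idx <- starts[j]:ends[j]
      if (any(fI_in[idx] > th$theta_detect)) sum(mass[idx]) else 0
    }, numeric(1))
  }
  n_rings <- sum(ring_mass >= 0.05 * sum(prof$f_I * prof$n))

  evidence <- list(r_out = r_out, core_S = core_S, core_I = core_I,
                   core_occupancy = core_occ, inside_S = in_S,
                   inside_I = in_I, rim_I = rim_I, has_rim = has_rim,
                   n_rings = n_rings, center = center, thresholds = th)

  label <-
    if (n_rings >= 2) "CONCENTRIC_RINGS"
    else if (core_occ < th$theta_hollow) "HOLLOW_RING"
    else if (has_rim && core_S > th$theta_filled &&
             core_I < th$theta_sparse) "FILLED_RING"
    else if (in_S > th$theta_mix && in_I > th$theta_mix) "DISPERSE"
    else if (core_I > th$theta_filled) "SOLID_MASS"
    else "DISPERSE"
  structure(list(label = label, evidence = evidence),
            class = "pattern_label")
}

#' @export
print.pattern_label <- function(x, ...) {
  cat("Pattern:", x$label, "\n")
  if (!is.null(x$evidence))
    cat(sprintf(
      "  r_out = %.1f, core S/I/occ = %.2f/%.2f/%.2f, rings = %d\n",
      x$evidence$r_out, x$evidence$core_S, x$evidence$core_I,
      x$evidence$core_occupancy, x$evidence$n_rings))
  invisible(x)
}

#' Growth law of an infected-cell time series
#'
#' Distinguishes quadratic ("surface") growth, the signature of a compact
#' expanding infected mass where only the rim grows, from linear growth, the
#' signature of an expanding hollow ring of constant thickness. Fits
#' `sqrt(I)` linear in `t` (quadratic law) and `I` linear in `t` over the
#' whole series, and a changepoint model that is quadratic before and linear
#' after a transition time; all residuals are compared on the `I` scale.
#' The mixed law is preferred only when it reduces the summed squared
#' residuals of the best single law by more than 10 percent (ring formation:
#' quadratic early, linear late).
#'
#' @param ts a [population_ts()] data frame (or any data frame with `t`, `I`).
#' @param min_points minimum number of points with `I > 0`.
#' @return List of class `growth_law_result` with `law` in
#'   `QUADRATIC, LINEAR, MIXED_QUAD_THEN_LINEAR, NONE`, the changepoint
#'   `t_change` (for the mixed law), goodness-of-fit `r2` per candidate and
#'   the residual sums `ss`.
#' @examples
#' tt <- 1:60
#' growth_law(population_ts(tt, rep(0, 60), (3 * tt)^2))$law
#' @export
growth_law <- function(ts, min_points = 5L) {
  t <- ts$t; I <- ts$I
  keep <- I > 0
  if (sum(keep) < min_points) {
    return(structure(list(law = "NONE", t_change = NA_real_,
                          r2 = c(quadratic = NA, linear = NA),
                          ss = c(quadratic = NA, linear = NA, mixed = NA)),
                     class = "growth_law_result"))
  }
  t <- t[keep]; I <- I[keep]
  # the growth law describes the expansion phase: when the founder region
  # partially dies off before expansion takes over, start at the minimum
  imin <- which.min(I)
  if (imin > 1 && imin <= length(I) - min_points + 1) {
    t <- t[imin:length(t)]; I <- I[imin:length(I)]
  }
  n <- length(t)

  ss_of <- function(pred) sum((I - pred)^2)
  r2_of <- function(y, pred) {
    tot <- sum((y - mean(y))^2)
    if (tot == 0) return(1)
    max(0, min(1, 1 - sum((y - pred)^2) / tot))
  }

  fit_quad <- lm(sqrt(I) ~ t)
  pred_quad <- pmax(0, fitted(fit_quad))^2
  fit_lin <- lm(I ~ t)
  pred_lin <- fitted(fit_lin)
  ss <- c(quadratic = ss_of(pred_quad), linear = ss_of(pred_lin))
  r2 <- c(quadratic = r2_of(sqrt(I), fitted(fit_quad)),
          linear = r2_of(I, pred_lin))

  # changepoint scan: quadratic on [1, cp], linear on [cp, n]
  best_cp <- NA_real_; ss_mixed <- Inf
  if (n >= 8) {
    for (cp in 4:(n - 3)) {
      i1 <- 1:cp; i2 <- cp:n
      f1 <- lm(sqrt(I[i1]) ~ t[i1])
      f2 <- lm(I[i2] ~ t[i2])
      s <- ss_of_segments(I, i1, i2, pmax(0, fitted(f1))^2, fitted(f2))
      if (s < ss_mixed) { ss_mixed <- s; best_cp <- t[cp] }
    }
  }
  ss <- c(ss, mixed = ss_mixed)

  best_single <- names(ss)[which.min(ss[1:2])]
  law <- if (is.finite(ss_mixed) && ss_mixed < 0.9 * min(ss[1:2]))
    "MIXED_QUAD_THEN_LINEAR"
  else if (best_single == "quadratic") "QUADRATIC" else "LINEAR"
  structure(list(law = law,
                 t_change = if (law == "MIXED_QUAD_THEN_LINEAR") best_cp
                            else NA_real_,
                 r2 = r2, ss = ss),
            class = "growth_law_result")
}

# residuals of a two-segment fit on the I scale; the changepoint row belongs
# to both segments, count it once (second segment)
ss_of_segments <- function(I, i1, i2, pred1, pred2) {
  sum((I[i1[-length(i1)]] - pred1[-length(pred1)])^2) +
    sum((I[i2] - pred2)^2)
}

#' @export
print.growth_law_result <- function(x, ...) {
  cat("Growth law:", x$law)
  if (!is.na(x$t_change)) cat(sprintf(" (changepoint at t = %g)", x$t_change))
  cat("\n")
  invisible(x)
}

#' Classify the long-run outcome of a lattice run
#'
#' Maps the termination reason, the boundary-contact flag and the invasion
#' flag onto the outcome regimes of the phase diagram:
#' \describe{
#' \item{CELL_EXTINCTION_PRE_BOUNDARY}{both populations extinct before any
#'   cell reached the grid boundary (virus-mediated extinction).}
#' \item{CELL_EXTINCTION_POST_BOUNDARY}{extinction after boundary contact
#'   (boundary-mediated extinction: the cell wave could no longer escape).}
#' \item{COEXISTENCE}{both populations alive at `max_steps`.}
#' \item{VIRUS_EXTINCTION_AFTER_INVASION}{virus extinct, cells persist, the
#'   infected population had grown at least `gamma`-fold.}
#' \item{VIRUS_EXTINCTION_NO_INVASION}{virus extinct without ever invading.}
#' }
#' The invasion flag is `max_t n_I(t) >= gamma * n_I(0)`.
#'
#' @param run a `lattice_run`.
#' @param gamma invasion fold-change criterion (default 4).
#' @return Character outcome label with attribute `invaded`.
#' @export
classify_outcome <- function(run, gamma = 4) {
  stopifnot(inherits(run, "lattice_run"))
  ts <- run$ts
  last <- ts[nrow(ts), ]
  I0 <- ts$n_I[1]
  invaded <- I0 > 0 && run$max_I >= gamma * I0
  label <-
    if (run$termination == "CELLS_EXTINCT" ||
        (last$n_S == 0 && last$n_I > 0)) {
      if (last$boundary_contacted) "CELL_EXTINCTION_POST_BOUNDARY"
      else "CELL_EXTINCTION_PRE_BOUNDARY"
    } else if (run$termination == "VIRUS_EXTINCT") {
      if (invaded) "VIRUS_EXTINCTION_AFTER_INVASION"
      else "VIRUS_EXTINCTION_NO_INVASION"
    } else "COEXISTENCE"
  attr(label, "invaded") <- invaded
  label
}
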