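# Reaction-diffusion (PDE) layer for the metapopulation model: pulled-front
# wave speeds, the co-moving target-cell front density H and its H = 1
# criterion, and empirical front-speed measurement from patch profiles.

#' Diffusion coefficient implied by a migration rate
#'
#' Under the symmetric migration convention (rate `m/2` to each neighbor,
#' total outflow `m` per cell) the continuum limit of the hopping process is
#' diffusion with coefficient `D = m * h^2 / 2`, where `h` is the patch
#' spacing.
#'
#' @param m migration rate (total outflow per cell).
#' @param h patch spacing.
#' @return Diffusion coefficient (length^2 per time).
#' @examples
#' diffusion_from_migration(2, 1)  # 1
#' @export
diffusion_from_migration <- function(m, h = 1) {
  stopifnot(m >= 0, h >= 0)
  m * h^2 / 2
}

#' Pulled-front wave speeds of the uninfected and infected waves
#'
#' Linear-spreading (Fisher/KPP) estimates. The uninfected wave advances
#' into empty space with leading-edge growth rate `r - d`, giving
#' `v_S = 2*sqrt(D_S*(r - d))`. The infected wave advances into a medium
#' holding `S_front` target cells per patch with leading-edge growth rate
#' `beta*S_front/k - a`, giving `v_I = 2*sqrt(D_I*(beta*S_front/k - a))`;
#' the speed is zero when the argument is not positive (the infection cannot
#' advance), and is monotone increasing in the target density ahead of the
#' front.
#'
#' @param p a [metapop_params()] object.
#' @param S_front target-cell density ahead of the infected front
#'   (cells per patch, in `[0, k]`); default `k`.
#' @return List of class `wave_estimates` with `v_S, v_I, D_S, D_I,
#'   S_front`.
#' @export
front_speeds <- function(p, S_front = p$k) {
  stopifnot(inherits(p, "metapop_params"),
            S_front >= 0, S_front <= p$k)
  D_S <- diffusion_from_migration(p$m_S, p$h)
  D_I <- diffusion_from_migration(p$m_I, p$h)
  gS <- p$r - p$d
  gI <- p$beta * S_front / p$k - p$a
  structure(list(
    v_S = if (gS > 0) 2 * sqrt(D_S * gS) else 0,
    v_I = if (gI > 0) 2 * sqrt(D_I * gI) else 0,
    D_S = D_S, D_I = D_I, S_front = S_front),
    class = "wave_estimates")
}

#' @export
print.wave_estimates <- function(x, ...) {
  cat(sprintf("v_S = %.4g, v_I(S_front = %g) = %.4g  (D_S = %g, D_I = %g)\n",
              x$v_S, x$S_front, x$v_I, x$D_S, x$D_I))
  invisible(x)
}

#' Co-moving target-cell front density H
#'
#' When the infected wave catches up with the uninfected wave, it depresses
#' the target density at the front until the two waves move at the same
#' speed. Equating the linear-spreading speeds `v_S = v_I` yields the
#' density of target cells carried by the co-moving front:
#' `H = k*(a + (r - d)*D_S/D_I)/beta`, which reduces to
#' `H = k*(a + r)/beta` in the symmetric case `D_S = D_I`, `d = 0`.
#' `H < 1` (fewer than one target cell per patch at the front) marks the
#' regime in which the virus destroys the target-cell wave outright
#' (virus-mediated extinction); `H > 1` marks co-traveling waves that die
#' only at the boundary.
#'
#' @param p a [metapop_params()] object (`beta > 0` required).
#' @return List of class `co_moving_density` with `H` and `H_lt_1`.
#' @examples
#' p <- metapop_params(r = .01, beta = 2, a = .01, k = 100)
#' co_moving_density(p)$H  # 1: exactly on the regime boundary
#' @export
co_moving_density <- function(p) {
  stopifnot(inherits(p, "metapop_params"))
  if (p$beta <= 0) stop("H is undefined for beta = 0")
  D_S <- diffusion_from_migration(p$m_S, p$h)
  D_I <- diffusion_from_migration(p$m_I, p$h)
  if (D_I <= 0) stop("H is undefined for m_I = 0")
  H <- p$k * (p$a + (p$r - p$d) * D_S / D_I) / p$beta
  structure(list(H = H, H_lt_1 = H < 1, D_S = D_S, D_I = D_I),
            class = "co_moving_density")
}

#' Measure a front speed from patch profiles
#'
#' Tracks the front position over time as the outermost patch (to the right
#' of the domain middle by default) where the chosen population is at least
#' `threshold`, refined by linear interpolation between that patch and its
#' neighbor, and fits position against time by least squares.
#'
#' @param profiles matrix of patch profiles, one row per time point.
#' @param times time of each row.
#' @param threshold detection level (cells per patch); the conventional
#'   half-capacity `k/2` tracks the mid-height of the front.
#' @param h patch spacing (converts patch index to length).
#' @param direction `"right"` or `"left"` of the domain middle.
#' @return List of class `front_speed` with `speed` (length per time),
#'   `r2` of the linear fit, and the tracked `positions`; `speed` is `NA`
#'   (with `detected = FALSE`) when fewer than three profiles show a front.
#' @export
measure_front_speed <- function(profiles, times, threshold, h = 1,
                                direction = c("right", "left")) {
  direction <- match.arg(direction)
  stopifnot(is.matrix(profiles), nrow(profiles) == length(times))
  n <- ncol(profiles)
  if (direction == "left") profiles <- profiles[, n:1, drop = FALSE]
  pos <- rep(NA_real_, length(times))
  for (i in seq_along(times)) {
    v <- profiles[i, ]
    above <- which(v >= threshold)
    if (!length(above)) next
    j <- max(above)
    pos[i] <-
      if (j < n && v[j] > v[j + 1])
        j + (v[j] - threshold) / (v[j] - v[j + 1])
      else j
  }
  ok <- !is.na(pos)
  if (sum(ok) < 3)
    return(structure(list(speed = NA_real_, r2 = NA_real_,
                          positions = pos, detected = FALSE),
                     class = "front_speed"))
  fit <- lm(pos[ok] ~ times[ok])
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(speed = unname(coef(fit)[2]) * h, r2 = r2,
                 positions = pos, detected = TRUE),
            class = "front_speed")
}

#' @export
print.front_speed <- function(x, ...) {
  if (x$detected)
    cat(sprintf("Front speed: %.4g (R^2 = %.3f)\n", x$speed, x$r2))
  else cat("No propagating front detected\n")
  invisible(x)
}
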