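# Mass-action ODE description of a local neighborhood, its equilibria and
# the local-theory outcome predictor.
#
#   dS/dt = R*S*(1 - (S + I)/K) - D*S - B*S*I/K
#   dI/dt = B*S*I/K - A*I
#
# With D = 0 the closed-form equilibria are S1 = A*K/B and
# I1 = R*K*(B - A)/(B*(R + B)); the coexistence equilibrium exists (and the
# virus invades) iff A < B, i.e. the basic reproductive ratio R0 = B/A > 1.

#' Parameters of the local mass-action ODE model
#'
#' Rates as in [lattice_params()] plus the carrying capacity `K` of the
#' local neighborhood. On the lattice a cell interacts with itself and its
#' eight Moore neighbors, so the characteristic local scale is `K = 9`.
#'
#' @param R,D,B,A rates (division, uninfected death, transmission, infected
#'   death).
#' @param K carrying capacity in cells (default 9).
#' @return Object of class `ode_params`.
#' @export
ode_params <- function(R, D = 0, B, A, K = 9) {
  stopifnot(R >= 0, D >= 0, B >= 0, A >= 0, K > 0)
  structure(list(R = R, D = D, B = B, A = A, K = K), class = "ode_params")
}

#' Right-hand side of the local ODE model
#'
#' @param S,I population sizes (cells), non-negative.
#' @param p an [ode_params()] object.
#' @return Numeric `c(dS, dI)`.
#' @examples
#' p <- ode_params(R = 0.014, B = 0.032, A = 0.008)
#' ode_rhs(p$K, 0, p)  # infection-free equilibrium
#' @export
ode_rhs <- function(S, I, p) {
  stopifnot(S >= 0, I >= 0)
  dS <- p$R * S * (1 - (S + I) / p$K) - p$D * S - p$B * S * I / p$K
  dI <- p$B * S * I / p$K - p$A * I
  c(dS = dS, dI = dI)
}

#' Equilibria, stability and basic reproductive ratio
#'
#' Computes the infection-free equilibrium `(K, 0)`, the coexistence
#' equilibrium `S1 = A*K/B`, `I1 = R*K*(B - A)/(B*(R + B))` (closed forms for
#' `D = 0`), the basic reproductive ratio `R0 = B/A`, and the stability type
#' of the coexistence equilibrium from the Jacobian eigenvalues: a stable
#' node (monotonic approach) when both eigenvalues are real and negative, a
#' stable spiral (damped oscillations) when they are complex with negative
#' real part.
#'
#' @param p an [ode_params()] object; the closed forms assume `D = 0`.
#' @return Object of class `ode_equilibria` with fields `S0, I0, S1, I1,
#'   R0, exists_coexistence, stability`.
#' @examples
#' eq <- ode_equilibria(ode_params(R = 0.014, B = 0.032, A = 0.008))
#' c(eq$S1, eq$I1)  # 2.25, 2.054
#' @export
ode_equilibria <- function(p) {
  stopifnot(inherits(p, "ode_params"))
  R0 <- if (p$A > 0) p$B / p$A else Inf
  exists <- p$B > 0 && p$A < p$B
  if (p$B > 0) {
    S1 <- p$A * p$K / p$B
    I1 <- p$R * p$K * (p$B - p$A) / (p$B * (p$R + p$B))
  } else {
    S1 <- NA_real_; I1 <- NA_real_
  }
  stability <- "N_A"
  if (exists && S1 > 0 && I1 > 0) {
    # Jacobian of (dS, dI) at (S1, I1), D = 0
    J11 <- p$R * (1 - (2 * S1 + I1) / p$K) - p$B * I1 / p$K
    J12 <- -p$R * S1 / p$K - p$B * S1 / p$K
    J21 <- p$B * I1 / p$K
    J22 <- p$B * S1 / p$K - p$A   # zero at the equilibrium
    tr <- J11 + J22
    det <- J11 * J22 - J12 * J21
    disc <- tr^2 - 4 * det
    stability <- if (det < 0 || tr > 0) "UNSTABLE"
      else if (disc >= 0) "STABLE_NODE" else "STABLE_SPIRAL"
  }
  structure(list(S0 = p$K, I0 = 0, S1 = S1, I1 = I1, R0 = R0,
                 exists_coexistence = exists, stability = stability,
                 params = p),
            class = "ode_equilibria")
}

#' @export
print.ode_equilibria <- function(x, ...) {
  cat(sprintf("Infection-free: (S, I) = (%g, 0)\n", x$S0))
  if (x$exists_coexistence)
    cat(sprintf("Coexistence: (S1, I1) = (%.4g, %.4g), %s\n",
                x$S1, x$I1, x$stability))
  else cat("No coexistence equilibrium (A >= B)\n")
  cat(sprintf("R0 = %.4g\n", x$R0))
  invisible(x)
}

#' Integrate the local ODE model
#'
#' Adaptive-step integration (lsoda) with non-negativity enforced to within
#' solver tolerance.
#'
#' @param p an [ode_params()] object.
#' @param S0,I0 non-negative initial conditions.
#' @param times output time grid.
#' @param rtol,atol solver tolerances.
#' @return Data frame `time, S, I`.
#' @export
ode_integrate <- function(p, S0, I0, times, rtol = 1e-8, atol = 1e-10) {
  stopifnot(S0 >= 0, I0 >= 0)
  rhs <- function(t, y, parms) {
    y <- pmax(y, 0)
    list(ode_rhs(y[1], y[2], p))
  }
  sol <- deSolve::ode(y = c(S = S0, I = I0), times = times, func = rhs,
                      parms = NULL, rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop("ODE solver failed: istate = ", attr(sol, "istate")[1])
  out <- as.data.frame(sol)
  out$S <- pmax(out$S, 0); out$I <- pmax(out$I, 0)
  out
}

#' Predict the global outcome of the spatial system from the local ODE
#'
#' The local-neighborhood theory: solve the mass-action model at the
#' neighborhood carrying capacity and read off the coexistence equilibrium.
#' If the local equilibrium of uninfected cells is below one cell
#' (`S1 < 1`), the spatial system is expected to show target-cell extinction
#' or low-level controlled persistence. If both local equilibria exceed one
#' cell, uncontrolled coexistence is expected. If the virus cannot invade
#' (`A >= B`) or invades but cannot sustain one infected cell locally
#' (`I1 < 1`), the virus is expected to die out.
#'
#' @param p an [ode_params()] object (`K = 9` for the lattice).
#' @return List of class `outcome_prediction` with `prediction` in
#'   `TARGET_EXTINCTION_OR_CONTROLLED, COEXISTENCE_PREDICTED,
#'   VIRUS_LOSS_PREDICTED` plus `S1, I1, R0`.
#' @examples
#' predict_outcome(ode_params(R = 0.014, B = 0.032, A = 0.008))$prediction
#' @export
predict_outcome <- function(p) {
  eq <- ode_equilibria(p)
  prediction <-
    if (!eq$exists_coexistence) "VIRUS_LOSS_PREDICTED"
    else if (eq$S1 < 1) "TARGET_EXTINCTION_OR_CONTROLLED"
    else if (eq$I1 > 1) "COEXISTENCE_PREDICTED"
    else "VIRUS_LOSS_PREDICTED"
  structure(list(prediction = prediction, S1 = eq$S1, I1 = eq$I1,
                 R0 = eq$R0, stability = eq$stability),
            class = "outcome_prediction")
}

#' @export
print.outcome_prediction <- function(x, ...) {
  cat(sprintf("Local-theory prediction: %s (S1 = %.3g, I1 = %.3g, R0 = %.3g)\n",
              x$prediction, x$S1, x$I1, x$R0))
  invisible(x)
}
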