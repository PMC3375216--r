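# Local mass-action ODE model: right-hand side, equilibria, stability,
# integration, outcome prediction.

test_that("rhs vanishes at both equilibria for random parameter draws", {
  set.seed(17)
  for (i in 1:200) {
    p <- ode_params(R = runif(1, 0.001, 2), B = runif(1, 0.001, 2),
                    A = runif(1, 0.001, 2), K = sample(c(4, 9, 100), 1))
    expect_equal(unname(ode_rhs(p$K, 0, p)), c(0, 0))
    eq <- ode_equilibria(p)
    if (eq$exists_coexistence) {
      expect_equal(unname(ode_rhs(eq$S1, eq$I1, p)), c(0, 0),
                   tolerance = 1e-12)
    }
  }
})

test_that("closed-form equilibria match the printed expressions", {
  eq <- ode_equilibria(ode_params(R = 0.014, B = 0.032, A = 0.008, K = 9))
  expect_equal(eq$S1, 2.25)
  expect_equal(eq$I1, 0.014 * 9 * (0.032 - 0.008) / (0.032 * 0.046))
  expect_equal(eq$I1, 2.0543, tolerance = 1e-4)
  expect_true(eq$exists_coexistence)
  expect_equal(eq$R0, 4)

  # degenerate boundary A = B and subthreshold A > B
  eq <- ode_equilibria(ode_params(R = 0.5, B = 0.3, A = 0.3))
  expect_equal(eq$I1, 0)
  expect_false(eq$exists_coexistence)
  eq <- ode_equilibria(ode_params(R = 0.5, B = 0.3, A = 0.4))
  expect_false(eq$exists_coexistence)
  expect_lt(eq$R0, 1)

  # A = 0: infinite reproductive ratio; B = 0: no coexistence branch
  expect_equal(ode_equilibria(ode_params(R = 1, B = 0.5, A = 0))$R0, Inf)
  expect_false(ode_equilibria(ode_params(R = 1, B = 0,
                                         A = 0.1))$exists_coexistence)
})

test_that("dS/dt = 0 on the S = 0 axis and infection decays there", {
  out <- ode_rhs(0, 3, ode_params(R = 1, B = 0.5, A = 0.2))
  expect_equal(unname(out), c(0, -0.2 * 3))
})

test_that("trajectories converge to the closed-form coexistence point", {
  p <- ode_params(R = 0.014, B = 0.032, A = 0.008, K = 9)
  eq <- ode_equilibria(p)
  tr <- ode_integrate(p, S0 = 8, I0 = 1, times = seq(0, 40000, by = 100))
  last <- tr[nrow(tr), ]
  expect_lt(abs(last$S - eq$S1) / eq$S1, 1e-3)
  expect_lt(abs(last$I - eq$I1) / eq$I1, 1e-3)
})

test_that("virus-free and subthreshold trajectories behave logistically", {
  p <- ode_params(R = 0.5, B = 0.4, A = 0.1, K = 9)
  tr <- ode_integrate(p, S0 = 0.5, I0 = 0, times = seq(0, 100, by = 1))
  expect_true(all(tr$I == 0))
  expect_true(all(diff(tr$S) >= -1e-9))
  expect_equal(tr$S[nrow(tr)], 9, tolerance = 1e-4)

  p <- ode_params(R = 0.5, B = 0.2, A = 0.4, K = 9)   # A > B
  tr <- ode_integrate(p, S0 = 4.5, I0 = 1, times = seq(0, 400, by = 1))
  expect_lt(tr$I[nrow(tr)], 1e-6)
  expect_equal(tr$S[nrow(tr)], 9, tolerance = 1e-3)
})

test_that("Jacobian stability type matches the approach seen in
           integration", {
  count_extrema <- function(x) {
    dx <- diff(x)
    sum(dx[-length(dx)] * dx[-1] < 0)
  }
  spiral <- ode_params(R = 0.014, B = 0.032, A = 0.008, K = 9)
  expect_equal(ode_equilibria(spiral)$stability, "STABLE_SPIRAL")
  tr <- ode_integrate(spiral, 8, 1, seq(0, 30000, by = 20))
  expect_gt(count_extrema(tr$I), 2)   # damped oscillations

  # a weakly invading virus approaches its equilibrium without oscillating
  node <- ode_params(R = 0.1, B = 0.5, A = 0.49, K = 9)
  expect_equal(ode_equilibria(node)$stability, "STABLE_NODE")
  tr <- ode_integrate(node, 8.9, 0.1, seq(0, 2000, by = 2))
  expect_lte(count_extrema(tr$I), 1)  # essentially monotone approach
})

test_that("the three-way outcome prediction follows the equilibria", {
  expect_equal(predict_outcome(ode_params(R = 1, B = 0.2,
                                          A = 0.5))$prediction,
               "VIRUS_LOSS_PREDICTED")
  expect_equal(predict_outcome(ode_params(R = 0.014, B = 0.032,
                                          A = 0.008))$prediction,
               "COEXISTENCE_PREDICTED")
  pr <- predict_outcome(ode_params(R = 1, B = 1, A = 0.05))
  expect_equal(pr$S1, 0.45)
  expect_equal(pr$prediction, "TARGET_EXTINCTION_OR_CONTROLLED")
  # invades but cannot hold one infected cell locally
  pr <- predict_outcome(ode_params(R = 0.0002, B = 0.019, A = 0.0032))
  expect_lt(pr$I1, 1)
  expect_equal(pr$prediction, "VIRUS_LOSS_PREDICTED")
})
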