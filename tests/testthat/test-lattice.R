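# Agent-based lattice model: initial conditions, update rule, conservation,
# determinism, absorbing states.

test_that("initial conditions place the documented cell counts", {
  p <- lattice_params(R = 0.5, B = 0.6, A = 0.62, N = 300)
  st <- init_lattice(p, full_init(30))
  expect_equal(sum(st$grid == 2L), 900)
  expect_equal(sum(st$grid == 1L), 89100)
  expect_equal(sum(st$grid == 0L), 0)
  expect_true(st$boundary_contacted)

  p <- lattice_params(R = 0.014, B = 0.032, A = 0.008, N = 30)
  st <- init_lattice(p, nested_init(5, 13))
  expect_equal(sum(st$grid == 2L), 25)
  expect_equal(sum(st$grid == 1L), 144)
  expect_equal(sum(st$grid == 0L), 731)
  expect_false(st$boundary_contacted)

  # degenerate: no infected square
  st <- init_lattice(p, full_init(0))
  expect_equal(sum(st$grid == 2L), 0)
  expect_equal(sum(st$grid == 1L), 900)

  # centered squares sit symmetric (shifted toward origin on parity clash)
  st <- init_lattice(lattice_params(R = 0, B = 0, A = 0, N = 10),
                     full_init(4))
  idx <- which(st$grid == 2L, arr.ind = TRUE)
  expect_equal(range(idx[, 1]), c(4, 7))
  st <- init_lattice(lattice_params(R = 0, B = 0, A = 0, N = 10),
                     full_init(5))
  idx <- which(st$grid == 2L, arr.ind = TRUE)
  expect_equal(range(idx[, 1]), c(3, 7))
})

test_that("inconsistent initial squares are rejected", {
  expect_error(init_condition("nested_squares", infected_side = 14,
                              susceptible_side = 13))
  p <- lattice_params(R = 0, B = 0, A = 0, N = 10)
  expect_error(init_lattice(p, full_init(11)), "exceeds")
})

test_that("an all-empty grid is absorbing", {
  p <- lattice_params(R = 1, B = 1, A = 0.5, N = 5, max_steps = 3, seed = 1)
  st <- init_lattice(p, init_condition("custom",
                                       custom_grid = matrix(0L, 5, 5)))
  st2 <- lattice_step(st, p, 3)
  expect_equal(sum(st2$grid), 0)
})

test_that("a lone infected cell with A = 1 survives one step with
           probability (1 - 1/N^2)^(N^2)", {
  N <- 4
  g <- matrix(0L, N, N); g[2, 2] <- 2L
  init <- init_condition("custom", custom_grid = g)
  p_expected <- (1 - 1 / N^2)^(N^2)
  n <- 20000
  set.seed(99)
  seeds <- sample.int(1e6, n)
  alive <- vapply(seq_len(n), function(i) {
    p <- lattice_params(R = 0, D = 0, B = 0, A = 1, N = N, max_steps = 1,
                        seed = seeds[i])
    run <- run_lattice(p, init, keep_snapshots = FALSE)
    run$ts$n_I[2] > 0
  }, logical(1))
  se <- sqrt(p_expected * (1 - p_expected) / n)
  expect_lt(abs(mean(alive) - p_expected), 5 * se)
})

test_that("population counts are conserved at every step", {
  run <- quick_run(R = 0.1, B = 0.3, A = 0.05, N = 20, steps = 200,
                   seed = 42, init = nested_init(3, 9), record_every = 50)
  expect_true(all(run$ts$n_S + run$ts$n_I + run$ts$n_empty == 400))
  # recount occupancy from the stored snapshots
  for (i in seq_along(run$snapshots)) {
    g <- run$snapshots[[i]]
    row <- run$ts[run$ts$t == run$snap_t[i], ]
    expect_equal(sum(g == 1L), row$n_S)
    expect_equal(sum(g == 2L), row$n_I)
  }
})

test_that("identical seeds give bit-identical runs, different seeds differ", {
  a <- quick_run(R = 0.2, B = 0.4, A = 0.1, N = 25, steps = 150, seed = 7,
                 init = nested_init())
  b <- quick_run(R = 0.2, B = 0.4, A = 0.1, N = 25, steps = 150, seed = 7,
                 init = nested_init())
  expect_identical(a$ts, b$ts)
  expect_identical(a$snapshots, b$snapshots)
  d <- quick_run(R = 0.2, B = 0.4, A = 0.1, N = 25, steps = 150, seed = 8,
                 init = nested_init())
  expect_false(identical(a$ts, d$ts))
})

test_that("virus cannot reappear after extinction and pure-death runs end
           VIRUS_EXTINCT", {
  run <- quick_run(R = 0.1, B = 0, A = 0.3, N = 15, steps = 500, seed = 3,
                   init = nested_init(3, 7), keep_snapshots = FALSE)
  expect_equal(run$termination, "VIRUS_EXTINCT")
  iext <- which(run$ts$n_I == 0)[1]
  expect_true(all(run$ts$n_I[iext:nrow(run$ts)] == 0))
})

test_that("growth-only dynamics fill the grid to N^2 (logistic filling)", {
  run <- quick_run(R = 0.5, B = 0, A = 0, N = 15, steps = 400, seed = 11,
                   init = nested_init(0, 5), keep_snapshots = FALSE)
  expect_true(all(diff(run$ts$n_S) >= 0))
  expect_equal(run$ts$n_S[nrow(run$ts)], 225)
})

test_that("one-step state distribution matches the exhaustive enumeration
           of the sampling process", {
  check_against_enumeration <- function(g, R, D, B, A, n = 50000) {
    exact <- enumerate_step_distribution(g, R, D, B, A)
    expect_equal(sum(exact), 1, tolerance = 1e-12)
    p <- lattice_params(R = R, D = D, B = B, A = A, N = nrow(g),
                        max_steps = 1)
    st0 <- init_lattice(p, init_condition("custom", custom_grid = g))
    keys <- vapply(seq_len(n), function(i) grid_key(lattice_step(st0,
                                                                 p)$grid),
                   character(1))
    emp <- table(keys) / n
    for (k in names(exact)[exact > 0.005]) {
      pe <- exact[[k]]
      pobs <- if (k %in% names(emp)) as.numeric(emp[[k]]) else 0
      expect_lt(abs(pobs - pe), 5 * sqrt(pe * (1 - pe) / n))
    }
  }
  set.seed(5)
  # infection and death micro-dynamics: infected center, one susceptible
  g <- matrix(0L, 3, 3); g[2, 2] <- 2L; g[1, 1] <- 1L
  check_against_enumeration(g, R = 0, D = 0.1, B = 0.6, A = 0.3)
  # division micro-dynamics: a lone corner cell
  g <- matrix(0L, 3, 3); g[1, 1] <- 1L
  check_against_enumeration(g, R = 0.5, D = 0.05, B = 0, A = 0)
})

test_that("scaling all weights by a common factor changes the time scale,
           not the emergent classification", {
  # matched expected event counts: 10x slower weights, 10x more steps
  lab <- function(c, steps) {
    labs <- vapply(1:3, function(s) {
      run <- quick_run(R = 0.014 * c, B = 0.032 * c, A = 0.008 * c,
                       N = 30, steps = steps, seed = 100 + s,
                       init = nested_init(), keep_snapshots = FALSE)
      as.character(classify_outcome(run))
    }, character(1))
    names(sort(table(labs), decreasing = TRUE))[1]
  }
  expect_equal(lab(1, 3000), lab(0.1, 30000))
})
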