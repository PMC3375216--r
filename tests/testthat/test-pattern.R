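# Radial profiles, spatial-pattern classification, growth laws, outcome
# labels.

test_that("radial profiles quantify constructed geometries", {
  g <- make_fixture("snapshot_hollow_ring", seed = 1,
                    params = list(N = 101, r1 = 10, r2 = 15))
  rp <- radial_profile(g)
  prof <- rp$profile
  # annuli fully inside the empty core / infected ring / susceptible field
  expect_gt(prof$f_empty[prof$r_out <= 9][1], 0.99)
  ring <- prof$r_in >= 10 & prof$r_out <= 15
  expect_true(all(prof$f_I[ring] > 0.9))
  outside <- prof$r_in >= 16 & prof$r_out <= 45
  expect_true(all(prof$f_S[outside] > 0.95))
  expect_true(rp$r_out >= 14 && rp$r_out <= 18)
  # fractions sum to one everywhere
  expect_equal(prof$f_empty + prof$f_S + prof$f_I, rep(1, nrow(prof)))

  uni <- matrix(1L, 41, 41)
  expect_true(all(radial_profile(uni)$profile$f_S == 1))
  expect_true(is.na(radial_profile(uni)$r_out))
})

test_that("geometric fixtures are labelled by their construction", {
  expect_equal(classify_pattern(make_fixture("snapshot_hollow_ring",
                                             seed = 2))$label,
               "HOLLOW_RING")
  expect_equal(classify_pattern(make_fixture("snapshot_filled_ring",
                                             seed = 2))$label,
               "FILLED_RING")
  expect_equal(classify_pattern(make_fixture("snapshot_disperse",
                                             seed = 2))$label,
               "DISPERSE")
  expect_equal(classify_pattern(make_fixture("snapshot_concentric",
                                             seed = 2))$label,
               "CONCENTRIC_RINGS")
})

test_that("pattern labels are invariant under rotation and reflection", {
  for (kind in c("snapshot_hollow_ring", "snapshot_filled_ring",
                 "snapshot_disperse")) {
    g <- make_fixture(kind, seed = 4)
    ref <- classify_pattern(g)$label
    rot90 <- t(g)[, nrow(g):1]
    expect_equal(classify_pattern(rot90)$label, ref)
    expect_equal(classify_pattern(g[nrow(g):1, ])$label, ref)
    expect_equal(classify_pattern(t(g))$label, ref)
  }
})

test_that("snapshots without infection are EXTINCT and empty input errors", {
  expect_equal(classify_pattern(matrix(1L, 21, 21))$label, "EXTINCT")
  expect_error(classify_pattern(list()))
})

test_that("exact growth laws are recognized", {
  tt <- 1:60
  expect_equal(growth_law(population_ts(tt, 0 * tt, (3 * tt)^2))$law,
               "QUADRATIC")
  expect_equal(growth_law(population_ts(tt, 0 * tt, 40 * tt))$law,
               "LINEAR")
  expect_equal(growth_law(population_ts(1:4, rep(0, 4), rep(0, 4)))$law,
               "NONE")
})

test_that("the mixed-law changepoint matches the brute-force scan", {
  tt <- 0:150
  I <- pmax(1, ifelse(tt < 50, tt^2, 2500 + 100 * (tt - 50)))
  gl <- growth_law(population_ts(tt, 0 * tt, I))
  expect_equal(gl$law, "MIXED_QUAD_THEN_LINEAR")
  oracle <- brute_force_changepoint(tt[I > 0], I[I > 0])
  expect_equal(gl$t_change, oracle$cp)
  expect_lt(abs(gl$t_change - 50), 5)
})

test_that("growth-law calls are invariant to count and time rescaling", {
  set.seed(31)
  tt <- 0:120
  cases <- list(
    quad = (10 + 0.4 * tt)^2 * exp(rnorm(121, 0, 0.05)),
    lin = pmax(1, 30 * tt * exp(rnorm(121, 0, 0.05))))
  for (I in cases) {
    base <- growth_law(population_ts(tt, 0 * tt, I))$law
    expect_equal(growth_law(population_ts(tt, 0 * tt, 17 * I))$law, base)
    expect_equal(growth_law(population_ts(tt * 3.5, 0 * tt, I))$law, base)
  }
})

test_that("goodness-of-fit values stay within [0, 1]", {
  set.seed(8)
  tt <- 1:40
  gl <- growth_law(population_ts(tt, 0 * tt, rpois(40, 50)))
  expect_true(all(gl$r2 >= 0 & gl$r2 <= 1, na.rm = TRUE))
})

test_that("outcome labels combine termination, boundary and invasion", {
  # strong virus, tiny grid: everything dies before reaching the boundary
  run <- quick_run(R = 0.001, B = 0.5, A = 0.005, N = 21, steps = 4000,
                   seed = 2, init = nested_init(5, 9),
                   keep_snapshots = FALSE)
  expect_equal(run$termination, "CELLS_EXTINCT")
  expect_equal(as.character(classify_outcome(run)),
               "CELL_EXTINCTION_PRE_BOUNDARY")

  # B = 0: virus dies without invading
  run <- quick_run(R = 0.1, B = 0, A = 0.2, N = 15, steps = 1000, seed = 2,
                   init = nested_init(3, 7), keep_snapshots = FALSE)
  lab <- classify_outcome(run)
  expect_equal(as.character(lab), "VIRUS_EXTINCTION_NO_INVASION")
  expect_false(attr(lab, "invaded"))

  # coexistence regime persists to the step budget
  run <- quick_run(R = 0.014, B = 0.032, A = 0.008, N = 30, steps = 3000,
                   seed = 5, init = nested_init(), keep_snapshots = FALSE)
  expect_equal(as.character(classify_outcome(run)), "COEXISTENCE")
})
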