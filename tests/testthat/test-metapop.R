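# Stochastic metapopulation model: initial conditions, Gillespie kernel
# bookkeeping, decoupling at m = 0, logistic behavior, outcome regimes.

test_that("the core initial condition reproduces the documented totals", {
  st <- init_metapop(metapop_params(r = .1, beta = 1, a = .1, k = 100,
                                    n = 101))
  expect_equal(sum(st$S), 1070)
  expect_equal(sum(st$I), 30)
  mid <- 51
  expect_equal(st$I[mid], 30)
  expect_equal(st$S[mid], 70)
  expect_true(all(st$S[c(mid - 5, mid + 5)] == 100))
  expect_true(all(st$S[c(mid - 6, mid + 6)] == 0))

  # the 11-patch core exactly fills a minimal domain
  st <- init_metapop(metapop_params(r = .1, beta = 1, a = .1, n = 11))
  expect_true(all(st$S + st$I > 0))
  expect_error(init_metapop(metapop_params(r = .1, beta = 1, a = .1,
                                           n = 9)))
})

test_that("an all-empty custom state is absorbing", {
  p <- metapop_params(r = 1, beta = 1, a = 1, n = 11, t_max = 10, seed = 1)
  st <- init_metapop(p, "custom", S = integer(11), I = integer(11))
  run <- simulate_metapop(p, st)
  expect_equal(run$termination, "CELLS_EXTINCT")
  expect_equal(sum(run$S) + sum(run$I), 0)
})

test_that("all-zero rates freeze the populations in place", {
  p <- metapop_params(r = 0, beta = 0, a = 0, d = 0, m_S = 0, n = 11,
                      t_max = 5, seed = 1)
  st <- init_metapop(p)
  run <- simulate_metapop(p, st)
  expect_equal(run$S, st$S)
  expect_equal(run$I, st$I)
})

test_that("incremental rate bookkeeping matches recomputation from
           scratch", {
  p <- metapop_params(r = 0.5, beta = 1, a = 0.1, k = 50, m_S = 2, n = 21,
                      t_max = 30, seed = 12)
  run <- simulate_metapop(p)
  expect_gt(run$n_events, 1000)
  expect_lt(run$rate_discrepancy, 1e-7)
})

test_that("identical seeds reproduce metapopulation runs exactly", {
  p <- metapop_params(r = 0.2, beta = 1, a = 0.1, k = 50, n = 21,
                      t_max = 20, seed = 33)
  a <- simulate_metapop(p)
  b <- simulate_metapop(p)
  expect_identical(a$ts, b$ts)
  expect_identical(a$S, b$S)
})

test_that("with m = 0 a patch follows the single-patch law (independent
           Gillespie oracle)", {
  k <- 30; t_end <- 3
  r <- 0.8; beta <- 2; a <- 0.3
  nrep <- 1000
  p <- metapop_params(r = r, beta = beta, a = a, k = k, m_S = 0, n = 3,
                      t_max = t_end, seed = 1)
  S_pkg <- integer(nrep); S_orc <- integer(nrep)
  I_pkg <- integer(nrep); I_orc <- integer(nrep)
  set.seed(77)
  oracle_seeds <- sample.int(1e6, nrep)
  for (i in seq_len(nrep)) {
    pp <- p; pp$seed <- 5000L + i
    st <- init_metapop(pp, "custom", S = c(20, 0, 20), I = c(5, 0, 5))
    run <- simulate_metapop(pp, st)
    S_pkg[i] <- run$S[1]; I_pkg[i] <- run$I[1]
    set.seed(oracle_seeds[i])
    o <- single_patch_gillespie(20, 5, r, beta, a, 0, k, t_end)
    S_orc[i] <- o["S"]; I_orc[i] <- o["I"]
  }
  # same mean and spread, and same binned distribution (chi-square)
  expect_lt(abs(mean(S_pkg) - mean(S_orc)),
            4 * sqrt(var(S_pkg) / nrep + var(S_orc) / nrep))
  expect_lt(abs(mean(I_pkg) - mean(I_orc)),
            4 * sqrt(var(I_pkg) / nrep + var(I_orc) / nrep))
  breaks <- unique(quantile(c(S_pkg, S_orc), probs = seq(0, 1, 0.2)))
  bins_p <- table(cut(S_pkg, breaks, include.lowest = TRUE))
  bins_o <- table(cut(S_orc, breaks, include.lowest = TRUE))
  pval <- suppressWarnings(
    stats::chisq.test(rbind(bins_p, bins_o))$p.value)
  expect_gt(pval, 0.001)
})

test_that("beta = 0 sends the infection extinct while S stays near its
           carrying capacity", {
  p <- metapop_params(r = 1, beta = 0, a = 0.5, k = 100, m_S = 0.5, n = 11,
                      t_max = 60, seed = 21)
  st <- init_metapop(p, "custom", S = rep(80L, 11), I = rep(10L, 11))
  run <- simulate_metapop(p, st)
  expect_equal(sum(run$I), 0)
  expect_true(all(abs(run$S - 100) < 40))
  expect_equal(run$termination, "VIRUS_EXTINCT")
})

test_that("metapopulation outcome labels land in their regimes", {
  lab <- function(r, beta, a, t_max, seed) {
    p <- metapop_params(r = r, beta = beta, a = a, k = 100, m_S = 1,
                        n = 100, t_max = t_max, seed = seed)
    as.character(classify_metapop_outcome(simulate_metapop(p)))
  }
  # no invasion when the local reproductive ratio is below one
  expect_equal(lab(0.1, 0.1, 0.2, 100, 1), "ME")
  # broad coexistence between the white and black lines
  expect_equal(lab(0.1, 1, 0.1, 60, 1), "MC")
  # strong virus, left of the H = 1 line: joint extinction in the interior
  expect_equal(lab(0.002, 1, 0.002, 400, 1), "MA")
  # co-traveling waves die at the wall right of the H = 1 line
  expect_equal(lab(0.05, 1, 0.005, 2000, 1), "MB")
})
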