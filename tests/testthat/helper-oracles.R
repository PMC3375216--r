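# Independent oracles used across the test suite. These re-derive expected
# behavior from the model definition by enumeration or direct simulation in
# plain R, without touching the package's compiled kernels.

# Exact one-step state distribution of the lattice sampling process on a
# tiny grid, by dynamic programming over the N^2 sequential draws. States
# are hashed as strings; transitions mirror the written update rule:
# sample a spot uniformly; an occupied cell acts (division/transmission,
# probability weight/Lambda) into a uniform Moore position, silently failing
# off-grid or on a blocked destination, and otherwise dies with probability
# weight/Lambda.
enumerate_step_distribution <- function(grid, R, D, B, A) {
  N <- nrow(grid)
  lambda <- max(1, R, D, B, A)
  pR <- R / lambda; pD <- D / lambda; pB <- B / lambda; pA <- A / lambda
  moore <- cbind(rep(-1:1, each = 3), rep(-1:1, 3))
  moore <- moore[!(moore[, 1] == 0 & moore[, 2] == 0), ]
  key <- function(g) paste(g, collapse = "")
  dist <- setNames(1, key(grid))
  decode <- function(k) matrix(as.integer(strsplit(k, "")[[1]]), N, N)
  for (draw in seq_len(N * N)) {
    nxt <- new.env()
    add <- function(g, p) {
      k <- key(g)
      assign(k, p + (if (exists(k, nxt)) get(k, nxt) else 0), nxt)
    }
    for (k in names(dist)) {
      p0 <- dist[[k]]
      g <- decode(k)
      for (i in seq_len(N)) for (j in seq_len(N)) {
        psel <- p0 / (N * N)
        st <- g[i, j]
        if (st == 0) { add(g, psel); next }
        pact <- if (st == 1) pR else pB
        pdie <- if (st == 1) pD else pA
        # action branch: uniform over the 8 conceptual neighbor positions
        for (d in seq_len(8)) {
          ni <- i + moore[d, 1]; nj <- j + moore[d, 2]
          g2 <- g
          if (ni >= 1 && ni <= N && nj >= 1 && nj <= N) {
            if (st == 1 && g[ni, nj] == 0) g2[ni, nj] <- 1
            if (st == 2 && g[ni, nj] == 1) g2[ni, nj] <- 2
          }
          add(g2, psel * pact / 8)
        }
        # death branch (no action occurred)
        g2 <- g; g2[i, j] <- 0
        add(g2, psel * (1 - pact) * pdie)
        # nothing happens
        add(g, psel * (1 - pact) * (1 - pdie))
      }
    }
    dist <- setNames(as.numeric(mget(ls(nxt), nxt)), ls(nxt))
  }
  dist
}

grid_key <- function(g) paste(g, collapse = "")

# Plain-R Gillespie simulation of a single well-mixed patch (the m = 0
# marginal law of the metapopulation model).
single_patch_gillespie <- function(S, I, r, beta, a, d, k, t_max) {
  t <- 0
  repeat {
    rates <- c(birth = r * S * max(0, 1 - (S + I) / k),
               inf = beta * S * I / k, sdeath = d * S, ideath = a * I)
    tot <- sum(rates)
    if (tot <= 0) break
    t <- t + rexp(1, tot)
    if (t > t_max) break
    ev <- sample(names(rates), 1, prob = rates)
    if (ev == "birth") S <- S + 1
    else if (ev == "inf") { S <- S - 1; I <- I + 1 }
    else if (ev == "sdeath") S <- S - 1
    else I <- I - 1
  }
  c(S = S, I = I)
}

# Brute-force changepoint oracle: for every candidate changepoint, fit
# sqrt(I) linear before and I linear after, and return the time minimizing
# the summed squared residuals on the I scale.
brute_force_changepoint <- function(t, I) {
  n <- length(t)
  best <- list(ss = Inf, cp = NA)
  for (cp in 4:(n - 3)) {
    i1 <- 1:cp; i2 <- cp:n
    f1 <- lm(sqrt(I[i1]) ~ t[i1]); f2 <- lm(I[i2] ~ t[i2])
    ss <- sum((I[i1[-cp]] - pmax(0, fitted(f1)[-cp])^2)^2) +
      sum((I[i2] - fitted(f2))^2)
    if (ss < best$ss) best <- list(ss = ss, cp = t[cp])
  }
  best
}

# Small lattice run helper used throughout
quick_run <- function(R, D = 0, B, A, N, steps, seed, init, ...) {
  p <- lattice_params(R = R, D = D, B = B, A = A, N = N,
                      max_steps = steps, seed = seed)
  run_lattice(p, init, ...)
}

nested_init <- function(isd = 5, ssd = 13) {
  init_condition("nested_squares", infected_side = isd,
                 susceptible_side = ssd)
}
full_init <- function(isd) {
  init_condition("center_square_in_full", infected_side = isd)
}
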