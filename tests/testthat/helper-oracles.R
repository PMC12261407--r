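# Independent scalar/loop oracles used to validate the vectorized
# implementations, plus small fixture builders.

sigm <- function(x) 1 / (1 + exp(-x))

# One LSTM cell step computed with explicit per-unit loops (single row).
oracle_cell_step <- function(x, hprev, cprev, p) {
  h <- length(p$b_I)
  I <- F_ <- O <- G <- C <- H <- numeric(h)
  for (j in seq_len(h)) {
    I[j] <- sigm(sum(x * p$W_xI[, j]) + sum(hprev * p$W_Ih[, j]) + p$b_I[j])
    F_[j] <- sigm(sum(x * p$W_xF[, j]) + sum(hprev * p$W_Fh[, j]) + p$b_F[j])
    O[j] <- sigm(sum(x * p$W_xO[, j]) + sum(hprev * p$W_Oh[, j]) + p$b_O[j])
    G[j] <- tanh(sum(x * p$W_xC[, j]) + sum(hprev * p$W_Ch[, j]) + p$b_C[j])
    C[j] <- F_[j] * cprev[j] + I[j] * G[j]
    H[j] <- O[j] * tanh(C[j])
  }
  list(I = I, F = F_, O = O, G = G, C = C, H = H)
}

# Full stacked bidirectional forward computed with loops (single window).
oracle_bilstm <- function(X, state) {
  h <- state$config$hidden_dim
  W <- nrow(X)
  input <- X
  for (l in seq_along(state$layers)) {
    Hf <- matrix(0, W, h); Hb <- matrix(0, W, h)
    hp <- rep(0, h); cp <- rep(0, h)
    for (t in seq_len(W)) {
      cs <- oracle_cell_step(input[t, ], hp, cp, state$layers[[l]]$fwd)
      Hf[t, ] <- cs$H; hp <- cs$H; cp <- cs$C
    }
    hp <- rep(0, h); cp <- rep(0, h)
    for (t in rev(seq_len(W))) {
      cs <- oracle_cell_step(input[t, ], hp, cp, state$layers[[l]]$bwd)
      Hb[t, ] <- cs$H; hp <- cs$H; cp <- cs$C
    }
    input <- cbind(Hf, Hb)
  }
  input
}

# 1-d optimal transport on support 0..15 by the greedy (north-west corner)
# primal solver, optimal for convex costs.
oracle_transport <- function(p, q) {
  i <- 1; j <- 1; cost <- 0
  p <- p; q <- q
  while (i <= length(p) && j <= length(q)) {
    m <- min(p[i], q[j])
    cost <- cost + m * abs(i - j)
    p[i] <- p[i] - m; q[j] <- q[j] - m
    if (p[i] <= 1e-15) i <- i + 1
    if (j <= length(q) && q[j] <= 1e-15) j <- j + 1
  }
  cost
}

# Brute-force double-loop autocorrelation.
oracle_acf <- function(x, max_lag) {
  n <- length(x); xb <- mean(x)
  den <- sum((x - xb)^2)
  vapply(seq_len(max_lag), function(k)
    sum((x[1:(n - k)] - xb) * (x[(1 + k):n] - xb)) / den, 1)
}

random_profile <- function() {
  p <- stats::rexp(16)
  p / sum(p)
}

random_state <- function(num_layers = 1, hidden_dim = 3, input_dim = 4,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- rt_config(num_layers = num_layers, hidden_dim = hidden_dim,
                   input_dim = input_dim)
  st <- init_model(cfg, seed = if (is.null(seed)) 1 else seed)
  st
}

# A tiny deterministic unit set: features carry the timing signal exactly.
tiny_units <- function(n = 120, seed = 5, noise = 0) {
  set.seed(seed)
  t0 <- 2 + 11 * stats::runif(n)
  s <- rep(1.2, n)
  y <- labels_from_timing(t0, s)
  x <- cbind(scale(t0), matrix(stats::rnorm(n * 8, sd = noise + 1e-8), n, 8))
  list(list(x = x, y = y))
}
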