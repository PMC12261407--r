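#' Model configuration
#'
#' Hyperparameters of the recurrent predictor. Defaults are a desk-scale
#' configuration; the search grid of [full_grid()] spans the values explored
#' for the published cell lines.
#'
#' @param num_layers Number of stacked bidirectional LSTM layers.
#' @param hidden_dim Hidden units per direction.
#' @param learning_rate Adam step size.
#' @param weight_decay L2 regularization coefficient.
#' @param batch_size Windows per optimization step.
#' @param window_length Bins per window fed to the recurrence (default 256).
#' @param epochs Training epochs (default 100).
#' @param seed Seed controlling initialization and shuffling.
#' @param input_dim Feature columns (default 9).
#' @return List of class `"rt_config"`.
#' @export
rt_config <- function(num_layers = 1L, hidden_dim = 32L, learning_rate = 1e-3,
                      weight_decay = 1e-4, batch_size = 8L,
                      window_length = 256L, epochs = 100L, seed = 1L,
                      input_dim = 9L) {
  cfg <- list(num_layers = as.integer(num_layers),
              hidden_dim = as.integer(hidden_dim),
              learning_rate = learning_rate, weight_decay = weight_decay,
              batch_size = as.integer(batch_size),
              window_length = as.integer(window_length),
              epochs = as.integer(epochs), seed = as.integer(seed),
              input_dim = as.integer(input_dim))
  stopifnot(cfg$num_layers >= 1, cfg$hidden_dim >= 1, cfg$learning_rate > 0,
            cfg$weight_decay >= 0, cfg$batch_size >= 1,
            cfg$window_length >= 2, cfg$epochs >= 1, cfg$input_dim >= 1)
  class(cfg) <- "rt_config"
  cfg
}

GATES <- c("I", "F", "O", "C")

init_dir_params <- function(d_in, h, r) {
  p <- list()
  for (g in GATES) {
    p[[paste0("W_x", g)]] <- matrix(stats::runif(d_in * h, -r, r), d_in, h)
    p[[paste0("W_", g, "h")]] <- matrix(stats::runif(h * h, -r, r), h, h)
    p[[paste0("b_", g)]] <- stats::runif(h, -r, r)
  }
  p
}

#' Initialize model parameters
#'
#' All tensors are drawn uniformly from +-1/sqrt(hidden_dim), a standard
#' recurrent-layer scheme; the draw is fully determined by the seed.
#'
#' @param config An [rt_config()].
#' @param seed Seed (default `config$seed`).
#' @return Model state: list with `layers` (each `fwd`/`bwd` parameter sets),
#'   `head` (`W` 2h x 16, `b` length 16) and `config`.
#' @export
init_model <- function(config, seed = config$seed) {
  set.seed(seed)
  h <- config$hidden_dim
  r <- 1 / sqrt(h)
  layers <- vector("list", config$num_layers)
  for (l in seq_len(config$num_layers)) {
    d_in <- if (l == 1) config$input_dim else 2 * h
    layers[[l]] <- list(fwd = init_dir_params(d_in, h, r),
                        bwd = init_dir_params(d_in, h, r))
  }
  head <- list(W = matrix(stats::runif(2 * h * 16, -r, r), 2 * h, 16),
               b = stats::runif(16, -r, r))
  structure(list(layers = layers, head = head, config = config),
            class = "rt_model_state")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' One LSTM cell step
#'
#' The gated update for a single bin: input/forget/output gates are sigmoids
#' of affine maps of the input and previous hidden state, the cell state is
#' `F * C_prev + I * tanh(candidate)`, and the hidden state is
#' `O * tanh(C)`.
#'
#' @param X_t Input rows (batch x d matrix, or a vector for one row).
#' @param H_prev,C_prev Previous hidden and cell state (batch x h).
#' @param params One direction's parameter set (from a model layer).
#' @return List with gate activations `I`, `F`, `O`, candidate `G`, and new
#'   states `C`, `H` (all batch x h).
#' @export
lstm_cell_step <- function(X_t, H_prev, C_prev, params) {
  if (is.null(dim(X_t))) X_t <- matrix(X_t, nrow = 1)
  if (is.null(dim(H_prev))) H_prev <- matrix(H_prev, nrow = 1)
  if (is.null(dim(C_prev))) C_prev <- matrix(C_prev, nrow = 1)
  if (ncol(X_t) != nrow(params$W_xI) || ncol(H_prev) != nrow(params$W_Ih))
    stop("dimension mismatch between inputs and parameters")
  bI <- matrix(params$b_I, nrow(X_t), length(params$b_I), byrow = TRUE)
  bF <- matrix(params$b_F, nrow(X_t), length(params$b_F), byrow = TRUE)
  bO <- matrix(params$b_O, nrow(X_t), length(params$b_O), byrow = TRUE)
  bC <- matrix(params$b_C, nrow(X_t), length(params$b_C), byrow = TRUE)
  I <- sigmoid(X_t %*% params$W_xI + H_prev %*% params$W_Ih + bI)
  F_ <- sigmoid(X_t %*% params$W_xF + H_prev %*% params$W_Fh + bF)
  O <- sigmoid(X_t %*% params$W_xO + H_prev %*% params$W_Oh + bO)
  G <- tanh(X_t %*% params$W_xC + H_prev %*% params$W_Ch + bC)
  C <- F_ * C_prev + I * G
  H <- O * tanh(C)
  list(I = I, F = F_, O = O, G = G, C = C, H = H)
}

# Run one direction over a window batch. Xs: list over time of B x d
# matrices; ord: time order of the recurrence (1:T fwd, T:1 bwd).
# Returns per-time hidden states plus the cache needed for backprop.
lstm_dir_forward <- function(Xs, params, ord) {
  T_ <- length(Xs)
  B <- nrow(Xs[[1]])
  h <- length(params$b_I)
  H <- vector("list", T_); cache <- vector("list", T_)
  Hp <- matrix(0, B, h); Cp <- matrix(0, B, h)
  for (t in ord) {
    cs <- lstm_cell_step(Xs[[t]], Hp, Cp, params)
    cache[[t]] <- c(cs, list(H_prev = Hp, C_prev = Cp))
    H[[t]] <- cs$H
    Hp <- cs$H; Cp <- cs$C
  }
  list(H = H, cache = cache)
}

# Full stacked bidirectional forward over a window batch.
# Xs: list over time of B x d matrices. Returns per-time B x 2h embeddings
# and (optionally) all caches.
bilstm_forward_batch <- function(Xs, state, keep_cache = FALSE) {
  T_ <- length(Xs)
  caches <- if (keep_cache) vector("list", length(state$layers)) else NULL
  input <- Xs
  for (l in seq_along(state$layers)) {
    fwd <- lstm_dir_forward(input, state$layers[[l]]$fwd, seq_len(T_))
    bwd <- lstm_dir_forward(input, state$layers[[l]]$bwd, rev(seq_len(T_)))
    if (keep_cache)
      caches[[l]] <- list(fwd = fwd$cache, bwd = bwd$cache, input = input)
    input <- lapply(seq_len(T_), function(t) cbind(fwd$H[[t]], bwd$H[[t]]))
  }
  list(emb = input, caches = caches)
}

#' Bidirectional LSTM embeddings for one window
#'
#' Runs the stacked bidirectional recurrence over an ordered window of bins:
#' the forward direction recurs left to right, the backward direction right
#' to left, initial states are zero at both ends, and each layer beyond the
#' first consumes the previous layer's concatenated hidden states.
#'
#' @param X Window matrix (bins x features).
#' @param state Model state from [init_model()] or a fitted model.
#' @return Embedding matrix (bins x 2*hidden_dim), forward half first.
#' @export
bilstm_forward <- function(X, state) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (any(!is.finite(X))) stop("non-finite values in input window")
  Xs <- lapply(seq_len(nrow(X)), function(t) X[t, , drop = FALSE])
  out <- bilstm_forward_batch(Xs, state)
  do.call(rbind, out$emb)
}

#' Per-bin 16-fraction log-probabilities
#'
#' Affine prediction head followed by a row-wise log-softmax (stabilized by
#' max subtraction).
#'
#' @param emb Embeddings (bins x 2*hidden_dim).
#' @param state Model state.
#' @return Matrix (bins x 16) of log-probabilities; each row's exponentials
#'   sum to 1.
#' @export
predict_logprobs <- function(emb, state) {
  if (is.null(dim(emb))) emb <- matrix(emb, nrow = 1)
  if (ncol(emb) != nrow(state$head$W))
    stop("embedding width does not match the prediction head")
  logits <- emb %*% state$head$W +
    matrix(state$head$b, nrow(emb), 16, byrow = TRUE)
  log_softmax_rows(logits)
}

log_softmax_rows <- function(logits) {
  mx <- apply(logits, 1, max)
  z <- logits - mx
  z - log(rowSums(exp(z)))
}

#' Per-bin 16-fraction probability profiles
#'
#' Exponential of [predict_logprobs()]; rows are probability vectors over
#' the S1..S16 fractions.
#'
#' @param X Window matrix (bins x features).
#' @param state Model state.
#' @return Matrix (bins x 16), rows nonnegative summing to 1.
#' @export
predict_profiles <- function(X, state) {
  out <- exp(predict_logprobs(bilstm_forward(X, state), state))
  colnames(out) <- FRACTION_NAMES
  out
}
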