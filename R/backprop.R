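# Reverse-mode gradients for the stacked bidirectional LSTM and the
# prediction head. Everything operates on the same window-batch layout as
# bilstm_forward_batch: lists over time of B x (.) matrices.

# Apply f leaf-wise across parallel parameter trees.
tree_zip <- function(f, ...) {
  trees <- list(...)
  a <- trees[[1]]
  if (is.list(a)) {
    out <- lapply(seq_along(a), function(i)
      do.call(tree_zip, c(list(f), lapply(trees, `[[`, i))))
    names(out) <- names(a)
    out
  } else {
    do.call(f, trees)
  }
}

zero_dir_grads <- function(params) lapply(params, function(p) p * 0)

# Backward through one direction. dH_out: list over time of B x h gradients
# w.r.t. this direction's hidden outputs. Returns parameter gradients and
# the gradient w.r.t. the layer input at each time step.
lstm_dir_backward <- function(cache, Xs, params, dH_out, ord) {
  T_ <- length(Xs)
  B <- nrow(Xs[[1]]); h <- length(params$b_I)
  g <- zero_dir_grads(params)
  dX <- vector("list", T_)
  dH_carry <- matrix(0, B, h); dC_carry <- matrix(0, B, h)
  for (i in rev(seq_len(T_))) {
    t <- ord[i]
    cs <- cache[[t]]
    dH <- dH_out[[t]] + dH_carry
    tC <- tanh(cs$C)
    dO_a <- dH * tC * cs$O * (1 - cs$O)
    dC <- dH * cs$O * (1 - tC^2) + dC_carry
    dF_a <- dC * cs$C_prev * cs$F * (1 - cs$F)
    dI_a <- dC * cs$G * cs$I * (1 - cs$I)
    dG_a <- dC * cs$I * (1 - cs$G^2)
    dC_carry <- dC * cs$F
    X_t <- Xs[[t]]; Hp <- cs$H_prev
    g$W_xI <- g$W_xI + crossprod(X_t, dI_a)
    g$W_xF <- g$W_xF + crossprod(X_t, dF_a)
    g$W_xO <- g$W_xO + crossprod(X_t, dO_a)
    g$W_xC <- g$W_xC + crossprod(X_t, dG_a)
    g$W_Ih <- g$W_Ih + crossprod(Hp, dI_a)
    g$W_Fh <- g$W_Fh + crossprod(Hp, dF_a)
    g$W_Oh <- g$W_Oh + crossprod(Hp, dO_a)
    g$W_Ch <- g$W_Ch + crossprod(Hp, dG_a)
    g$b_I <- g$b_I + colSums(dI_a)
    g$b_F <- g$b_F + colSums(dF_a)
    g$b_O <- g$b_O + colSums(dO_a)
    g$b_C <- g$b_C + colSums(dG_a)
    dX[[t]] <- dI_a %*% t(params$W_xI) + dF_a %*% t(params$W_xF) +
      dO_a %*% t(params$W_xO) + dG_a %*% t(params$W_xC)
    dH_carry <- dI_a %*% t(params$W_Ih) + dF_a %*% t(params$W_Fh) +
      dO_a %*% t(params$W_Oh) + dG_a %*% t(params$W_Ch)
  }
  list(grads = g, dX = dX)
}

# Backward through the full stack. d_emb: list over time of B x 2h gradients
# w.r.t. the final layer's concatenated embeddings.
bilstm_backward <- function(state, caches, d_emb) {
  L <- length(state$layers)
  h <- state$config$hidden_dim
  T_ <- length(d_emb)
  grads <- vector("list", L)
  d_top <- d_emb
  for (l in rev(seq_len(L))) {
    Xs <- caches[[l]]$input
    dHf <- lapply(d_top, function(m) m[, seq_len(h), drop = FALSE])
    dHb <- lapply(d_top, function(m) m[, h + seq_len(h), drop = FALSE])
    bf <- lstm_dir_backward(caches[[l]]$fwd, Xs, state$layers[[l]]$fwd,
                            dHf, seq_len(T_))
    bb <- lstm_dir_backward(caches[[l]]$bwd, Xs, state$layers[[l]]$bwd,
                            dHb, rev(seq_len(T_)))
    grads[[l]] <- list(fwd = bf$grads, bwd = bb$grads)
    if (l > 1)
      d_top <- lapply(seq_len(T_), function(t) bf$dX[[t]] + bb$dX[[t]])
  }
  grads
}

# Forward + loss + full gradient for one window batch.
# Xs/Ys: lists over time of B x d / B x 16 matrices. Loss is the mean KL
# over all B*T rows. Returns loss and a gradient tree mirroring the state.
batch_loss_and_grads <- function(state, Xs, Ys) {
  T_ <- length(Xs); B <- nrow(Xs[[1]])
  fwd <- bilstm_forward_batch(Xs, state, keep_cache = TRUE)
  E <- do.call(rbind, fwd$emb)               # (T*B) x 2h, time-major
  Tg <- do.call(rbind, Ys)
  logp <- predict_logprobs(E, state)
  loss <- kl_divergence_loss(logp, Tg)
  nrows <- nrow(E)
  P <- exp(logp)
  dlogits <- (P - Tg) / nrows
  g_head <- list(W = crossprod(E, dlogits), b = colSums(dlogits))
  dE <- dlogits %*% t(state$head$W)
  d_emb <- lapply(seq_len(T_), function(t)
    dE[(t - 1) * B + seq_len(B), , drop = FALSE])
  g_layers <- bilstm_backward(state, fwd$caches, d_emb)
  list(loss = loss, grads = list(layers = g_layers, head = g_head))
}

# One Adam step with classic L2 weight decay folded into the gradient.
# opt: list(m, v, t). Returns list(state, opt).
adam_step <- function(state, grads, opt, lr, wd,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  p <- list(layers = state$layers, head = state$head)
  if (is.null(opt)) {
    opt <- list(m = tree_zip(function(x) x * 0, p),
                v = tree_zip(function(x) x * 0, p), t = 0L)
  }
  opt$t <- opt$t + 1L
  g <- if (wd > 0) tree_zip(function(gr, pa) gr + wd * pa, grads, p) else grads
  opt$m <- tree_zip(function(m, gr) beta1 * m + (1 - beta1) * gr, opt$m, g)
  opt$v <- tree_zip(function(v, gr) beta2 * v + (1 - beta2) * gr^2, opt$v, g)
  bc1 <- 1 - beta1^opt$t; bc2 <- 1 - beta2^opt$t
  p <- tree_zip(function(pa, m, v) pa - lr * (m / bc1) / (sqrt(v / bc2) + eps),
                p, opt$m, opt$v)
  state$layers <- p$layers
  state$head <- p$head
  list(state = state, opt = opt)
}
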