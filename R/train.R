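#' Kullback-Leibler divergence loss
#'
#' Mean over rows of `sum(target * (log(target) - log_pred))`, with
#' `0 * log 0 = 0`. This is the training criterion: the observed 16-fraction
#' profile is the true distribution, the model emits log-probabilities.
#'
#' @param log_pred Matrix of row-wise log-probabilities (n x 16).
#' @param target Matrix of probability rows (n x 16), each summing to 1.
#' @return Nonnegative scalar.
#' @export
kl_divergence_loss <- function(log_pred, target) {
  if (!all(dim(log_pred) == dim(target))) stop("shape mismatch")
  term <- target * (ifelse(target > 0, log(target), 0) - log_pred)
  term[target == 0] <- 0
  mean(rowSums(term))
}

is_autosome <- function(chrom) grepl("^[0-9]+$", norm_chrom(chrom))

#' Build train/validation/test splits
#'
#' Intra-cell-line mode holds out one chromosome for validation (default
#' chr6) and one for testing (default chr9) and trains on the remaining
#' autosomes of a single cell line. Leave-one-cell-line-out mode tests on
#' the full left-out cell line, trains on the other cell lines' autosomes
#' minus the validation and test chromosomes, and validates on those cell
#' lines' validation chromosome. Sex chromosomes are always excluded (with a
#' warning if present).
#'
#' @param cells Named list: cell line -> named list: chromosome ->
#'   `list(x = feature matrix, y = profile matrix)`.
#' @param mode `"intra"` or `"loco"`.
#' @param cell Cell line for intra mode (default: first).
#' @param test_cell Left-out cell line for loco mode.
#' @param val_chrom,test_chrom Held-out chromosomes (defaults chr6, chr9).
#' @return List with `train`, `validation`, `test`: each a data.frame of
#'   unit keys (`cell`, `chrom`).
#' @export
make_splits <- function(cells, mode = c("intra", "loco"), cell = NULL,
                        test_cell = NULL, val_chrom = "chr6",
                        test_chrom = "chr9") {
  mode <- match.arg(mode)
  all_keys <- do.call(rbind, lapply(names(cells), function(cl)
    data.frame(cell = cl, chrom = names(cells[[cl]]), stringsAsFactors = FALSE)))
  sex <- !is_autosome(all_keys$chrom)
  if (any(sex)) {
    warning("excluding sex chromosome(s): ",
            paste(unique(all_keys$chrom[sex]), collapse = ", "))
    all_keys <- all_keys[!sex, , drop = FALSE]
  }
  vs <- norm_chrom(val_chrom); ts <- norm_chrom(test_chrom)
  nc <- norm_chrom(all_keys$chrom)
  if (mode == "intra") {
    if (is.null(cell)) cell <- names(cells)[1]
    if (!cell %in% names(cells)) stop("unknown cell line: ", cell)
    k <- all_keys[all_keys$cell == cell, , drop = FALSE]
    nk <- norm_chrom(k$chrom)
    if (!vs %in% nk || !ts %in% nk)
      stop("requested validation/test chromosome absent from cell line ", cell)
    out <- list(train = k[!(nk %in% c(vs, ts)), , drop = FALSE],
                validation = k[nk == vs, , drop = FALSE],
                test = k[nk == ts, , drop = FALSE])
  } else {
    if (is.null(test_cell)) stop("loco mode requires test_cell")
    if (!test_cell %in% names(cells)) stop("unknown cell line: ", test_cell)
    others <- all_keys[all_keys$cell != test_cell, , drop = FALSE]
    no <- norm_chrom(others$chrom)
    out <- list(train = others[!(no %in% c(vs, ts)), , drop = FALSE],
                validation = others[no == vs, , drop = FALSE],
                test = all_keys[all_keys$cell == test_cell, , drop = FALSE])
  }
  key <- function(df) paste(df$cell, norm_chrom(df$chrom))
  if (length(intersect(key(out$train), c(key(out$validation), key(out$test)))) ||
      length(intersect(key(out$validation), key(out$test))))
    stop("split overlap detected")
  out
}

#' Gather split units into training lists
#'
#' @param cells Data structure as in [make_splits()].
#' @param keys One component of a split (data.frame `cell`, `chrom`).
#' @return List of units `list(x, y, cell, chrom)`.
#' @export
collect_units <- function(cells, keys) {
  lapply(seq_len(nrow(keys)), function(i) {
    u <- cells[[keys$cell[i]]][[keys$chrom[i]]]
    c(u, list(cell = keys$cell[i], chrom = keys$chrom[i]))
  })
}

# Cut each unit's rows into non-overlapping windows of window_length
# contiguous bins (final short window kept; windows never cross units).
make_windows <- function(units, window_length) {
  out <- list()
  for (u in units) {
    n <- nrow(u$x)
    starts <- seq(1, n, by = window_length)
    for (s in starts) {
      e <- min(s + window_length - 1, n)
      if (e - s + 1 < 2 && length(starts) > 1) {
        # a trailing single bin is glued to the previous window
        out[[length(out)]]$x <- rbind(out[[length(out)]]$x,
                                      u$x[s:e, , drop = FALSE])
        out[[length(out)]]$y <- rbind(out[[length(out)]]$y,
                                      u$y[s:e, , drop = FALSE])
      } else {
        out[[length(out) + 1]] <- list(x = u$x[s:e, , drop = FALSE],
                                       y = u$y[s:e, , drop = FALSE])
      }
    }
  }
  out
}

# Stack same-length windows into the time-major batch layout.
stack_batch <- function(wins) {
  T_ <- nrow(wins[[1]]$x)
  Xs <- lapply(seq_len(T_), function(t)
    do.call(rbind, lapply(wins, function(w) w$x[t, , drop = FALSE])))
  Ys <- lapply(seq_len(T_), function(t)
    do.call(rbind, lapply(wins, function(w) w$y[t, , drop = FALSE])))
  list(Xs = Xs, Ys = Ys)
}

eval_kl <- function(state, batches) {
  tot <- 0; n <- 0
  for (b in batches) {
    T_ <- length(b$Xs)
    fwd <- bilstm_forward_batch(b$Xs, state)
    E <- do.call(rbind, fwd$emb)
    Tg <- do.call(rbind, b$Ys)
    tot <- tot + kl_divergence_loss(predict_logprobs(E, state), Tg) * nrow(E)
    n <- n + nrow(E)
  }
  tot / n
}

# Group windows (by index) into same-length batches of at most batch_size.
group_batches <- function(wins, idx, batch_size) {
  lens <- vapply(wins[idx], function(w) nrow(w$x), 1L)
  batches <- list()
  for (L in unique(lens)) {
    ids <- idx[lens == L]
    starts <- seq(1, length(ids), by = batch_size)
    for (s in starts) {
      e <- min(s + batch_size - 1, length(ids))
      batches[[length(batches) + 1]] <- ids[s:e]
    }
  }
  batches
}

#' Fit the recurrent 16-fraction replication-timing model
#'
#' Trains the stacked bidirectional LSTM plus prediction head with Adam on
#' the KL divergence between observed and predicted per-bin fraction
#' profiles, with L2 regularization through `weight_decay`. Each
#' chromosome's bins are cut into non-overlapping windows of
#' `config$window_length` contiguous bins; hidden state is not carried
#' across windows or chromosomes. Window order is reshuffled every epoch
#' (seeded by `config$seed`); the returned state is that of the final epoch.
#'
#' @param x Feature matrix (bins x 9), or a list of units
#'   `list(x, y, ...)` (one per chromosome).
#' @param y Profile matrix (bins x 16) when `x` is a matrix.
#' @param chrom Optional chromosome id per row of `x`; windows never cross
#'   chromosomes.
#' @param validation Optional validation data: `list(x, y)` or list of
#'   units; its KL divergence is recorded every epoch.
#' @param config An [rt_config()].
#' @param verbose Print per-epoch losses.
#' @return Object of class `"rt_lstm"`: `state`, `config`, `history`
#'   (data.frame epoch/train_loss/val_loss), `call`.
#' @export
rt_lstm <- function(x, y = NULL, chrom = NULL, validation = NULL,
                    config = rt_config(), verbose = FALSE) {
  units <- as_units(x, y, chrom)
  if (length(units) == 0 || sum(vapply(units, function(u) nrow(u$x), 1L)) == 0)
    stop("empty training set")
  config$input_dim <- ncol(units[[1]]$x)
  wins <- make_windows(units, config$window_length)
  val_batches <- NULL
  if (!is.null(validation)) {
    vunits <- if (!is.null(validation$x)) list(validation) else validation
    vwins <- make_windows(vunits, config$window_length)
    vidx <- seq_along(vwins)
    val_batches <- lapply(group_batches(vwins, vidx, config$batch_size),
                          function(ids) stack_batch(vwins[ids]))
  }
  state <- init_model(config)          # seeds the RNG stream
  opt <- NULL
  hist <- data.frame(epoch = seq_len(config$epochs), train_loss = NA_real_,
                     val_loss = NA_real_)
  for (ep in seq_len(config$epochs)) {
    idx <- sample(length(wins))
    batches <- group_batches(wins, idx, config$batch_size)
    batches <- batches[sample(length(batches))]
    tot <- 0; nrows <- 0
    for (ids in batches) {
      b <- stack_batch(wins[ids])
      lg <- batch_loss_and_grads(state, b$Xs, b$Ys)
      if (!is.finite(lg$loss))
        stop("training diverged (non-finite loss) at epoch ", ep)
      nb <- length(b$Xs) * nrow(b$Xs[[1]])
      tot <- tot + lg$loss * nb; nrows <- nrows + nb
      st <- adam_step(state, lg$grads, opt, config$learning_rate,
                      config$weight_decay)
      state <- st$state; opt <- st$opt
    }
    hist$train_loss[ep] <- tot / nrows
    if (!is.null(val_batches)) hist$val_loss[ep] <- eval_kl(state, val_batches)
    if (verbose)
      cat(sprintf("epoch %3d  train %.5f  val %s\n", ep, hist$train_loss[ep],
                  ifelse(is.na(hist$val_loss[ep]), "-",
                         sprintf("%.5f", hist$val_loss[ep]))))
  }
  structure(list(state = state, config = config, history = hist,
                 call = match.call()),
            class = "rt_lstm")
}

as_units <- function(x, y, chrom) {
  if (is.list(x) && !is.data.frame(x) && is.null(dim(x))) {
    if (!is.null(x$x)) return(list(x))
    return(x)
  }
  x <- as.matrix(x)
  if (is.null(y)) stop("y is required when x is a matrix")
  y <- as.matrix(y)
  if (nrow(x) != nrow(y)) stop("x and y differ in rows")
  if (is.null(chrom)) chrom <- rep("chr", nrow(x))
  lapply(split(seq_len(nrow(x)), factor(chrom, levels = unique(chrom))),
         function(i) list(x = x[i, , drop = FALSE], y = y[i, , drop = FALSE]))
}

n_params <- function(config) {
  h <- config$hidden_dim
  tot <- 0
  for (l in seq_len(config$num_layers)) {
    d_in <- if (l == 1) config$input_dim else 2 * h
    tot <- tot + 2 * 4 * (d_in * h + h * h + h)
  }
  tot + 2 * h * 16 + 16
}

#' The full hyperparameter grid
#'
#' Cross of layer counts (1,2,3,4), batch sizes (8,16,32,64), hidden
#' dimensions (16,32,64,128,256), learning rates (1e-5,1e-4,1e-3) and L2
#' weight decays (0,1e-5,1e-4,1e-3): 960 configurations.
#'
#' @return data.frame with one row per configuration.
#' @export
full_grid <- function() {
  expand.grid(num_layers = c(1L, 2L, 3L, 4L),
              batch_size = c(8L, 16L, 32L, 64L),
              hidden_dim = c(16L, 32L, 64L, 128L, 256L),
              learning_rate = c(1e-5, 1e-4, 1e-3),
              weight_decay = c(0, 1e-5, 1e-4, 1e-3),
              KEEP.OUT.ATTRS = FALSE)
}

#' A reduced grid for desk-scale runs
#' @return data.frame of 4 configurations.
#' @export
default_grid <- function() {
  expand.grid(num_layers = 1L, batch_size = 8L, hidden_dim = c(16L, 32L),
              learning_rate = 1e-3, weight_decay = c(0, 1e-4),
              KEEP.OUT.ATTRS = FALSE)
}

#' Hyperparameter grid search on a validation set
#'
#' Trains one model per grid row and selects the configuration with the
#' lowest final validation KL divergence. Ties are broken by fewer
#' parameters, then lower learning rate.
#'
#' @param train,validation Unit lists (see [rt_lstm()]).
#' @param grid data.frame as from [full_grid()] or [default_grid()].
#' @param epochs,window_length,seed Shared settings for every run.
#' @param verbose Print progress.
#' @return List: `best_config` ([rt_config()]), `best_fit`, `results`
#'   (grid with a `val_kl` column), `fits`.
#' @export
grid_search <- function(train, validation, grid = default_grid(),
                        epochs = 100L, window_length = 256L, seed = 1L,
                        verbose = FALSE) {
  if (nrow(grid) == 0) stop("empty grid")
  fits <- vector("list", nrow(grid))
  val_kl <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- rt_config(num_layers = grid$num_layers[i],
                     hidden_dim = grid$hidden_dim[i],
                     learning_rate = grid$learning_rate[i],
                     weight_decay = grid$weight_decay[i],
                     batch_size = grid$batch_size[i],
                     window_length = window_length, epochs = epochs,
                     seed = seed)
    fits[[i]] <- rt_lstm(train, validation = validation, config = cfg)
    val_kl[i] <- utils::tail(fits[[i]]$history$val_loss, 1)
    if (verbose) cat(sprintf("config %d/%d: val KL %.5f\n", i, nrow(grid),
                             val_kl[i]))
  }
  np <- vapply(fits, function(f) n_params(f$config), 1)
  ord <- order(val_kl, np, grid$learning_rate)
  best <- ord[1]
  list(best_config = fits[[best]]$config, best_fit = fits[[best]],
       results = cbind(grid, val_kl = val_kl), fits = fits)
}
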