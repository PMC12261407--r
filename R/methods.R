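#' @export
print.rt_lstm <- function(x, ...) {
  cfg <- x$config
  cat("Bidirectional LSTM replication-timing model\n")
  cat(sprintf("  layers: %d  hidden: %d per direction  parameters: %d\n",
              cfg$num_layers, cfg$hidden_dim, n_params(cfg)))
  cat(sprintf("  trained %d epochs (lr %g, weight decay %g, batch %d, window %d)\n",
              cfg$epochs, cfg$learning_rate, cfg$weight_decay,
              cfg$batch_size, cfg$window_length))
  tl <- utils::tail(x$history$train_loss, 1)
  vl <- utils::tail(x$history$val_loss, 1)
  cat(sprintf("  final KL: train %.5f%s\n", tl,
              ifelse(is.na(vl), "", sprintf("  validation %.5f", vl))))
  invisible(x)
}

#' @export
summary.rt_lstm <- function(object, ...) {
  out <- list(config = object$config, n_params = n_params(object$config),
              history = object$history)
  class(out) <- "summary.rt_lstm"
  out
}

#' @export
print.summary.rt_lstm <- function(x, ...) {
  cat("Model configuration:\n")
  cfg <- x$config
  for (nm in c("num_layers", "hidden_dim", "learning_rate", "weight_decay",
               "batch_size", "window_length", "epochs", "seed"))
    cat(sprintf("  %-14s %s\n", nm, format(cfg[[nm]])))
  cat(sprintf("  %-14s %d\n", "parameters", x$n_params))
  h <- x$history
  shown <- h[unique(pmin(nrow(h), c(1, seq(10, nrow(h), by = 10), nrow(h)))), ]
  cat("Loss trajectory (KL divergence):\n")
  print(shown, row.names = FALSE)
  invisible(x)
}

#' @export
coef.rt_lstm <- function(object, ...) {
  list(layers = object$state$layers, head = object$state$head)
}

#' Predict 16-fraction profiles for new bins
#'
#' @param object Fitted `"rt_lstm"`.
#' @param newdata Feature matrix (bins x 9) or unit list.
#' @param chrom Optional per-row chromosome ids (windows never cross them).
#' @param type `"prob"` (default), `"logprob"`, or `"argmax"` (0-based
#'   dominant fraction per bin).
#' @param ... Unused.
#' @return Matrix (bins x 16) or integer vector for `"argmax"`.
#' @export
predict.rt_lstm <- function(object, newdata, chrom = NULL,
                            type = c("prob", "logprob", "argmax"), ...) {
  type <- match.arg(type)
  units <- as_units(newdata, if (is.matrix(newdata) || is.data.frame(newdata))
    matrix(0, nrow(as.matrix(newdata)), 16) else NULL, chrom)
  wins <- make_windows(units, object$config$window_length)
  lp <- do.call(rbind, lapply(wins, function(w)
    predict_logprobs(bilstm_forward(w$x, object$state), object$state)))
  colnames(lp) <- FRACTION_NAMES
  switch(type,
         logprob = lp,
         prob = exp(lp),
         argmax = apply(exp(lp), 1, argmax_fraction))
}

#' Residuals: observed minus fitted fraction profiles
#'
#' @param object Fitted `"rt_lstm"`.
#' @param x,y Feature and observed profile matrices.
#' @param chrom Optional chromosome ids.
#' @param ... Unused.
#' @return Matrix (bins x 16) of probability residuals.
#' @export
residuals.rt_lstm <- function(object, x, y, chrom = NULL, ...) {
  y - predict(object, x, chrom = chrom)
}

#' Plot the training history
#'
#' @param x Fitted `"rt_lstm"`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.rt_lstm <- function(x, ...) {
  h <- x$history
  cols <- c("train_loss", if (!all(is.na(h$val_loss))) "val_loss")
  graphics::matplot(h$epoch, h[, cols, drop = FALSE], type = "l", lty = 1,
                    xlab = "epoch", ylab = "KL divergence", ...)
  graphics::legend("topright", legend = cols, lty = 1,
                   col = seq_along(cols), bty = "n")
  invisible(x)
}
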