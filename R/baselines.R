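# Baseline regressors for contextualizing the recurrent model: per-fraction
# linear / lasso / forest / SVR fits with clip-and-renormalize
# postprocessing, and a two-layer MLP trained with the same KL loss and
# Adam optimizer as the main model.

clip_renormalize <- function(pred) {
  pred <- pmin(pmax(pred, 0), 1)
  s <- rowSums(pred)
  zero <- s == 0
  if (any(zero)) {
    message(sum(zero), " prediction row(s) all-zero after clipping; ",
            "fell back to uniform")
    pred[zero, ] <- 1 / 16
    s[zero] <- 1
  }
  pred / s
}

fit_mlp <- function(x_train, y_train, hidden_dim, learning_rate, weight_decay,
                    epochs, seed) {
  set.seed(seed)
  d <- ncol(x_train); h <- hidden_dim; n <- nrow(x_train)
  r <- 1 / sqrt(h)
  p <- list(W1 = matrix(stats::runif(d * h, -r, r), d, h),
            b1 = stats::runif(h, -r, r),
            W2 = matrix(stats::runif(h * 16, -r, r), h, 16),
            b2 = stats::runif(16, -r, r))
  opt <- NULL
  fake_state <- function(p) list(layers = list(), head = list(W = p$W2, b = p$b2))
  for (ep in seq_len(epochs)) {
    Z <- x_train %*% p$W1 + matrix(p$b1, n, h, byrow = TRUE)
    A <- pmax(Z, 0)
    logits <- A %*% p$W2 + matrix(p$b2, n, 16, byrow = TRUE)
    logp <- log_softmax_rows(logits)
    P <- exp(logp)
    dlogits <- (P - y_train) / n
    dA <- dlogits %*% t(p$W2)
    dZ <- dA * (Z > 0)
    g <- list(W1 = crossprod(x_train, dZ), b1 = colSums(dZ),
              W2 = crossprod(A, dlogits), b2 = colSums(dlogits))
    if (is.null(opt)) {
      opt <- list(m = tree_zip(function(x) x * 0, p),
                  v = tree_zip(function(x) x * 0, p), t = 0L)
    }
    opt$t <- opt$t + 1L
    if (weight_decay > 0)
      g <- tree_zip(function(gr, pa) gr + weight_decay * pa, g, p)
    opt$m <- tree_zip(function(m, gr) 0.9 * m + 0.1 * gr, opt$m, g)
    opt$v <- tree_zip(function(v, gr) 0.999 * v + 0.001 * gr^2, opt$v, g)
    bc1 <- 1 - 0.9^opt$t; bc2 <- 1 - 0.999^opt$t
    p <- tree_zip(function(pa, m, v)
      pa - learning_rate * (m / bc1) / (sqrt(v / bc2) + 1e-8), p, opt$m, opt$v)
  }
  p
}

predict_mlp <- function(p, x) {
  A <- pmax(x %*% p$W1 + matrix(p$b1, nrow(x), length(p$b1), byrow = TRUE), 0)
  exp(log_softmax_rows(A %*% p$W2 + matrix(p$b2, nrow(x), 16, byrow = TRUE)))
}

#' Baseline regression predictors of 16-fraction profiles
#'
#' Trains one regressor per S-phase fraction (linear, lasso, random forest,
#' SVR) or a single two-layer MLP with 16 outputs trained with KL loss and
#' Adam. Non-network predictions are clipped to \[0, 1\] and renormalized
#' per bin; an all-zero clipped row falls back to uniform 1/16 (logged).
#' The lasso regularization strength is a single shared value chosen on the
#' validation set over `lambda_grid`.
#'
#' @param x_train,y_train Training features (n x 9) and profiles (n x 16).
#' @param x_test Features to predict.
#' @param family One of `"linear"`, `"lasso"`, `"mlp"`, `"forest"`, `"svr"`.
#' @param x_val,y_val Validation data (required for `"lasso"`).
#' @param hidden_dim,learning_rate,weight_decay,epochs,seed MLP settings.
#' @param lambda_grid Lasso candidates (default `10^(-5:0)`).
#' @return Matrix (nrow(x_test) x 16) of probability rows.
#' @export
baseline_regressors <- function(x_train, y_train, x_test,
                                family = c("linear", "lasso", "mlp",
                                           "forest", "svr"),
                                x_val = NULL, y_val = NULL,
                                hidden_dim = 32, learning_rate = 1e-3,
                                weight_decay = 1e-4, epochs = 100, seed = 1,
                                lambda_grid = 10^seq(-5, 0)) {
  family <- match.arg(family)
  x_train <- as.matrix(x_train); y_train <- as.matrix(y_train)
  x_test <- as.matrix(x_test)
  per_fraction <- function(fit_fun, pred_fun) {
    sapply(seq_len(16), function(k) {
      m <- fit_fun(y_train[, k])
      pred_fun(m)
    })
  }
  pred <- switch(
    family,
    linear = {
      Xtr <- cbind(1, x_train); Xte <- cbind(1, x_test)
      per_fraction(function(yk) stats::lm.fit(Xtr, yk)$coefficients,
                   function(cf) { cf[is.na(cf)] <- 0; as.numeric(Xte %*% cf) })
    },
    lasso = {
      if (is.null(x_val) || is.null(y_val))
        stop("lasso requires validation data to choose lambda")
      x_val <- as.matrix(x_val); y_val <- as.matrix(y_val)
      val_err <- vapply(lambda_grid, function(lam) {
        pv <- sapply(seq_len(16), function(k) {
          m <- glmnet::glmnet(x_train, y_train[, k], alpha = 1, lambda = lam)
          as.numeric(stats::predict(m, x_val))
        })
        mean((pv - y_val)^2)
      }, 1)
      lam <- lambda_grid[which.min(val_err)]
      sapply(seq_len(16), function(k) {
        m <- glmnet::glmnet(x_train, y_train[, k], alpha = 1, lambda = lam)
        as.numeric(stats::predict(m, x_test))
      })
    },
    forest = {
      if (!requireNamespace("randomForest", quietly = TRUE))
        stop("family 'forest' requires the randomForest package")
      set.seed(seed)
      sapply(seq_len(16), function(k)
        stats::predict(randomForest::randomForest(x_train, y_train[, k]),
                       x_test))
    },
    svr = {
      if (!requireNamespace("e1071", quietly = TRUE))
        stop("family 'svr' requires the e1071 package")
      sapply(seq_len(16), function(k)
        stats::predict(e1071::svm(x_train, y_train[, k]), x_test))
    },
    mlp = {
      p <- fit_mlp(x_train, y_train, hidden_dim, learning_rate,
                   weight_decay, epochs, seed)
      predict_mlp(p, x_test)
    })
  pred <- matrix(pred, nrow = nrow(x_test), ncol = 16,
                 dimnames = list(NULL, FRACTION_NAMES))
  if (family == "mlp") pred else clip_renormalize(pred)
}
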