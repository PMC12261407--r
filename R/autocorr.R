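#' Sample autocorrelation of a per-bin series
#'
#' Standard biased sample autocorrelation,
#' `r(k) = sum_i (x_i - xbar)(x_{i+k} - xbar) / sum_i (x_i - xbar)^2`,
#' the normalization under which the N(0, 1/n) band applies. A constant
#' series has no defined autocorrelation and returns `NA`s with a warning.
#'
#' @param x Numeric series (one chromosome's bins in order).
#' @param max_lag Largest lag (default `length(x) - 1`).
#' @return Numeric vector of `r(k)` for k = 1..max_lag.
#' @export
acf_series <- function(x, max_lag = length(x) - 1) {
  n <- length(x)
  if (n < 2) stop("need at least 2 points")
  if (max_lag >= n) stop("max_lag must be < length(x)")
  if (stats::sd(x) == 0) {
    warning("constant series: autocorrelation undefined")
    return(rep(NA_real_, max_lag))
  }
  as.numeric(stats::acf(x, lag.max = max_lag, plot = FALSE,
                        demean = TRUE)$acf)[-1]
}

#' Gaussian confidence band for autocorrelation
#'
#' Two-sided band under the null `r(k) ~ N(0, 1/n)`:
#' `z_{(1+level)/2} / sqrt(n)`.
#'
#' @param n Series length.
#' @param level 0.95 or 0.99 (any value in (0,1) accepted).
#' @return Positive half-width of the band.
#' @export
confidence_bands <- function(n, level = 0.95) {
  stopifnot(n >= 2, level > 0, level < 1)
  stats::qnorm((1 + level) / 2) / sqrt(n)
}

#' Fraction-averaged autocorrelation of 16-fraction profiles
#'
#' Treats each of the 16 fraction columns of one chromosome as an
#' independent series, computes each column's autocorrelation, and averages
#' across fractions per lag. Constant columns are excluded from the average
#' (logged via message). 95% and 99% N(0, 1/n) bands are attached.
#'
#' @param profiles Matrix (bins x 16) for a single chromosome, bins in order.
#' @param max_lag Largest lag (default `nrow - 1`).
#' @param chromosome Optional id recorded in the result.
#' @return List of class `"autocorr_track"`: `lags`, `acf`, `band95`,
#'   `band99`, `n`, `n_fractions_used`, `chromosome`.
#' @export
fraction_averaged_acf <- function(profiles, max_lag = nrow(profiles) - 1,
                                  chromosome = NA_character_) {
  n <- nrow(profiles)
  if (n < 2) stop("need at least 2 bins")
  ok <- apply(profiles, 2, function(col) stats::sd(col) > 0)
  if (!all(ok))
    message(sum(!ok), " constant fraction column(s) excluded from the average")
  if (!any(ok)) stop("all fraction columns constant")
  per <- sapply(which(ok), function(j) acf_series(profiles[, j], max_lag))
  per <- matrix(per, nrow = max_lag)
  structure(list(lags = seq_len(max_lag), acf = rowMeans(per),
                 band95 = confidence_bands(n, 0.95),
                 band99 = confidence_bands(n, 0.99),
                 n = n, n_fractions_used = sum(ok), chromosome = chromosome),
            class = "autocorr_track")
}

#' @export
print.autocorr_track <- function(x, ...) {
  cat(sprintf("Autocorrelation track (%s): n = %d bins, %d lags, %d fractions\n",
              ifelse(is.na(x$chromosome), "unnamed", x$chromosome),
              x$n, length(x$lags), x$n_fractions_used))
  cat(sprintf("  bands: +-%.4f (95%%), +-%.4f (99%%)\n", x$band95, x$band99))
  cat("  first lags:", paste(sprintf("%.3f", utils::head(x$acf, 5)),
                             collapse = " "), "\n")
  invisible(x)
}
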