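#' Dominant S-phase fraction of a profile
#'
#' 0-based index of the maximum replication probability; ties resolve to the
#' earliest fraction.
#'
#' @param profile Length-16 probability vector.
#' @return Integer in 0..15.
#' @export
argmax_fraction <- function(profile) {
  which.max(profile) - 1L
}

#' Argmax RT fraction error
#'
#' Absolute difference between the dominant fractions of observed and
#' predicted profiles; an ARFE of 2 means the prediction peaks two S-phase
#' fractions away from the measurement.
#'
#' @param obs,pred Length-16 probability vectors.
#' @return Integer in 0..15.
#' @export
arfe <- function(obs, pred) {
  abs(argmax_fraction(obs) - argmax_fraction(pred))
}

#' Per-bin KL divergence
#'
#' `sum(obs * log(obs / pmax(pred, epsilon)))` with `0 * log 0 = 0`; the
#' epsilon floor applies to predictions only, guarding against exact zeros
#' from clipped baseline predictors.
#'
#' @param obs,pred Length-16 probability vectors.
#' @param epsilon Floor for predicted probabilities (default 1e-12).
#' @return Nonnegative scalar.
#' @export
kl_per_bin <- function(obs, pred, epsilon = 1e-12) {
  stopifnot(epsilon > 0)
  nz <- obs > 0
  sum(obs[nz] * (log(obs[nz]) - log(pmax(pred[nz], epsilon))))
}

#' Per-bin Spearman correlation
#'
#' Rank correlation of the 16 paired fraction values, average ranks for
#' ties. Constant vectors have no defined rank correlation and yield `NA`.
#'
#' @param obs,pred Length-16 vectors.
#' @return Correlation in \[-1, 1\], or `NA` if either vector is constant.
#' @export
spearman_per_bin <- function(obs, pred) {
  if (length(unique(obs)) < 2 || length(unique(pred)) < 2) return(NA_real_)
  stats::cor(obs, pred, method = "spearman")
}

#' Cumulative replication fraction
#'
#' Prefix sums of a fraction profile: entry k is the proportion of cells
#' finished replicating by fraction k.
#'
#' @param profile Length-16 probability vector.
#' @return Non-decreasing length-16 vector ending at 1.
#' @export
cumulative_fraction <- function(profile) {
  cumsum(profile)
}

#' Kolmogorov-Smirnov distance between two profiles
#'
#' Maximum absolute difference between the cumulative replication fraction
#' curves.
#'
#' @param obs,pred Length-16 probability vectors.
#' @return Value in \[0, 1\].
#' @export
ks_distance <- function(obs, pred) {
  max(abs(cumsum(obs) - cumsum(pred)))
}

#' Wasserstein distance between two profiles
#'
#' Sum of absolute CDF differences with unit spacing between adjacent
#' fractions; equals the 1-d optimal transport cost on support 0..15.
#'
#' @param obs,pred Length-16 probability vectors.
#' @return Value in \[0, 15\].
#' @export
wasserstein_distance <- function(obs, pred) {
  sum(abs(cumsum(obs) - cumsum(pred)))
}

#' Five-metric evaluation of predicted profiles
#'
#' Computes the per-bin ARFE, KL divergence, Spearman correlation, KS and
#' Wasserstein distances of predictions against observations, plus mean and
#' median summaries. Bins with undefined Spearman (constant profile) are
#' excluded from that metric's summaries.
#'
#' @param obs,pred Matrices (bins x 16) of probability rows.
#' @param model_id Identifier recorded in the report.
#' @param epsilon KL floor for predicted probabilities.
#' @return List of class `"metric_report"`: `per_bin` (data.frame),
#'   `summary` (data.frame metric/mean/median), `model_id`.
#' @export
evaluate_profiles <- function(obs, pred, model_id = "model", epsilon = 1e-12) {
  stopifnot(all(dim(obs) == dim(pred)), ncol(obs) == 16)
  n <- nrow(obs)
  per <- data.frame(
    arfe = vapply(seq_len(n), function(i) arfe(obs[i, ], pred[i, ]), 1L),
    kl = vapply(seq_len(n), function(i) kl_per_bin(obs[i, ], pred[i, ], epsilon), 1),
    spearman = vapply(seq_len(n), function(i) spearman_per_bin(obs[i, ], pred[i, ]), 1),
    ks = vapply(seq_len(n), function(i) ks_distance(obs[i, ], pred[i, ]), 1),
    wasserstein = vapply(seq_len(n), function(i) wasserstein_distance(obs[i, ], pred[i, ]), 1))
  sm <- data.frame(
    metric = names(per),
    mean = vapply(per, function(v) mean(v, na.rm = TRUE), 1),
    median = vapply(per, function(v) stats::median(v, na.rm = TRUE), 1))
  rownames(sm) <- NULL
  structure(list(per_bin = per, summary = sm, model_id = model_id),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("Metric report for", x$model_id, "over", nrow(x$per_bin), "bins\n")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Single-feature quantile baseline
#'
#' Sorts a feature, partitions the bins into 16 equal-count quantile groups
#' (`group = floor(rank * 16 / n)`, stable input order for ties) and labels
#' group j with fraction j (ascending) or 15 - j (descending). Scored by
#' mean absolute error against the observed dominant fractions.
#'
#' @param feature Per-bin feature values (length >= 16).
#' @param direction `"ascending"` or `"descending"`.
#' @param observed_argmax Per-bin observed dominant fractions (0..15).
#' @param feature_name Label recorded in the result.
#' @return List of class `"quantile_baseline"`: `feature_name`, `direction`,
#'   `predicted_fraction` (integer per bin), `mae`.
#' @export
quantile_baseline <- function(feature, direction = c("ascending", "descending"),
                              observed_argmax = NULL, feature_name = "feature") {
  direction <- match.arg(direction)
  n <- length(feature)
  if (n < 16) stop("need at least 16 bins for a 16-quantile partition")
  rk <- numeric(n)
  rk[order(feature)] <- seq_len(n) - 1  # stable sort: ties keep input order
  grp <- as.integer(floor(rk * 16 / n))
  pred <- if (direction == "ascending") grp else 15L - grp
  mae <- if (is.null(observed_argmax)) NA_real_ else
    mean(abs(pred - observed_argmax))
  structure(list(feature_name = feature_name, direction = direction,
                 predicted_fraction = pred, mae = mae),
            class = "quantile_baseline")
}

#' Point-mass profiles from fraction labels
#'
#' Expands integer fraction labels (0..15) into bins x 16 probability rows
#' with all mass on the labeled fraction, so label predictors can enter the
#' distribution metrics.
#'
#' @param labels Integer vector in 0..15.
#' @return Matrix (length(labels) x 16).
#' @export
labels_to_profiles <- function(labels) {
  out <- matrix(0, length(labels), 16, dimnames = list(NULL, FRACTION_NAMES))
  out[cbind(seq_along(labels), labels + 1L)] <- 1
  out
}

#' Borda count across rankings
#'
#' For each ranking (e.g. one per cell line x metric) the best model earns
#' M-1 points and the worst 0; ties share the mean of the contested points.
#' Points are summed across rankings.
#'
#' @param values data.frame with columns `ranking` (id), `model`, `value`.
#' @param orientation Named vector mapping ranking id -> `"lower"` or
#'   `"higher"` (is better); or a single value recycled.
#' @return Named numeric vector of total points per model.
#' @export
borda_rank <- function(values, orientation = "lower") {
  models <- unique(values$model)
  rankings <- unique(values$ranking)
  if (length(orientation) == 1)
    orientation <- stats::setNames(rep(orientation, length(rankings)), rankings)
  pts <- stats::setNames(numeric(length(models)), models)
  M <- length(models)
  for (r in rankings) {
    sub <- values[values$ranking == r, ]
    if (!setequal(sub$model, models))
      stop("ranking ", r, " is missing model(s)")
    v <- sub$value[match(models, sub$model)]
    better_high <- identical(orientation[[as.character(r)]], "higher")
    # points M-1 (best) .. 0 (worst); ties share the mean of contested points
    rk <- rank(if (better_high) v else -v)   # 1 = worst under this sign
    pts <- pts + (rk - 1)
  }
  pts
}

#' One-sided paired Wilcoxon comparison of two per-bin metric vectors
#'
#' Wilcoxon signed-rank test on paired bins; zero differences are dropped.
#'
#' @param metric_a,metric_b Equal-length per-bin vectors, paired by bin.
#' @param alternative `"less"` or `"greater"` (a relative to b).
#' @return p-value, or `NA` if every difference is zero.
#' @export
paired_comparison <- function(metric_a, metric_b,
                              alternative = c("less", "greater")) {
  alternative <- match.arg(alternative)
  if (length(metric_a) != length(metric_b)) stop("unequal lengths")
  keep <- !is.na(metric_a) & !is.na(metric_b)
  d <- metric_a[keep] - metric_b[keep]
  if (all(d == 0)) return(NA_real_)
  suppressWarnings(stats::wilcox.test(metric_a[keep], metric_b[keep],
                                      paired = TRUE,
                                      alternative = alternative))$p.value
}
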