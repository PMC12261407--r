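# Replication kinetics from cumulative replication fractions: logistic fits
# per bin give T_rep (time of 50% completion) and T_width (time between 25%
# and 75% completion), on the continuous 0 (S1) to 15 (S16) fraction scale.

interp_crossing <- function(cdf, times, p) {
  if (cdf[1] >= p) return(times[1])
  i <- which(cdf >= p)[1]
  if (is.na(i)) return(times[length(times)])
  t0 <- times[i - 1]; t1 <- times[i]
  c0 <- cdf[i - 1]; c1 <- cdf[i]
  if (c1 == c0) return(t1)
  t0 + (p - c0) / (c1 - c0) * (t1 - t0)
}

#' Fit a logistic sigmoid to a cumulative replication fraction curve
#'
#' Least-squares fit of `f(t) = 1 / (1 + exp(-(t - t0)/s))` to the 16
#' cumulative values. Initialization: `t0` at the interpolated 0.5 crossing,
#' `s = 1`; bounds `t0` in \[-5, 20\], `s` in \[1e-3, 20\]. If the optimizer
#' fails the fit is flagged unconverged and `t_rep` falls back to the
#' interpolated crossing (with `t_width` undefined).
#'
#' @param cdf Length-16 non-decreasing cumulative vector.
#' @param times Evaluation times (default `0:15`).
#' @param tol Tolerance for the non-decreasing check.
#' @return List of class `"sigmoid_fit"`: `t0`, `s`, `rss`, `converged`,
#'   `t_rep`, `t_width`.
#' @export
fit_sigmoid <- function(cdf, times = 0:15, tol = 1e-8) {
  if (any(diff(cdf) < -tol)) stop("cumulative curve is decreasing")
  t0_init <- interp_crossing(cdf, times, 0.5)
  df <- data.frame(t = times, y = cdf)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ 1 / (1 + exp(-(t - t0) / s)), data = df,
                      start = list(t0 = min(max(t0_init, -5), 20), s = 1),
                      lower = c(-5, 1e-3), upper = c(20, 20),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    out <- list(t0 = NA_real_, s = NA_real_, rss = NA_real_,
                converged = FALSE, t_rep = t0_init, t_width = NA_real_)
  } else {
    cf <- stats::coef(fit)
    out <- list(t0 = unname(cf["t0"]), s = unname(cf["s"]),
                rss = sum(stats::residuals(fit)^2), converged = TRUE,
                t_rep = unname(cf["t0"]),
                t_width = 2 * unname(cf["s"]) * log(3))
  }
  class(out) <- "sigmoid_fit"
  out
}

#' Time of 50% replication
#'
#' For the logistic parameterization this is the fitted midpoint `t0`; an
#' unconverged fit reports the interpolation fallback.
#'
#' @param fit A `"sigmoid_fit"`.
#' @return Time on the 0-15 fraction scale.
#' @export
t_rep <- function(fit) fit$t_rep

#' Replication-timing heterogeneity width
#'
#' Time between 75% and 25% completion: `2 * s * log(3)` for the logistic
#' curve. `NA` for unconverged fits.
#'
#' @param fit A `"sigmoid_fit"`.
#' @return Nonnegative time, invariant to `t0`.
#' @export
t_width <- function(fit) fit$t_width

# Per-bin kinetics for a whole profile matrix.
#' Fit replication kinetics for every bin
#'
#' @param profiles Matrix (bins x 16) of probability rows.
#' @return data.frame with `t_rep`, `t_width`, `s`, `rss`, `converged`.
#' @export
profile_kinetics <- function(profiles) {
  rows <- lapply(seq_len(nrow(profiles)), function(i) {
    f <- fit_sigmoid(cumulative_fraction(profiles[i, ]))
    data.frame(t_rep = f$t_rep, t_width = f$t_width, s = f$s, rss = f$rss,
               converged = f$converged)
  })
  do.call(rbind, rows)
}

#' Concordance of observed and predicted T_rep
#'
#' Pearson correlation of per-bin `t_rep` values over bins where both
#' logistic fits converged.
#'
#' @param obs,pred Matrices (bins x 16) of probability rows, aligned.
#' @return Correlation; attribute `"n_excluded"` counts dropped bins.
#' @export
trep_concordance <- function(obs, pred) {
  stopifnot(all(dim(obs) == dim(pred)))
  ko <- profile_kinetics(obs)
  kp <- profile_kinetics(pred)
  use <- ko$converged & kp$converged
  if (sum(use) < 3) stop("fewer than 3 bins with successful fits")
  r <- stats::cor(ko$t_rep[use], kp$t_rep[use])
  attr(r, "n_excluded") <- sum(!use)
  r
}

#' Cumulative replication curves by initiation-zone temporal category
#'
#' Assigns bins to the IZ temporal categories (early S1-S3, early-mid S4-S6,
#' late-mid S7-S9, late S10-S12) by >= 1 bp overlap with the annotated
#' intervals; a bin overlapping several categories enters all of them
#' (reported via message). Empty categories are omitted with a warning.
#'
#' @param profiles Matrix (bins x 16).
#' @param bins Matching bin table (valid rows).
#' @param iz data.frame (`chrom`, `start`, `end`, `category`; 0-based
#'   half-open) or `GRanges` with a `category` column.
#' @return Named list per category: `curves` (bins x 16 CDF matrix),
#'   `mean_curve` (length 16), `bin_rows` (row indices).
#' @export
iz_category_curves <- function(profiles, bins, iz) {
  if (!is.data.frame(iz)) {
    iz <- data.frame(chrom = as.character(GenomicRanges::seqnames(iz)),
                     start = GenomicRanges::start(iz) - 1,
                     end = GenomicRanges::end(iz),
                     category = S4Vectors::mcols(iz)$category,
                     stringsAsFactors = FALSE)
  }
  cats <- c("early", "early-mid", "late-mid", "late")
  bad <- setdiff(unique(iz$category), cats)
  if (length(bad)) stop("unknown IZ category: ", paste(bad, collapse = ", "))
  bg <- GenomicRanges::GRanges(seqnames = norm_chrom(bins$chrom),
                               ranges = IRanges::IRanges(bins$start + 1, bins$end))
  cdfs <- t(apply(profiles, 1, cumulative_fraction))
  out <- list()
  assigned <- integer(nrow(bins))
  for (cat in cats) {
    sub <- iz[iz$category == cat, , drop = FALSE]
    if (nrow(sub) == 0) next
    gr <- GenomicRanges::GRanges(seqnames = norm_chrom(sub$chrom),
                                 ranges = IRanges::IRanges(sub$start + 1, sub$end))
    hit <- suppressWarnings(GenomicRanges::countOverlaps(bg, gr)) > 0
    if (!any(hit)) {
      warning("no bins overlap category ", cat, "; omitted")
      next
    }
    assigned[hit] <- assigned[hit] + 1L
    out[[cat]] <- list(curves = cdfs[hit, , drop = FALSE],
                       mean_curve = colMeans(cdfs[hit, , drop = FALSE]),
                       bin_rows = which(hit))
  }
  if (any(assigned > 1))
    message(sum(assigned > 1), " bin(s) assigned to multiple categories")
  out
}
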