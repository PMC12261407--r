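#' Fixed feature column order
#'
#' The nine per-bin features, in the column order used throughout the
#' package: six histone fold-change tracks, GC content, gene density, and
#' the two-stage (early/late log-ratio) replication timing.
#'
#' @export
FEATURE_NAMES <- c("H3K27ac", "H3K27me3", "H3K36me3", "H3K4me1", "H3K4me3",
                   "H3K9me3", "GC_content", "gene_density", "two_stage_RT")

#' Adjustment factor for the early/late log-ratio
#'
#' The most frequent absolute difference between consecutive per-bin RPKM
#' values, pooled over the early and late fractions. Differences are taken
#' within chromosomes only and rounded to `digits` decimals before the mode;
#' among equally frequent values the smallest wins. A modal value of 0 falls
#' back to the smallest nonzero rounded difference, or `epsilon` if all
#' differences are zero. The factor's sole purpose is to keep the log-ratio
#' denominator away from zero.
#'
#' @param early_rpkm,late_rpkm Genome-ordered per-bin RPKM vectors.
#' @param chrom Optional chromosome id per bin; differences never cross a
#'   chromosome boundary. Default: one chromosome.
#' @param digits Decimals used to discretize differences (default 3).
#' @param epsilon Fallback when every difference is zero (default 1e-3).
#' @return A nonnegative scalar.
#' @export
adjustment_factor <- function(early_rpkm, late_rpkm, chrom = NULL,
                              digits = 3, epsilon = 1e-3) {
  n <- length(early_rpkm)
  if (n != length(late_rpkm)) stop("early and late vectors differ in length")
  if (n < 2) stop("need at least 2 bins")
  if (is.null(chrom)) chrom <- rep("chr", n)
  diffs <- numeric(0)
  for (ch in unique(chrom)) {
    for (v in list(early_rpkm[chrom == ch], late_rpkm[chrom == ch])) {
      if (length(v) >= 2) diffs <- c(diffs, abs(diff(v)))
    }
  }
  if (length(diffs) == 0) stop("need at least 2 bins on some chromosome")
  d <- round(diffs, digits)
  tab <- table(d)
  vals <- as.numeric(names(tab))
  mode_val <- min(vals[tab == max(tab)])
  if (mode_val > 0) return(mode_val)
  nz <- vals[vals > 0]
  if (length(nz) > 0) min(nz) else epsilon
}

#' Two-stage replication timing feature
#'
#' Per-bin `log2((early + a) / (late + a))` of early and late S-phase RPKM,
#' the classic E/L Repli-Seq signal.
#'
#' @param early_rpkm,late_rpkm Per-bin RPKM vectors.
#' @param a Adjustment factor (see [adjustment_factor()]); must be positive
#'   whenever any late value is 0.
#' @return Numeric vector of log2 ratios.
#' @export
two_stage_rt <- function(early_rpkm, late_rpkm, a = 0) {
  if (a < 0) stop("adjustment factor must be nonnegative")
  den <- late_rpkm + a
  if (any(den == 0)) {
    stop("late RPKM + adjustment factor is zero at bin(s) ",
         paste(utils::head(which(den == 0), 5), collapse = ", "))
  }
  log2((early_rpkm + a) / den)
}

#' Assemble the n x 9 feature matrix
#'
#' Binds the nine aligned per-bin vectors into a matrix with the fixed
#' column order of [FEATURE_NAMES], restricted to valid bins. With
#' `scale = TRUE` each column is centered and scaled; the statistics (by
#' default computed on the rows themselves, or on the rows flagged by
#' `train_rows` so that test data can reuse training-split statistics) are
#' stored in the result for exact inversion. A zero-variance column keeps a
#' divisor of 1.
#'
#' @param histones Named list or 9-less matrix of the six histone vectors in
#'   the order H3K27ac, H3K27me3, H3K36me3, H3K4me1, H3K4me3, H3K9me3.
#' @param gc,density,rt2 The remaining three feature vectors.
#' @param bins Bin table; rows with `valid == FALSE` are dropped.
#' @param scale Standardize columns (default TRUE).
#' @param train_rows Optional logical/integer subset of the *valid* rows on
#'   which scaling statistics are computed.
#' @param scaling Optional precomputed scaling record (list with `center`,
#'   `scale`) to apply instead of computing one.
#' @return List of class `"feature_matrix"`: `values` (matrix), `bins`
#'   (valid-bin table), `scaling` (list or `"none"`).
#' @export
assemble_features <- function(histones, gc, density, rt2, bins,
                              scale = TRUE, train_rows = NULL, scaling = NULL) {
  if (is.list(histones)) histones <- do.call(cbind, histones)
  mat <- cbind(histones, gc, density, rt2)
  if (ncol(mat) != 9) stop("expected 6 histone columns + gc + density + rt2")
  colnames(mat) <- FEATURE_NAMES
  if (nrow(mat) != nrow(bins)) stop("feature vectors not aligned to bin table")
  keep <- bins$valid
  mat <- mat[keep, , drop = FALSE]
  if (any(!is.finite(mat))) stop("non-finite feature values after assembly")
  sc <- "none"
  if (!is.null(scaling)) {
    mat <- sweep(sweep(mat, 2, scaling$center, "-"), 2, scaling$scale, "/")
    sc <- scaling
  } else if (scale) {
    ref <- if (is.null(train_rows)) mat else mat[train_rows, , drop = FALSE]
    ctr <- colMeans(ref)
    sdv <- apply(ref, 2, stats::sd)
    sdv[!is.finite(sdv) | sdv == 0] <- 1
    mat <- sweep(sweep(mat, 2, ctr, "-"), 2, sdv, "/")
    sc <- list(center = ctr, scale = sdv)
  }
  structure(list(values = mat, bins = bins[keep, , drop = FALSE], scaling = sc),
            class = "feature_matrix")
}

#' Undo feature standardization
#'
#' @param fm A `"feature_matrix"` with a stored scaling record.
#' @return The raw (unscaled) matrix.
#' @export
unscale_features <- function(fm) {
  if (identical(fm$scaling, "none")) return(fm$values)
  sweep(sweep(fm$values, 2, fm$scaling$scale, "*"), 2, fm$scaling$center, "+")
}

#' Write a feature matrix as TSV (+ JSON scaling sidecar)
#'
#' @param fm `"feature_matrix"` object.
#' @param path Output TSV path; the scaling record goes to
#'   `paste0(path, ".scaling.json")` when scaling was applied.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- cbind(fm$bins[, c("chrom", "start", "end")], as.data.frame(fm$values))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!identical(fm$scaling, "none")) {
    jsonlite::write_json(lapply(fm$scaling, as.list),
                         paste0(path, ".scaling.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Read a feature matrix TSV written by [write_feature_matrix()]
#'
#' @param path TSV path.
#' @return `"feature_matrix"` object (scaling reloaded if the sidecar exists).
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  vals <- as.matrix(df[, FEATURE_NAMES])
  bins <- data.frame(chrom = df$chrom, start = df$start, end = df$end,
                     index = NA_integer_, valid = TRUE, stringsAsFactors = FALSE)
  side <- paste0(path, ".scaling.json")
  sc <- "none"
  if (file.exists(side)) {
    raw <- jsonlite::read_json(side, simplifyVector = TRUE)
    sc <- list(center = unlist(raw$center), scale = unlist(raw$scale))
  }
  structure(list(values = vals, bins = bins, scaling = sc),
            class = "feature_matrix")
}
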