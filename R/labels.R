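#' Fraction labels S1..S16
#' @export
FRACTION_NAMES <- paste0("S", 1:16)

#' Load a 16-fraction replication-timing matrix
#'
#' Accepts the deposited fraction-by-bin layout (16 rows S1..S16, one column
#' per 50-kb bin with `chrom:start-end` or `chrom_start_end` headers) or its
#' transpose; orientation is auto-detected from the shape. An optional first
#' column of fraction names is recognized.
#'
#' @param path TSV/CSV path.
#' @param bins Optional companion bin table supplying coordinates when the
#'   headers do not encode them.
#' @param sep Field separator (default tab).
#' @return List: `matrix` (bins x 16, columns S1..S16) and `bins` (bin table
#'   parsed from headers or passed through).
#' @export
load_rt_matrix <- function(path, bins = NULL, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = c("NA", "N/A", "NaN"))
  first_chr <- is.character(df[[1]]) || all(grepl("^S[0-9]+$", df[[1]]))
  row_ids <- NULL
  if (is.character(df[[1]])) {
    row_ids <- df[[1]]
    df <- df[, -1, drop = FALSE]
  }
  m <- as.matrix(df)
  headers <- colnames(m)
  if (nrow(m) == 16) {
    mat <- t(m)
    bin_ids <- headers
  } else if (ncol(m) == 16) {
    mat <- m
    bin_ids <- row_ids
  } else {
    stop("neither dimension of the table equals 16 fractions (",
         nrow(m), " x ", ncol(m), ")")
  }
  dimnames(mat) <- list(NULL, FRACTION_NAMES)
  if (is.null(bins)) {
    bins <- parse_bin_ids(bin_ids, nrow(mat))
  }
  if (nrow(bins) != nrow(mat)) stop("bin table does not match matrix rows")
  list(matrix = mat, bins = bins)
}

parse_bin_ids <- function(ids, n) {
  if (is.null(ids) || !any(grepl("[:_-]", ids))) {
    return(data.frame(chrom = rep(NA_character_, n), start = NA_real_,
                      end = NA_real_, index = seq_len(n) - 1L, valid = TRUE,
                      stringsAsFactors = FALSE))
  }
  parts <- regmatches(ids, regexec("^(.+?)[:_]([0-9]+)[-_]([0-9]+)$", ids))
  bad <- vapply(parts, length, 1L) != 4
  if (any(bad)) stop("unparseable bin header(s): ",
                     paste(utils::head(ids[bad], 3), collapse = ", "))
  data.frame(chrom = vapply(parts, `[`, "", 2),
             start = as.numeric(vapply(parts, `[`, "", 3)),
             end = as.numeric(vapply(parts, `[`, "", 4)),
             index = seq_len(n) - 1L, valid = TRUE, stringsAsFactors = FALSE)
}

#' Filter bins by label quality and blacklist overlap
#'
#' Marks a bin invalid when its 16 fraction values are all zero, contain any
#' missing value, or the bin overlaps a blacklist interval by at least one
#' base pair.
#'
#' @param raw Bins x 16 matrix aligned to `bins`.
#' @param bins Bin table.
#' @param blacklist Optional `GRanges` or data.frame (`chrom`,`start`,`end`,
#'   0-based half-open) of excluded regions.
#' @return `bins` with an updated `valid` column; attribute `"filter_report"`
#'   holds counts removed per rule.
#' @export
filter_bins <- function(raw, bins, blacklist = NULL) {
  if (nrow(raw) != nrow(bins)) stop("matrix not aligned to bin table")
  any_na <- apply(raw, 1, function(r) any(is.na(r)))
  all_zero <- !any_na & apply(raw, 1, function(r) all(r == 0))
  black <- rep(FALSE, nrow(bins))
  if (!is.null(blacklist)) {
    if (is.data.frame(blacklist)) {
      blacklist <- GenomicRanges::GRanges(
        seqnames = norm_chrom(blacklist$chrom),
        ranges = IRanges::IRanges(start = blacklist$start + 1, end = blacklist$end))
    } else if (length(blacklist) > 0) {
      blacklist <- GenomicRanges::GRanges(
        seqnames = norm_chrom(GenomicRanges::seqnames(blacklist)),
        ranges = IRanges::ranges(blacklist))
    }
    if (length(blacklist) > 0) {
      bg <- GenomicRanges::GRanges(
        seqnames = norm_chrom(bins$chrom),
        ranges = IRanges::IRanges(start = bins$start + 1, end = bins$end))
      black <- suppressWarnings(
        GenomicRanges::countOverlaps(bg, blacklist)) > 0
    }
  }
  bins$valid <- bins$valid & !(any_na | all_zero | black)
  attr(bins, "filter_report") <- c(na = sum(any_na), all_zero = sum(all_zero),
                                   blacklist = sum(black))
  bins
}

#' Normalize fraction profiles to probability vectors
#'
#' Clips negative entries to zero, then divides each row by its sum so the
#' 16 fraction values sum to 1.
#'
#' @param raw Matrix (rows = bins over which [filter_bins()] already ran, so
#'   no all-zero/NA rows remain).
#' @return Matrix of row-stochastic profiles, columns S1..S16.
#' @export
normalize_profiles <- function(raw) {
  if (any(is.na(raw))) stop("missing values present; run filter_bins first")
  m <- pmax(raw, 0)
  s <- rowSums(m)
  if (any(s == 0)) {
    stop("row(s) all-zero after clipping negatives: bin ",
         paste(utils::head(which(s == 0), 5), collapse = ", "))
  }
  out <- m / s
  colnames(out) <- FRACTION_NAMES
  out
}

#' Write profiles as TSV with coordinates
#'
#' @param profiles Bins x 16 matrix.
#' @param bins Matching bin table (valid rows only).
#' @param path Output path.
#' @export
write_profiles <- function(profiles, bins, path) {
  df <- cbind(bins[, c("chrom", "start", "end")], as.data.frame(profiles))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a profiles TSV written by [write_profiles()]
#' @param path TSV path.
#' @return List: `matrix` (bins x 16), `bins`.
#' @export
read_profiles <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  list(matrix = as.matrix(df[, FRACTION_NAMES]),
       bins = data.frame(chrom = df$chrom, start = df$start, end = df$end,
                         index = NA_integer_, valid = TRUE,
                         stringsAsFactors = FALSE))
}
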