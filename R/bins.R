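#' Read a chrom.sizes file
#'
#' Two-column whitespace-separated text: chromosome name and length in bp.
#'
#' @param path Path to the chrom.sizes file.
#' @return Named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "", stringsAsFactors = FALSE,
                          col.names = c("chrom", "length"))
  stats::setNames(as.numeric(df$length), df$chrom)
}

#' Partition a genome into fixed-size bins
#'
#' Cuts each chromosome into consecutive `bin_size`-bp bins (0-based,
#' half-open coordinates). The final bin of a chromosome is truncated at the
#' chromosome end and kept.
#'
#' @param chrom_sizes Named numeric vector of chromosome lengths in bp.
#' @param bin_size Bin width in bp (default 50000, the working resolution of
#'   16-fraction Repli-Seq).
#' @return A bin table: data.frame with columns `chrom`, `start`, `end`,
#'   `index` (0-based ordinal within chromosome) and `valid` (logical mask,
#'   all `TRUE` initially).
#' @export
bin_genome <- function(chrom_sizes, bin_size = 50000L) {
  if (bin_size <= 0) stop("bin_size must be positive")
  if (length(chrom_sizes) == 0) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      index = integer(), valid = logical()))
  }
  if (any(chrom_sizes <= 0)) stop("all chromosome lengths must be positive")
  pieces <- lapply(names(chrom_sizes), function(ch) {
    len <- chrom_sizes[[ch]]
    n <- ceiling(len / bin_size)
    start <- (seq_len(n) - 1) * bin_size
    data.frame(chrom = ch, start = start,
               end = pmin(start + bin_size, len),
               index = seq_len(n) - 1L,
               valid = TRUE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

# GRanges view of a bin table (1-based closed coordinates for IRanges).
bins_to_granges <- function(bins) {
  GenomicRanges::GRanges(
    seqnames = bins$chrom,
    ranges = IRanges::IRanges(start = bins$start + 1, end = bins$end)
  )
}

# Strip a leading "chr" prefix so hg/mm style names compare equal.
norm_chrom <- function(x) sub("^chr", "", as.character(x))
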