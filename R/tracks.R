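#' Read a signal track (bedGraph or bigWig)
#'
#' Thin wrapper over [rtracklayer::import()] returning a `GRanges` with a
#' `score` column. Format is guessed from the file extension unless given.
#'
#' @param path File path.
#' @param format Optional explicit format ("bedGraph" or "BigWig").
#' @return `GRanges` with metadata column `score`.
#' @export
read_signal_track <- function(path, format = NULL) {
  gr <- if (is.null(format)) rtracklayer::import(path) else
    rtracklayer::import(path, format = format)
  if (!"score" %in% names(S4Vectors::mcols(gr)))
    stop("track has no score column: ", path)
  gr
}

#' Read a BED file of intervals
#'
#' @param path BED3+ file.
#' @return `GRanges`.
#' @export
read_bed <- function(path) {
  rtracklayer::import(path, format = "BED")
}

# Coerce data.frame (chrom,start,end,value; 0-based half-open) or GRanges
# with score into a normalized-chromosome GRanges.
as_signal_granges <- function(track) {
  if (is.data.frame(track)) {
    gr <- GenomicRanges::GRanges(
      seqnames = norm_chrom(track$chrom),
      ranges = IRanges::IRanges(start = track$start + 1, end = track$end))
    S4Vectors::mcols(gr)$score <- track$value
    gr
  } else {
    gr <- track
    GenomicRanges::GRanges(
      seqnames = norm_chrom(GenomicRanges::seqnames(gr)),
      ranges = IRanges::ranges(gr),
      score = S4Vectors::mcols(gr)$score)
  }
}

#' Per-bin mean signal
#'
#' Length-weighted mean of a coverage/fold-change track over each bin. Base
#' pairs not covered by any interval contribute value 0, i.e. the denominator
#' is always the full bin length.
#'
#' @param track `GRanges` with `score`, or data.frame with columns
#'   `chrom`, `start`, `end`, `value` (0-based half-open).
#' @param bins Bin table from [bin_genome()].
#' @return Numeric vector, one mean per bin row.
#' @export
mean_signal <- function(track, bins) {
  gr <- as_signal_granges(track)
  bg <- GenomicRanges::GRanges(
    seqnames = norm_chrom(bins$chrom),
    ranges = IRanges::IRanges(start = bins$start + 1, end = bins$end))
  missing_chr <- !(norm_chrom(bins$chrom) %in%
                     unique(as.character(GenomicRanges::seqnames(gr))))
  if (any(missing_chr) && length(gr) > 0)
    warning("no signal on chromosome(s): ",
            paste(unique(bins$chrom[missing_chr]), collapse = ", "),
            "; zeros assigned")
  out <- numeric(nrow(bins))
  if (length(gr) == 0) return(out)
  hits <- suppressWarnings(GenomicRanges::findOverlaps(bg, gr))
  if (length(hits) == 0) return(out)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov <- IRanges::pintersect(IRanges::ranges(bg)[qi], IRanges::ranges(gr)[si])
  contrib <- IRanges::width(ov) * S4Vectors::mcols(gr)$score[si]
  sums <- tapply(contrib, qi, sum)
  out[as.integer(names(sums))] <- as.numeric(sums)
  out / (bins$end - bins$start)
}

#' Per-bin gene counts
#'
#' Number of annotation records overlapping each bin by at least one base
#' pair. Records are counted as given: duplicates and isoforms each count,
#' and a record spanning several bins increments all of them.
#'
#' @param genes `GRanges`, or data.frame with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param bins Bin table.
#' @return Integer vector of counts per bin row.
#' @export
gene_density <- function(genes, bins) {
  if (is.data.frame(genes)) {
    genes <- GenomicRanges::GRanges(
      seqnames = norm_chrom(genes$chrom),
      ranges = IRanges::IRanges(start = genes$start + 1, end = genes$end))
  } else if (length(genes) > 0) {
    genes <- GenomicRanges::GRanges(
      seqnames = norm_chrom(GenomicRanges::seqnames(genes)),
      ranges = IRanges::ranges(genes))
  }
  bg <- GenomicRanges::GRanges(
    seqnames = norm_chrom(bins$chrom),
    ranges = IRanges::IRanges(start = bins$start + 1, end = bins$end))
  if (length(genes) == 0) return(integer(nrow(bins)))
  suppressWarnings(GenomicRanges::countOverlaps(bg, genes))
}

#' Per-bin GC content
#'
#' Fraction of base pairs that are G or C (case-insensitive) in each bin.
#' Ambiguity codes (N etc.) count in the denominator only.
#'
#' @param sequences Named `DNAStringSet` (or named character vector) of
#'   chromosome sequences.
#' @param bins Bin table; every bin must lie within its sequence.
#' @return Numeric vector of fractions in \[0, 1\].
#' @export
gc_content <- function(sequences, bins) {
  if (is.character(sequences)) sequences <- Biostrings::DNAStringSet(sequences)
  seq_names <- norm_chrom(names(sequences))
  out <- numeric(nrow(bins))
  for (ch in unique(bins$chrom)) {
    idx <- which(bins$chrom == ch)
    si <- match(norm_chrom(ch), seq_names)
    if (is.na(si)) stop("no sequence for chromosome ", ch)
    sq <- sequences[[si]]
    if (max(bins$end[idx]) > length(sq))
      stop("bin extends past end of sequence for chromosome ", ch)
    views <- Biostrings::Views(sq, start = bins$start[idx] + 1, end = bins$end[idx])
    gc <- Biostrings::letterFrequency(views, letters = c("G", "C"))
    out[idx] <- rowSums(gc) / (bins$end[idx] - bins$start[idx])
  }
  out
}

#' RPKM normalization of per-bin read counts
#'
#' @param counts Integer vector of reads per bin.
#' @param bins Bin table (bin lengths taken from coordinates).
#' @param total_mapped_reads Library size; must be positive.
#' @return Numeric vector: `count / ((bin_length/1e3) * (total/1e6))`.
#' @export
rpkm <- function(counts, bins, total_mapped_reads) {
  if (length(counts) != nrow(bins)) stop("counts and bins differ in length")
  if (total_mapped_reads <= 0) stop("total_mapped_reads must be positive")
  counts / (((bins$end - bins$start) / 1e3) * (total_mapped_reads / 1e6))
}
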