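# Emission of toy raw files for a synthetic cell line, and the matching
# re-ingestion path through the feature pipeline. The emitted FASTA has the
# exact per-bin GC fraction of the feature matrix and the gene BED the exact
# per-bin counts, so round-tripping is exact for those two features and
# within text-precision rounding for the signal tracks.

fmt_num <- function(x) formatC(x, format = "g", digits = 17)

write_bedgraph <- function(bins, values, path) {
  df <- data.frame(bins$chrom, format(bins$start, scientific = FALSE, trim = TRUE),
                   format(bins$end, scientific = FALSE, trim = TRUE),
                   fmt_num(values))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Write the toy raw files for a synthetic cell line
#'
#' Emits chrom.sizes, genome.fa (per-bin GC matched exactly), one bedGraph
#' per histone mark, early/late RPKM bedGraphs, genes.bed (per-bin counts
#' matched exactly, genes nested within bins), blacklist.bed, izs.bed (with
#' a category column) and the 16-fraction label matrix TSV in the deposited
#' fraction-by-bin layout.
#'
#' @param sim A `"synth_cell_line"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_files <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bins <- sim$bins
  utils::write.table(
    data.frame(names(sim$chrom_sizes),
               format(sim$chrom_sizes, scientific = FALSE, trim = TRUE)),
    file.path(dir, "chrom.sizes"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)

  # genome with exact per-bin GC
  gc_counts <- round(sim$features$values[, "GC_content"] * (bins$end - bins$start))
  seqs <- lapply(names(sim$chrom_sizes), function(ch) {
    idx <- which(bins$chrom == ch)
    parts <- lapply(idx, function(i) {
      L <- bins$end[i] - bins$start[i]
      g <- gc_counts[i]
      paste(sample(c(rep(c("G", "C"), length.out = g),
                     rep(c("A", "T"), length.out = L - g))), collapse = "")
    })
    paste(unlist(parts), collapse = "")
  })
  names(seqs) <- names(sim$chrom_sizes)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(unlist(seqs)),
                              file.path(dir, "genome.fa"))

  for (nm in names(SYNTH_FEATURE_MAPS))
    write_bedgraph(bins, sim$features$values[, nm],
                   file.path(dir, paste0(nm, ".bedGraph")))
  write_bedgraph(bins, sim$early_rpkm, file.path(dir, "early_rpkm.bedGraph"))
  write_bedgraph(bins, sim$late_rpkm, file.path(dir, "late_rpkm.bedGraph"))

  # genes: per-bin counts realized as short intervals nested in the bin
  dens <- sim$features$values[, "gene_density"]
  gene_rows <- list()
  for (i in which(dens > 0)) {
    k <- dens[i]
    L <- bins$end[i] - bins$start[i]
    w <- max(1, floor(L / (2 * k)))
    st <- bins$start[i] + (seq_len(k) - 1) * floor(L / k)
    gene_rows[[length(gene_rows) + 1]] <- data.frame(
      chrom = bins$chrom[i], start = st, end = st + w,
      name = paste0("g", i, "_", seq_len(k)), stringsAsFactors = FALSE)
  }
  genes <- if (length(gene_rows)) do.call(rbind, gene_rows) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               name = character())
  utils::write.table(
    data.frame(genes$chrom, format(genes$start, scientific = FALSE, trim = TRUE),
               format(genes$end, scientific = FALSE, trim = TRUE), genes$name),
    file.path(dir, "genes.bed"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)

  # a small blacklist: clip 1 bp into the last bin of chromosome 1
  ch1 <- bins[bins$chrom == names(sim$chrom_sizes)[1], ]
  last <- ch1[nrow(ch1), ]
  utils::write.table(
    data.frame(last$chrom,
               format(last$end - 1, scientific = FALSE, trim = TRUE),
               format(last$end, scientific = FALSE, trim = TRUE)),
    file.path(dir, "blacklist.bed"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)

  if (nrow(sim$izs) > 0) {
    utils::write.table(
      data.frame(sim$izs$chrom,
                 format(sim$izs$start, scientific = FALSE, trim = TRUE),
                 format(sim$izs$end, scientific = FALSE, trim = TRUE),
                 sim$izs$category),
      file.path(dir, "izs.bed"), sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
  }

  # labels in the deposited layout: rows S1..S16, columns chrom:start-end
  lab <- t(sim$labels)
  ids <- paste0(bins$chrom, ":", format(bins$start, scientific = FALSE, trim = TRUE),
                "-", format(bins$end, scientific = FALSE, trim = TRUE))
  df <- data.frame(fraction = FRACTION_NAMES,
                   matrix(fmt_num(lab), nrow = 16), stringsAsFactors = FALSE)
  colnames(df) <- c("fraction", ids)
  utils::write.table(df, file.path(dir, "labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Rebuild the feature matrix from raw files
#'
#' The full feature pipeline over a directory of standard files: bins the
#' genome from chrom.sizes, takes per-bin mean fold-change of each histone
#' bedGraph, GC content from the FASTA, gene counts from the BED, early/late
#' RPKM bedGraphs through the adjustment factor into the two-stage RT
#' log-ratio, and assembles the nine columns.
#'
#' @param dir Directory as written by [write_synthetic_files()] (or any
#'   directory using those file names).
#' @param bin_size Bin width in bp.
#' @param scale Standardize columns (default `FALSE`: raw values).
#' @return A `"feature_matrix"`.
#' @export
ingest_features <- function(dir, bin_size = 50000L, scale = FALSE) {
  sizes <- read_chrom_sizes(file.path(dir, "chrom.sizes"))
  bins <- bin_genome(sizes, bin_size)
  histones <- lapply(names(SYNTH_FEATURE_MAPS), function(nm)
    mean_signal(read_signal_track(file.path(dir, paste0(nm, ".bedGraph"))), bins))
  seqs <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  gc <- gc_content(seqs, bins)
  genes_path <- file.path(dir, "genes.bed")
  genes <- if (file.size(genes_path) > 0) read_bed(genes_path) else
    GenomicRanges::GRanges()
  dens <- gene_density(genes, bins)
  early <- mean_signal(read_signal_track(file.path(dir, "early_rpkm.bedGraph")), bins)
  late <- mean_signal(read_signal_track(file.path(dir, "late_rpkm.bedGraph")), bins)
  a <- adjustment_factor(early, late, chrom = bins$chrom)
  rt2 <- two_stage_rt(early, late, a)
  assemble_features(histones, gc, dens, rt2, bins, scale = scale)
}
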