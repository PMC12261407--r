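test_that("bin_genome partitions chromosomes with a truncated last bin", {
  b <- bin_genome(c(chrA = 150000), 50000)
  expect_equal(nrow(b), 3)
  expect_equal(b$start, c(0, 50000, 100000))
  expect_equal(b$end, c(50000, 100000, 150000))

  b2 <- bin_genome(c(chrA = 125000), 50000)
  expect_equal(nrow(b2), 3)
  expect_equal(b2$end[3], 125000)
  expect_equal(b2$end[3] - b2$start[3], 25000)

  expect_equal(nrow(bin_genome(numeric(0))), 0)
  expect_error(bin_genome(c(chrA = 0)), "positive")
  expect_error(bin_genome(c(chrA = 100), bin_size = 0), "positive")

  # ordering: chromosome-major then start-ascending
  b3 <- bin_genome(c(chr1 = 100000, chr2 = 100000), 50000)
  expect_equal(b3$chrom, c("chr1", "chr1", "chr2", "chr2"))
  expect_true(all(diff(b3$start[b3$chrom == "chr1"]) > 0))
})

test_that("mean_signal is the length-weighted mean with uncovered bp as 0", {
  bins <- bin_genome(c(chr1 = 100000), 50000)
  full <- data.frame(chrom = "chr1", start = 0, end = 50000, value = 2.0)
  expect_equal(mean_signal(full, bins), c(2.0, 0))

  half <- data.frame(chrom = "chr1", start = 0, end = 25000, value = 4.0)
  expect_equal(mean_signal(half, bins)[1], 2.0)

  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), value = numeric())
  expect_equal(mean_signal(empty, bins), c(0, 0))

  # chromosome absent from the track: warning + zeros there
  bins2 <- bin_genome(c(chr1 = 50000, chr2 = 50000), 50000)
  expect_warning(v <- mean_signal(full, bins2), "chr2")
  expect_equal(v, c(2, 0))
})

test_that("mean_signal of a sub-interval indicator equals the covered fraction", {
  set.seed(71)
  bins <- bin_genome(c(chr1 = 200000), 50000)
  for (rep in 1:20) {
    i <- sample(4, 1)
    a <- bins$start[i] + sample(0:49000, 1)
    b <- min(a + sample(1:49999, 1), bins$end[i])
    tr <- data.frame(chrom = "chr1", start = a, end = b, value = 1)
    got <- mean_signal(tr, bins)[i]
    expect_equal(got, (b - a) / 50000, tolerance = 1e-12)
  }
})

test_that("gene_density counts >=1 bp overlaps, records as given", {
  bins <- bin_genome(c(chr1 = 100000), 50000)
  spanning <- data.frame(chrom = "chr1", start = 49000, end = 51000)
  expect_equal(gene_density(spanning, bins), c(1L, 1L))

  exact <- data.frame(chrom = "chr1", start = 0, end = 50000)
  expect_equal(gene_density(exact, bins), c(1L, 0L))

  dup <- rbind(exact, exact)
  expect_equal(gene_density(dup, bins), c(2L, 0L))

  expect_equal(gene_density(exact[0, ], bins), c(0L, 0L))
})

test_that("gene_density matches a brute-force overlap counter", {
  set.seed(12)
  bins <- bin_genome(c(c1 = 10000, c2 = 7000), 1000)
  for (rep in 1:10) {
    ng <- sample(1:30, 1)
    genes <- data.frame(chrom = sample(c("c1", "c2"), ng, TRUE),
                        start = sample(0:9000, ng, TRUE))
    genes$end <- genes$start + sample(1:3000, ng, TRUE)
    brute <- vapply(seq_len(nrow(bins)), function(i) {
      sum(genes$chrom == bins$chrom[i] &
            genes$start < bins$end[i] & genes$end > bins$start[i])
    }, 1L)
    expect_equal(as.integer(gene_density(genes, bins)), brute)
  }
})

test_that("gc_content counts G+C over the full bin length", {
  bins <- data.frame(chrom = "c", start = 0, end = 4, index = 0L, valid = TRUE)
  expect_equal(gc_content(c(c = "GCGC"), bins), 1.0)
  expect_equal(gc_content(c(c = "GATC"), bins), 0.5)
  expect_equal(gc_content(c(c = "GCNN"), bins), 0.5)
  bad <- data.frame(chrom = "c", start = 0, end = 10, index = 0L, valid = TRUE)
  expect_error(gc_content(c(c = "GATC"), bad), "past end")
})

test_that("rpkm normalizes by bin kb and library millions", {
  bins <- bin_genome(c(chr1 = 125000), 50000)
  expect_equal(rpkm(c(50, 0, 75), bins, 1e6)[1:2], c(1, 0))
  expect_equal(rpkm(c(0, 0, 75), bins, 2e6)[3], 1.5)  # 25-kb truncated bin
  expect_error(rpkm(c(1, 1, 1), bins, 0), "positive")
})

test_that("adjustment_factor takes the modal rounded |difference| with fallbacks", {
  expect_equal(adjustment_factor(c(1, 1.5, 2), c(3, 3.5, 4)), 0.5)
  # constant vectors: mode 0, no nonzero differences -> epsilon
  expect_equal(adjustment_factor(c(1, 1, 1), c(2, 2, 2)), 1e-3)
  # mode 0 with nonzero present -> smallest nonzero
  expect_equal(adjustment_factor(c(0, 1, 1), c(2, 2, 3)), 1.0)
  expect_error(adjustment_factor(1, 2), "at least 2")
})

test_that("adjustment_factor never crosses chromosome boundaries", {
  e <- c(1, 2, 100, 101); l <- c(5, 6, 300, 301)
  chrom <- c("a", "a", "b", "b")
  a1 <- adjustment_factor(e, l, chrom = chrom)
  # concatenation order of chromosomes is irrelevant
  ord <- c(3, 4, 1, 2)
  a2 <- adjustment_factor(e[ord], l[ord], chrom = chrom[ord])
  expect_equal(a1, a2)
  expect_equal(a1, 1)  # within-chromosome diffs are all 1
})

test_that("two_stage_rt is the shifted log2 ratio and antisymmetric", {
  expect_equal(two_stage_rt(2, 1, 0), 1.0)
  expect_equal(two_stage_rt(3, 1, 1), 1.0)
  x <- c(1, 2, 3); expect_equal(two_stage_rt(x, x, 0.5), rep(0, 3))
  set.seed(4)
  e <- rexp(20); l <- rexp(20)
  expect_equal(two_stage_rt(e, l, 0.3), -two_stage_rt(l, e, 0.3))
  expect_error(two_stage_rt(1, 0, 0), "zero")
})

test_that("assemble_features enforces order, masking and invertible scaling", {
  set.seed(9)
  n <- 40
  bins <- bin_genome(c(chr1 = n * 1000), 1000)
  bins$valid[c(3, 17)] <- FALSE
  hist6 <- replicate(6, rnorm(n))
  fm <- assemble_features(hist6, runif(n), rpois(n, 2), rnorm(n), bins,
                          scale = TRUE)
  expect_equal(colnames(fm$values), FEATURE_NAMES)
  expect_equal(nrow(fm$values), n - 2)
  expect_true(all(is.finite(fm$values)))
})

test_that("scaling round-trips and guards constant columns", {
  set.seed(10)
  n <- 30
  bins <- bin_genome(c(chr1 = n * 1000), 1000)
  hist6 <- replicate(6, rnorm(n))
  gc <- runif(n); dens <- rpois(n, 2); rt2 <- rnorm(n)
  raw <- assemble_features(hist6, gc, dens, rt2, bins, scale = FALSE)
  sc <- assemble_features(hist6, gc, dens, rt2, bins, scale = TRUE)
  expect_equal(unscale_features(sc), raw$values, tolerance = 1e-10)
  # constant column scales to zeros, divisor guarded to 1
  sc2 <- assemble_features(hist6, rep(0.5, n), dens, rt2, bins, scale = TRUE)
  expect_equal(unname(sc2$values[, "GC_content"]), rep(0, n))
  expect_equal(unname(sc2$scaling$scale["GC_content"]), 1)
  expect_error(suppressWarnings(
    assemble_features(hist6[-1, ], gc, dens, rt2, bins)), "aligned")
})

test_that("feature matrix TSV + scaling sidecar round-trips", {
  set.seed(11)
  n <- 20
  bins <- bin_genome(c(chr1 = n * 1000), 1000)
  fm <- assemble_features(replicate(6, rnorm(n)), runif(n), rpois(n, 1),
                          rnorm(n), bins, scale = TRUE)
  path <- file.path(tempdir(), "fm.tsv")
  write_feature_matrix(fm, path)
  back <- read_feature_matrix(path)
  expect_equal(unname(back$values), unname(fm$values), tolerance = 1e-6)
  expect_equal(back$scaling$center, fm$scaling$center, tolerance = 1e-6)
})
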