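small_spec <- function(...) {
  synth_spec(n_chromosomes = 2, bins_per_chromosome = 48, bin_size = 2000, ...)
}

test_that("the generator is fully seed-deterministic", {
  a <- simulate_cell_line(small_spec(seed = 5))
  b <- simulate_cell_line(small_spec(seed = 5))
  expect_identical(a$labels, b$labels)
  expect_identical(a$features$values, b$features$values)
  expect_identical(a$izs, b$izs)
  c_ <- simulate_cell_line(small_spec(seed = 6))
  expect_false(identical(a$labels, c_$labels))
})

test_that("latent timing smoothness controls autocorrelation", {
  lag1 <- vapply(c(2, 10, 30), function(sm) {
    mean(vapply(1:5, function(sd_) {
      lat <- generate_latent_timing(synth_spec(n_chromosomes = 1,
                                               bins_per_chromosome = 400,
                                               timing_smoothness = sm,
                                               seed = sd_))
      acf_series(lat$t0, 1)[1]
    }, 1))
  }, 1)
  expect_true(all(diff(lag1) > 0))
  # infinite smoothness: constant timing
  lat_inf <- generate_latent_timing(synth_spec(n_chromosomes = 1,
                                               bins_per_chromosome = 64,
                                               timing_smoothness = Inf, seed = 3))
  expect_equal(lat_inf$t0, rep(7.5, 64))
  # bounds and width pattern: s largest near mid-S
  lat <- generate_latent_timing(synth_spec(seed = 4))
  expect_true(all(lat$t0 >= 0 & lat$t0 <= 15))
  expect_gt(cor(-abs(lat$t0 - 7.5), lat$s), 0.95)
})

test_that("labels_from_timing yields unimodal rows that refit their parameters", {
  pr <- labels_from_timing(c(4, 7.5, 11), c(1, 2, 0.8))
  expect_equal(rowSums(pr), rep(1, 3), tolerance = 1e-12)
  expect_true(all(pr >= 0))
  # near-degenerate width: point mass at round(t0)
  pm <- labels_from_timing(c(6.4, 9.6), c(1e-4, 1e-4))
  expect_equal(apply(pm, 1, argmax_fraction), c(6L, 10L))
  expect_gt(min(apply(pm, 1, max)), 0.999)
  # round trip through the kinetics fit over the generator's own (t0, s)
  # manifold (width peaks at mid-S). The integer-grid cumulative curve sits
  # half a step later than the underlying sigmoid and the 16-bin support
  # truncates wide edge profiles, so recovery is within one fraction overall
  # and tighter mid-range.
  s_of <- function(t0) 0.7 + 1.8 * exp(-((t0 - 7.5)^2) / (2 * 3.5^2))
  for (t0 in c(2, 3, 5, 7.5, 10, 12, 13)) {
    f <- fit_sigmoid(cumulative_fraction(labels_from_timing(t0, s_of(t0))[1, ]))
    expect_lt(abs(f$t_rep - t0), 1.0)
    expect_lt(abs(f$s - s_of(t0)) / s_of(t0), 0.25)
    if (t0 >= 5 && t0 <= 9) expect_lt(abs(f$t_rep - t0), 0.6)
  }
})

test_that("features track the latent timing with the expected signs", {
  spec0 <- synth_spec(n_chromosomes = 1, bins_per_chromosome = 200,
                      feature_noise = 0, seed = 7)
  sim0 <- simulate_cell_line(spec0)
  v <- sim0$features$values
  # noiseless: |Spearman| = 1 against t0 with documented directions
  expect_equal(cor(v[, "two_stage_RT"], sim0$t0, method = "spearman"), -1)
  expect_equal(cor(v[, "H3K27ac"], sim0$t0, method = "spearman"), -1)
  expect_equal(cor(v[, "H3K9me3"], sim0$t0, method = "spearman"), 1)
  expect_equal(cor(v[, "H3K27me3"], sim0$t0, method = "spearman"), 1)
  expect_lt(cor(v[, "GC_content"], sim0$t0), -0.9)   # rounding breaks ties
  # higher noise lowers |correlation| with t0
  cors <- vapply(c(0.05, 0.5, 2), function(fn) {
    sim <- simulate_cell_line(synth_spec(n_chromosomes = 1,
                                         bins_per_chromosome = 300,
                                         feature_noise = fn, seed = 8))
    abs(cor(sim$features$values[, "two_stage_RT"], sim$t0))
  }, 1)
  expect_true(all(diff(cors) < 0))
})

test_that("place_izs finds early-replicating local minima with categories", {
  spec <- small_spec(seed = 9)
  bins <- bin_genome(c(chr1 = 48 * 2000), 2000)
  # monotone timing: no interior minima
  expect_equal(nrow(suppressMessages(
    place_izs(seq(1, 14, length.out = 48), bins, spec))), 0)
  # one constructed dip at t0 = 2 -> one early IZ
  t0 <- rep(8, 48); t0[20] <- 2
  izs <- suppressMessages(place_izs(t0, bins, spec))
  expect_equal(nrow(izs), 1)
  expect_equal(izs$category, "early")
  expect_equal(izs$start, bins$start[20])
  # IZ bins are never later than both flanks
  sim <- simulate_cell_line(synth_spec(seed = 10))
  for (i in seq_len(nrow(sim$izs))) {
    idx <- which(sim$bins$chrom == sim$izs$chrom[i] &
                   sim$bins$start >= sim$izs$start[i] &
                   sim$bins$end <= sim$izs$end[i])
    lo <- min(idx) - 1; hi <- max(idx) + 1
    expect_lte(min(sim$t0[idx]), sim$t0[lo])
    expect_lte(min(sim$t0[idx]), sim$t0[hi])
  }
  # late minima (round(t0) > 11) are discarded
  t0_late <- rep(14.5, 48); t0_late[10] <- 13
  expect_equal(nrow(suppressMessages(place_izs(t0_late, bins, spec))), 0)
})

test_that("emitted toy files re-ingest to the identical feature matrix", {
  sim <- simulate_cell_line(small_spec(seed = 11))
  dir <- file.path(tempdir(), "synthfiles")
  write_synthetic_files(sim, dir)
  fm <- ingest_features(dir, bin_size = 2000)
  v0 <- sim$features$values; v1 <- fm$values
  expect_equal(unname(v1[, "GC_content"]), unname(v0[, "GC_content"]))   # exact
  expect_equal(unname(v1[, "gene_density"]), unname(v0[, "gene_density"]))
  for (nm in setdiff(FEATURE_NAMES, c("GC_content", "gene_density")))
    expect_equal(unname(v1[, nm]), unname(v0[, nm]), tolerance = 1e-6)
  # label TSV round-trips through the label loader + pipeline
  lab <- load_rt_matrix(file.path(dir, "labels.tsv"))
  expect_equal(unname(lab$matrix), unname(sim$labels), tolerance = 1e-9)
  bl <- utils::read.table(file.path(dir, "blacklist.bed"))
  bins2 <- filter_bins(lab$matrix, lab$bins,
                       data.frame(chrom = bl$V1, start = bl$V2, end = bl$V3))
  expect_equal(sum(!bins2$valid), 1)   # the blacklisted bin only
  norm <- normalize_profiles(lab$matrix[bins2$valid, ])
  expect_equal(rowSums(norm), rep(1, sum(bins2$valid)), tolerance = 1e-8)
})

test_that("ablating two-stage RT degrades the argmax accuracy", {
  sim <- simulate_cell_line(synth_spec(n_chromosomes = 3,
                                       bins_per_chromosome = 200, seed = 12))
  cells <- cohort_cells(list(cellA = sim))
  sp <- make_splits(cells, "intra", cell = "cellA",
                    val_chrom = "chr2", test_chrom = "chr3")
  tr <- collect_units(cells, sp$train)
  te <- collect_units(cells, sp$test)
  sc <- scale_units(tr, te)
  cfg <- rt_config(num_layers = 1, hidden_dim = 16, learning_rate = 1e-3,
                   weight_decay = 0, batch_size = 8, epochs = 40, seed = 3)
  obs <- do.call(rbind, lapply(sc[[2]], `[[`, "y"))
  fit_full <- rt_lstm(sc[[1]], config = cfg)
  arfe_full <- evaluate_profiles(obs, predict(fit_full, sc[[2]]))$summary$mean[1]
  drop_rt2 <- function(us) lapply(us, function(u) {
    u$x[, "two_stage_RT"] <- 0
    u
  })
  fit_abl <- rt_lstm(drop_rt2(sc[[1]]), config = cfg)
  arfe_abl <- evaluate_profiles(
    obs, predict(fit_abl, drop_rt2(sc[[2]])))$summary$mean[1]
  expect_gt(arfe_abl, arfe_full)
})
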