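# Seeded generator of complete synthetic cell lines: a smooth latent
# replication-timing signal per chromosome, unimodal 16-fraction profiles
# with bin-specific width (widest in mid-S, the observed T_width pattern),
# correlated two-stage E/L signal, noisy covariate tracks, IZ annotations,
# and matching toy raw files so the whole feature pipeline is testable
# offline.

#' Synthetic cell-line specification
#'
#' @param n_chromosomes Chromosomes per cell line.
#' @param bins_per_chromosome Bins per chromosome (>= 32).
#' @param bin_size Bin width in bp (study resolution 50000; toy file
#'   emission is practical at smaller widths).
#' @param seed Seed; fully determines every output.
#' @param timing_smoothness Correlation length of the latent timing signal,
#'   in bins (Gaussian kernel sd). `Inf` gives a constant signal.
#' @param heterogeneity_range `(s_min, s_max)` profile widths on the 0-15
#'   fraction scale.
#' @param feature_noise Noise scale relative to each feature's signal sd.
#' @param iz_count Initiation zones retained per chromosome.
#' @return List of class `"synth_spec"`.
#' @export
synth_spec <- function(n_chromosomes = 5L, bins_per_chromosome = 400L,
                       bin_size = 50000L, seed = 1L, timing_smoothness = 20,
                       heterogeneity_range = c(0.7, 2.5),
                       feature_noise = 0.25, iz_count = 5L) {
  spec <- list(n_chromosomes = as.integer(n_chromosomes),
               bins_per_chromosome = as.integer(bins_per_chromosome),
               bin_size = as.integer(bin_size), seed = as.integer(seed),
               timing_smoothness = timing_smoothness,
               heterogeneity_range = heterogeneity_range,
               feature_noise = feature_noise, iz_count = as.integer(iz_count))
  stopifnot(spec$n_chromosomes >= 1, spec$bins_per_chromosome >= 32,
            spec$bin_size >= 4, heterogeneity_range[1] > 0,
            heterogeneity_range[2] >= heterogeneity_range[1],
            feature_noise >= 0)
  class(spec) <- "synth_spec"
  spec
}

smooth_noise <- function(n, sd_bins) {
  if (is.infinite(sd_bins)) return(rep(0, n))
  m <- ceiling(3 * sd_bins)
  z <- stats::rnorm(n + 2 * m)
  if (sd_bins <= 0) return(z[m + seq_len(n)])
  k <- stats::dnorm(seq(-m, m), sd = sd_bins)
  k <- k / sum(k)
  as.numeric(stats::filter(z, k, sides = 2))[m + seq_len(n)]
}

#' Generate the latent replication-timing signal
#'
#' Smooth bounded random signal `t0` in (1, 14) per chromosome (filtered
#' white noise with the requested correlation length, rescaled), and a
#' smoothly varying profile width `s` within `heterogeneity_range`, largest
#' at mid-S.
#'
#' @param spec A [synth_spec()].
#' @param seed Seed (default `spec$seed`); set `NULL` to continue the
#'   current RNG stream.
#' @return data.frame with `chrom`, `t0`, `s`.
#' @export
generate_latent_timing <- function(spec, seed = spec$seed) {
  if (!is.null(seed)) set.seed(seed)
  rng <- spec$heterogeneity_range
  pieces <- lapply(seq_len(spec$n_chromosomes), function(ci) {
    n <- spec$bins_per_chromosome
    z <- smooth_noise(n, spec$timing_smoothness)
    if (max(z) - min(z) < 1e-12) {
      t0 <- rep(7.5, n)
    } else {
      t0 <- 1 + 13 * (z - min(z)) / (max(z) - min(z))
    }
    s <- rng[1] + (rng[2] - rng[1]) * exp(-((t0 - 7.5)^2) / (2 * 3.5^2))
    data.frame(chrom = paste0("chr", ci), t0 = t0, s = s,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, pieces)
}

#' 16-fraction profiles from the latent timing signal
#'
#' Profile k is proportional to the logistic density with location `t0` and
#' scale `s` evaluated at integer times 0..15, renormalized to sum to 1 —
#' so the cumulative curve is (up to discretization) the logistic sigmoid
#' the dynamics module fits.
#'
#' @param t0,s Per-bin location and width vectors.
#' @return Matrix (bins x 16), rows summing to 1.
#' @export
labels_from_timing <- function(t0, s) {
  stopifnot(length(t0) == length(s), all(s > 0))
  times <- 0:15
  dens <- sapply(times, function(tt) stats::dlogis(tt, t0, s))
  dens <- matrix(dens, nrow = length(t0))
  tot <- rowSums(dens)
  deg <- tot == 0 | !is.finite(tot)
  if (any(deg)) {      # width so small the density underflows: point mass
    dens[deg, ] <- 0
    dens[cbind(which(deg), pmin(pmax(round(t0[deg]), 0), 15) + 1)] <- 1
    tot[deg] <- 1
  }
  out <- dens / tot
  colnames(out) <- FRACTION_NAMES
  out
}

# Monotone signal maps encoding the expected biology: active marks, GC and
# gene density decrease with later timing, repressive marks increase, and
# the E/L log-ratio decreases. Documented constants, not claims about data.
SYNTH_FEATURE_MAPS <- list(
  H3K27ac  = function(t0) 2.0 * (15 - t0) / 15,
  H3K27me3 = function(t0) 1.4 * t0 / 15,
  H3K36me3 = function(t0) 1.5 * (15 - t0) / 15,
  H3K4me1  = function(t0) 1.2 * (15 - t0) / 15,
  H3K4me3  = function(t0) 1.8 * (15 - t0) / 15,
  H3K9me3  = function(t0) 1.9 * t0 / 15)

#' Feature tracks from the latent timing signal
#'
#' Histone fold-change tracks are monotone maps of `t0` plus Gaussian noise
#' (activating marks decreasing, H3K9me3/H3K27me3 increasing); GC content
#' and gene density decrease with later timing; the two-stage RT feature is
#' produced by building early/late RPKM tracks from an affine-decreasing
#' map of `t0` and passing them through [adjustment_factor()] and
#' [two_stage_rt()] — the exact path re-ingestion takes. Noise sd is
#' `spec$feature_noise` times each signal component's sd.
#'
#' @param t0,s Latent vectors (s unused but kept for symmetry).
#' @param chrom Per-bin chromosome ids.
#' @param spec A [synth_spec()].
#' @return List: `features` (raw `"feature_matrix"` over all bins),
#'   `early_rpkm`, `late_rpkm`, `adjustment`.
#' @export
features_from_timing <- function(t0, s, chrom, spec) {
  n <- length(t0)
  noise <- function(signal) {
    sdv <- stats::sd(signal)
    if (spec$feature_noise == 0 || sdv == 0) rep(0, n)
    else stats::rnorm(n, 0, spec$feature_noise * sdv)
  }
  hist_mat <- sapply(names(SYNTH_FEATURE_MAPS), function(nm) {
    sig <- SYNTH_FEATURE_MAPS[[nm]](t0)
    pmax(sig + noise(sig), 0)
  })
  gc_target <- pmin(pmax(0.35 + 0.10 * (15 - t0) / 15 +
                           noise(0.10 * (15 - t0) / 15), 0), 1)
  gc <- round(gc_target * spec$bin_size) / spec$bin_size  # representable
  dens_sig <- 2.5 * (15 - t0) / 15
  density <- pmax(round(dens_sig + noise(dens_sig)), 0)
  u <- (7.5 - t0) / 2.5
  u <- u + noise(u)
  early <- 2^(u / 2)
  late <- 2^(-u / 2)
  a <- adjustment_factor(early, late, chrom = chrom)
  rt2 <- two_stage_rt(early, late, a)
  bins <- data.frame(chrom = chrom, start = 0, end = spec$bin_size,
                     index = 0L, valid = TRUE)  # placeholder; caller rebinds
  fm <- structure(list(values = cbind(hist_mat, GC_content = gc,
                                      gene_density = density,
                                      two_stage_RT = rt2),
                       bins = bins, scaling = "none"),
                  class = "feature_matrix")
  colnames(fm$values) <- FEATURE_NAMES
  list(features = fm, early_rpkm = early, late_rpkm = late, adjustment = a)
}

#' Place initiation zones on the latent timing signal
#'
#' Local minima of `t0` (bins replicating earlier than both flanks; runs of
#' consecutive minima merged) become IZ intervals, labeled by the temporal
#' category containing `round(t0)`: early (0-2), early-mid (3-5), late-mid
#' (6-8), late (9-11); minima rounding above 11 are discarded. At most
#' `spec$iz_count` zones per chromosome are kept, in genomic order; fewer
#' existing minima are returned as-is (with a message).
#'
#' @param t0 Latent timing vector.
#' @param bins Bin table aligned to `t0`.
#' @param spec A [synth_spec()].
#' @return data.frame (`chrom`, `start`, `end`, `category`), 0-based
#'   half-open.
#' @export
place_izs <- function(t0, bins, spec) {
  out <- list()
  for (ch in unique(bins$chrom)) {
    idx <- which(bins$chrom == ch)
    v <- t0[idx]
    n <- length(v)
    if (n < 3) next
    # runs of equal value; an interior run strictly below both neighboring
    # runs is a (possibly multi-bin) local minimum
    runs <- rle(v)
    pos <- cumsum(runs$lengths) - runs$lengths + 1
    nr <- length(runs$values)
    zones <- list()
    min_runs <- if (nr < 3) integer(0) else
      1 + which(runs$values[2:(nr - 1)] < runs$values[1:(nr - 2)] &
                  runs$values[2:(nr - 1)] < runs$values[3:nr])
    for (j in min_runs) {
      lo <- pos[j]; hi <- pos[j] + runs$lengths[j] - 1
      tt <- round(min(v[lo:hi]))
      if (tt > 11) next
      cat_ <- c("early", "early-mid", "late-mid", "late")[findInterval(tt, c(0, 3, 6, 9))]
      zones[[length(zones) + 1]] <- data.frame(
        chrom = ch, start = bins$start[idx[lo]], end = bins$end[idx[hi]],
        category = cat_, stringsAsFactors = FALSE)
    }
    if (length(zones) < spec$iz_count)
      message("chromosome ", ch, ": only ", length(zones),
              " initiation zone(s) found")
    if (length(zones) > 0)
      out <- c(out, zones[seq_len(min(length(zones), spec$iz_count))])
  }
  if (length(out) == 0)
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      category = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Simulate one complete synthetic cell line
#'
#' Runs the latent-timing, label, feature and IZ generators under a single
#' seed; `(spec, seed)` fully determine the output.
#'
#' @param spec A [synth_spec()].
#' @return List of class `"synth_cell_line"`: `spec`, `chrom_sizes`, `bins`,
#'   `t0`, `s`, `labels` (bins x 16), `features` (`"feature_matrix"`),
#'   `early_rpkm`, `late_rpkm`, `adjustment`, `izs`.
#' @export
simulate_cell_line <- function(spec = synth_spec()) {
  set.seed(spec$seed)
  lat <- generate_latent_timing(spec, seed = NULL)
  chrom_sizes <- stats::setNames(
    rep(spec$bins_per_chromosome * spec$bin_size, spec$n_chromosomes),
    paste0("chr", seq_len(spec$n_chromosomes)))
  bins <- bin_genome(chrom_sizes, spec$bin_size)
  labels <- labels_from_timing(lat$t0, lat$s)
  ft <- features_from_timing(lat$t0, lat$s, lat$chrom, spec)
  ft$features$bins <- bins
  izs <- place_izs(lat$t0, bins, spec)
  structure(list(spec = spec, chrom_sizes = chrom_sizes, bins = bins,
                 t0 = lat$t0, s = lat$s, labels = labels,
                 features = ft$features, early_rpkm = ft$early_rpkm,
                 late_rpkm = ft$late_rpkm, adjustment = ft$adjustment,
                 izs = izs),
            class = "synth_cell_line")
}

#' Simulate a cohort of cell lines for split experiments
#'
#' Each line uses `spec$seed + line index - 1` so lines differ but the
#' cohort is reproducible.
#'
#' @param n_lines Number of cell lines.
#' @param spec Base [synth_spec()].
#' @return Named list `cell1..cellN` of `"synth_cell_line"` objects.
#' @export
simulate_cohort <- function(n_lines = 5L, spec = synth_spec()) {
  out <- lapply(seq_len(n_lines), function(i) {
    sp <- spec
    sp$seed <- spec$seed + i - 1L
    simulate_cell_line(sp)
  })
  names(out) <- paste0("cell", seq_len(n_lines))
  out
}

#' Arrange simulated cell lines for [make_splits()]
#'
#' @param sims List of `"synth_cell_line"` objects (e.g. from
#'   [simulate_cohort()]).
#' @return Named list: cell -> chromosome -> `list(x, y)` with raw
#'   (unscaled) features.
#' @export
cohort_cells <- function(sims) {
  lapply(sims, function(sim) {
    chroms <- unique(sim$bins$chrom)
    out <- lapply(chroms, function(ch) {
      i <- sim$bins$chrom == ch
      list(x = sim$features$values[i, , drop = FALSE],
           y = sim$labels[i, , drop = FALSE])
    })
    stats::setNames(out, chroms)
  })
}

#' Standardize split units with training-split statistics
#'
#' @param train,... Unit lists; scaling center/sd computed on the rows of
#'   `train` and applied to every list passed.
#' @return List of rescaled unit lists (same order as the arguments), with
#'   the scaling record attached as attribute `"scaling"`.
#' @export
scale_units <- function(train, ...) {
  xs <- do.call(rbind, lapply(train, `[[`, "x"))
  ctr <- colMeans(xs)
  sdv <- apply(xs, 2, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  apply_sc <- function(units) lapply(units, function(u) {
    u$x <- sweep(sweep(u$x, 2, ctr, "-"), 2, sdv, "/")
    u
  })
  out <- lapply(c(list(train), list(...)), apply_sc)
  attr(out, "scaling") <- list(center = ctr, scale = sdv)
  out
}
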