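# replitimer

Predicting high-resolution (16-fraction) DNA replication timing from
chromatin features, with a complete offline test bed.

## What it does, and for whom

Replication timing (RT) is the order in which genomic loci are duplicated
during S phase. High-resolution Repli-Seq sorts cells into sixteen S-phase
fractions (S1 earliest .. S16 latest) and yields, for each 50-kb bin, a
probability vector over replication times — but the assay is costly and
rare. `replitimer` is for computational genomicists who want to predict
those 16-fraction profiles from nine widely available per-bin features: six
histone ChIP-seq fold-change tracks (H3K27ac, H3K27me3, H3K36me3, H3K4me1,
H3K4me3, H3K9me3), GC content, gene density, and the classic two-stage
(early/late log2-ratio) RT signal.

The core is a stacked **bidirectional LSTM** over the ordered bins of each
chromosome. For bin $t$, each direction computes

    I_t = sigma(X_t W_xI + H_{t-1} W_Ih + b_I)          (input gate)
    F_t = sigma(X_t W_xF + H_{t-1} W_Fh + b_F)          (forget gate)
    O_t = sigma(X_t W_xO + H_{t-1} W_Oh + b_O)          (output gate)
    C_t = F_t * C_{t-1} + I_t * tanh(X_t W_xC + H_{t-1} W_Ch + b_c)
    H_t = O_t * tanh(C_t)

the final layer's forward/backward states are concatenated, and a fully
connected head plus row-wise log-softmax/exponential produces a 16-fraction
probability vector per bin. Training minimizes per-bin KL divergence (with
L2 weight decay) under Adam; forward pass, backpropagation through time and
the optimizer are implemented in base R and verified against scalar loop
oracles and finite-difference gradients in the test suite.

Around the model the package provides:

- **features** — genome binning, per-bin mean signal from bedGraph/bigWig,
  GC from FASTA, gene counts from BED, RPKM, the adjustment-factor E/L
  log-ratio, and assembly of the fixed 9-column matrix
  (`ingest_features()`, `assemble_features()`).
- **labels** — loading deposited fraction-by-bin matrices, filtering
  (all-zero / missing / blacklist-overlap bins), clip-and-renormalize to
  probability vectors.
- **training** — chr6-validation / chr9-test intra-cell-line splits,
  leave-one-cell-line-out splits, and the 960-point hyperparameter grid
  (`make_splits()`, `rt_lstm()`, `grid_search()`, `full_grid()`).
- **evaluation** — per-bin ARFE, KL, Spearman, Kolmogorov–Smirnov and
  Wasserstein metrics, single-feature quantile baselines, linear / lasso /
  MLP / random-forest / SVR baseline regressors, Borda rank aggregation and
  one-sided Wilcoxon comparisons.
- **dynamics** — logistic fits of cumulative replication curves giving
  T_rep (50% completion time) and T_width (25–75% span), plus
  initiation-zone temporal-category curves.
- **autocorr** — chromosome-wise, fraction-averaged autocorrelation with
  N(0, 1/n) confidence bands.
- **synthetic** — a seeded generator of complete synthetic cell lines
  (latent timing signal, unimodal profiles, correlated noisy features, IZ
  annotations, and matching toy bedGraph/BED/FASTA/TSV files).

## Worked example

Simulate a cell line (5 chromosomes x 400 bins), hold out one chromosome,
train, and evaluate:

```r
library(replitimer)

sim   <- simulate_cell_line(synth_spec(seed = 11))
cells <- cohort_cells(list(cellA = sim))
sp <- make_splits(cells, mode = "intra", cell = "cellA",
                  val_chrom = "chr4", test_chrom = "chr5")
sc <- scale_units(collect_units(cells, sp$train),
                  collect_units(cells, sp$validation),
                  collect_units(cells, sp$test))

cfg <- rt_config(num_layers = 1, hidden_dim = 32, learning_rate = 1e-3,
                 weight_decay = 1e-4, batch_size = 8, epochs = 100, seed = 3)
fit <- rt_lstm(sc[[1]], validation = sc[[2]], config = cfg)
fit
#> Bidirectional LSTM replication-timing model
#>   layers: 1  hidden: 32 per direction  parameters: 11792
#>   trained 100 epochs (lr 0.001, weight decay 1e-04, batch 8, window 256)
#>   final KL: train 0.00656  validation 0.00637

obs  <- do.call(rbind, lapply(sc[[3]], `[[`, "y"))
pred <- predict(fit, sc[[3]])
evaluate_profiles(obs, pred, "bilstm")
#> Metric report for bilstm over 400 bins
#>       metric    mean   median
#>         arfe 0.39250 0.000000
#>           kl 0.01174 0.009748
#>     spearman 0.98840 0.991176
#>           ks 0.03944 0.033412
#>  wasserstein 0.22840 0.199809

trep_concordance(obs, pred)
#> [1] 0.9960936
```

Read: on the held-out chromosome the predicted dominant fraction is on
average 0.39 fractions from the observed one (median exactly right), the
per-bin rank agreement between predicted and observed 16-fraction vectors
is ~0.99, and per-bin T_rep times from predicted and observed kinetics
correlate at 0.996. For context, predicting the uniform profile everywhere
gives mean KL 0.494 versus the model's 0.012.

A thin command-line wrapper over the same functions is installed at
`inst/cli/replitimer.R` (subcommands `simulate`, `features`, `train`,
`evaluate`, `dynamics`, `autocorr`).

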