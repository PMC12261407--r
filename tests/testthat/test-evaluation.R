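test_that("argmax_fraction and arfe follow the 0-based, earliest-tie rules", {
  expect_equal(argmax_fraction(c(0, 0, 1, rep(0, 13))), 2L)
  expect_equal(argmax_fraction(rep(1 / 16, 16)), 0L)
  expect_equal(argmax_fraction(c(0, 0.2, 0.5, 0.3, rep(0, 12))), 2L)

  p <- random_profile()
  expect_equal(arfe(p, p), 0L)
  expect_equal(arfe(c(1, rep(0, 15)), c(rep(0, 15), 1)), 15L)
  a <- c(rep(0, 3), 1, rep(0, 12)); b <- c(rep(0, 5), 1, rep(0, 10))
  expect_equal(arfe(a, b), 2L)        # "2 S phase fractions off"
  expect_equal(arfe(b, a), arfe(a, b))  # symmetry
})

test_that("kl_per_bin uses the epsilon floor on predictions only", {
  p <- random_profile()
  expect_equal(kl_per_bin(p, p), 0, tolerance = 1e-12)
  expect_equal(kl_per_bin(c(1, rep(0, 15)), rep(1 / 16, 16)), log(16))
  # prediction zeros where obs > 0 stay finite
  obs <- c(0.5, 0.5, rep(0, 14)); pred <- c(1, rep(0, 15))
  expect_true(is.finite(kl_per_bin(obs, pred)))
  # observed zeros contribute nothing even with pred zero there
  expect_equal(kl_per_bin(c(1, rep(0, 15)), c(1, rep(0, 15))), 0)
})

test_that("spearman_per_bin is a tie-aware rank correlation", {
  set.seed(60)
  p <- sort(random_profile())
  expect_equal(spearman_per_bin(p, p), 1)
  expect_equal(spearman_per_bin(p, rev(p)), -1)
  # invariance under strictly increasing transforms
  for (rep in 1:5) {
    obs <- random_profile()
    expect_equal(spearman_per_bin(obs, exp(3 * obs) + obs^2), 1,
                 tolerance = 1e-12)
  }
  expect_true(is.na(spearman_per_bin(rep(1 / 16, 16), p)))
})

test_that("cumulative_fraction gives valid CDFs", {
  expect_equal(cumulative_fraction(rep(1 / 16, 16)), (1:16) / 16)
  expect_equal(cumulative_fraction(c(1, rep(0, 15))), rep(1, 16))
  expect_equal(cumulative_fraction(c(0.5, 0.5, rep(0, 14)))[1:3], c(0.5, 1, 1))
  p <- random_profile()
  cdf <- cumulative_fraction(p)
  expect_true(all(diff(cdf) >= -1e-12))
  expect_equal(cdf[16], 1, tolerance = 1e-8)
})

test_that("ks_distance is the max CDF gap", {
  p <- random_profile()
  expect_equal(ks_distance(p, p), 0)
  expect_equal(ks_distance(c(1, rep(0, 15)), c(rep(0, 15), 1)), 1)
  expect_equal(ks_distance(c(1, rep(0, 15)), c(0.5, 0.5, rep(0, 14))), 0.5)
  set.seed(61)
  for (rep in 1:20) {
    a <- random_profile(); b <- random_profile()
    expect_lte(ks_distance(a, b), 1)
    expect_gte(ks_distance(a, b), 0)
  }
  expect_lt(ks_distance(p, p + 1e-12), 1e-10)  # zero iff equal (within tol)
})

test_that("wasserstein_distance equals the primal transport cost", {
  p <- random_profile()
  expect_equal(wasserstein_distance(p, p), 0)
  expect_equal(wasserstein_distance(c(1, rep(0, 15)), c(rep(0, 15), 1)), 15)
  for (k in 1:15) {
    a <- rep(0, 16); a[k] <- 1
    b <- rep(0, 16); b[k + 1] <- 1
    expect_equal(wasserstein_distance(a, b), 1)
  }
  set.seed(62)
  for (rep in 1:50) {
    a <- random_profile(); b <- random_profile()
    expect_equal(wasserstein_distance(a, b), oracle_transport(a, b),
                 tolerance = 1e-8)
  }
})

test_that("evaluate_profiles summarizes the five metrics per bin", {
  set.seed(63)
  obs <- t(replicate(30, random_profile()))
  pred <- t(replicate(30, random_profile()))
  rep_ <- evaluate_profiles(obs, pred, "m")
  expect_equal(nrow(rep_$per_bin), 30)
  expect_true(all(rep_$per_bin$kl >= 0))
  expect_true(all(rep_$per_bin$ks >= 0 & rep_$per_bin$ks <= 1))
  expect_true(all(rep_$per_bin$wasserstein >= 0 & rep_$per_bin$wasserstein <= 15))
  expect_equal(rep_$summary$mean[1], mean(rep_$per_bin$arfe))
  perfect <- evaluate_profiles(obs, obs, "self")
  expect_equal(perfect$summary$mean, c(0, 0, 1, 0, 0), tolerance = 1e-10)
})

test_that("quantile_baseline partitions into 16 balanced groups", {
  # 16 distinct values ascending: labels are the sort ranks
  v <- c(5, 1, 16, 2, 9, 3, 12, 4, 7, 6, 14, 8, 10, 11, 13, 15)
  qb <- quantile_baseline(v, "ascending")
  expect_equal(qb$predicted_fraction[order(v)], 0:15)
  qd <- quantile_baseline(v, "descending")
  expect_equal(qb$predicted_fraction + qd$predicted_fraction, rep(15L, 16))
  # 32 values 0..31, observed argmax floor(v/2): mae 0
  v32 <- 0:31
  qb32 <- quantile_baseline(v32, "ascending", observed_argmax = floor(v32 / 2))
  expect_equal(qb32$mae, 0)
  # group sizes differ by at most 1 for distinct values
  set.seed(64)
  v2 <- rnorm(53)
  sizes <- table(quantile_baseline(v2, "ascending")$predicted_fraction)
  expect_lte(diff(range(sizes)), 1)
  expect_error(quantile_baseline(rnorm(10), "ascending"), "16")
})

test_that("borda_rank awards M-1..0 with shared ties", {
  vals <- expand.grid(ranking = 1:25, model = paste0("m", 1:6))
  vals$value <- ifelse(vals$model == "m1", 0, runif(nrow(vals)) + 1)
  pts <- borda_rank(vals, orientation = "lower")
  expect_equal(unname(pts["m1"]), 125)   # best everywhere: 25 * 5
  v2 <- data.frame(ranking = 1, model = c("a", "b"), value = c(1, 2))
  expect_equal(borda_rank(v2, "lower"), c(a = 1, b = 0))
  v3 <- data.frame(ranking = 1, model = c("a", "b", "c"), value = c(2, 1, 1))
  expect_equal(borda_rank(v3, "lower"), c(a = 0, b = 1.5, c = 1.5))
  expect_equal(borda_rank(v3, "higher"), c(a = 2, b = 0.5, c = 0.5))
  v4 <- rbind(v3, transform(v3, ranking = 2))[-1, ]  # model a absent in ranking 1
  expect_error(borda_rank(v4, "lower"), "missing")
})

test_that("paired_comparison is a one-sided signed-rank test", {
  set.seed(65)
  a <- runif(30); b <- a + runif(30, 0.1, 0.5)   # a strictly below b
  expect_lt(paired_comparison(a, b, "less"), 0.01)
  expect_gt(paired_comparison(a, b, "greater"), 0.9)
  expect_lt(paired_comparison(b, a, "greater"), 0.01)
  expect_true(is.na(paired_comparison(a, a, "less")))
})

test_that("baseline regressors clip, renormalize and fall back sensibly", {
  expect_equal(replitimer:::clip_renormalize(
    matrix(c(-0.2, 0.6, 0.6, rep(0, 13)), 1))[1, 1:3],
    c(S1 = 0, S2 = 0.5, S3 = 0.5), ignore_attr = TRUE)
  expect_message(
    u <- replitimer:::clip_renormalize(matrix(-1, 2, 16)), "uniform")
  expect_equal(u, matrix(1 / 16, 2, 16))

  # constant-feature linear fit returns the clipped mean training row
  set.seed(66)
  y <- t(replicate(20, random_profile()))
  x <- matrix(0, 20, 9)
  pred <- baseline_regressors(x, y, matrix(0, 3, 9), "linear")
  target <- colMeans(y) / sum(colMeans(y))
  for (i in 1:3) expect_equal(unname(pred[i, ]), unname(target),
                              tolerance = 1e-8)

  # every family emits probability rows
  x <- matrix(rnorm(40 * 9), 40, 9)
  y <- t(replicate(40, random_profile()))
  xt <- matrix(rnorm(5 * 9), 5, 9)
  for (fam in c("linear", "mlp")) {
    p <- baseline_regressors(x, y, xt, fam, epochs = 20)
    expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-8)
    expect_true(all(p >= 0))
  }
  p <- baseline_regressors(x, y, xt, "lasso", x_val = x, y_val = y)
  expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-8)
  expect_error(baseline_regressors(x, y, xt, "lasso"), "validation")
})

test_that("labels_to_profiles expands argmax labels to point masses", {
  m <- labels_to_profiles(c(0L, 15L, 3L))
  expect_equal(dim(m), c(3, 16))
  expect_equal(apply(m, 1, argmax_fraction), c(0L, 15L, 3L))
  expect_equal(rowSums(m), rep(1, 3))
})
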