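test_that("batch adjustment is the identity for a single batch", {
  set.seed(1)
  m <- tiny_beta(matrix(runif(200), 20, 10))
  out <- combat_adjust(m)
  expect_equal(out$values, m$values, tolerance = 1e-8)
})

test_that("a pure location shift between batches is removed exactly", {
  set.seed(2)
  base <- matrix(runif(30, 0.2, 0.7), 30, 1)[, rep(1, 10)]
  shifted <- base
  shifted[, 6:10] <- shifted[, 6:10] + 0.2
  m <- tiny_beta(shifted, batches = rep(c("b1", "b2"), each = 5))
  out <- combat_adjust(m)
  m1 <- rowMeans(out$values[, 1:5])
  m2 <- rowMeans(out$values[, 6:10])
  expect_lt(max(abs(m1 - m2)), 1e-6)
})

test_that("batch-mean differences shrink at least tenfold on simulated batches", {
  for (seed in 1:10) {
    sim <- simulate_methylation(methyl_sim_config(
      n_cases = 15, n_controls = 15, n_probes = 120, n_true_dmp = 0,
      batch_count = 2, batch_shift = 0.08, batch_scale = 1.3,
      missing_rate = 0, seed = seed
    ))
    b <- sim$beta$sample_meta$batch
    gap <- function(v) {
      mean(abs(rowMeans(v[, b == "batch1"]) - rowMeans(v[, b == "batch2"])))
    }
    before <- gap(sim$beta$values)
    after <- gap(combat_adjust(sim$beta)$values)
    expect_lt(after, before / 10)
  }
})

test_that("batch adjustment commutes with sample reordering", {
  set.seed(3)
  sim <- simulate_methylation(methyl_sim_config(
    n_cases = 8, n_controls = 8, n_probes = 60, n_true_dmp = 0,
    batch_count = 2, missing_rate = 0, seed = 5
  ))
  out1 <- combat_adjust(sim$beta)
  perm <- sample(ncol(sim$beta$values))
  m2 <- sim$beta
  m2$values <- m2$values[, perm]
  m2$sample_meta <- m2$sample_meta[perm, ]
  out2 <- combat_adjust(m2)
  expect_equal(out2$values, out1$values[, perm], tolerance = 1e-10)
})

test_that("batch adjustment agrees with the reference empirical-Bayes implementation", {
  skip_if_not_installed("sva")
  set.seed(4)
  x <- matrix(rnorm(80 * 12, mean = 0.5, sd = 0.05), 80, 12)
  x[, 7:12] <- x[, 7:12] + 0.05
  x <- pmin(pmax(x, 0), 1)
  rownames(x) <- sprintf("cg%03d", 1:80)
  colnames(x) <- sprintf("S%02d", 1:12)
  batch <- rep(c("b1", "b2"), each = 6)
  ours <- combat_adjust(x, batch = batch)
  ref <- suppressMessages(sva::ComBat(x, batch = batch))
  expect_equal(ours, ref, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("a batch with fewer than 2 samples is refused by name", {
  m <- tiny_beta(matrix(runif(30), 10, 3), batches = c("b1", "b1", "b2"))
  expect_error(combat_adjust(m), "b2")
})

test_that("probe filters fire in order with first-failure accounting", {
  set.seed(5)
  n <- 100
  v <- matrix(runif(n * 10), n, 10)
  ann <- tiny_annotation(sprintf("cg%03d", seq_len(n)))
  ann$chromosome[1:10] <- "chrX"
  ann$snp_maf[11:15] <- 0.2
  ann$control_probe[16:20] <- TRUE
  ann$region_class[21:30] <- "intergenic"
  # overlap: probe 1 is chrX AND has high MAF; charged to the earlier XY rule
  ann$snp_maf[1] <- 0.3
  m <- tiny_beta(v)
  rownames(m$values) <- ann$probe_id
  out <- filter_probes(m, ann)
  expect_equal(out$report$probes_retained, 70)
  rules <- tidy(out$report)
  expect_equal(rules$removed[rules$rule == "chrXY"], 10)
  expect_equal(rules$removed[rules$rule == "snp_maf"], 5)
  expect_equal(rules$removed[rules$rule == "control_probe"], 5)
  expect_equal(rules$removed[rules$rule == "region"], 10)
  expect_equal(sum(rules$removed) + out$report$probes_retained, n)
})

test_that("missingness and MAF boundaries are retained (strict thresholds)", {
  v <- matrix(runif(40), 4, 10)
  v[1, 1:3] <- NA # 30% missing -> removed
  v[2, 1:2] <- NA # 20% exactly -> retained
  ann <- tiny_annotation(sprintf("cg%03d", 1:4))
  ann$snp_maf[3] <- 0.1 # exactly 0.1 -> retained
  ann$snp_maf[4] <- 0.100001 # just above -> removed
  m <- tiny_beta(v)
  rownames(m$values) <- ann$probe_id
  out <- filter_probes(m, ann)
  kept <- rownames(out$beta$values)
  expect_false("cg001" %in% kept)
  expect_true("cg002" %in% kept)
  expect_true("cg003" %in% kept)
  expect_false("cg004" %in% kept)
})

test_that("unknown region classes abort with the offending probes", {
  v <- matrix(runif(20), 2, 10)
  ann <- tiny_annotation(c("cg001", "cg002"))
  ann$region_class[2] <- "Enhancer"
  m <- tiny_beta(v)
  rownames(m$values) <- ann$probe_id
  expect_error(filter_probes(m, ann), "Enhancer")
})

test_that("KNN imputation matches hand arithmetic and the twin-probe case", {
  # probe 1 missing at sample 1; its three nearest neighbours hold .2/.4/.6
  x <- rbind(
    c(NA, 0.50, 0.50, 0.50),
    c(0.2, 0.50, 0.50, 0.50),
    c(0.4, 0.51, 0.51, 0.51),
    c(0.6, 0.49, 0.49, 0.49),
    c(0.9, 0.95, 0.95, 0.95)
  )
  rownames(x) <- sprintf("p%d", 1:5)
  colnames(x) <- sprintf("s%d", 1:4)
  out <- knn_impute(x, k = 3)
  expect_equal(out[1, 1], mean(c(0.2, 0.4, 0.6)))
  expect_equal(out[-1, ], x[-1, ]) # observed cells untouched

  # a masked duplicate of a complete probe recovers the original exactly
  y <- matrix(runif(40), 4, 10)
  y <- rbind(y, y[1, ])
  rownames(y) <- sprintf("p%d", 1:5)
  colnames(y) <- sprintf("s%d", 1:10)
  y[5, 3] <- NA
  imp <- knn_impute(y, k = 1)
  expect_equal(imp[5, 3], y[1, 3], tolerance = 1e-12)
})

test_that("KNN imputation equals the brute-force oracle on random matrices", {
  for (seed in 1:5) {
    set.seed(seed)
    x <- matrix(runif(50 * 20), 50, 20)
    x[sample(length(x), 80)] <- NA
    keep <- rowSums(!is.na(x)) > 0
    x <- x[keep, , drop = FALSE]
    rownames(x) <- sprintf("p%03d", seq_len(nrow(x)))
    colnames(x) <- sprintf("s%02d", 1:20)
    expect_equal(knn_impute(x, k = 3), oracle_knn(x, k = 3), tolerance = 1e-12)
  }
})

test_that("complete matrices pass through imputation unchanged", {
  x <- matrix(runif(20), 4, 5)
  expect_identical(knn_impute(x), x)
  expect_error(knn_impute(rbind(x, NA)), "entirely missing")
})

test_that("zero-mean normalisation centres rows and is idempotent", {
  m <- tiny_beta(matrix(c(0.2, 0.4, 0.6, 0.1, 0.2, 0.3), 2, 3, byrow = TRUE))
  out <- zero_mean_normalize(m)
  expect_equal(unname(out$values[1, ]), c(-0.2, 0, 0.2))
  expect_true(out$normalized)
  expect_lt(max(abs(rowMeans(out$values))), 1e-12)
  expect_equal(zero_mean_normalize(out)$values, out$values)
})

test_that("the preprocessing cascade runs end-to-end and conserves probes", {
  sim <- simulate_methylation(methyl_sim_config(
    n_cases = 10, n_controls = 10, n_probes = 200, n_true_dmp = 10,
    missing_rate = 0.03, seed = 8
  ))
  pp <- preprocess_beta(sim$beta, sim$annotation)
  expect_true(pp$beta$normalized)
  expect_false(anyNA(pp$beta$values))
  rep <- pp$report
  expect_equal(sum(tidy(rep)$removed) + rep$probes_retained, 200)
  expect_lt(max(abs(rowMeans(pp$beta$values))), 1e-10)
})
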