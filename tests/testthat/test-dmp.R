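test_that("pooled t matches hand computation and t.test on small vectors", {
  x <- rbind(
    a = c(1, 2, 3, 1, 2, 3), # identical groups
    b = c(1, 2, 3, 4, 2, 3, 4, 5)[1:6] # placeholder, replaced below
  )
  out <- student_t_per_probe(x[1, , drop = FALSE], 1:3, 4:6)
  expect_equal(out$t_stat, 0)
  expect_equal(out$p, 1)

  y <- matrix(c(1, 2, 3, 4, 2, 3, 4, 5), 1)
  res <- student_t_per_probe(y, 1:4, 5:8)
  expect_equal(res$t_stat, -1.0954451, tolerance = 1e-6)
  expect_equal(res$df, 6)
  expect_equal(res$p, 0.3153336, tolerance = 1e-6)
  orc <- oracle_pooled_t(c(1, 2, 3, 4), c(2, 3, 4, 5))
  expect_equal(res$t_stat, orc$t, tolerance = 1e-12)
  expect_equal(res$p, orc$p, tolerance = 1e-12)

  # swapping groups negates t, p unchanged
  swapped <- student_t_per_probe(y, 5:8, 1:4)
  expect_equal(swapped$t_stat, -res$t_stat)
  expect_equal(swapped$p, res$p)
})

test_that("vectorised t equals a two-loop t.test oracle on random matrices", {
  set.seed(11)
  x <- matrix(rnorm(40 * 12), 40, 12)
  rownames(x) <- sprintf("p%02d", 1:40)
  res <- student_t_per_probe(x, 1:5, 6:12)
  for (i in seq_len(nrow(x))) {
    orc <- oracle_pooled_t(x[i, 1:5], x[i, 6:12])
    expect_equal(res$t_stat[i], orc$t, tolerance = 1e-10)
    expect_equal(res$p[i], orc$p, tolerance = 1e-10)
  }
  # Welch option agrees with t.test(var.equal = FALSE)
  resw <- student_t_per_probe(x, 1:5, 6:12, welch = TRUE)
  ht <- t.test(x[3, 1:5], x[3, 6:12])
  expect_equal(resw$t_stat[3], unname(ht$statistic), tolerance = 1e-10)
  expect_equal(resw$p[3], ht$p.value, tolerance = 1e-10)
})

test_that("degenerate zero-variance probes are handled per contract", {
  x <- rbind(same = rep(1, 6), diff = c(1, 1, 1, 2, 2, 2))
  out <- student_t_per_probe(x, 1:3, 4:6)
  expect_equal(out$t_stat[1], 0)
  expect_equal(out$p[1], 1)
  expect_equal(out$p[2], .Machine$double.xmin)
  expect_true(out$degenerate[2])
})

test_that("BH adjustment equals the step-up definition on random vectors", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.7), 0.7)
  set.seed(12)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p))
    expect_true(all(q <= 1))
    # monotone in raw-p rank
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
  expect_error(bh_adjust(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_adjust(c(0.5, 1.2)), "\\(0, 1\\]")
})

test_that("planted differential probes are recovered at high power", {
  sim <- simulate_methylation(methyl_sim_config(
    n_cases = 50, n_controls = 50, n_probes = 1000, n_true_dmp = 50,
    delta_beta = 0.15, missing_rate = 0, batch_count = 1, seed = 21
  ))
  norm <- zero_mean_normalize(sim$beta)
  res <- call_dmps(norm, sim$annotation, contrast = "FTD_vs_control")
  recovery <- mean(sim$truth$probe_id %in% res$significant_probes)
  expect_gte(recovery, 0.8)
  # direction matches the planted sign
  rec <- res$records[match(sim$truth$probe_id, res$records$probe_id), ]
  expect_true(all(sign(rec$t_stat) == sim$truth$sign))
})

test_that("null contrasts rarely discover anything at the nominal level", {
  hits <- vapply(1:30, function(seed) {
    sim <- simulate_methylation(methyl_sim_config(
      n_cases = 15, n_controls = 15, n_probes = 150, n_true_dmp = 0,
      missing_rate = 0, batch_count = 1, seed = 400 + seed
    ))
    norm <- zero_mean_normalize(sim$beta)
    res <- call_dmps(norm, sim$annotation, contrast = "FTD_vs_control")
    length(res$significant_probes) > 0
  }, logical(1))
  # P(any BH discovery under the global null) <= alpha; allow 2 binomial SEs
  expect_lte(mean(hits), 0.05 + 2 * sqrt(0.05 * 0.95 / 30))
})

test_that("hypo and hyper partition the significant probes disjointly", {
  sim <- simulate_methylation(methyl_sim_config(
    n_cases = 30, n_controls = 30, n_probes = 400, n_true_dmp = 30,
    missing_rate = 0, batch_count = 1, seed = 31
  ))
  norm <- zero_mean_normalize(sim$beta)
  res <- call_dmps(norm, sim$annotation, contrast = "FTD_vs_control")
  sig <- res$records[res$records$probe_id %in% res$significant_probes, ]
  expect_setequal(unique(sig$direction), c("hyper", "hypo"))
  expect_equal(sum(sig$direction == "hyper") + sum(sig$direction == "hypo"), nrow(sig))
  g <- glance(res)
  expect_equal(g$n_hyper + g$n_hypo, g$n_significant_probes)
  expect_equal(g$n_tests, 400)
})

test_that("multi-gene probes contribute each symbol to the significant gene set", {
  v <- matrix(c(rep(0.2, 10), rep(0.8, 10)), 1, 20)[rep(1, 3), ]
  v <- v + matrix(rnorm(60, sd = 0.01), 3, 20)
  v <- pmin(pmax(v, 0), 1)
  m <- tiny_beta(v, groups = rep(c("case_FTD", "control"), each = 10))
  ann <- tiny_annotation(rownames(m$values))
  ann$gene_symbol <- c("GA;GB", "GC", "GC")
  res <- call_dmps(zero_mean_normalize(m), ann, contrast = "FTD_vs_control")
  expect_setequal(res$significant_genes, c("GA", "GB", "GC"))
  expect_equal(length(res$significant_probes), 3)
})

test_that("per-gene probe reports look up without re-correction", {
  sim <- simulate_methylation(methyl_sim_config(
    n_cases = 10, n_controls = 10, n_probes = 100, n_true_dmp = 5,
    missing_rate = 0, batch_count = 1, seed = 41
  ))
  norm <- zero_mean_normalize(sim$beta)
  res <- call_dmps(norm, sim$annotation, contrast = "FTD_vs_control")
  some_gene <- strsplit(res$records$gene_symbol[1], ";")[[1]][1]
  rep1 <- gene_probe_report(res, some_gene)
  expect_gt(nrow(rep1), 0)
  expect_equal(
    rep1$p_bh,
    res$records$p_bh[match(rep1$probe_id, res$records$probe_id)]
  )
  expect_warning(out <- gene_probe_report(res, "NOSUCHGENE"), "NOSUCHGENE")
  expect_equal(nrow(out), 0)
})

test_that("empty contrast groups are refused", {
  m <- tiny_beta(matrix(runif(40), 4, 10))
  ann <- tiny_annotation(rownames(m$values))
  expect_error(
    call_dmps(zero_mean_normalize(m), ann, contrast = "FTD_vs_control"),
    "empty contrast group"
  )
})
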