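test_that("GWAS filtering is strict at the threshold and counts genes", {
  snps <- tibble::tibble(
    rsid = sprintf("rs%03d", 1:4),
    chromosome = "chr1", position = 1:4 * 100L,
    gwas_p = c(0.049999, 0.05, 0.2, 0.01),
    func_class = "intronic", consequence = "none", cadd = NA_real_,
    gene_symbol = c("A", "B", "C", "A")
  )
  out <- filter_gwas(snps)
  expect_equal(out$snps$rsid, c("rs001", "rs004"))
  expect_equal(out$genes, "A")
  # all above threshold -> empty
  none <- filter_gwas(dplyr::mutate(snps, gwas_p = gwas_p + 0.95))
  expect_equal(nrow(none$snps), 0)
  # blacklisted genes dropped
  bl <- filter_gwas(snps, blacklist = "A")
  expect_equal(nrow(bl$snps), 0)
})

test_that("retained SNP and gene counts follow the construction", {
  set.seed(21)
  genes <- sprintf("G%02d", 1:25)
  snps <- tibble::tibble(
    rsid = sprintf("rs%03d", 1:100),
    chromosome = "chr2", position = 1:100 * 10L,
    gwas_p = c(runif(40, 0, 0.049), runif(60, 0.05, 1)),
    func_class = "intronic", consequence = "none", cadd = NA_real_,
    gene_symbol = c(rep(genes, length.out = 40), sample(genes, 60, TRUE))
  )
  out <- filter_gwas(snps)
  expect_equal(nrow(out$snps), 40)
  expect_equal(length(out$genes), 25)
})

test_that("double-hit overlap reduces to the shared hypergeometric tail", {
  expect_equal(double_hit_overlap(LETTERS[1:10], LETTERS[11:20], M = 100)$p, 1)
  full <- double_hit_overlap(LETTERS[1:10], LETTERS[1:10], M = 20)
  expect_equal(full$x, 10)
  expect_equal(full$p, 1 / choose(20, 10), tolerance = 1e-12)
  expect_equal(full$p, hypergeom_upper_tail(20, 10, 10, 10))
  expect_error(double_hit_overlap(LETTERS[1:15], LETTERS[10:20], M = 19), "union")
  expect_error(double_hit_overlap(character(), LETTERS, M = 100), "nonempty")
})

test_that("planted risk genes that are also DMP genes give a significant overlap", {
  ps <- vapply(1:5, function(seed) {
    universe <- sprintf("G%04d", 1:800)
    g <- simulate_gwas(
      gwas_sim_config(n_snps = 2000, n_risk_genes = 40, seed = seed),
      universe
    )
    flt <- filter_gwas(g$snps)
    dmp_genes <- c(g$risk_genes, sample(setdiff(universe, g$risk_genes), 30))
    double_hit_overlap(flt$genes, dmp_genes, M = 800)$p
  }, numeric(1))
  expect_true(all(ps < 0.01))
})

test_that("null risk-gene overlap p-values are consistent with uniformity", {
  set.seed(22)
  ps <- vapply(1:60, function(seed) {
    universe <- sprintf("G%04d", 1:600)
    g <- simulate_gwas(
      gwas_sim_config(n_snps = 800, n_risk_genes = 0, seed = 3000 + seed),
      universe
    )
    flt <- filter_gwas(g$snps)
    dmp_genes <- sample(universe, 60)
    double_hit_overlap(flt$genes, dmp_genes, M = 600)$p
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif", alternative = "greater"))
  expect_gt(ks$p.value, 0.01)
})

test_that("the worked-example candidate table filters to 30 SNPs over 26 genes", {
  fx <- table1_fixture(distractors = TRUE)
  cand <- candidate_filter(fx$snps, fx$dmps)
  expect_equal(nrow(cand), 30)
  g <- glance(cand)
  expect_equal(g$n_genes, 26)
  expect_equal(g$n_hyper_genes, 8)
  expect_equal(g$n_hypo_genes, 18)
  # every emitted row satisfies every predicate
  expect_true(all(cand$gwas_p < 0.05))
  expect_true(all(cand$func_class %in% c("exonic", "splicing")))
  expect_true(all(cand$consequence %in% c("nonsynonymous", "stopgain")))
  expect_true(all(cand$cadd > 15))
  expect_true(all(cand$dmp_p_bh < 0.05))
  # no distractor survives; each was built to fail exactly one criterion
  expect_false(any(grepl("^DHGENE", cand$gene_symbol)))
  # candidate rows are a subset of the nominal GWAS filter output
  flt <- filter_gwas(fx$snps)
  expect_true(all(cand$rsid %in% flt$snps$rsid))
  # duplicated genes: unique-gene count below SNP-row count
  expect_lt(g$n_genes, g$n_snps)
  dup <- names(which(table(cand$gene_symbol) == 2))
  expect_setequal(dup, c("DLG1", "GGA1", "IGHMBP2", "PRR5-ARHGAP8"))
  # min(P) for gene from the unfiltered table: second DLG1 row keeps the best p
  dlg1 <- cand[cand$gene_symbol == "DLG1", ]
  expect_equal(unique(dlg1$min_p_for_gene), 6.01e-4)
})

test_that("a synonymous high-CADD distractor is excluded by consequence alone", {
  fx <- table1_fixture(distractors = TRUE)
  syn <- fx$snps[fx$snps$gene_symbol == "DHGENE3", ]
  expect_equal(syn$consequence, "synonymous")
  expect_gt(syn$cadd, 15)
  cand <- candidate_filter(fx$snps, fx$dmps)
  expect_false("DHGENE3" %in% cand$gene_symbol)
  # CADD boundary 15 exactly is excluded (strict >), 14 too
  expect_false(any(c("DHGENE4", "DHGENE6") %in% cand$gene_symbol))
  # gwas_p = 0.05 exactly is excluded (strict <)
  expect_false("DHGENE7" %in% cand$gene_symbol)
})

test_that("min(P) per gene is computed over the unfiltered table when absent", {
  snps <- tibble::tibble(
    rsid = c("rs1", "rs2", "rs3"),
    chromosome = "chr1", position = c(100L, 200L, 300L),
    gwas_p = c(0.01, 0.001, 0.2),
    func_class = c("exonic", "intronic", "intronic"),
    consequence = c("nonsynonymous", "none", "none"),
    cadd = c(20, NA, NA),
    gene_symbol = c("GX", "GX", "GX")
  )
  dmp <- tibble::tibble(
    gene_symbol = "GX", probe_id = "cg1", p_bh = 0.01, t_stat = -4
  )
  cand <- candidate_filter(snps, dmp)
  expect_equal(nrow(cand), 1)
  # the intronic rs2 contributes the gene-level minimum
  expect_equal(cand$min_p_for_gene, 0.001)
  expect_equal(cand$direction, "hypo")
})

test_that("SNPs on genes missing from the methylation results warn and drop", {
  snps <- tibble::tibble(
    rsid = "rs9", chromosome = "chr1", position = 1L,
    gwas_p = 0.01, func_class = "exonic", consequence = "nonsynonymous",
    cadd = 30, gene_symbol = "UNSEEN"
  )
  dmp <- tibble::tibble(gene_symbol = "OTHER", probe_id = "cg1", p_bh = 0.01, t_stat = 2)
  expect_warning(cand <- candidate_filter(snps, dmp), "UNSEEN")
  expect_equal(nrow(cand), 0)
})

test_that("colocalization detects CpG-site hits and the fixture has none", {
  snps <- tibble::tibble(
    rsid = c("rsA", "rsB", "rsC"),
    chromosome = c("chr1", "1", "chr2"),
    position = c(1000L, 1001L, 5000L)
  )
  ann <- tibble::tibble(
    probe_id = c("cg1", "cg2"),
    chromosome = c("1", "chr2"),
    position = c(1000L, 6000L)
  )
  hits <- probe_snp_colocalization(snps, ann)
  # rsA at the C of the CpG, rsB at the G; chr naming normalised
  expect_setequal(hits$rsid, c("rsA", "rsB"))
  expect_true(all(hits$probe_id == "cg1"))
  # window extension picks up rsC
  hits2 <- probe_snp_colocalization(snps, ann, window = 1000)
  expect_true("rsC" %in% hits2$rsid)
  expect_equal(nrow(probe_snp_colocalization(snps[0, ], ann)), 0)

  fx <- table1_fixture()
  probe_ann <- tibble::tibble(
    probe_id = fx$dmps$probe_id,
    chromosome = fx$dmps$chromosome,
    position = fx$dmps$position
  )
  expect_equal(nrow(probe_snp_colocalization(fx$snps, probe_ann)), 0)
})

test_that("positional gene mapping assigns the nearest gene within the window", {
  genes <- tibble::tibble(
    chromosome = c("chr1", "chr1", "chr2"),
    start = c(0L, 10000L, 0L), end = c(1000L, 11000L, 500L),
    gene_symbol = c("NEAR", "FAR", "OTHERCHR")
  )
  snps <- tibble::tibble(
    rsid = c("rs1", "rs2", "rs3"),
    chromosome = c("chr1", "chr1", "chr3"),
    position = c(500L, 30000L, 100L)
  )
  out <- map_snps_to_genes(snps, genes, window = 5000)
  expect_equal(out$gene_symbol, c("NEAR", NA, NA))
})
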