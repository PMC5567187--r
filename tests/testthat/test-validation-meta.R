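make_expr <- function(n_genes, n_per_class, seed = 1, de = integer(), effect = 2,
                      heavy_tails = FALSE) {
  set.seed(seed)
  sds <- if (heavy_tails) sqrt(1 / rgamma(n_genes, shape = 2, rate = 2)) else rep(1, n_genes)
  e <- matrix(rnorm(n_genes * 2 * n_per_class, sd = rep(sds, 2 * n_per_class)),
    n_genes, 2 * n_per_class,
    dimnames = list(sprintf("G%04d", 1:n_genes), sprintf("s%02d", 1:(2 * n_per_class)))
  )
  labels <- rep(c("case", "control"), each = n_per_class)
  e[de, labels == "case"] <- e[de, labels == "case"] + effect
  list(expr = e + 7, labels = labels)
}

test_that("the d0 = 0 limit reduces the moderated t to the ordinary pooled t", {
  d <- make_expr(50, 4, seed = 1)
  mod <- moderated_t(d$expr, d$labels, d0 = 0)
  ord <- student_t_per_probe(d$expr, which(d$labels == "case"), which(d$labels == "control"))
  expect_equal(mod$t_mod, ord$t_stat, tolerance = 1e-12)
  expect_equal(mod$p, ord$p, tolerance = 1e-12)
})

test_that("the d0 = Inf limit pools every gene to the common variance", {
  d <- make_expr(50, 4, seed = 2)
  mod <- moderated_t(d$expr, d$labels, d0 = Inf)
  # all genes share one residual variance: t proportional to the mean diff
  ratio <- mod$t_mod / mod$log_fc
  expect_lt(diff(range(ratio)), 1e-10)
})

test_that("estimated moderation agrees with the reference empirical-Bayes fit", {
  skip_if_not_installed("limma")
  d <- make_expr(400, 4, seed = 3, heavy_tails = TRUE)
  mod <- moderated_t(d$expr, d$labels)
  design <- cbind(1, d$labels == "case")
  fit <- limma::eBayes(limma::lmFit(d$expr, design))
  expect_equal(attr(mod, "d0"), fit$df.prior, tolerance = 0.05)
  expect_equal(attr(mod, "s0_sq"), fit$s2.prior, tolerance = 0.05)
  expect_equal(mod$t_mod, fit$t[, 2], tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(mod$p, fit$p.value[, 2], tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("null moderated p-values are uniform and shrinkage calms the statistic tail", {
  d <- make_expr(5000, 4, seed = 4, heavy_tails = TRUE)
  mod <- moderated_t(d$expr, d$labels)
  ks <- suppressWarnings(stats::ks.test(mod$p, "punif"))
  expect_gt(ks$p.value, 0.01)
  ord <- moderated_t(d$expr, d$labels, d0 = 0)
  # with only 3 residual df per gene the ordinary statistic explodes for
  # genes whose sample variance is underestimated; shrinkage toward the
  # common variance thins that statistic tail
  expect_lt(sum(abs(mod$t_mod) > 4), sum(abs(ord$t_mod) > 4))
})

test_that("Fisher overrepresentation matches enumeration and is symmetric", {
  # margins 4/4/4/4, table [[3,1],[1,3]]
  platform <- sprintf("G%02d", 1:8)
  query <- platform[1:4]
  de <- platform[c(1:3, 5)]
  p <- fisher_overrepresentation(query, de, platform)
  expect_equal(p, 34 / 70, tolerance = 1e-12)
  tab <- matrix(c(3, 1, 1, 3), 2)
  expect_equal(p, oracle_fisher2x2(tab), tolerance = 1e-12)
  expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-12)
  # swapping both row and column labels leaves p unchanged
  p_swapped <- fisher_overrepresentation(setdiff(platform, query), setdiff(platform, de), platform)
  expect_equal(p, p_swapped, tolerance = 1e-12)
  expect_error(fisher_overrepresentation(query, de, character()), "empty platform")
})

test_that("query equal to the DE set on a large platform is near-minimal", {
  platform <- sprintf("G%04d", 1:2000)
  de <- platform[1:40]
  p <- fisher_overrepresentation(de, de, platform)
  expect_lt(p, 1e-60)
})

test_that("Fisher p-values are consistent with uniformity under independence", {
  set.seed(41)
  platform <- sprintf("G%04d", 1:1000)
  ps <- replicate(120, {
    q <- sample(platform, 100)
    de <- sample(platform, 100)
    fisher_overrepresentation(q, de, platform)
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif", alternative = "greater"))
  expect_gt(ks$p.value, 0.01)
})

test_that("genes validated in more sets rank first; per-set BH uses platform size", {
  genes <- sprintf("G%04d", 1:300)
  two_hits <- genes[1:5]
  one_hit <- genes[6:10]
  sets <- list(
    make_synthetic_validation_set(genes, de_genes = c(two_hits, one_hit),
      n_per_class = 6, name = "set1", effect = 4, seed = 51
    ),
    make_synthetic_validation_set(genes, de_genes = two_hits,
      n_per_class = 6, name = "set2", effect = 4, seed = 52
    ),
    make_synthetic_validation_set(genes, de_genes = character(),
      n_per_class = 6, name = "set3", seed = 53
    )
  )
  out <- validate_genes(c(two_hits, one_hit, genes[11:20]), sets)
  rk <- out$ranking
  expect_setequal(rk$gene[rk$n_sets_validated == 2], two_hits)
  expect_true(all(rk$n_sets_validated[match(one_hit, rk$gene)] <= 1))
  # ranking is sorted by validating-set count
  expect_true(all(diff(rk$n_sets_validated) <= 0))
  expect_equal(out$n_validated, sum(rk$n_sets_validated >= 1))
  # a set with zero DE genes contributes nothing
  expect_equal(length(out$de_sets$set3), 0)
  expect_true(all(out$grid$set3 != "validated"))
})

test_that("genes missing from a platform are not-assayed, not not-DE", {
  genes <- sprintf("G%04d", 1:100)
  s1 <- make_synthetic_validation_set(genes[1:50], de_genes = genes[1:5],
    n_per_class = 5, name = "narrow", effect = 4, seed = 61
  )
  out <- validate_genes(c(genes[1:5], genes[60:62]), list(s1))
  grid <- out$grid
  expect_true(all(grid$narrow[grid$gene %in% toupper(genes[60:62])] == "not_assayed"))
  expect_true(all(grid$narrow[grid$gene %in% toupper(genes[1:5])] == "validated"))
})

test_that("adding a data set never decreases a gene's validating-set count", {
  genes <- sprintf("G%04d", 1:150)
  s1 <- make_synthetic_validation_set(genes, de_genes = genes[1:8],
    n_per_class = 6, name = "a", effect = 4, seed = 71
  )
  s2 <- make_synthetic_validation_set(genes, de_genes = genes[5:12],
    n_per_class = 6, name = "b", effect = 4, seed = 72
  )
  out1 <- validate_genes(genes[1:20], list(s1))
  out2 <- validate_genes(genes[1:20], list(s1, s2))
  c1 <- out1$ranking$n_sets_validated[match(genes[1:20], out1$ranking$gene)]
  c2 <- out2$ranking$n_sets_validated[match(genes[1:20], out2$ranking$gene)]
  expect_true(all(c2 >= c1))
})

test_that("duplicate platform rows collapse to the highest-variance probe", {
  e <- matrix(rnorm(4 * 8), 4, 8,
    dimnames = list(c("GA", "GA", "GB", "GC"), sprintf("s%d", 1:8))
  )
  e[1, ] <- e[1, ] * 0.1 # low-variance duplicate
  vs <- validation_set(e, rep(c("case", "control"), each = 4), "dup")
  expect_equal(nrow(vs$expr), 3)
  expect_equal(unname(vs$expr["GA", ]), unname(e[2, ]))
})
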