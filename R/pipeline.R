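# End-to-end orchestration over synthetic inputs: every scalar threshold of
# the analysis is a named config key whose default is the published value,
# so the default run is the reference run.

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline. Defaults are the reference
#' thresholds: 20% probe missingness, MAF 0.1, alpha 0.05, fold difference
#' 1.5, CADD 15, |r| 0.6 with p < 0.001 for network edges, K = 3 imputation
#' neighbours. Unknown keys are rejected.
#'
#' @param ... Overrides for any config key.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    stages = c(
      "simulate", "qc", "dmp", "cluster", "enrich", "integrate",
      "network", "validate"
    ),
    seed = 1L,
    missing_threshold = 0.20,
    maf_threshold = 0.10,
    alpha = 0.05,
    fold_threshold = 1.5,
    cadd_threshold = 15,
    gwas_p_threshold = 0.05,
    r_min = 0.6,
    p_max = 0.001,
    knn_k = 3,
    contrast = "FTDALS_vs_control",
    hg19_universe = 25318L,
    genome_build = "hg19",
    methyl = list(),
    gwas = list(),
    atlas = list(),
    n_validation_sets = 4L,
    validation_n_per_class = 4L,
    validation_n_genes = 500L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

#' Run the full pipeline on synthetic data
#'
#' Executes the enabled stages in their fixed order — simulate, qc
#' (batch adjustment, probe filters, imputation, normalisation), dmp,
#' cluster, enrich (tissue-specificity sets), integrate (double-hit overlap
#' and candidate filter), network, validate — and writes a run directory
#' containing a manifest (config and seed), per-stage TSV outputs, and a
#' machine-readable `results.json`. Re-running with the same config and
#' seed reproduces the results exactly. A stage whose prerequisites were
#' toggled off fails with the missing stage named.
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Run directory (created if needed).
#' @return The results list, invisibly (also serialised to
#'   `results.json`).
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir = tempfile("run")) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  on_stage <- function(s) s %in% cfg$stages
  res <- list(seed = cfg$seed)
  state <- new.env(parent = emptyenv())

  if (!on_stage("simulate")) stop("stage 'simulate' is required for the synthetic run", call. = FALSE)
  mcfg <- do.call(methyl_sim_config, c(list(seed = cfg$seed), cfg$methyl))
  sim <- simulate_methylation(mcfg)
  state$sim <- sim
  res$simulate <- list(
    n_probes = nrow(sim$beta$values), n_samples = ncol(sim$beta$values),
    n_true_dmp = nrow(sim$truth)
  )

  if (on_stage("qc")) {
    pp <- preprocess_beta(sim$beta, sim$annotation,
      missing = cfg$missing_threshold, maf = cfg$maf_threshold,
      knn_k = cfg$knn_k
    )
    state$beta <- pp$beta
    write_filter_report(pp$report, file.path(out_dir, "filter_report.json"))
    res$qc <- list(
      probes_retained = pp$report$probes_retained,
      genes_retained = pp$report$genes_retained
    )
  }

  if (on_stage("dmp")) {
    if (is.null(state$beta)) stop("stage 'dmp' needs stage 'qc'", call. = FALSE)
    dmp <- call_dmps(state$beta, sim$annotation,
      contrast = cfg$contrast, alpha = cfg$alpha
    )
    state$dmp <- dmp
    readr::write_tsv(dmp$records, file.path(out_dir, "dmp_records.tsv"), progress = FALSE)
    res$dmp <- as.list(glance(dmp))
    truth <- sim$truth$probe_id
    if (length(truth)) {
      res$dmp$recovery <- mean(truth %in% dmp$significant_probes)
    }
  }

  if (on_stage("cluster")) {
    if (is.null(state$dmp)) stop("stage 'cluster' needs stage 'dmp'", call. = FALSE)
    sig <- state$dmp$significant_probes
    res$cluster <- if (length(sig) >= 2) {
      x <- samples_matrix(state$beta, probes = sig)
      cl <- select_k_and_label(hierarchical_cluster(x), x,
        k_range = 2:min(6, nrow(x) - 1)
      )
      sep_p <- cluster_separation_test(
        cl$labels,
        state$beta$sample_meta$group,
        target = if (cfg$contrast == "FTD_vs_control") c("case_FTD", "case_FTDALS") else "case_FTDALS"
      )
      pc <- pca_components(x, n_components = 2)
      readr::write_tsv(tidy(cl), file.path(out_dir, "cluster_labels.tsv"), progress = FALSE)
      readr::write_tsv(cl$db_by_k, file.path(out_dir, "db_curve.tsv"), progress = FALSE)
      readr::write_tsv(tidy(pc), file.path(out_dir, "pca_scores.tsv"), progress = FALSE)
      list(
        k_star = cl$k_star, separation_p = sep_p,
        pc1_variance = pc$explained_variance_ratio[1]
      )
    } else {
      list(k_star = NA, separation_p = NA, note = "fewer than 2 significant probes")
    }
  }

  atlas <- NULL
  if (on_stage("enrich") || on_stage("network")) {
    gene_universe <- unique(unlist(strsplit(sim$annotation$gene_symbol, ";")))
    gene_universe <- gene_universe[gene_universe != ""]
    acfg <- do.call(atlas_sim_config, c(
      list(seed = cfg$seed + 1L),
      cfg$atlas
    ))
    if (is.null(cfg$atlas$n_genes)) {
      acfg$n_genes <- max(length(gene_universe), acfg$n_tissues * acfg$n_specific_per_tissue)
    }
    atlas <- simulate_expression_atlas(acfg)
    # align atlas gene ids with the methylation gene universe
    rownames(atlas$expr)[seq_len(min(length(gene_universe), nrow(atlas$expr)))] <-
      gene_universe[seq_len(min(length(gene_universe), nrow(atlas$expr)))]
  }

  if (on_stage("enrich")) {
    if (is.null(state$dmp)) stop("stage 'enrich' needs stage 'dmp'", call. = FALSE)
    sets <- build_specificity_sets(atlas$expr, atlas$tissue,
      fold_threshold = cfg$fold_threshold, alpha = cfg$alpha
    )
    res$enrich <- if (length(state$dmp$significant_genes) > 0 &&
      length(intersect(
        toupper(state$dmp$significant_genes),
        toupper(rownames(atlas$expr))
      )) > 0) {
      er <- enrich(state$dmp$significant_genes, sets)
      readr::write_tsv(
        dplyr::select(tibble::as_tibble(er), -"overlap_genes"),
        file.path(out_dir, "tissue_enrichment.tsv"),
        progress = FALSE
      )
      list(n_sets = length(sets), n_significant = sum(er$p_bh < cfg$alpha))
    } else {
      list(n_sets = length(sets), n_significant = 0L, note = "no testable query genes")
    }
  }

  if (on_stage("integrate")) {
    if (is.null(state$dmp)) stop("stage 'integrate' needs stage 'dmp'", call. = FALSE)
    gene_universe <- unique(unlist(strsplit(sim$annotation$gene_symbol, ";")))
    gene_universe <- gene_universe[gene_universe != ""]
    gcfg <- do.call(gwas_sim_config, c(list(seed = cfg$seed + 2L), cfg$gwas))
    gw <- simulate_gwas(gcfg, gene_universe)
    flt <- filter_gwas(gw$snps, p_threshold = cfg$gwas_p_threshold)
    res$integrate <- list(
      n_snps_retained = nrow(flt$snps),
      n_gwas_genes = length(flt$genes)
    )
    if (length(state$dmp$significant_genes) > 0 && length(flt$genes) > 0) {
      M <- max(cfg$hg19_universe, length(union(flt$genes, state$dmp$significant_genes)))
      ov <- double_hit_overlap(flt$genes, state$dmp$significant_genes, M = M)
      res$integrate$overlap_x <- ov$x
      res$integrate$overlap_p <- ov$p
      cand <- candidate_filter(gw$snps, state$dmp,
        cadd_threshold = cfg$cadd_threshold,
        p_threshold = cfg$gwas_p_threshold, alpha = cfg$alpha
      )
      state$cand <- cand
      readr::write_tsv(cand, file.path(out_dir, "candidates.tsv"), progress = FALSE)
      res$integrate <- c(res$integrate, as.list(glance(cand)))
    }
  }

  if (on_stage("network")) {
    if (is.null(state$dmp)) stop("stage 'network' needs stage 'dmp'", call. = FALSE)
    q <- state$dmp$significant_genes
    res$network <- if (length(intersect(q, rownames(atlas$expr))) >= 2) {
      cors <- spearman_matrix(atlas$expr, genes = q)
      net <- build_network(cors, r_min = cfg$r_min, p_max = cfg$p_max)
      state$net <- net
      write_network(net, file.path(out_dir, "network_edges.tsv"))
      readr::write_tsv(degree_prioritize(net), file.path(out_dir, "gene_degree.tsv"),
        progress = FALSE
      )
      as.list(glance(net))
    } else {
      list(n_nodes = 0L, n_edges = 0L, note = "fewer than 2 query genes in the atlas")
    }
  }

  if (on_stage("validate")) {
    if (is.null(state$dmp)) stop("stage 'validate' needs stage 'dmp'", call. = FALSE)
    q <- state$dmp$significant_genes
    res$validate <- if (length(q) > 0) {
      vsets <- lapply(seq_len(cfg$n_validation_sets), function(i) {
        make_synthetic_validation_set(
          genes = unique(c(q, sprintf("VG%04d", seq_len(cfg$validation_n_genes)))),
          de_genes = if (i <= 2) q[seq_len(ceiling(length(q) / 2))] else character(),
          n_per_class = cfg$validation_n_per_class,
          name = sprintf("synthetic_set_%d", i),
          seed = cfg$seed + 10L + i
        )
      })
      out <- validate_genes(q, vsets, alpha = cfg$alpha)
      readr::write_tsv(out$ranking, file.path(out_dir, "validation_ranking.tsv"),
        progress = FALSE
      )
      c(as.list(glance(out)), list(fisher_p_min = min(out$fisher_p)))
    } else {
      list(n_validated = 0L, note = "no query genes")
    }
  }

  manifest <- list(
    config = unclass(cfg),
    package_version = as.character(utils::packageVersion("doublehit")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA, force = TRUE
  )
  jsonlite::write_json(res, file.path(out_dir, "results.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA, force = TRUE
  )
  invisible(res)
}

#' Synthetic case/control expression set with planted DE genes
#'
#' @param genes Gene symbols on the synthetic platform.
#' @param de_genes Subset planted as differentially expressed (2 log2
#'   units).
#' @param n_per_class Samples per class.
#' @param name Set label.
#' @param effect Planted effect size, log2 units.
#' @param seed Integer seed.
#' @return A [validation_set()].
#' @export
make_synthetic_validation_set <- function(genes, de_genes = character(),
                                          n_per_class = 4,
                                          name = "synthetic_set",
                                          effect = 2, seed = 1L) {
  genes <- unique(toupper(genes))
  with_local_seed(seed, {
    n <- 2 * n_per_class
    expr <- matrix(stats::rnorm(length(genes) * n, mean = 7, sd = 1),
      length(genes), n,
      dimnames = list(genes, sprintf("V%03d", seq_len(n)))
    )
    labels <- rep(c("case", "control"), each = n_per_class)
    de <- match(unique(toupper(de_genes)), genes)
    de <- de[!is.na(de)]
    expr[de, labels == "case"] <- expr[de, labels == "case"] +
      sample(c(-effect, effect), length(de), replace = TRUE)
    validation_set(expr, labels, name = name)
  })
}

#' Summarise a completed run directory
#'
#' Pure reporting: every number comes from `results.json` or the stage TSV
#' files; nothing is recomputed. Missing stage outputs are marked absent.
#'
#' @param run_dir Directory written by [run_pipeline()].
#' @return Character vector of report lines (also printed).
#' @export
pipeline_report <- function(run_dir) {
  res_path <- file.path(run_dir, "results.json")
  if (!file.exists(res_path)) stop("no results.json in ", run_dir, call. = FALSE)
  res <- jsonlite::read_json(res_path, simplifyVector = TRUE)
  fmt <- function(x, d = 4) {
    if (is.null(x) || length(x) == 0 || all(is.na(x))) "absent" else format(signif(x, d))
  }
  lines <- c(
    sprintf("run summary (seed %s)", fmt(res$seed)),
    sprintf(
      "  simulate: %s probes x %s samples, %s true DMPs",
      fmt(res$simulate$n_probes), fmt(res$simulate$n_samples),
      fmt(res$simulate$n_true_dmp)
    ),
    if (!is.null(res$qc)) {
      sprintf(
        "  qc: %s probes retained over %s genes",
        fmt(res$qc$probes_retained), fmt(res$qc$genes_retained)
      )
    } else "  qc: absent",
    if (!is.null(res$dmp)) {
      sprintf(
        "  dmp (%s): %s significant probes / %s genes (%s hyper, %s hypo)",
        res$dmp$contrast, fmt(res$dmp$n_significant_probes),
        fmt(res$dmp$n_significant_genes), fmt(res$dmp$n_hyper), fmt(res$dmp$n_hypo)
      )
    } else "  dmp: absent",
    if (!is.null(res$cluster)) {
      sprintf(
        "  cluster: k* = %s, separation p = %s",
        fmt(res$cluster$k_star), fmt(res$cluster$separation_p)
      )
    } else "  cluster: absent",
    if (!is.null(res$enrich)) {
      sprintf(
        "  enrich: %s specificity sets, %s significant",
        fmt(res$enrich$n_sets), fmt(res$enrich$n_significant)
      )
    } else "  enrich: absent",
    if (!is.null(res$integrate)) {
      sprintf(
        "  integrate: overlap x = %s (p = %s); candidates: %s SNPs / %s genes",
        fmt(res$integrate$overlap_x), fmt(res$integrate$overlap_p),
        fmt(res$integrate$n_snps), fmt(res$integrate$n_genes)
      )
    } else "  integrate: absent",
    if (!is.null(res$network)) {
      sprintf(
        "  network: %s nodes, %s edges",
        fmt(res$network$n_nodes), fmt(res$network$n_edges)
      )
    } else "  network: absent",
    if (!is.null(res$validate)) {
      sprintf(
        "  validate: %s of %s genes validated",
        fmt(res$validate$n_validated), fmt(res$validate$n_query)
      )
    } else "  validate: absent"
  )
  cat(lines, sep = "\n")
  invisible(lines)
}
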