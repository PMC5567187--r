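# Synthetic-data generators. Every input the pipeline consumes can be
# simulated here with the statistical structure the downstream stages assume,
# so the full analysis is exercisable without any external download.

# run code under a seed without disturbing the caller's RNG stream
with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Configuration for the methylation simulator
#'
#' Defaults emulate the structure of the blood 450K cohort the pipeline is
#' designed for: 128 cases (7 of them the FTD-ALS subtype) versus 193
#' controls processed in two batches, bimodal beta values, a designated set
#' of truly differential probes with a case-mean shift of `delta_beta`, and
#' uniform missing-at-random dropout. The probe count is a desk-scale stand-in
#' for a full array.
#'
#' @param n_cases,n_controls Sample counts per arm.
#' @param n_ftdals How many of the cases carry the FTD-ALS subtype label
#'   (default 7, capped at `n_cases`).
#' @param n_probes Number of probes simulated.
#' @param n_true_dmp Number of truly differential probes (case mean shifted).
#' @param delta_beta Case-mean shift on the beta scale for true DMPs.
#' @param batch_count Number of processing batches (round-robin assignment).
#' @param batch_shift Additive batch offset on the beta scale (batch b gets
#'   `batch_shift * (b - 1)`).
#' @param batch_scale Multiplicative noise scale per batch (batch b gets
#'   `batch_scale^(b - 1)`).
#' @param missing_rate Fraction of cells set missing, uniformly at random.
#' @param sd_logit Noise standard deviation on the logit scale
#'   (about 0.05 on the beta scale at mid-range methylation).
#' @param seed Integer seed; simulation is bit-reproducible given the seed.
#'
#' @return A list of class `methyl_sim_config`.
#' @export
methyl_sim_config <- function(n_cases = 128, n_controls = 193,
                              n_ftdals = min(7L, n_cases),
                              n_probes = 2000, n_true_dmp = 50,
                              delta_beta = 0.15, batch_count = 2,
                              batch_shift = 0.05, batch_scale = 1.2,
                              missing_rate = 0.02, sd_logit = 0.35,
                              seed = 1L) {
  cfg <- list(
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    n_ftdals = as.integer(n_ftdals), n_probes = as.integer(n_probes),
    n_true_dmp = as.integer(n_true_dmp), delta_beta = delta_beta,
    batch_count = as.integer(batch_count), batch_shift = batch_shift,
    batch_scale = batch_scale, missing_rate = missing_rate,
    sd_logit = sd_logit, seed = as.integer(seed)
  )
  if (cfg$n_true_dmp > cfg$n_probes) stop("n_true_dmp must be <= n_probes", call. = FALSE)
  if (cfg$n_ftdals > cfg$n_cases) stop("n_ftdals must be <= n_cases", call. = FALSE)
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) stop("missing_rate must be in [0, 1)", call. = FALSE)
  if (cfg$n_true_dmp > 0 && cfg$n_cases > 0 &&
      (cfg$delta_beta < 0 || cfg$delta_beta > 0.6)) {
    # baseline means for true DMPs are drawn in [0.2, 0.8]; a shift above 0.6
    # would push a shifted mean outside [0, 1]
    stop("delta_beta = ", cfg$delta_beta,
      " would push case means outside [0, 1]; use a value in [0, 0.6]",
      call. = FALSE
    )
  }
  if (cfg$batch_count < 1) stop("batch_count must be >= 1", call. = FALSE)
  structure(cfg, class = "methyl_sim_config")
}

#' Simulate a methylation beta-value matrix with annotation and truth
#'
#' Values are generated on the logit scale (baseline drawn from a bimodal
#' mixture, Gaussian noise) and inverse-transformed, which keeps the \[0, 1\]
#' support and gives the heteroscedastic, boundary-compressed noise typical
#' of beta values. True DMPs get a case-mean shift of `+/- delta_beta` on the
#' beta scale (baseline restricted to \[0.2, 0.8\] so the shifted mean stays
#' inside the support); batches add a location offset and scale the noise.
#' The annotation gives every probe a gene, gene-region class, CpG-island
#' relation and chromosome, plus SNP/control/blacklist flags, so each probe
#' filter downstream has targets. True DMPs are planted only on probes that
#' survive every filter.
#'
#' @param cfg A [methyl_sim_config()].
#' @return A list with elements `beta` ([beta_matrix()]), `annotation`
#'   (probe annotation tibble), and `truth` (tibble `probe_id`, `sign` with
#'   `+1` for hyper-, `-1` for hypomethylated planting).
#' @export
simulate_methylation <- function(cfg = methyl_sim_config()) {
  stopifnot(inherits(cfg, "methyl_sim_config"))
  with_local_seed(cfg$seed, {
    n_samp <- cfg$n_cases + cfg$n_controls
    probe_ids <- sprintf("cg%07d", seq_len(cfg$n_probes))
    sample_ids <- sprintf("S%04d", seq_len(n_samp))
    group <- c(
      rep("case_FTDALS", cfg$n_ftdals),
      rep("case_FTD", cfg$n_cases - cfg$n_ftdals),
      rep("control", cfg$n_controls)
    )
    batch <- if (n_samp) sprintf("batch%d", ((seq_len(n_samp) - 1L) %% cfg$batch_count) + 1L) else character()

    ann <- simulate_probe_annotation(probe_ids)
    clean <- ann$probe_id[ann$chromosome %in% sprintf("chr%d", 1:22) &
      (is.na(ann$snp_maf) | ann$snp_maf <= 0.1) &
      !ann$control_probe & !ann$blacklist &
      ann$region_class != "intergenic"]
    if (cfg$n_true_dmp > length(clean)) {
      stop("not enough filter-clean probes to plant ", cfg$n_true_dmp, " true DMPs", call. = FALSE)
    }
    truth_probes <- sort(sample(clean, cfg$n_true_dmp))
    truth_sign <- sample(c(-1, 1), cfg$n_true_dmp, replace = TRUE)

    # baseline methylation: bimodal on the logit scale; true DMPs pinned to
    # the intermediate range so the beta-scale shift is representable
    base_logit <- ifelse(stats::runif(cfg$n_probes) < 0.5,
      stats::rnorm(cfg$n_probes, -2, 0.7), stats::rnorm(cfg$n_probes, 2, 0.7)
    )
    base <- stats::plogis(base_logit)
    ti <- match(truth_probes, probe_ids)
    base[ti] <- stats::runif(cfg$n_true_dmp, 0.2, 0.8)
    # flip sign where the shift would leave [0.05, 0.95]
    shifted <- base[ti] + truth_sign * cfg$delta_beta
    flip <- shifted > 0.95 | shifted < 0.05
    truth_sign[flip] <- -truth_sign[flip]

    eps <- matrix(stats::rnorm(cfg$n_probes * n_samp, sd = cfg$sd_logit),
      cfg$n_probes, n_samp
    )
    b_idx <- ((seq_len(n_samp) - 1L) %% cfg$batch_count) + 1L
    scale_s <- cfg$batch_scale^(b_idx - 1L)
    shift_s <- cfg$batch_shift * (b_idx - 1L)
    # heteroscedastic noise: logit-scale perturbation mapped back to beta scale
    vals <- stats::plogis(stats::qlogis(pmin(pmax(base, 1e-6), 1 - 1e-6)) +
      sweep(eps, 2, scale_s, `*`))
    vals <- sweep(vals, 2, shift_s, `+`)
    if (cfg$n_true_dmp > 0 && cfg$n_cases > 0) {
      case_cols <- seq_len(cfg$n_cases)
      vals[ti, case_cols] <- vals[ti, case_cols] + truth_sign * cfg$delta_beta
    }
    vals <- pmin(pmax(vals, 0), 1)
    if (cfg$missing_rate > 0) {
      drop <- stats::runif(length(vals)) < cfg$missing_rate
      vals[drop] <- NA_real_
    }
    dimnames(vals) <- list(probe_ids, sample_ids)

    meta <- tibble::tibble(sample_id = sample_ids, group = group, batch = batch)
    list(
      beta = beta_matrix(vals, meta),
      annotation = ann,
      truth = tibble::tibble(probe_id = truth_probes, sign = truth_sign)
    )
  })
}

# internal: 450K-manifest-style probe annotation with filterable strata
simulate_probe_annotation <- function(probe_ids) {
  n <- length(probe_ids)
  chroms <- sample(c(sprintf("chr%d", 1:22), "chrX", "chrY"),
    n, replace = TRUE,
    prob = c(rep(0.93 / 22, 22), 0.05, 0.02)
  )
  region <- sample(
    c("TSS1500", "TSS200", "5UTR", "1stExon", "Body", "3UTR", "intergenic"),
    n, replace = TRUE,
    prob = c(0.15, 0.12, 0.1, 0.08, 0.35, 0.1, 0.1)
  )
  island <- sample(
    c("Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf", "open_sea"),
    n, replace = TRUE, prob = c(0.3, 0.12, 0.12, 0.05, 0.05, 0.36)
  )
  has_snp <- stats::runif(n) < 0.08
  maf <- ifelse(has_snp, round(stats::runif(n, 0, 0.5), 3), NA_real_)
  # ~3 probes per gene on average; a small fraction of probes map to 2 genes
  n_genes <- max(1L, ceiling(n / 3))
  gene <- sprintf("G%05d", sample.int(n_genes, n, replace = TRUE))
  two <- which(stats::runif(n) < 0.03)
  gene[two] <- paste(gene[two], sprintf("G%05d", sample.int(n_genes, length(two), replace = TRUE)), sep = ";")
  gene[region == "intergenic"] <- ""
  tibble::tibble(
    probe_id = probe_ids,
    chromosome = chroms,
    position = sample.int(2e8, n, replace = TRUE),
    gene_symbol = gene,
    region_class = region,
    island_relation = island,
    snp_maf = maf,
    control_probe = stats::runif(n) < 0.02,
    blacklist = stats::runif(n) < 0.02
  )
}

#' Configuration for the GWAS summary-statistics simulator
#'
#' @param n_snps Number of SNP rows.
#' @param n_risk_genes Number of genes whose SNPs get association p-values
#'   enriched below 0.05.
#' @param frac_exonic Fraction of SNPs annotated exonic.
#' @param cadd_high_rate Fraction of exonic/splicing SNPs with CADD above 15.
#' @param seed Integer seed.
#' @return A list of class `gwas_sim_config`.
#' @export
gwas_sim_config <- function(n_snps = 5000, n_risk_genes = 20,
                            frac_exonic = 0.1, cadd_high_rate = 0.3,
                            seed = 1L) {
  cfg <- list(
    n_snps = as.integer(n_snps), n_risk_genes = as.integer(n_risk_genes),
    frac_exonic = frac_exonic, cadd_high_rate = cadd_high_rate,
    seed = as.integer(seed)
  )
  if (cfg$frac_exonic < 0 || cfg$frac_exonic > 1) stop("frac_exonic must be in [0, 1]", call. = FALSE)
  if (cfg$cadd_high_rate < 0 || cfg$cadd_high_rate > 1) stop("cadd_high_rate must be in [0, 1]", call. = FALSE)
  structure(cfg, class = "gwas_sim_config")
}

#' Simulate an annotated GWAS summary-statistics table
#'
#' P-values are uniform under the null; SNPs mapped to the designated risk
#' genes are drawn below 0.05. Functional class, amino-acid consequence and
#' CADD score columns carry the strata the candidate filter consumes
#' (variant annotation is an input to the pipeline, never computed by it).
#'
#' @param cfg A [gwas_sim_config()].
#' @param gene_universe Nonempty character vector of gene symbols SNPs map to.
#' @return A list with `snps` (tibble of SNP records) and `risk_genes`
#'   (character, the planted risk genes).
#' @export
simulate_gwas <- function(cfg = gwas_sim_config(), gene_universe) {
  stopifnot(inherits(cfg, "gwas_sim_config"))
  if (length(gene_universe) == 0) stop("gene_universe must be nonempty", call. = FALSE)
  gene_universe <- unique(gene_universe)
  with_local_seed(cfg$seed, {
    n <- cfg$n_snps
    risk <- if (cfg$n_risk_genes > 0) {
      sample(gene_universe, min(cfg$n_risk_genes, length(gene_universe)))
    } else {
      character()
    }
    gene <- sample(gene_universe, n, replace = TRUE)
    p <- stats::runif(n)
    in_risk <- gene %in% risk
    p[in_risk] <- stats::runif(sum(in_risk), 0, 0.05)

    other_classes <- c("splicing", "intronic", "intergenic", "UTR5", "UTR3")
    func <- ifelse(stats::runif(n) < cfg$frac_exonic, "exonic",
      sample(other_classes, n, replace = TRUE, prob = c(0.02, 0.55, 0.3, 0.065, 0.065))
    )
    cons <- rep("none", n)
    ex <- func == "exonic"
    cons[ex] <- sample(c("nonsynonymous", "synonymous", "stopgain"),
      sum(ex), replace = TRUE, prob = c(0.6, 0.35, 0.05)
    )
    cons[func == "splicing"] <- "nonsynonymous"
    cadd <- rep(NA_real_, n)
    coding <- func %in% c("exonic", "splicing")
    hi <- coding & stats::runif(n) < cfg$cadd_high_rate
    cadd[hi] <- round(15 + stats::rexp(sum(hi), 1 / 8), 2)
    cadd[coding & !hi] <- round(stats::runif(sum(coding & !hi), 0, 15), 2)

    snps <- tibble::tibble(
      rsid = sprintf("rs%08d", sample.int(9e7, n)),
      chromosome = sample(sprintf("chr%d", 1:22), n, replace = TRUE),
      position = sample.int(2e8, n, replace = TRUE),
      gwas_p = p,
      func_class = func,
      consequence = cons,
      cadd = cadd,
      gene_symbol = gene
    )
    list(snps = snps, risk_genes = risk)
  })
}

#' Configuration for the tissue-expression-atlas simulator
#'
#' Defaults are a desk-scale stand-in for a bulk multi-tissue atlas
#' (thousands of genes over tens of tissues).
#'
#' @param n_genes Number of genes.
#' @param n_tissues Number of tissue types.
#' @param n_specific_per_tissue Planted tissue-specific genes per tissue.
#' @param log_fold Within-tissue elevation for specific genes, log2 scale.
#' @param n_samples_per_tissue Samples per tissue.
#' @param sd_log Noise SD on the log2 scale.
#' @param seed Integer seed.
#' @return A list of class `atlas_sim_config`.
#' @export
atlas_sim_config <- function(n_genes = 1000, n_tissues = 10,
                             n_specific_per_tissue = 20, log_fold = 3,
                             n_samples_per_tissue = 15, sd_log = 1,
                             seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), n_tissues = as.integer(n_tissues),
    n_specific_per_tissue = as.integer(n_specific_per_tissue),
    log_fold = log_fold,
    n_samples_per_tissue = as.integer(n_samples_per_tissue),
    sd_log = sd_log, seed = as.integer(seed)
  )
  if (cfg$n_tissues * cfg$n_specific_per_tissue > cfg$n_genes) {
    stop("n_tissues * n_specific_per_tissue must be <= n_genes", call. = FALSE)
  }
  structure(cfg, class = "atlas_sim_config")
}

#' Simulate a tissue-structured expression atlas
#'
#' Linear-scale (nonnegative) expression: log2 values are Gaussian around a
#' per-gene baseline, and each planted tissue-specific gene has its
#' within-tissue log2 mean raised by `log_fold`. Specific genes are disjoint
#' across tissues by construction (the specificity-set builder may still
#' discover overlaps when thresholds allow).
#'
#' @param cfg An [atlas_sim_config()].
#' @return A list with `expr` (genes x samples matrix, linear scale),
#'   `tissue` (character vector of tissue labels per sample) and `truth`
#'   (named list tissue -> planted specific genes).
#' @export
simulate_expression_atlas <- function(cfg = atlas_sim_config()) {
  stopifnot(inherits(cfg, "atlas_sim_config"))
  with_local_seed(cfg$seed, {
    genes <- sprintf("G%05d", seq_len(cfg$n_genes))
    tissues <- sprintf("tissue%02d", seq_len(cfg$n_tissues))
    tissue <- rep(tissues, each = cfg$n_samples_per_tissue)
    n_samp <- length(tissue)
    base <- stats::rnorm(cfg$n_genes, 5, 1.5)
    lg <- matrix(stats::rnorm(cfg$n_genes * n_samp, sd = cfg$sd_log),
      cfg$n_genes, n_samp
    ) + base
    spec_ids <- split(
      genes[seq_len(cfg$n_tissues * cfg$n_specific_per_tissue)],
      rep(tissues, each = cfg$n_specific_per_tissue)
    )
    for (tt in tissues) {
      gi <- match(spec_ids[[tt]], genes)
      lg[gi, tissue == tt] <- lg[gi, tissue == tt] + cfg$log_fold
    }
    expr <- 2^lg
    dimnames(expr) <- list(genes, sprintf("A%04d", seq_len(n_samp)))
    list(expr = expr, tissue = tissue, truth = spec_ids[tissues])
  })
}

#' Simulate expression with planted correlated gene blocks
#'
#' Supports co-expression network tests: genes inside each planted block
#' share a latent factor giving pairwise correlation near `rho`; all other
#' genes are independent noise.
#'
#' @param n_genes Total genes.
#' @param n_samples Samples.
#' @param blocks List of integer block sizes (blocks take the first genes).
#' @param rho Target within-block correlation.
#' @param seed Integer seed.
#' @return A list with `expr` (genes x samples, linear scale) and `blocks`
#'   (list of gene-id character vectors).
#' @export
simulate_coexpr_blocks <- function(n_genes = 50, n_samples = 100,
                                   blocks = list(10), rho = 0.9, seed = 1L) {
  stopifnot(sum(unlist(blocks)) <= n_genes, rho >= 0, rho < 1)
  with_local_seed(seed, {
    genes <- sprintf("G%05d", seq_len(n_genes))
    lg <- matrix(stats::rnorm(n_genes * n_samples), n_genes, n_samples)
    a <- sqrt(rho)
    b <- sqrt(1 - rho)
    idx <- 0L
    block_genes <- list()
    for (k in seq_along(blocks)) {
      size <- blocks[[k]]
      factor_k <- stats::rnorm(n_samples)
      rows <- idx + seq_len(size)
      lg[rows, ] <- a * matrix(factor_k, size, n_samples, byrow = TRUE) +
        b * lg[rows, ]
      block_genes[[k]] <- genes[rows]
      idx <- idx + size
    }
    expr <- 2^(lg + 5)
    dimnames(expr) <- list(genes, sprintf("B%04d", seq_len(n_samples)))
    list(expr = expr, blocks = block_genes)
  })
}

#' Simulate a GMT gene-set collection with planted overlaps
#'
#' @param universe Character vector of gene symbols.
#' @param n_sets Number of sets.
#' @param set_size Genes per set.
#' @param planted Optional character vector; when given, the first set is
#'   seeded with these genes (guaranteed overlap for enrichment tests).
#' @param seed Integer seed.
#' @return A [gene_set_collection()].
#' @export
simulate_gene_sets <- function(universe, n_sets = 20, set_size = 50,
                               planted = NULL, seed = 1L) {
  with_local_seed(seed, {
    sets <- lapply(seq_len(n_sets), function(i) sample(universe, min(set_size, length(universe))))
    names(sets) <- sprintf("SET_%02d", seq_len(n_sets))
    if (!is.null(planted)) {
      sets[[1]] <- unique(c(planted, sets[[1]]))[seq_len(min(set_size + length(planted), length(universe)))]
      names(sets)[1] <- "SET_PLANTED"
    }
    gene_set_collection(sets, universe_size = length(universe), name = "simulated")
  })
}
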