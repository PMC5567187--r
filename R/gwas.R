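# The double-hit model: filter annotated GWAS summary statistics, test the
# overlap of GWAS genes with differentially methylated genes, and emit the
# candidate table (genes carrying both a deleterious associated coding SNP
# and a significant methylation change).

snp_required_cols <- c(
  "rsid", "chromosome", "position", "gwas_p", "func_class",
  "consequence", "cadd", "gene_symbol"
)

check_snp_table <- function(snps) {
  snps <- tibble::as_tibble(snps)
  miss <- setdiff(snp_required_cols, names(snps))
  if (length(miss)) stop("SNP table missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  bad <- !is.na(snps$consequence) & snps$consequence != "none" &
    !(snps$func_class %in% c("exonic", "splicing"))
  if (any(bad)) {
    stop("consequence must be 'none' outside exonic/splicing rows", call. = FALSE)
  }
  snps
}

#' Retain nominally associated SNPs and their genes
#'
#' Keeps SNPs with unadjusted association p strictly below `p_threshold`,
#' drops any SNP mapped to a blacklisted ("spurious") gene, and returns the
#' retained rows together with the unique mapped gene symbols.
#'
#' @param snps SNP summary-statistics tibble (columns `rsid`, `chromosome`,
#'   `position`, `gwas_p`, `func_class`, `consequence`, `cadd`,
#'   `gene_symbol`).
#' @param p_threshold Association threshold (strict <, default 0.05).
#' @param blacklist Character vector of gene symbols to drop.
#' @return A list: `snps` (retained rows) and `genes` (unique symbols).
#' @export
filter_gwas <- function(snps, p_threshold = 0.05, blacklist = character()) {
  snps <- check_snp_table(snps)
  keep <- snps$gwas_p < p_threshold & !(snps$gene_symbol %in% blacklist)
  out <- snps[keep, ]
  list(snps = out, genes = unique(out$gene_symbol))
}

#' Double-hit overlap test
#'
#' Single hypergeometric upper-tail test of the overlap between the GWAS
#' gene set (size K) and the differentially methylated gene set (size N)
#' against a background of M genes.
#'
#' @param gwas_genes,dmp_genes Nonempty character vectors of gene symbols.
#' @param M Background universe size (e.g. the annotated genome gene
#'   count); must cover the union of both sets.
#' @return A one-row `enrichment_result` tibble (`M`, `K`, `N`, `x`, `p`,
#'   `overlap_genes`).
#' @export
double_hit_overlap <- function(gwas_genes, dmp_genes, M) {
  gwas_genes <- unique(toupper(gwas_genes))
  dmp_genes <- unique(toupper(dmp_genes))
  if (length(gwas_genes) == 0 || length(dmp_genes) == 0) {
    stop("both gene sets must be nonempty", call. = FALSE)
  }
  if (M < length(union(gwas_genes, dmp_genes))) {
    stop("background M smaller than the union of the gene sets", call. = FALSE)
  }
  ov <- intersect(gwas_genes, dmp_genes)
  out <- tibble::tibble(
    set = "double_hit",
    M = as.integer(M), K = length(gwas_genes), N = length(dmp_genes),
    x = length(ov),
    p = hypergeom_upper_tail(M, length(gwas_genes), length(dmp_genes), length(ov)),
    p_bh = NA_real_,
    overlap_genes = list(ov)
  )
  class(out) <- c("enrichment_result", class(out))
  out
}

# internal: tolerate either a dmp_result or a fixture-style records tibble
as_dmp_records <- function(dmp) {
  if (inherits(dmp, "dmp_result")) {
    rec <- dmp$records
    tibble::tibble(
      probe_id = rec$probe_id,
      gene_symbol = rec$gene_symbol,
      p_bh = rec$p_bh,
      t_stat = rec$t_stat,
      region = rec$island_relation %||% NA_character_
    )
  } else {
    rec <- tibble::as_tibble(dmp)
    if ("dmp_p_bh" %in% names(rec)) rec <- dplyr::rename(rec, p_bh = "dmp_p_bh")
    if ("island_relation" %in% names(rec) && !"region" %in% names(rec)) {
      rec$region <- rec$island_relation
    }
    if (!"region" %in% names(rec)) rec$region <- NA_character_
    rec[, intersect(c("probe_id", "gene_symbol", "p_bh", "t_stat", "region"), names(rec))]
  }
}

#' Candidate-gene filter (the double-hit refinement)
#'
#' A SNP row survives iff its association p is strictly below
#' `p_threshold`, it lies in an exonic or splicing region with a
#' nonsynonymous or stopgain consequence, its CADD deleteriousness score is
#' strictly above `cadd_threshold`, and its mapped gene has at least one
#' probe significantly differentially methylated (adjusted p below
#' `alpha`). One output row per retained SNP, joined with the gene's most
#' significant probe; the gene set partitions by the probe t sign into
#' hyper- and hypomethylated candidates. `min_p_for_gene` is the minimum
#' association p over the *unfiltered* SNP table for the gene (intronic and
#' intergenic SNPs included).
#'
#' @param snps SNP summary-statistics tibble (see [filter_gwas()]).
#' @param dmp A `dmp_result` or a records tibble with `gene_symbol`,
#'   `probe_id`, `p_bh` (or `dmp_p_bh`) and `t_stat`.
#' @param cadd_threshold CADD cut-off (strict >, default 15).
#' @param p_threshold Association cut-off (strict <, default 0.05).
#' @param alpha Methylation significance cut-off on adjusted p (default
#'   0.05).
#' @return A `candidate_table` tibble, one row per retained SNP: gene,
#'   SNP fields, `min_p_for_gene`, best probe fields (`probe_id`,
#'   `dmp_p_bh`, `region`, `t_stat`), and `direction`.
#' @export
candidate_filter <- function(snps, dmp, cadd_threshold = 15,
                             p_threshold = 0.05, alpha = 0.05) {
  snps <- check_snp_table(snps)
  rec <- as_dmp_records(dmp)
  # per-gene best (most significant) probe among the gene's probes
  rec_long <- tidyr::separate_rows(rec, "gene_symbol", sep = ";")
  rec_long <- rec_long[!is.na(rec_long$gene_symbol) & rec_long$gene_symbol != "", ]
  best <- dplyr::slice_min(dplyr::group_by(rec_long, .data$gene_symbol),
    order_by = .data$p_bh, n = 1, with_ties = FALSE
  )
  best <- dplyr::ungroup(best)

  min_p <- dplyr::summarise(dplyr::group_by(snps, .data$gene_symbol),
    min_p_for_gene = min(.data$gwas_p),
    .groups = "drop"
  )

  keep <- snps$gwas_p < p_threshold &
    snps$func_class %in% c("exonic", "splicing") &
    snps$consequence %in% c("nonsynonymous", "stopgain") &
    !is.na(snps$cadd) & snps$cadd > cadd_threshold
  out <- snps[keep, ]
  known <- out$gene_symbol %in% best$gene_symbol
  if (any(!known)) {
    warning(
      sum(!known), " SNP(s) dropped: gene absent from the methylation results (",
      paste(utils::head(unique(out$gene_symbol[!known]), 5), collapse = ", "), ")",
      call. = FALSE
    )
    out <- out[known, ]
  }
  out <- dplyr::left_join(out,
    best[, c("gene_symbol", "probe_id", "p_bh", "region", "t_stat")],
    by = "gene_symbol", suffix = c("", ".dmp")
  )
  out <- dplyr::rename(out, dmp_p_bh = "p_bh", dmp_t_stat = "t_stat")
  out <- out[!is.na(out$dmp_p_bh) & out$dmp_p_bh < alpha, ]
  if ("min_p_for_gene" %in% names(snps)) {
    # supplied column (e.g. the worked-example table, whose full SNP list
    # is not available) takes precedence over the within-table minimum
    out$min_p_for_gene <- snps$min_p_for_gene[match(out$rsid, snps$rsid)]
  } else {
    out <- dplyr::left_join(out, min_p, by = "gene_symbol")
  }
  out$direction <- ifelse(out$dmp_t_stat > 0, "hyper", "hypo")
  out <- out[order(out$direction == "hyper", out$gwas_p), ]
  class(out) <- c("candidate_table", class(out))
  out
}

#' @method glance candidate_table
#' @export
glance.candidate_table <- function(x, ...) {
  genes <- unique(x$gene_symbol)
  dir <- x$direction[match(genes, x$gene_symbol)]
  tibble::tibble(
    n_snps = nrow(x),
    n_genes = length(genes),
    n_hyper_genes = sum(dir == "hyper"),
    n_hypo_genes = sum(dir == "hypo")
  )
}

#' SNP / methylation-probe colocalization
#'
#' Reports SNPs whose genomic position falls within a probe's CpG target
#' interval (the probe position and the following base, i.e. the 2-bp CpG
#' site, widened by `window` on both sides). Chromosome naming conventions
#' ("chr1" vs "1") are normalised before matching; coordinates are assumed
#' 1-based on a shared genome build.
#'
#' @param snps SNP tibble with `chromosome` and `position`.
#' @param probe_annotation Probe tibble with `probe_id`, `chromosome`,
#'   `position`.
#' @param window Extra bases on each side of the CpG site (default 0).
#' @return A tibble of colocalized pairs: `rsid`, `probe_id`,
#'   `chromosome`, `snp_position`, `probe_position`.
#' @export
probe_snp_colocalization <- function(snps, probe_annotation, window = 0) {
  snps <- tibble::as_tibble(snps)
  ann <- tibble::as_tibble(probe_annotation)
  empty <- tibble::tibble(
    rsid = character(), probe_id = character(), chromosome = character(),
    snp_position = integer(), probe_position = integer()
  )
  if (nrow(snps) == 0 || nrow(ann) == 0) {
    return(empty)
  }
  norm_chr <- function(x) sub("^chr", "", tolower(as.character(x)))
  s <- tibble::tibble(
    rsid = snps$rsid, chromosome = norm_chr(snps$chromosome),
    snp_position = snps$position
  )
  p <- tibble::tibble(
    probe_id = ann$probe_id, chromosome = norm_chr(ann$chromosome),
    probe_position = ann$position
  )
  hits <- dplyr::inner_join(s, p, by = "chromosome", relationship = "many-to-many")
  hits <- hits[hits$snp_position >= hits$probe_position - window &
    hits$snp_position <= hits$probe_position + 1 + window, ]
  if (nrow(hits) == 0) {
    return(empty)
  }
  hits$chromosome <- paste0("chr", hits$chromosome)
  hits[, c("rsid", "probe_id", "chromosome", "snp_position", "probe_position")]
}

#' Map SNPs to the nearest gene from a gene model
#'
#' Lightweight positional mapper for synthetic data: assigns each SNP the
#' symbol of the nearest gene whose interval (extended by `window`)
#' contains or is closest to the SNP. Gene models use BED-style 0-based
#' half-open intervals and are converted internally to the 1-based
#' convention.
#'
#' @param snps SNP tibble with `chromosome`, `position`.
#' @param genes Tibble with `chromosome`, `start` (0-based), `end`,
#'   `gene_symbol`.
#' @param window Maximum distance for assignment; farther SNPs get `NA`.
#' @return `snps` with a (re)filled `gene_symbol` column.
#' @export
map_snps_to_genes <- function(snps, genes, window = 10000) {
  snps <- tibble::as_tibble(snps)
  genes <- tibble::as_tibble(genes)
  norm_chr <- function(x) sub("^chr", "", tolower(as.character(x)))
  gs <- split(genes, norm_chr(genes$chromosome))
  sym <- vapply(seq_len(nrow(snps)), function(i) {
    g <- gs[[norm_chr(snps$chromosome[i])]]
    if (is.null(g) || nrow(g) == 0) {
      return(NA_character_)
    }
    pos <- snps$position[i]
    start1 <- g$start + 1L
    d <- pmax(start1 - pos, pos - g$end, 0L)
    j <- which.min(d)
    if (d[j] > window) NA_character_ else g$gene_symbol[j]
  }, character(1))
  snps$gene_symbol <- sym
  snps
}
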