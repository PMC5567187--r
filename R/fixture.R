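#' Bundled candidate-gene worked example
#'
#' Loads the packaged worked-example tables: 30 risk SNPs over 26 genes with
#' deleterious coding variants, and the matching differentially methylated
#' probe per gene, transcribed from the candidate table of a published
#' blood-methylation / GWAS integration study of FTD-ALS. Optionally the
#' synthetic distractor rows are appended; each distractor violates exactly
#' one candidate-filter criterion (named in `distractor_reason`), so the
#' filter's predicates can be exercised one at a time. Genomic coordinates
#' in these tables are synthetic placeholders (see the file headers).
#'
#' @param distractors Logical; include the flagged distractor rows.
#' @return A list with two tibbles, `snps` (SNP records: `gene_symbol`,
#'   `chromosome`, `strand`, `rsid`, `gwas_p`, `func_class`, `consequence`,
#'   `cadd`, `min_p_for_gene`, `position`, `distractor_reason`) and `dmps`
#'   (one probe per gene: `probe_id`, `dmp_p_bh`, `island_relation`,
#'   `t_stat`, `degree`, `pathway_overlap`, `validated`, plus coordinates).
#' @export
table1_fixture <- function(distractors = FALSE) {
  snp_path <- system.file("extdata", "candidate_snps_table.tsv", package = "doublehit")
  dmp_path <- system.file("extdata", "candidate_dmps_table.tsv", package = "doublehit")
  snps <- readr::read_tsv(snp_path,
    comment = "#", show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      gwas_p = "d", cadd = "d", min_p_for_gene = "d", position = "i",
      .default = "c"
    )
  )
  dmps <- readr::read_tsv(dmp_path,
    comment = "#", show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      dmp_p_bh = "d", t_stat = "d", position = "i", degree = "i",
      pathway_overlap = "l", validated = "l", .default = "c"
    )
  )
  if (!distractors) {
    snps <- snps[is.na(snps$distractor_reason), ]
    dmps <- dmps[is.na(dmps$distractor_reason), ]
  }
  list(snps = snps, dmps = dmps)
}
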