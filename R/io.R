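# TSV readers/writers for the remaining tabular interfaces. All files are
# plain TSV with a header; gene/probe identifiers in the first column.

#' Read / write a probe-annotation table
#'
#' Columns: `probe_id`, `chromosome`, `position` (1-based), `gene_symbol`
#' (possibly empty or ";"-separated), `region_class`, `island_relation`,
#' `snp_maf`, `control_probe`, `blacklist`.
#'
#' @param path TSV path.
#' @return A tibble ([read_probe_annotation()]); `path` invisibly
#'   ([write_probe_annotation()]).
#' @export
read_probe_annotation <- function(path) {
  readr::read_tsv(path,
    show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      position = "i", snp_maf = "d", control_probe = "l", blacklist = "l",
      .default = "c"
    )
  )
}

#' @param x Annotation tibble.
#' @rdname read_probe_annotation
#' @export
write_probe_annotation <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x), path, progress = FALSE)
  invisible(path)
}

#' Read / write a genes-by-samples expression matrix
#'
#' TSV with a `gene_symbol` first column and one column per sample;
#' optional companion label file (columns `sample_id` and a label column
#' such as `tissue` or `class`).
#'
#' @param path Expression TSV path.
#' @return A numeric matrix with gene rownames.
#' @export
read_expression_matrix <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(d[-1])
  rownames(m) <- d[[1]]
  m
}

#' @param x Genes x samples numeric matrix.
#' @rdname read_expression_matrix
#' @export
write_expression_matrix <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x, rownames = "gene_symbol"), path,
    progress = FALSE
  )
  invisible(path)
}

#' Read / write a GWAS summary-statistics table
#'
#' Columns as in [filter_gwas()]: `rsid`, `chromosome`, `position`,
#' `gwas_p`, `func_class`, `consequence`, `cadd`, `gene_symbol`.
#'
#' @param path TSV path.
#' @return A validated tibble of SNP records.
#' @export
read_gwas_table <- function(path) {
  check_snp_table(readr::read_tsv(path,
    show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      position = "i", gwas_p = "d", cadd = "d", .default = "c"
    )
  ))
}

#' @param x SNP tibble.
#' @rdname read_gwas_table
#' @export
write_gwas_table <- function(x, path) {
  readr::write_tsv(check_snp_table(x), path, progress = FALSE)
  invisible(path)
}
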