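# Small in-code fixtures shared across test files.

tiny_beta <- function(values, groups = NULL, batches = NULL, normalized = FALSE) {
  n <- ncol(values)
  if (is.null(rownames(values))) rownames(values) <- sprintf("cg%03d", seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- sprintf("S%02d", seq_len(n))
  beta_matrix(
    values,
    tibble::tibble(
      sample_id = colnames(values),
      group = groups %||% rep("control", n),
      batch = batches %||% rep("batch1", n)
    ),
    normalized = normalized
  )
}

tiny_annotation <- function(probe_ids, gene = NULL) {
  n <- length(probe_ids)
  tibble::tibble(
    probe_id = probe_ids,
    chromosome = rep("chr1", n),
    position = seq_len(n) * 1000L,
    gene_symbol = gene %||% sprintf("GENE%03d", seq_len(n)),
    region_class = rep("Body", n),
    island_relation = rep("open_sea", n),
    snp_maf = rep(NA_real_, n),
    control_probe = rep(FALSE, n),
    blacklist = rep(FALSE, n)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
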