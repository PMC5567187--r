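# Per-probe case/control differential methylation with BH control,
# direction calls from the t sign, and gene-level reporting.

#' Pooled-variance Student t-test per probe
#'
#' Vectorised two-sample Student t over the rows of a matrix: pooled
#' variance, df = n_a + n_b - 2, two-sided p from the t distribution.
#' Degenerate probes with zero pooled variance get t = 0, p = 1 when the
#' group means agree, and p equal to the smallest representable positive
#' value (flagged) when they differ.
#'
#' @param x Numeric matrix (probes x samples), no missing values.
#' @param idx_a,idx_b Column indices (or names) of the two groups, each of
#'   size >= 2.
#' @param welch Use Welch's unequal-variance form instead of the pooled
#'   form.
#' @return A tibble: `t_stat`, `df`, `p`, `mean_a`, `mean_b`, `degenerate`.
#' @export
student_t_per_probe <- function(x, idx_a, idx_b, welch = FALSE) {
  stopifnot(is.matrix(x))
  if (anyNA(x)) stop("missing values present; impute first", call. = FALSE)
  a <- x[, idx_a, drop = FALSE]
  b <- x[, idx_b, drop = FALSE]
  na <- ncol(a)
  nb <- ncol(b)
  if (na < 2 || nb < 2) stop("each group needs >= 2 samples", call. = FALSE)
  ma <- rowMeans(a)
  mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  if (welch) {
    se2 <- va / na + vb / nb
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se2 <- sp2 * (1 / na + 1 / nb)
    df <- rep(na + nb - 2, nrow(x))
  }
  tt <- (ma - mb) / sqrt(se2)
  p <- 2 * stats::pt(-abs(tt), df)
  zero_var <- se2 <= 0 | !is.finite(se2)
  eq <- zero_var & (ma == mb)
  ne <- zero_var & (ma != mb)
  tt[eq] <- 0
  p[eq] <- 1
  df[zero_var & !is.finite(df)] <- na + nb - 2
  tt[ne] <- sign(ma[ne] - mb[ne]) * Inf
  p[ne] <- .Machine$double.xmin
  tibble::tibble(
    probe_id = rownames(x) %||% as.character(seq_len(nrow(x))),
    t_stat = unname(tt), df = unname(df), p = unname(p),
    mean_a = unname(ma), mean_b = unname(mb),
    degenerate = unname(ne)
  )
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment. Input p-values must lie in
#' (0, 1].
#'
#' @param p Numeric vector of raw p-values.
#' @return Adjusted p-values in input order, each >= its raw p, capped at 1.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p) | p <= 0 | p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Genome-wide differential methylation call
#'
#' Runs the per-probe pooled t-test for a named contrast, BH-adjusts across
#' all tested probes, annotates gene symbols and CpG context, and calls the
#' direction from the t sign (on the zero-mean scale, hypermethylation is a
#' positive case-minus-control difference).
#'
#' @param m A zero-mean normalised [beta_matrix()].
#' @param annotation Probe-annotation tibble covering the probes of `m`.
#' @param contrast One of `"FTD_vs_control"` (all cases vs controls),
#'   `"FTDALS_vs_control"`, or `"control_vs_external"` (requires groups
#'   `control` and `external_control` in the metadata).
#' @param alpha BH significance threshold (default 0.05).
#' @param welch Forwarded to [student_t_per_probe()].
#' @return A `dmp_result`: list with `records` (tibble, one row per probe:
#'   t, p, p_bh, direction, gene symbols, region and island annotation),
#'   `n_tests`, `alpha`, `contrast`, and the derived `significant_probes`
#'   and `significant_genes` (one gene entry per annotated symbol, so gene
#'   counts can exceed probe counts).
#' @export
call_dmps <- function(m, annotation, contrast = c(
                        "FTDALS_vs_control",
                        "FTD_vs_control",
                        "control_vs_external"
                      ),
                      alpha = 0.05, welch = FALSE) {
  stopifnot(inherits(m, "beta_matrix"))
  contrast <- match.arg(contrast)
  groups <- switch(contrast,
    FTD_vs_control = list(a = c("case_FTD", "case_FTDALS"), b = "control"),
    FTDALS_vs_control = list(a = "case_FTDALS", b = "control"),
    control_vs_external = list(a = "control", b = "external_control")
  )
  sa <- group_samples(m, groups$a)
  sb <- group_samples(m, groups$b)
  if (length(sa) == 0 || length(sb) == 0) {
    stop("empty contrast group for ", contrast, call. = FALSE)
  }
  tt <- student_t_per_probe(m$values, sa, sb, welch = welch)
  tt$p_bh <- bh_adjust(tt$p)
  ann <- tibble::as_tibble(annotation)
  ann <- ann[match(tt$probe_id, ann$probe_id), c("probe_id", "gene_symbol", "region_class", "island_relation")]
  records <- dplyr::left_join(tt, ann, by = "probe_id")
  records$direction <- ifelse(records$t_stat > 0, "hyper", "hypo")
  records <- dplyr::rename(records, case_mean = "mean_a", control_mean = "mean_b")

  sig <- records[records$p_bh < alpha & records$t_stat != 0, ]
  sig_genes <- unique(unlist(strsplit(sig$gene_symbol, ";", fixed = TRUE)))
  sig_genes <- sig_genes[!is.na(sig_genes) & sig_genes != ""]
  structure(
    list(
      records = records,
      n_tests = nrow(records),
      alpha = alpha,
      contrast = contrast,
      significant_probes = sig$probe_id,
      significant_genes = sig_genes
    ),
    class = "dmp_result"
  )
}

#' @export
print.dmp_result <- function(x, ...) {
  cat(sprintf(
    "<dmp_result> %s: %d probes tested, %d significant (P_BH < %g) over %d genes\n",
    x$contrast, x$n_tests, length(x$significant_probes), x$alpha,
    length(x$significant_genes)
  ))
  invisible(x)
}

#' Tidy a differential-methylation result
#'
#' @param x A `dmp_result`.
#' @param ... Unused.
#' @return The per-probe records tibble.
#' @method tidy dmp_result
#' @export
tidy.dmp_result <- function(x, ...) x$records

#' One-line summary of a differential-methylation result
#'
#' @param x A `dmp_result`.
#' @param ... Unused.
#' @return A one-row tibble: contrast, probes tested, significant probe and
#'   gene counts, hyper/hypo split.
#' @method glance dmp_result
#' @export
glance.dmp_result <- function(x, ...) {
  sig <- x$records[x$records$probe_id %in% x$significant_probes, ]
  tibble::tibble(
    contrast = x$contrast,
    n_tests = x$n_tests,
    alpha = x$alpha,
    n_significant_probes = length(x$significant_probes),
    n_significant_genes = length(x$significant_genes),
    n_hyper = sum(sig$direction == "hyper"),
    n_hypo = sum(sig$direction == "hypo")
  )
}

#' Volcano-style plot of a differential-methylation result
#'
#' @param object A `dmp_result`.
#' @param ... Unused.
#' @return A ggplot object: case-minus-control difference vs -log10 p,
#'   significant probes coloured by direction.
#' @method autoplot dmp_result
#' @export
autoplot.dmp_result <- function(object, ...) {
  d <- object$records
  d$status <- ifelse(d$probe_id %in% object$significant_probes, d$direction, "ns")
  ggplot2::ggplot(
    d,
    ggplot2::aes(
      x = .data$case_mean - .data$control_mean,
      y = -log10(.data$p), colour = .data$status
    )
  ) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(hyper = "#b2182b", hypo = "#2166ac", ns = "grey70")) +
    ggplot2::labs(
      x = "case - control (relative beta)", y = "-log10 P",
      colour = NULL, title = object$contrast
    ) +
    ggplot2::theme_minimal()
}

#' Per-gene probe report
#'
#' Looks up all probes annotated to the requested genes within an existing
#' genome-wide result; no re-correction is performed, the reported adjusted
#' p-values are those of the genome-wide call. Genes absent from the
#' annotation are listed with zero probes and a warning.
#'
#' @param result A `dmp_result`.
#' @param genes Character vector of gene symbols.
#' @return A tibble, one row per (gene, probe): region class, t, p, p_bh,
#'   direction.
#' @export
gene_probe_report <- function(result, genes) {
  stopifnot(inherits(result, "dmp_result"))
  rec <- result$records
  out <- lapply(genes, function(g) {
    hit <- vapply(
      strsplit(rec$gene_symbol, ";", fixed = TRUE),
      function(s) g %in% s, logical(1)
    )
    if (!any(hit)) {
      warning("gene ", g, " has no probes in the result", call. = FALSE)
      return(tibble::tibble(
        gene = g, probe_id = character(), region_class = character(),
        island_relation = character(), t_stat = numeric(), p = numeric(),
        p_bh = numeric(), direction = character()
      ))
    }
    d <- rec[hit, c("probe_id", "region_class", "island_relation", "t_stat", "p", "p_bh", "direction")]
    dplyr::bind_cols(tibble::tibble(gene = g), d)
  })
  dplyr::bind_rows(out)
}

#' Group-mean summary per significant gene
#'
#' Reduces the per-gene group profiles to three numeric columns: the mean
#' relative methylation of FTD-ALS cases, FTD cases and controls over each
#' gene's significant probes.
#'
#' @param result A `dmp_result`.
#' @param m The zero-mean [beta_matrix()] the result was computed from.
#' @return A tibble: gene, mean_FTDALS, mean_FTD, mean_control, direction.
#' @export
gene_group_means <- function(result, m) {
  stopifnot(inherits(result, "dmp_result"), inherits(m, "beta_matrix"))
  sig <- result$records[result$records$probe_id %in% result$significant_probes, ]
  if (nrow(sig) == 0) {
    return(tibble::tibble(
      gene = character(), mean_FTDALS = numeric(),
      mean_FTD = numeric(), mean_control = numeric(), direction = character()
    ))
  }
  long <- tidyr::separate_rows(sig, "gene_symbol", sep = ";")
  long <- long[long$gene_symbol != "", ]
  grp_mean <- function(probes, grp) {
    cols <- group_samples(m, grp)
    if (length(cols) == 0) {
      return(NA_real_)
    }
    mean(m$values[probes, cols, drop = FALSE])
  }
  out <- dplyr::group_by(long, .data$gene_symbol)
  out <- dplyr::summarise(out,
    mean_FTDALS = grp_mean(.data$probe_id, "case_FTDALS"),
    mean_FTD = grp_mean(.data$probe_id, "case_FTD"),
    mean_control = grp_mean(.data$probe_id, "control"),
    direction = .data$direction[which.max(abs(.data$t_stat))],
    .groups = "drop"
  )
  dplyr::rename(out, gene = "gene_symbol")
}
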