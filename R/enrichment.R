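# Gene-set machinery: specificity-set construction from a tissue atlas,
# hypergeometric overrepresentation with per-call BH correction, and GMT IO.

#' A named collection of gene sets with an explicit universe size
#'
#' The universe size M is a property of the resource the sets came from
#' (e.g. the gene count of an expression atlas or of a genome annotation)
#' and is always supplied explicitly, never inferred silently.
#'
#' @param sets Named list of character vectors (gene symbols; stored
#'   uppercase, deduplicated).
#' @param universe_size Background gene count M (must cover the union of
#'   the sets).
#' @param name Collection label.
#' @param min_set_size Sets smaller than this are dropped.
#' @param universe_genes Optional explicit background gene list; when
#'   present, queries are restricted to it before testing.
#' @return A `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, universe_size, name = "collection",
                                min_set_size = 1, universe_genes = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)), universe_size >= 1)
  sets <- lapply(sets, function(g) unique(toupper(g)))
  sets <- sets[lengths(sets) >= min_set_size]
  union_n <- length(unique(unlist(sets)))
  if (universe_size < union_n) {
    stop("universe_size (", universe_size, ") smaller than the union of the sets (", union_n, ")", call. = FALSE)
  }
  if (!is.null(universe_genes)) {
    universe_genes <- unique(toupper(universe_genes))
    if (length(universe_genes) != universe_size) {
      stop("universe_genes length must equal universe_size", call. = FALSE)
    }
  }
  structure(
    list(
      name = name, sets = sets, universe_size = as.integer(universe_size),
      universe_genes = universe_genes
    ),
    class = "gene_set_collection"
  )
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf(
    "<gene_set_collection> '%s': %d sets, universe M = %d\n",
    x$name, length(x$sets), x$universe_size
  ))
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Read / write gene sets in GMT format
#'
#' Tab-separated lines: set name, description, then member genes.
#'
#' @param path GMT file path.
#' @param universe_size Background size M for the resulting collection.
#' @param name Collection label (default: the file name).
#' @return [read_gmt()] returns a [gene_set_collection()]; [write_gmt()]
#'   returns `path` invisibly.
#' @export
read_gmt <- function(path, universe_size, name = basename(path)) {
  sets <- fgsea::gmtPathways(path)
  gene_set_collection(sets, universe_size = universe_size, name = name)
}

#' @param x A `gene_set_collection`.
#' @rdname read_gmt
#' @export
write_gmt <- function(x, path) {
  stopifnot(inherits(x, "gene_set_collection"))
  lines <- vapply(names(x$sets), function(nm) {
    paste(c(nm, "na", x$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Build tissue-specificity gene sets from an expression atlas
#'
#' For each tissue, every gene is tested tissue-vs-rest with the pooled
#' Student t-test on the linear-scale expression values; p-values are
#' BH-corrected across genes within the tissue. A gene enters the tissue's
#' set when its adjusted p is at most `alpha` and its fold difference
#' (within-tissue mean over remaining-sample mean) is strictly above
#' `fold_threshold` or strictly below its reciprocal. The universe M is the
#' atlas gene count.
#'
#' @param expr Genes x samples matrix of nonnegative linear-scale
#'   expression.
#' @param tissue Tissue label per sample (>= 2 tissues, >= 2 samples each).
#' @param fold_threshold Fold-difference threshold (strict, default 1.5).
#' @param alpha BH-adjusted p threshold (inclusive, default 0.05).
#' @param min_set_size Sets smaller than this are dropped.
#' @return A [gene_set_collection()] of per-tissue specificity sets.
#' @export
build_specificity_sets <- function(expr, tissue, fold_threshold = 1.5,
                                   alpha = 0.05, min_set_size = 1) {
  stopifnot(is.matrix(expr), length(tissue) == ncol(expr), fold_threshold > 1)
  if (any(expr < 0)) {
    stop("expression must be nonnegative linear-scale values", call. = FALSE)
  }
  tissues <- unique(tissue)
  if (length(tissues) < 2) stop("need >= 2 tissues", call. = FALSE)
  if (any(table(tissue) < 2)) stop("need >= 2 samples per tissue", call. = FALSE)
  sets <- lapply(tissues, function(tt) {
    inside <- which(tissue == tt)
    outside <- which(tissue != tt)
    tst <- student_t_per_probe(expr, inside, outside)
    p_bh <- bh_adjust(tst$p)
    fd <- tst$mean_a / tst$mean_b
    keep <- p_bh <= alpha & (fd > fold_threshold | fd < 1 / fold_threshold)
    rownames(expr)[keep]
  })
  names(sets) <- tissues
  gene_set_collection(sets,
    universe_size = nrow(expr), universe_genes = rownames(expr),
    name = "tissue_specificity", min_set_size = min_set_size
  )
}

#' Hypergeometric upper-tail probability
#'
#' Exact `P(X >= x)` for `X ~ Hypergeometric(M, K, N)`: the chance of an
#' overlap of at least x between a size-N query and a size-K set both drawn
#' from a size-M universe. Computed in log space via [stats::phyper()].
#'
#' @param M Universe size.
#' @param K Set size.
#' @param N Query size.
#' @param x Observed overlap, `0 <= x <= min(K, N) <= M`.
#' @return The upper-tail probability; 1 when `x = 0`.
#' @export
hypergeom_upper_tail <- function(M, K, N, x) {
  if (any(c(M, K, N, x) < 0) || K > M || N > M || x > min(K, N)) {
    stop("inconsistent counts: need 0 <= x <= min(K, N) <= M", call. = FALSE)
  }
  stats::phyper(x - 1, K, M - K, N, lower.tail = FALSE)
}

#' Overrepresentation of a gene list in a set collection
#'
#' One hypergeometric upper-tail test per set; BH correction spans exactly
#' the sets tested in this call (the per-resource correction scope). The
#' query is deduplicated, uppercased, and — since sets are defined against
#' the collection's universe — its size N is the query length after that
#' normalisation.
#'
#' @param query Character vector of gene symbols.
#' @param collection A [gene_set_collection()].
#' @return An `enrichment_result` tibble, one row per set, sorted by
#'   adjusted p: `set`, `M`, `K`, `N`, `x`, `p`, `p_bh`, `overlap_genes`
#'   (list column).
#' @export
enrich <- function(query, collection) {
  stopifnot(inherits(collection, "gene_set_collection"))
  query <- unique(toupper(query))
  if (length(query) == 0) stop("empty query", call. = FALSE)
  if (!is.null(collection$universe_genes)) {
    inside <- intersect(query, collection$universe_genes)
    if (length(inside) == 0) {
      stop("query has no genes in the collection's universe", call. = FALSE)
    }
    if (length(inside) < length(query)) {
      message(
        length(query) - length(inside),
        " query gene(s) outside the universe dropped before testing"
      )
    }
    query <- inside
  }
  M <- collection$universe_size
  N <- length(query)
  if (N > M) stop("query larger than the universe", call. = FALSE)
  rows <- purrr::imap(collection$sets, function(genes, nm) {
    ov <- intersect(query, genes)
    tibble::tibble(
      set = nm, M = M, K = length(genes), N = N, x = length(ov),
      p = hypergeom_upper_tail(M, length(genes), N, length(ov)),
      overlap_genes = list(ov)
    )
  })
  out <- dplyr::bind_rows(rows)
  out$p_bh <- bh_adjust(out$p)
  out <- out[order(out$p_bh, out$p), c("set", "M", "K", "N", "x", "p", "p_bh", "overlap_genes")]
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Bar plot of an enrichment result
#'
#' @param object An `enrichment_result`.
#' @param alpha Significance line drawn at this adjusted-p level.
#' @param ... Unused.
#' @return A ggplot object of -log10 adjusted p per set.
#' @method autoplot enrichment_result
#' @export
autoplot.enrichment_result <- function(object, alpha = 0.05, ...) {
  d <- tibble::as_tibble(object)
  d$set <- factor(d$set, levels = rev(d$set))
  ggplot2::ggplot(d, ggplot2::aes(x = -log10(.data$p_bh), y = .data$set)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::geom_vline(xintercept = -log10(alpha), linetype = 2) +
    ggplot2::labs(x = "-log10 adjusted P", y = NULL) +
    ggplot2::theme_minimal()
}

#' Keyword pre-selection of gene sets
#'
#' Retains the sets whose names match any keyword, case-insensitive
#' substring match (used to restrict a pathway resource a priori to e.g.
#' brain or neurological function).
#'
#' @param collection A [gene_set_collection()].
#' @param keywords Nonempty character vector of keywords.
#' @return A filtered [gene_set_collection()] (same universe). Empty
#'   matches give an empty collection with a warning.
#' @export
filter_brain_sets <- function(collection, keywords) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (length(keywords) == 0) stop("keyword list must be nonempty", call. = FALSE)
  nm <- names(collection$sets)
  hit <- Reduce(`|`, lapply(keywords, function(k) grepl(k, nm, ignore.case = TRUE)))
  if (!any(hit)) warning("no set name matches any keyword", call. = FALSE)
  out <- collection
  out$sets <- collection$sets[hit]
  out$name <- paste0(collection$name, "_filtered")
  out
}
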