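# Thresholded Spearman co-expression network over candidate genes, with
# degree-based prioritisation.

#' Pairwise Spearman correlation matrix with p-values
#'
#' Rank-based correlation (average ranks for ties) between all gene pairs,
#' with two-sided p-values from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))`. Constant genes have undefined
#' correlation and are dropped with a warning.
#'
#' @param expr Genes x samples numeric matrix (>= 5 samples).
#' @param genes Optional gene subset; symbols absent from `expr` are
#'   dropped with a message (the retained intersection is used).
#' @return A list: `rho` and `p` (square matrices, `NA` diagonal), and
#'   `n` (sample count).
#' @export
spearman_matrix <- function(expr, genes = NULL) {
  stopifnot(is.matrix(expr))
  if (!is.null(genes)) {
    inside <- intersect(genes, rownames(expr))
    if (length(inside) < length(genes)) {
      message(
        length(genes) - length(inside),
        " gene(s) absent from the expression data; ", length(inside), " retained"
      )
    }
    expr <- expr[inside, , drop = FALSE]
  }
  n <- ncol(expr)
  if (n < 5) stop("need >= 5 samples", call. = FALSE)
  const <- apply(expr, 1, function(r) stats::var(r) == 0)
  if (any(const)) {
    warning(
      sum(const), " constant gene(s) dropped: ",
      paste(utils::head(rownames(expr)[const], 5), collapse = ", "),
      call. = FALSE
    )
    expr <- expr[!const, , drop = FALSE]
  }
  if (nrow(expr) < 2) stop("fewer than 2 usable genes", call. = FALSE)
  rho <- stats::cor(t(expr), method = "spearman")
  tt <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  p[abs(rho) >= 1] <- 0
  diag(rho) <- NA_real_
  diag(p) <- NA_real_
  list(rho = rho, p = p, n = n)
}

#' Build a thresholded co-expression network
#'
#' An edge joins two genes iff the absolute Spearman correlation is
#' strictly above `r_min` and the unadjusted pairwise p is strictly below
#' `p_max`. Isolated genes are removed unless `keep_isolated`. Optional
#' per-gene attributes (methylation direction, CADD, SNP flag) are joined
#' onto the nodes.
#'
#' @param cors Output of [spearman_matrix()] (or a list with `rho`, `p`).
#' @param r_min Absolute-correlation threshold (strict >, default 0.6).
#' @param p_max P-value threshold (strict <, default 0.001).
#' @param node_attrs Optional tibble keyed by `gene_symbol` (e.g. columns
#'   `direction`, `cadd`, `has_snp`).
#' @param keep_isolated Keep genes without edges (default FALSE).
#' @return A `coexpr_network`: list with `nodes` (tibble `gene_symbol`,
#'   `degree`, any joined attributes) and `edges` (tibble `gene_a`,
#'   `gene_b`, `rho`, `p`, `sign`), plus the thresholds.
#' @export
build_network <- function(cors, r_min = 0.6, p_max = 0.001,
                          node_attrs = NULL, keep_isolated = FALSE) {
  rho <- cors$rho
  p <- cors$p
  stopifnot(is.matrix(rho), all(dim(rho) == dim(p)))
  genes <- rownames(rho)
  idx <- which(upper.tri(rho) & abs(rho) > r_min & p < p_max, arr.ind = TRUE)
  rho_e <- rho[idx]
  edges <- tibble::tibble(
    gene_a = genes[idx[, 1]],
    gene_b = genes[idx[, 2]],
    rho = rho_e,
    p = p[idx],
    sign = ifelse(rho_e > 0, "positive", "negative")
  )
  # deterministic order irrespective of gene input order
  swap <- edges$gene_a > edges$gene_b
  tmp <- edges$gene_a[swap]
  edges$gene_a[swap] <- edges$gene_b[swap]
  edges$gene_b[swap] <- tmp
  edges <- edges[order(edges$gene_a, edges$gene_b), ]
  deg <- table(factor(c(edges$gene_a, edges$gene_b), levels = sort(genes)))
  nodes <- tibble::tibble(
    gene_symbol = names(deg),
    degree = as.integer(deg)
  )
  if (!keep_isolated) nodes <- nodes[nodes$degree > 0, ]
  if (!is.null(node_attrs)) {
    nodes <- dplyr::left_join(nodes, tibble::as_tibble(node_attrs), by = "gene_symbol")
  }
  structure(
    list(nodes = nodes, edges = edges, r_min = r_min, p_max = p_max),
    class = "coexpr_network"
  )
}

#' @export
print.coexpr_network <- function(x, ...) {
  cat(sprintf(
    "<coexpr_network> %d genes, %d edges (|rho| > %g, p < %g)\n",
    nrow(x$nodes), nrow(x$edges), x$r_min, x$p_max
  ))
  invisible(x)
}

#' Tidy the edge list of a co-expression network
#'
#' @param x A `coexpr_network`.
#' @param ... Unused.
#' @return The edge tibble.
#' @method tidy coexpr_network
#' @export
tidy.coexpr_network <- function(x, ...) x$edges

#' @method glance coexpr_network
#' @export
glance.coexpr_network <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    r_min = x$r_min,
    p_max = x$p_max
  )
}

#' Rank network genes by degree
#'
#' Sorts genes by decreasing edge count (ties broken alphabetically); the
#' reported degree is cross-checked against an independent incident-edge
#' count and the handshake identity.
#'
#' @param net A `coexpr_network`.
#' @return The node tibble sorted by degree.
#' @export
degree_prioritize <- function(net) {
  stopifnot(inherits(net, "coexpr_network"))
  recount <- vapply(net$nodes$gene_symbol, function(g) {
    sum(net$edges$gene_a == g) + sum(net$edges$gene_b == g)
  }, integer(1))
  if (!identical(unname(recount), net$nodes$degree)) {
    stop("internal degree bookkeeping mismatch", call. = FALSE)
  }
  net$nodes[order(-net$nodes$degree, net$nodes$gene_symbol), ]
}

#' Convert a co-expression network to igraph
#'
#' @param net A `coexpr_network`.
#' @return An [igraph::graph_from_data_frame()] undirected graph carrying
#'   the edge (`rho`, `p`, `sign`) and node attributes.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "coexpr_network"))
  igraph::graph_from_data_frame(net$edges,
    directed = FALSE,
    vertices = net$nodes
  )
}

#' Export a network as edge-list TSV and GraphML
#'
#' @param net A `coexpr_network`.
#' @param edges_path TSV path for the edge list.
#' @param graphml_path Optional GraphML path (written via igraph).
#' @return `net`, invisibly.
#' @export
write_network <- function(net, edges_path, graphml_path = NULL) {
  stopifnot(inherits(net, "coexpr_network"))
  readr::write_tsv(net$edges, edges_path, progress = FALSE)
  if (!is.null(graphml_path)) {
    igraph::write_graph(as_igraph(net), graphml_path, format = "graphml")
  }
  invisible(net)
}

#' Plot a co-expression network
#'
#' Fruchterman-Reingold layout; edge colour encodes the correlation sign,
#' node colour the methylation direction when present.
#'
#' @param object A `coexpr_network`.
#' @param seed Layout seed.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot coexpr_network
#' @export
autoplot.coexpr_network <- function(object, seed = 1L, ...) {
  g <- as_igraph(object)
  xy <- with_local_seed(seed, igraph::layout_with_fr(g))
  nd <- object$nodes
  nd$x <- xy[, 1]
  nd$y <- xy[, 2]
  ed <- object$edges
  ed$x <- nd$x[match(ed$gene_a, nd$gene_symbol)]
  ed$y <- nd$y[match(ed$gene_a, nd$gene_symbol)]
  ed$xend <- nd$x[match(ed$gene_b, nd$gene_symbol)]
  ed$yend <- nd$y[match(ed$gene_b, nd$gene_symbol)]
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = ed,
      ggplot2::aes(
        x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend,
        colour = .data$sign, linewidth = abs(.data$rho)
      ),
      alpha = 0.6
    ) +
    ggplot2::scale_colour_manual(values = c(positive = "#b2182b", negative = "#2166ac")) +
    ggplot2::scale_linewidth(range = c(0.2, 1.2), guide = "none")
  if ("direction" %in% names(nd)) {
    p <- p + ggplot2::geom_point(
      data = nd,
      ggplot2::aes(x = .data$x, y = .data$y, fill = .data$direction),
      shape = 21, size = 3
    )
  } else {
    p <- p + ggplot2::geom_point(data = nd, ggplot2::aes(x = .data$x, y = .data$y), size = 3)
  }
  p + ggplot2::theme_void()
}
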