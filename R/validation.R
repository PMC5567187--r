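# Expression-based validation: per-dataset differential expression with
# empirical-Bayes variance moderation, per-dataset BH correction, overlap of
# the methylation-derived genes with the DE genes, Fisher
# overrepresentation, and cross-dataset ranking.

#' Bundle an expression validation data set
#'
#' @param expr Genes x samples numeric matrix (log-scale expression).
#'   Rownames are uppercase gene symbols; duplicates are collapsed to the
#'   highest-variance row.
#' @param labels Per-sample class, `"case"` or `"control"` (>= 2 each).
#' @param name Data-set label.
#' @param platform_probe_count Number of probes assayed on the platform;
#'   used as the BH divisor (defaults to the gene count).
#' @return A `validation_set`.
#' @export
validation_set <- function(expr, labels, name,
                           platform_probe_count = nrow(expr)) {
  stopifnot(is.matrix(expr), length(labels) == ncol(expr))
  if (!all(labels %in% c("case", "control"))) {
    stop("labels must be 'case' or 'control'", call. = FALSE)
  }
  if (sum(labels == "case") < 2 || sum(labels == "control") < 2) {
    stop("need >= 2 samples per class", call. = FALSE)
  }
  rownames(expr) <- toupper(rownames(expr))
  if (anyDuplicated(rownames(expr))) {
    v <- apply(expr, 1, stats::var)
    ord <- order(rownames(expr), -v)
    expr <- expr[ord, , drop = FALSE]
    expr <- expr[!duplicated(rownames(expr)), , drop = FALSE]
  }
  structure(
    list(
      expr = expr, labels = labels, name = name,
      platform_probe_count = as.integer(max(platform_probe_count, nrow(expr)))
    ),
    class = "validation_set"
  )
}

# internal: solve trigamma(y) = x by Newton iteration (x > 0)
trigamma_inverse <- function(x) {
  vapply(x, function(xi) {
    if (!is.finite(xi) || xi <= 0) {
      return(Inf)
    }
    if (xi > 1e7) {
      return(1 / sqrt(xi))
    }
    if (xi < 1e-6) {
      return(1 / xi)
    }
    y <- 0.5 + 1 / xi
    for (i in 1:50) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, 2)
      y <- y + dif
      if (abs(dif) / y < 1e-8) break
    }
    y
  }, numeric(1))
}

#' Moderated two-sample t-statistics
#'
#' Per-gene linear contrast with empirical-Bayes variance moderation: each
#' gene's pooled variance `s2_g` (df `d_g = n - 2`) is shrunk toward a
#' common prior `s0^2` with prior df `d0`,
#' `s2_tilde = (d0 * s0^2 + d_g * s2_g) / (d0 + d_g)`, and the moderated t
#' uses `d0 + d_g` degrees of freedom. The hyperparameters `(d0, s0^2)` are
#' estimated by method of moments on the log sample variances (matching the
#' scaled-F marginal of the hierarchical model). When the observed
#' variances are too homogeneous to estimate a finite `d0`, the `d0 = Inf`
#' limit is used (all variances shrunk to `s0^2`) with a message.
#'
#' @param expr Genes x samples matrix (no missing values).
#' @param labels `"case"`/`"control"` per sample.
#' @param d0 Optional prior df override: `0` gives the ordinary t test,
#'   `Inf` full pooling.
#' @return A tibble: `gene`, `log_fc` (case minus control), `t_mod`,
#'   `df_total`, `p`, plus the estimates `d0` and `s0_sq` as attributes.
#' @export
moderated_t <- function(expr, labels, d0 = NULL) {
  stopifnot(is.matrix(expr), length(labels) == ncol(expr))
  idx_a <- which(labels == "case")
  idx_b <- which(labels == "control")
  if (length(idx_a) < 2 || length(idx_b) < 2) {
    stop("need >= 2 samples per class", call. = FALSE)
  }
  na <- length(idx_a)
  nb <- length(idx_b)
  dg <- na + nb - 2
  ma <- rowMeans(expr[, idx_a, drop = FALSE])
  mb <- rowMeans(expr[, idx_b, drop = FALSE])
  s2 <- (rowSums((expr[, idx_a, drop = FALSE] - ma)^2) +
    rowSums((expr[, idx_b, drop = FALSE] - mb)^2)) / dg

  ok <- s2 > 0
  if (is.null(d0)) {
    # method of moments on z = log s2: E z = log s0^2 + digamma(dg/2) -
    # log(dg/2) - (digamma(d0/2) - log(d0/2)); Var z = trigamma(dg/2) +
    # trigamma(d0/2)
    z <- log(s2[ok])
    if (length(z) < 2) {
      d0 <- Inf
      s0_sq <- mean(s2[ok])
    } else {
      excess <- stats::var(z) - trigamma(dg / 2)
      if (excess <= 0) {
        message("variances too homogeneous; using the d0 = Inf limit")
        d0 <- Inf
        s0_sq <- exp(mean(z) - digamma(dg / 2) + log(dg / 2))
      } else {
        d0 <- 2 * trigamma_inverse(excess)
        s0_sq <- exp(mean(z) - digamma(dg / 2) + log(dg / 2) +
          digamma(d0 / 2) - log(d0 / 2))
      }
    }
  } else {
    s0_sq <- if (is.finite(d0) && d0 == 0) NA_real_ else exp(mean(log(s2[ok])))
  }

  if (is.infinite(d0)) {
    s2_tilde <- rep(s0_sq, length(s2))
    df_total <- rep(Inf, length(s2))
  } else if (d0 == 0) {
    s2_tilde <- s2
    df_total <- rep(dg, length(s2))
  } else {
    s2_tilde <- (d0 * s0_sq + dg * s2) / (d0 + dg)
    df_total <- rep(d0 + dg, length(s2))
  }
  se <- sqrt(s2_tilde * (1 / na + 1 / nb))
  tt <- (ma - mb) / se
  p <- 2 * stats::pt(-abs(tt), df = pmin(df_total, 1e6))
  out <- tibble::tibble(
    gene = rownames(expr) %||% as.character(seq_along(tt)),
    log_fc = unname(ma - mb), t_mod = unname(tt),
    df_total = unname(df_total), p = unname(p)
  )
  attr(out, "d0") <- d0
  attr(out, "s0_sq") <- s0_sq
  out
}

#' Fisher exact overrepresentation test
#'
#' Two-sided Fisher exact test on the 2x2 table query/not x DE/not over the
#' platform gene universe.
#'
#' @param query_genes Genes of interest (restricted to the platform).
#' @param de_genes Differentially expressed genes on the platform.
#' @param platform_genes The platform universe (nonempty).
#' @return The two-sided p-value.
#' @export
fisher_overrepresentation <- function(query_genes, de_genes, platform_genes) {
  platform_genes <- unique(toupper(platform_genes))
  if (length(platform_genes) == 0) stop("empty platform universe", call. = FALSE)
  query_genes <- intersect(unique(toupper(query_genes)), platform_genes)
  de_genes <- intersect(unique(toupper(de_genes)), platform_genes)
  in_q <- platform_genes %in% query_genes
  in_d <- platform_genes %in% de_genes
  tab <- table(
    factor(in_q, levels = c(TRUE, FALSE)),
    factor(in_d, levels = c(TRUE, FALSE))
  )
  stats::fisher.test(tab)$p.value
}

#' Validate query genes across expression data sets
#'
#' Per data set: moderated-t differential expression, BH correction over
#' the set's own platform probe count, and the DE gene set at adjusted
#' p < `alpha`. A query gene is validated by a set iff it is DE there;
#' genes not assayed on a platform are counted as not-assayed, distinct
#' from not-DE. Genes are ranked by the number of validating sets, ties by
#' their best adjusted p.
#'
#' @param query_genes Character vector (e.g. significant DMP genes).
#' @param sets List of [validation_set()]s.
#' @param alpha DE significance threshold on adjusted p (default 0.05).
#' @param require_direction If `TRUE`, a hyper-methylated query gene only
#'   validates when down-regulated (and vice versa); needs a `direction`
#'   attribute column in `query_genes` names — supply a named character
#'   vector gene -> "hyper"/"hypo".
#' @return A `validation_outcome`: list with `grid` (tibble gene x set of
#'   "validated"/"not_de"/"not_assayed"), `ranking` (tibble `gene`,
#'   `n_sets_validated`, `best_p_bh`), `de_sets` (named list of per-set DE
#'   genes), `fisher_p` (named vector), and `n_validated`.
#' @export
validate_genes <- function(query_genes, sets, alpha = 0.05,
                           require_direction = FALSE) {
  if (length(sets) == 0) stop("need >= 1 validation set", call. = FALSE)
  direction <- NULL
  if (require_direction) {
    if (is.null(names(query_genes))) {
      stop("require_direction needs a named vector gene -> direction", call. = FALSE)
    }
    direction <- stats::setNames(unname(query_genes), toupper(names(query_genes)))
    query_genes <- names(query_genes)
  }
  query_genes <- unique(toupper(query_genes))
  set_names <- vapply(sets, function(s) s$name, character(1))

  per_set <- lapply(sets, function(s) {
    de <- moderated_t(s$expr, s$labels)
    de$p_bh <- stats::p.adjust(de$p, method = "BH", n = s$platform_probe_count)
    de
  })
  de_sets <- lapply(per_set, function(d) d$gene[d$p_bh < alpha])
  names(de_sets) <- set_names

  status <- sapply(seq_along(sets), function(i) {
    d <- per_set[[i]]
    st <- rep("not_assayed", length(query_genes))
    assayed <- query_genes %in% d$gene
    st[assayed] <- "not_de"
    ok <- query_genes %in% de_sets[[i]]
    if (require_direction) {
      fc <- d$log_fc[match(query_genes, d$gene)]
      dirn <- direction[query_genes]
      concord <- (dirn == "hyper" & fc < 0) | (dirn == "hypo" & fc > 0)
      ok <- ok & !is.na(concord) & concord
    }
    st[ok] <- "validated"
    st
  })
  status <- matrix(status, nrow = length(query_genes), dimnames = list(query_genes, set_names))

  best_p <- sapply(seq_along(sets), function(i) {
    per_set[[i]]$p_bh[match(query_genes, per_set[[i]]$gene)]
  })
  best_p <- matrix(best_p, nrow = length(query_genes))
  best_p[status != "validated"] <- NA_real_
  n_val_sets <- rowSums(status == "validated")
  ranking <- tibble::tibble(
    gene = query_genes,
    n_sets_validated = as.integer(n_val_sets),
    best_p_bh = suppressWarnings(apply(best_p, 1, min, na.rm = TRUE))
  )
  ranking$best_p_bh[!is.finite(ranking$best_p_bh)] <- NA_real_
  ranking <- ranking[order(-ranking$n_sets_validated, ranking$best_p_bh, ranking$gene), ]

  fisher_p <- vapply(seq_along(sets), function(i) {
    fisher_overrepresentation(query_genes, de_sets[[i]], rownames(sets[[i]]$expr))
  }, numeric(1))
  names(fisher_p) <- set_names

  grid <- tibble::as_tibble(status, rownames = "gene")
  structure(
    list(
      grid = grid, ranking = ranking, de_sets = de_sets,
      fisher_p = fisher_p,
      n_validated = sum(n_val_sets >= 1),
      alpha = alpha
    ),
    class = "validation_outcome"
  )
}

#' @export
print.validation_outcome <- function(x, ...) {
  cat(sprintf(
    "<validation_outcome> %d of %d query genes validated in >= 1 of %d sets\n",
    x$n_validated, nrow(x$ranking), length(x$de_sets)
  ))
  invisible(x)
}

#' @method tidy validation_outcome
#' @export
tidy.validation_outcome <- function(x, ...) x$ranking

#' @method glance validation_outcome
#' @export
glance.validation_outcome <- function(x, ...) {
  tibble::tibble(
    n_query = nrow(x$ranking),
    n_validated = x$n_validated,
    n_sets = length(x$de_sets),
    n_sets_with_de = sum(lengths(x$de_sets) > 0)
  )
}

#' Validation-grid plot
#'
#' Genes x data sets tile plot; validated cells shaded.
#'
#' @param object A `validation_outcome`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot validation_outcome
#' @export
autoplot.validation_outcome <- function(object, ...) {
  keep <- object$ranking$gene[object$ranking$n_sets_validated > 0]
  d <- tidyr::pivot_longer(object$grid, -"gene",
    names_to = "set", values_to = "status"
  )
  d <- d[d$gene %in% keep, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$set, y = .data$gene, fill = .data$status)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_manual(values = c(
      validated = "grey40", not_de = "grey90", not_assayed = "white"
    )) +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}
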