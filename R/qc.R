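# Preprocessing cascade for beta-value matrices. Pipeline order is fixed:
# combat_adjust -> filter_probes -> knn_impute -> zero_mean_normalize.

#' Parametric empirical-Bayes batch adjustment
#'
#' Removes additive and multiplicative per-batch, per-probe effects from a
#' beta-value matrix. Each probe is standardised against the pooled
#' batch-mean model; batch location and scale effects are estimated per
#' probe, shrunk toward batch-level priors (normal prior on location,
#' inverse-gamma on scale, hyperparameters by method of moments, posterior
#' solved iteratively), and the matrix is back-transformed. Missing cells
#' are tolerated: all moments use the available cells, and missing cells
#' stay missing. With a single batch the input is returned unchanged.
#'
#' @param m A [beta_matrix()] (or plain numeric matrix, probes x samples).
#' @param batch Batch labels per sample; defaults to `sample_meta$batch`
#'   when `m` is a `beta_matrix`.
#' @param tol,max_iter Convergence control for the posterior iteration.
#' @return Same type as `m`, dimensions unchanged. Values may leave
#'   \[0, 1\] slightly; they are clipped back when `m` is a raw-scale
#'   `beta_matrix`.
#' @export
combat_adjust <- function(m, batch = NULL, tol = 1e-8, max_iter = 100L) {
  is_bm <- inherits(m, "beta_matrix")
  x <- if (is_bm) m$values else m
  if (is_bm && is.null(batch)) batch <- m$sample_meta$batch
  stopifnot(is.matrix(x), length(batch) == ncol(x))
  batch <- factor(batch)
  if (nlevels(batch) < 2) {
    return(m)
  }
  counts <- table(batch)
  if (any(counts < 2)) {
    stop("batch(es) with fewer than 2 samples: ",
      paste(names(counts)[counts < 2], collapse = ", "),
      call. = FALSE
    )
  }

  obs <- !is.na(x)
  n_probe <- nrow(x)
  levs <- levels(batch)
  nb <- length(levs)

  # per-probe, per-batch observed means and counts
  bm <- sapply(levs, function(b) rowMeans(x[, batch == b, drop = FALSE], na.rm = TRUE))
  bn <- sapply(levs, function(b) rowSums(obs[, batch == b, drop = FALSE]))
  if (any(rowSums(bn) == 0)) stop("probe(s) with no observed values", call. = FALSE)
  n_obs <- rowSums(bn)

  # pooled model: grand mean weighted by batch sizes; residual variance
  w <- bn / n_obs
  grand <- rowSums(w * bm, na.rm = TRUE)
  fitted <- bm[, as.integer(batch), drop = FALSE]
  resid <- x - fitted
  var_pooled <- rowSums(resid^2, na.rm = TRUE) / n_obs
  const <- var_pooled <= .Machine$double.eps
  sd_pooled <- sqrt(var_pooled)
  sd_pooled[const] <- 1 # location-only fallback for constant probes
  if (any(const)) {
    message(sum(const), " constant probe(s): scale shrinkage skipped, location-only adjustment")
  }

  z <- (x - grand) / sd_pooled
  out <- z
  for (bi in seq_len(nb)) {
    cols <- which(batch == levs[bi])
    zb <- z[, cols, drop = FALSE]
    nobs_b <- rowSums(!is.na(zb))
    gamma_hat <- rowMeans(zb, na.rm = TRUE)
    delta_hat <- apply(zb, 1, stats::var, na.rm = TRUE)
    delta_hat[is.na(delta_hat) | delta_hat <= 0] <- 0

    gamma_bar <- mean(gamma_hat, na.rm = TRUE)
    t2 <- stats::var(gamma_hat, na.rm = TRUE)
    if (!is.finite(t2)) t2 <- 0
    m_d <- mean(delta_hat, na.rm = TRUE)
    s2_d <- stats::var(delta_hat, na.rm = TRUE)
    if (!is.finite(s2_d) || s2_d <= .Machine$double.eps) {
      # degenerate scale spread (e.g. noise-free data): no scale shrinkage
      a_prior <- NA_real_
      b_prior <- NA_real_
    } else {
      a_prior <- (2 * s2_d + m_d^2) / s2_d
      b_prior <- (m_d * s2_d + m_d^3) / s2_d
    }

    gamma_star <- gamma_hat
    delta_star <- pmax(delta_hat, 1)
    if (is.na(a_prior)) {
      # location-only EB: shrink gamma with delta fixed at its estimate (or 1)
      d_use <- ifelse(delta_hat > 0, delta_hat, 1)
      gamma_star <- (t2 * nobs_b * gamma_hat + d_use * gamma_bar) /
        (t2 * nobs_b + d_use)
      delta_star <- rep(1, n_probe)
    } else {
      g_old <- gamma_hat
      d_old <- delta_hat
      d_old[d_old <= 0] <- m_d
      for (it in seq_len(max_iter)) {
        g_new <- (t2 * nobs_b * gamma_hat + d_old * gamma_bar) /
          (t2 * nobs_b + d_old)
        sum2 <- rowSums((zb - g_new)^2, na.rm = TRUE)
        d_new <- (0.5 * sum2 + b_prior) / (nobs_b / 2 + a_prior - 1)
        change <- max(abs(g_new - g_old) / pmax(abs(g_old), 1e-12),
          abs(d_new - d_old) / pmax(abs(d_old), 1e-12),
          na.rm = TRUE
        )
        g_old <- g_new
        d_old <- d_new
        if (change < tol) break
      }
      gamma_star <- g_old
      delta_star <- pmax(d_old, .Machine$double.eps)
    }
    out[, cols] <- (zb - gamma_star) / sqrt(delta_star)
  }
  adj <- out * sd_pooled + grand
  adj[!obs] <- NA_real_
  if (is_bm) {
    if (!m$normalized) adj <- pmin(pmax(adj, 0), 1)
    m$values <- adj
    m
  } else {
    adj
  }
}

#' Probe filter cascade
#'
#' Applies the standard 450K probe filters in a fixed order, each probe
#' charged to the first rule it fails: (1) more than `missing` fraction of
#' missing values; (2) located on chromosome X or Y; (3) annotated SNP with
#' MAF strictly above `maf`; (4) control probe; (5) blacklisted ("spurious")
#' probe; (6) gene-region class outside the retained vocabulary (TSS1500,
#' TSS200, 5UTR, 1stExon, Body, 3UTR). Boundary cases (exactly 20% missing,
#' MAF exactly 0.1) are retained.
#'
#' @param m A [beta_matrix()].
#' @param annotation Probe-annotation tibble covering every probe of `m`
#'   (columns `probe_id`, `chromosome`, `gene_symbol`, `region_class`,
#'   `snp_maf`, `control_probe`, `blacklist`).
#' @param missing Missingness threshold (strict >, default 0.20).
#' @param maf MAF threshold (strict >, default 0.10).
#' @param keep_regions Gene-region classes retained.
#' @return A list: `beta` (filtered `beta_matrix`) and `report`, a
#'   `filter_report` with one row per rule (probes removed) plus the
#'   retained probe and gene counts. Removed + retained always equals the
#'   input probe count.
#' @export
filter_probes <- function(m, annotation, missing = 0.20, maf = 0.10,
                          keep_regions = c(
                            "TSS1500", "TSS200", "5UTR",
                            "1stExon", "Body", "3UTR"
                          )) {
  stopifnot(inherits(m, "beta_matrix"))
  annotation <- tibble::as_tibble(annotation)
  probes <- rownames(m$values)
  if (!all(probes %in% annotation$probe_id)) {
    stop("annotation does not cover all probes", call. = FALSE)
  }
  ann <- annotation[match(probes, annotation$probe_id), ]
  known <- c(keep_regions, "intergenic", "other", "")
  unknown <- setdiff(unique(ann$region_class), known)
  if (length(unknown)) {
    stop(
      "unknown region_class value(s) ", paste(unknown, collapse = ", "),
      " for probes: ",
      paste(utils::head(ann$probe_id[ann$region_class %in% unknown], 5), collapse = ", "),
      call. = FALSE
    )
  }

  frac_missing <- rowMeans(is.na(m$values))
  fails <- list(
    missingness = frac_missing > missing,
    chrXY = ann$chromosome %in% c("chrX", "chrY", "X", "Y"),
    snp_maf = !is.na(ann$snp_maf) & ann$snp_maf > maf,
    control_probe = ann$control_probe,
    blacklist = ann$blacklist,
    region = !(ann$region_class %in% keep_regions)
  )
  # first failing rule wins
  assigned <- rep(NA_character_, length(probes))
  for (rule in names(fails)) {
    hit <- fails[[rule]] & is.na(assigned)
    assigned[hit] <- rule
  }
  keep <- is.na(assigned)
  removed <- vapply(names(fails), function(r) sum(assigned == r, na.rm = TRUE), integer(1))

  kept <- subset_beta(m, probes = probes[keep])
  genes <- unique(unlist(strsplit(ann$gene_symbol[keep], ";", fixed = TRUE)))
  genes <- genes[!is.na(genes) & genes != ""]
  report <- structure(
    list(
      rules = tibble::tibble(rule = names(removed), removed = unname(removed)),
      probes_in = length(probes),
      probes_retained = sum(keep),
      genes_retained = length(genes)
    ),
    class = "filter_report"
  )
  list(beta = kept, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report>", x$probes_in, "probes in,", x$probes_retained,
    "retained over", x$genes_retained, "genes\n"
  )
  for (i in seq_len(nrow(x$rules))) {
    cat(sprintf("  %-14s removed %d\n", x$rules$rule[i], x$rules$removed[i]))
  }
  invisible(x)
}

#' @method tidy filter_report
#' @export
tidy.filter_report <- function(x, ...) x$rules

#' Serialise a filter report to JSON
#'
#' @param x A `filter_report`.
#' @param path File to write.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(x, path) {
  stopifnot(inherits(x, "filter_report"))
  jsonlite::write_json(
    list(
      removed = as.list(stats::setNames(x$rules$removed, x$rules$rule)),
      probes_in = x$probes_in,
      probes_retained = x$probes_retained,
      genes_retained = x$genes_retained
    ),
    path,
    auto_unbox = TRUE
  )
  invisible(path)
}

# internal: overlap-normalised distance between probe p and all probe rows:
# root-mean-square difference over samples observed in both
probe_rms_dist <- function(x, p) {
  obs <- !is.na(x)
  diffs <- sweep(x, 2, x[p, ], `-`)
  shared <- obs %*% obs[p, ] # counts of co-observed samples per probe
  ss <- rowSums(diffs^2, na.rm = TRUE)
  d <- sqrt(ss / pmax(shared[, 1], 1))
  d[shared[, 1] == 0] <- Inf
  d
}

#' K-nearest-neighbour imputation of missing beta values
#'
#' For each missing cell (probe p, sample s), the k probes nearest to p are
#' found by overlap-normalised Euclidean distance (root-mean-square
#' difference over samples observed in both probes, so distances are
#' comparable across overlap sizes), restricted to probes observed at s; the
#' imputed value is the unweighted mean of those k neighbours' values at s.
#' When no neighbour is observed at s, the probe's own mean is used (with a
#' message). Observed cells are never touched.
#'
#' @param m A [beta_matrix()] (or plain matrix, probes x samples).
#' @param k Number of neighbours (default 3).
#' @return Same type as `m`, complete (no missing cells).
#' @export
knn_impute <- function(m, k = 3) {
  is_bm <- inherits(m, "beta_matrix")
  x <- if (is_bm) m$values else m
  stopifnot(is.matrix(x), k >= 1)
  if (!anyNA(x)) {
    return(m)
  }
  if (any(rowSums(!is.na(x)) == 0)) {
    stop("probe(s) entirely missing cannot be imputed", call. = FALSE)
  }
  probe_means <- rowMeans(x, na.rm = TRUE)
  out <- x
  todo <- which(rowSums(is.na(x)) > 0)
  fallback <- 0L
  for (p in todo) {
    d <- probe_rms_dist(x, p)
    d[p] <- Inf
    miss_s <- which(is.na(x[p, ]))
    ord <- order(d)
    for (s in miss_s) {
      cand <- ord[!is.na(x[ord, s]) & is.finite(d[ord])]
      if (length(cand) == 0) {
        out[p, s] <- probe_means[p]
        fallback <- fallback + 1L
      } else {
        nn <- cand[seq_len(min(k, length(cand)))]
        out[p, s] <- mean(x[nn, s])
      }
    }
  }
  if (fallback > 0) {
    message(fallback, " cell(s) imputed with the probe mean (no observed neighbour)")
  }
  if (is_bm) {
    m$values <- out
    m
  } else {
    out
  }
}

#' Zero-mean normalisation per probe
#'
#' Centres every probe row at mean zero across all samples (cases and
#' controls together), the relative scale on which hypermethylation sits
#' above 0 and hypomethylation below 0. Idempotent.
#'
#' @param m A [beta_matrix()] (or plain matrix) with no missing values.
#' @return Same type as `m`; a `beta_matrix` is flagged `normalized`.
#' @export
zero_mean_normalize <- function(m) {
  is_bm <- inherits(m, "beta_matrix")
  x <- if (is_bm) m$values else m
  stopifnot(is.matrix(x))
  if (anyNA(x)) stop("missing values present; impute before normalising", call. = FALSE)
  x <- x - rowMeans(x)
  if (is_bm) {
    m$values <- x
    m$normalized <- TRUE
    m
  } else {
    x
  }
}

#' Run the full preprocessing cascade
#'
#' Fixed order: batch adjustment, probe filtering, KNN imputation, zero-mean
#' normalisation.
#'
#' @param m A [beta_matrix()].
#' @param annotation Probe-annotation tibble (see [filter_probes()]).
#' @param missing,maf,knn_k Thresholds forwarded to the stages.
#' @return A list: `beta` (processed `beta_matrix`, zero-mean scale) and
#'   `report` (the [filter_probes()] report).
#' @export
preprocess_beta <- function(m, annotation, missing = 0.20, maf = 0.10, knn_k = 3) {
  adj <- combat_adjust(m)
  flt <- filter_probes(adj, annotation, missing = missing, maf = maf)
  imp <- knn_impute(flt$beta, k = knn_k)
  list(beta = zero_mean_normalize(imp), report = flt$report)
}
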