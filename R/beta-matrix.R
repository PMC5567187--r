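#' Construct a beta-value matrix with sample metadata
#'
#' The central methylation container: a probes x samples numeric matrix of
#' beta values (methylated fraction, in \[0, 1\] until zero-mean
#' normalisation makes values relative) plus a per-sample metadata tibble
#' carrying the diagnostic group and processing batch.
#'
#' @param values Numeric matrix, probes in rows, samples in columns. Row and
#'   column names are the probe and sample identifiers and must be unique.
#' @param sample_meta Data frame with columns `sample_id`, `group`
#'   (one of `"case_FTD"`, `"case_FTDALS"`, `"control"`) and `batch`.
#'   Row order must cover exactly the columns of `values`.
#' @param normalized Logical; `TRUE` once values are on the zero-mean
#'   relative scale (no longer constrained to \[0, 1\]).
#'
#' @return An object of class `beta_matrix`: a list with elements `values`,
#'   `sample_meta` (tibble) and `normalized`.
#' @export
beta_matrix <- function(values, sample_meta, normalized = FALSE) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have probe rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) stop("duplicate probe ids", call. = FALSE)
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids", call. = FALSE)
  sample_meta <- tibble::as_tibble(sample_meta)
  req <- c("sample_id", "group", "batch")
  if (!all(req %in% names(sample_meta))) {
    stop("`sample_meta` needs columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (!setequal(sample_meta$sample_id, colnames(values)) ||
      nrow(sample_meta) != ncol(values)) {
    stop("`sample_meta$sample_id` must match the columns of `values`", call. = FALSE)
  }
  sample_meta <- sample_meta[match(colnames(values), sample_meta$sample_id), ]
  if (!normalized) {
    rng <- range(values, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 1) {
      stop("raw beta values must lie in [0, 1]", call. = FALSE)
    }
  }
  structure(
    list(values = values, sample_meta = sample_meta, normalized = normalized),
    class = "beta_matrix"
  )
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf(
    "<beta_matrix> %d probes x %d samples (%s scale)\n",
    nrow(x$values), ncol(x$values),
    if (x$normalized) "zero-mean relative" else "raw beta"
  ))
  grp <- table(x$sample_meta$group)
  cat("  groups: ", paste(names(grp), grp, sep = "=", collapse = ", "), "\n", sep = "")
  cat("  batches:", paste(sort(unique(x$sample_meta$batch)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.beta_matrix <- function(x) dim(x$values)

#' Convert a beta matrix to a long tibble
#'
#' One row per (probe, sample) cell, joined with the sample metadata; the
#' tidy view used by the plotting helpers.
#'
#' @param x A [beta_matrix()].
#' @param ... Unused.
#' @return A tibble with columns `probe_id`, `sample_id`, `beta`, `group`,
#'   `batch`.
#' @method tidy beta_matrix
#' @export
tidy.beta_matrix <- function(x, ...) {
  out <- tibble::as_tibble(x$values, rownames = "probe_id")
  out <- tidyr::pivot_longer(out, -"probe_id",
    names_to = "sample_id", values_to = "beta"
  )
  dplyr::left_join(out, x$sample_meta, by = "sample_id")
}

#' Read / write a beta matrix as TSV
#'
#' The on-disk format is a TSV with a `probe_id` first column and one column
#' per sample, plus a sample-metadata TSV (`sample_id`, `group`, `batch`).
#'
#' @param values_path Path of the probes x samples TSV.
#' @param meta_path Path of the sample metadata TSV.
#' @param normalized Passed to [beta_matrix()].
#' @return [read_beta_matrix()] returns a `beta_matrix`;
#'   [write_beta_matrix()] returns the input invisibly.
#' @export
read_beta_matrix <- function(values_path, meta_path, normalized = FALSE) {
  vals <- readr::read_tsv(values_path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(vals[-1])
  rownames(m) <- vals[[1]]
  meta <- readr::read_tsv(meta_path, show_col_types = FALSE, progress = FALSE)
  beta_matrix(m, meta, normalized = normalized)
}

#' @param x A `beta_matrix`.
#' @rdname read_beta_matrix
#' @export
write_beta_matrix <- function(x, values_path, meta_path) {
  stopifnot(inherits(x, "beta_matrix"))
  out <- tibble::as_tibble(x$values, rownames = "probe_id")
  readr::write_tsv(out, values_path, progress = FALSE)
  readr::write_tsv(x$sample_meta, meta_path, progress = FALSE)
  invisible(x)
}

#' Subset a beta matrix by probes and/or samples
#'
#' @param x A [beta_matrix()].
#' @param probes,samples Character vectors of ids to keep (default: all).
#' @return A `beta_matrix`.
#' @export
subset_beta <- function(x, probes = NULL, samples = NULL) {
  stopifnot(inherits(x, "beta_matrix"))
  v <- x$values
  if (!is.null(probes)) {
    missing <- setdiff(probes, rownames(v))
    if (length(missing)) stop("unknown probes: ", paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    v <- v[probes, , drop = FALSE]
  }
  if (!is.null(samples)) v <- v[, samples, drop = FALSE]
  beta_matrix(v, x$sample_meta[x$sample_meta$sample_id %in% colnames(v), ],
    normalized = x$normalized
  )
}

# internal: columns of the samples belonging to a diagnostic group
group_samples <- function(x, group) {
  x$sample_meta$sample_id[x$sample_meta$group %in% group]
}
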