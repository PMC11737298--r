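#' Single-cell count container
#'
#' Bundles a sparse genes x cells UMI count matrix with per-cell metadata.
#' Counts must be non-negative integers; gene ids and barcodes must be unique.
#'
#' @param counts A genes x cells matrix (coerced to [Matrix::dgCMatrix]) with
#'   gene ids as rownames and cell barcodes as colnames.
#' @param cells A data frame with one row per cell: columns `barcode` and
#'   `sample` (the sample/timepoint label). If `NULL`, every cell is labelled
#'   `"sample1"`.
#' @return An object of class `sc_counts`: a list with elements `counts`
#'   (dgCMatrix) and `cells` (tibble).
#' @export
sc_counts <- function(counts, cells = NULL) {
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("`counts` must carry gene ids as rownames and barcodes as colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids in count matrix", call. = FALSE)
  if (anyDuplicated(colnames(counts))) stop("duplicate cell barcodes in count matrix", call. = FALSE)
  x <- counts@x
  if (length(x) && (any(x < 0) || any(x != round(x)))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (is.null(cells)) {
    cells <- tibble::tibble(barcode = colnames(counts), sample = "sample1")
  }
  cells <- tibble::as_tibble(cells)
  if (!all(c("barcode", "sample") %in% names(cells))) {
    stop("`cells` needs columns `barcode` and `sample`", call. = FALSE)
  }
  if (!setequal(cells$barcode, colnames(counts)) || nrow(cells) != ncol(counts)) {
    stop("`cells` must describe exactly the barcodes of `counts`", call. = FALSE)
  }
  cells <- cells[match(colnames(counts), cells$barcode), , drop = FALSE]
  if (anyNA(cells$sample)) stop("every cell needs a `sample` label", call. = FALSE)
  structure(list(counts = counts, cells = cells), class = "sc_counts")
}

#' @exportS3Method base::print
print.sc_counts <- function(x, ...) {
  cat(sprintf(
    "<sc_counts> %d genes x %d cells across %d sample(s)\n",
    nrow(x$counts), ncol(x$counts), dplyr::n_distinct(x$cells$sample)
  ))
  invisible(x)
}

#' @export
dim.sc_counts <- function(x) dim(x$counts)

#' Normalized expression container
#'
#' Holds natural-log library-size-normalized expression,
#' `ln(1 + count / total * scale_factor)`, as a sparse matrix (a zero count
#' stays exactly zero), together with the per-cell metadata of the parent
#' [sc_counts] object.
#'
#' @param values Sparse genes x cells matrix of normalized values.
#' @param cells Per-cell metadata tibble (barcode, sample).
#' @param scale_factor The scale factor used during normalization.
#' @return An object of class `sc_norm`.
#' @export
sc_norm <- function(values, cells, scale_factor) {
  stopifnot(inherits(values, "CsparseMatrix"), is.numeric(scale_factor))
  structure(
    list(values = values, cells = tibble::as_tibble(cells), scale_factor = scale_factor),
    class = "sc_norm"
  )
}

#' @exportS3Method base::print
print.sc_norm <- function(x, ...) {
  cat(sprintf(
    "<sc_norm> %d genes x %d cells (ln-normalized, scale factor %g)\n",
    nrow(x$values), ncol(x$values), x$scale_factor
  ))
  invisible(x)
}

#' @export
dim.sc_norm <- function(x) dim(x$values)

#' Gene set (signature) object
#'
#' A named collection of up-regulated and (optionally) down-regulated genes,
#' e.g. the LCE-MM signature derived from subpopulation differential
#' expression, or a KEGG-style pathway.
#'
#' @param name Character scalar naming the set.
#' @param up Character vector of up genes.
#' @param down Character vector of down genes (may be empty).
#' @return An object of class `gene_set`.
#' @export
gene_set <- function(name, up, down = character()) {
  up <- unique(as.character(up))
  down <- unique(as.character(down))
  if (length(intersect(up, down))) stop("up and down gene lists must be disjoint", call. = FALSE)
  if (!length(up) && !length(down)) stop("gene set must contain at least one gene", call. = FALSE)
  structure(list(name = as.character(name), up = up, down = down), class = "gene_set")
}

#' @exportS3Method base::print
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d up, %d down\n", x$name, length(x$up), length(x$down)))
  invisible(x)
}

#' Bulk expression cohort container
#'
#' Pairs a samples x genes expression matrix (TPM or microarray intensity
#' scale, non-negative) with per-sample clinical outcome columns.
#'
#' @param expression Numeric samples x genes matrix with sample ids as
#'   rownames and gene ids as colnames.
#' @param clinical Tibble with one row per sample: `sample_id` plus any of
#'   `os_time` (years), `os_event` (0/1), `lytic_time` (days), `lytic_event`
#'   (0/1), `lesion_category` (one of `"0"`, `"1"`, `"2"`, `">=3"`),
#'   `lesion_count`. Outcome fields may be `NA` per sample.
#' @return An object of class `bulk_cohort`.
#' @export
bulk_cohort <- function(expression, clinical) {
  expression <- as.matrix(expression)
  if (is.null(rownames(expression)) || is.null(colnames(expression))) {
    stop("`expression` needs sample rownames and gene colnames", call. = FALSE)
  }
  if (any(!is.finite(expression)) || any(expression < 0)) {
    stop("expression values must be finite and non-negative", call. = FALSE)
  }
  clinical <- tibble::as_tibble(clinical)
  if (!"sample_id" %in% names(clinical)) stop("`clinical` needs a `sample_id` column", call. = FALSE)
  if (!setequal(clinical$sample_id, rownames(expression))) {
    stop("`clinical` must describe exactly the samples of `expression`", call. = FALSE)
  }
  clinical <- clinical[match(rownames(expression), clinical$sample_id), , drop = FALSE]
  for (col in c("os_time", "lytic_time")) {
    if (col %in% names(clinical) && any(clinical[[col]] < 0, na.rm = TRUE)) {
      stop(sprintf("`%s` must be non-negative", col), call. = FALSE)
    }
  }
  for (col in c("os_event", "lytic_event")) {
    if (col %in% names(clinical) && !all(clinical[[col]] %in% c(0, 1, NA))) {
      stop(sprintf("`%s` must be 0/1", col), call. = FALSE)
    }
  }
  structure(list(expression = expression, clinical = clinical), class = "bulk_cohort")
}

#' @exportS3Method base::print
print.bulk_cohort <- function(x, ...) {
  cat(sprintf(
    "<bulk_cohort> %d samples x %d genes; clinical columns: %s\n",
    nrow(x$expression), ncol(x$expression),
    paste(setdiff(names(x$clinical), "sample_id"), collapse = ", ")
  ))
  invisible(x)
}
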