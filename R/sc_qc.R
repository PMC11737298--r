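#' Per-cell QC statistics
#'
#' @param raw An [sc_counts] object.
#' @param ann A `gene_annotation` covering every gene in `raw`.
#' @return Tibble with `barcode`, `sample`, `total_counts`, `n_genes`
#'   (genes with at least one count), `mito_frac` (share of counts on
#'   mitochondrial genes).
#' @export
qc_stats <- function(raw, ann) {
  stopifnot(inherits(raw, "sc_counts"))
  missing <- setdiff(rownames(raw$counts), ann$gene_id)
  if (length(missing)) {
    stop(
      "annotation missing ", length(missing), " gene(s), e.g. ",
      paste(utils::head(missing, 3), collapse = ", "),
      call. = FALSE
    )
  }
  mito_genes <- ann$gene_id[ann$is_mitochondrial]
  m <- raw$counts
  total <- Matrix::colSums(m)
  n_genes <- Matrix::colSums(m > 0)
  mito <- Matrix::colSums(m[rownames(m) %in% mito_genes, , drop = FALSE])
  tibble::tibble(
    barcode = colnames(m),
    sample = raw$cells$sample,
    total_counts = as.numeric(total),
    n_genes = as.integer(n_genes),
    mito_frac = as.numeric(ifelse(total > 0, mito / pmax(total, 1), 0))
  )
}

#' Filter cells on detected genes and mitochondrial fraction
#'
#' Removes cells with low RNA detection (fewer than `min_genes` detected
#' genes) or high mitochondrial content (more than `max_mito` of all reads).
#' Boundary cells — exactly `min_genes` genes or exactly `max_mito`
#' mitochondrial fraction — are retained. Genes are left untouched;
#' filtering is idempotent.
#'
#' @param raw An [sc_counts] object.
#' @param ann A `gene_annotation` covering every gene in `raw`.
#' @param min_genes Minimum detected genes to keep a cell (default 250).
#' @param max_mito Maximum mitochondrial read fraction (default 0.10).
#' @param verbose Log per-sample retention counts.
#' @return Filtered [sc_counts]; the retained QC table is attached as
#'   attribute `"qc"`.
#' @export
qc_filter <- function(raw, ann, min_genes = 250, max_mito = 0.10, verbose = TRUE) {
  qc <- qc_stats(raw, ann)
  keep <- qc$n_genes >= min_genes & qc$mito_frac <= max_mito
  if (verbose) {
    kept <- qc |>
      dplyr::mutate(keep = keep) |>
      dplyr::count(.data$sample, .data$keep) |>
      tidyr::pivot_wider(names_from = "keep", values_from = "n", values_fill = 0L)
    for (i in seq_len(nrow(kept))) {
      message(sprintf(
        "qc_filter [%s]: kept %d, removed %d cells",
        kept$sample[i],
        if ("TRUE" %in% names(kept)) kept[["TRUE"]][i] else 0L,
        if ("FALSE" %in% names(kept)) kept[["FALSE"]][i] else 0L
      ))
    }
  }
  out <- sc_counts(raw$counts[, keep, drop = FALSE], raw$cells[keep, , drop = FALSE])
  attr(out, "qc") <- qc[keep, , drop = FALSE]
  out
}

#' Library-size normalization with natural-log transform
#'
#' Scales each cell's counts to its total, multiplies by `scale_factor`, and
#' applies `ln(1 + x)`. Zero counts map to exactly zero, so sparsity is
#' preserved.
#'
#' @param raw An [sc_counts] object with no all-zero cell.
#' @param scale_factor Per-cell scale (default 10,000).
#' @return An [sc_norm] object.
#' @export
normalize_counts <- function(raw, scale_factor = 1e4) {
  stopifnot(inherits(raw, "sc_counts"))
  total <- Matrix::colSums(raw$counts)
  if (any(total == 0)) {
    bad <- colnames(raw$counts)[total == 0][1]
    stop("cell with zero total counts: ", bad, call. = FALSE)
  }
  scaled <- raw$counts %*% Matrix::Diagonal(x = scale_factor / total)
  scaled@x <- log1p(scaled@x)
  dimnames(scaled) <- dimnames(raw$counts)
  sc_norm(methods::as(scaled, "CsparseMatrix"), raw$cells, scale_factor)
}

#' Dropout-curve variable-gene selection
#'
#' Fits a global Michaelis-Menten dropout curve `d = 1 - S / (K + S)` to the
#' per-gene (mean expression `S`, dropout rate `d`) cloud by least squares,
#' computes each gene's own Michaelis constant `K_j = S_j d_j / (1 - d_j)`,
#' and tests `K_j > K` one-sided using a delta-method standard error on the
#' binomial dropout rate (`var d_j = d_j (1 - d_j) / n`). Genes whose
#' BH-adjusted p-value falls below `fdr` are reported as variable.
#'
#' @param raw An [sc_counts] object with at least 50 cells.
#' @param fdr BH threshold (default 0.05).
#' @param exclude_ig Drop immunoglobulin genes (IGH/IGK/IGL prefixes) before
#'   testing — a robustness mode for clonal plasma-cell data where Ig
#'   transcripts otherwise dominate the variable set.
#' @return Tibble with `gene_id`, `mean_expr`, `dropout`, `K_gene`, `p`,
#'   `p_adj`, `variable`; attribute `"K"` holds the fitted global constant.
#' @export
select_variable_genes <- function(raw, fdr = 0.05, exclude_ig = FALSE) {
  stopifnot(inherits(raw, "sc_counts"))
  m <- raw$counts
  if (ncol(m) < 50) stop("variable-gene selection needs >= 50 cells", call. = FALSE)
  if (exclude_ig) {
    ig <- grepl("^IG[HKL]", rownames(m))
    m <- m[!ig, , drop = FALSE]
  }
  n <- ncol(m)
  S <- Matrix::rowMeans(m)
  d <- 1 - Matrix::rowMeans(m > 0)
  if (all(S == 0)) stop("all genes are zero", call. = FALSE)
  usable <- S > 0
  Su <- S[usable]
  du <- d[usable]
  sse <- function(K) sum((du - (1 - Su / (K + Su)))^2)
  K_hat <- stats::optimize(sse, interval = c(1e-8, max(Su) * 10))$minimum
  # per-gene K and its delta-method s.e.; d == 1 genes carry no signal
  denom <- pmax(1 - du, 1e-12)
  K_gene <- Su * du / denom
  se <- Su / denom^2 * sqrt(du * (1 - du) / n)
  z <- ifelse(se > 0, (K_gene - K_hat) / se, -Inf)
  p <- stats::pnorm(z, lower.tail = FALSE)
  p[du == 0] <- 1  # expressed in every cell: never selected
  p[du == 1] <- 1
  out <- tibble::tibble(
    gene_id = rownames(m)[usable],
    mean_expr = Su,
    dropout = du,
    K_gene = K_gene,
    p = p,
    p_adj = stats::p.adjust(p, method = "BH")
  )
  out$variable <- out$p_adj < fdr
  attr(out, "K") <- K_hat
  out
}
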