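marker_score_matrix <- function(norm, marker_map) {
  v <- norm$values
  missing <- setdiff(unlist(marker_map), rownames(v))
  if (length(missing)) {
    stop("marker gene(s) absent from matrix: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  sc <- vapply(marker_map, function(gs) {
    Matrix::colMeans(v[gs, , drop = FALSE])
  }, numeric(ncol(v)))
  if (is.null(dim(sc))) {
    sc <- matrix(sc, nrow = 1, dimnames = list(colnames(v), names(marker_map)))
  }
  sc
}

#' Light-chain restriction call per cell
#'
#' A cell is called kappa-restricted when its mean normalized kappa
#' expression is at least `rho` times the lambda mean and at least `tau_lc`
#' in absolute terms (symmetrically for lambda); otherwise ambiguous.
#'
#' @param norm An [sc_norm] object.
#' @param kappa_genes,lambda_genes Light-chain gene lists (defaults from
#'   [light_chain_genes()]).
#' @param rho Dominance ratio (default 5).
#' @param tau_lc Minimum mean expression of the dominant chain (default 0.5).
#' @return Tibble `barcode`, `kappa_score`, `lambda_score`,
#'   `restriction` in `{"kappa", "lambda", "ambiguous"}`.
#' @export
light_chain_restriction <- function(norm,
                                    kappa_genes = light_chain_genes()$kappa,
                                    lambda_genes = light_chain_genes()$lambda,
                                    rho = 5, tau_lc = 0.5) {
  stopifnot(inherits(norm, "sc_norm"))
  sc <- marker_score_matrix(norm, list(kappa = kappa_genes, lambda = lambda_genes))
  k <- sc[, "kappa"]
  l <- sc[, "lambda"]
  call <- dplyr::case_when(
    k >= rho * l & k >= tau_lc ~ "kappa",
    l >= rho * k & l >= tau_lc ~ "lambda",
    .default = "ambiguous"
  )
  tibble::tibble(
    barcode = colnames(norm$values),
    kappa_score = k, lambda_score = l, restriction = call
  )
}

#' Marker-rule cell typing
#'
#' Scores each cell against each label's marker genes (mean normalized
#' expression) and assigns the argmax label when the best score reaches
#' `tau_type`; otherwise `unassigned`. Cells whose best label is `MM`
#' additionally require an unambiguous light-chain restriction call — a
#' monotypic kappa or lambda pattern is what separates malignant plasma
#' cells from the polyclonal background.
#'
#' @param norm An [sc_norm] object.
#' @param marker_map Named list label -> marker genes; default
#'   [default_marker_map()].
#' @param tau_type Minimum best score to assign a label (default 0.5).
#' @param rho,tau_lc Passed to [light_chain_restriction()] for MM candidates.
#' @return Tibble of class `cell_type_assignment`: `barcode`, `sample`,
#'   `label`, `best_score`, `restriction`, plus one `score_<label>` column
#'   per marker-map entry.
#' @export
assign_cell_types <- function(norm, marker_map = default_marker_map(),
                              tau_type = 0.5, rho = 5, tau_lc = 0.5) {
  stopifnot(inherits(norm, "sc_norm"))
  sc <- marker_score_matrix(norm, marker_map)
  best <- max.col(sc, ties.method = "first")
  best_score <- sc[cbind(seq_len(nrow(sc)), best)]
  label <- colnames(sc)[best]
  label[best_score < tau_type] <- "unassigned"
  restr <- light_chain_restriction(norm, rho = rho, tau_lc = tau_lc)
  is_mm <- label == "MM"
  label[is_mm & restr$restriction == "ambiguous"] <- "unassigned"
  out <- tibble::tibble(
    barcode = colnames(norm$values),
    sample = norm$cells$sample,
    label = label,
    best_score = best_score,
    restriction = restr$restriction
  )
  scores <- tibble::as_tibble(sc, .name_repair = ~ paste0("score_", .x))
  out <- dplyr::bind_cols(out, scores)
  class(out) <- c("cell_type_assignment", class(out))
  out
}

#' Split myeloma cells by IGH constant-gene expression
#'
#' The defining contrast of light-chain escape at the single-cell level:
#' myeloma cells with no detectable immunoglobulin heavy-chain constant
#' expression secrete free light chain only (`LCE_MM`); cells expressing IGH
#' constant genes secrete intact immunoglobulin (`IGH_MM`).
#'
#' @param norm An [sc_norm] object.
#' @param mm_barcodes Barcodes of the myeloma cells to split (non-empty).
#' @param igh_genes IGH constant-region genes; default [igh_constant_genes()]
#'   intersected with the matrix.
#' @param tau_igh Minimum mean IGH constant expression to call `IGH_MM`
#'   (default 0.25).
#' @return Tibble of class `mm_split`: `barcode`, `igh_score`, `label`
#'   in `{"LCE_MM", "IGH_MM"}`, `restriction`.
#' @export
split_mm <- function(norm, mm_barcodes, igh_genes = NULL, tau_igh = 0.25) {
  stopifnot(inherits(norm, "sc_norm"))
  if (!length(mm_barcodes)) stop("empty MM cell set", call. = FALSE)
  if (is.null(igh_genes)) igh_genes <- intersect(igh_constant_genes(), rownames(norm$values))
  if (!length(igh_genes)) stop("no IGH constant gene present in matrix", call. = FALSE)
  missing <- setdiff(mm_barcodes, colnames(norm$values))
  if (length(missing)) stop("unknown barcode(s) in `mm_barcodes`", call. = FALSE)
  v <- norm$values[igh_genes, mm_barcodes, drop = FALSE]
  igh_score <- Matrix::colMeans(v)
  restr <- light_chain_restriction(norm)
  out <- tibble::tibble(
    barcode = mm_barcodes,
    igh_score = as.numeric(igh_score),
    label = ifelse(igh_score >= tau_igh, "IGH_MM", "LCE_MM"),
    restriction = restr$restriction[match(mm_barcodes, restr$barcode)]
  )
  class(out) <- c("mm_split", class(out))
  out
}
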