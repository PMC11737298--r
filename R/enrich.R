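#' Hypergeometric pathway enrichment
#'
#' For each pathway, tests over-representation of the query gene set by the
#' upper-tail hypergeometric probability `P(X >= k)` of the observed overlap
#' `k`, with the odds ratio from the 2x2 contingency table (Haldane 0.5
#' correction when a margin cell is zero) and Benjamini-Hochberg adjustment
#' across pathways. Query genes outside the declared universe are dropped
#' with a warning.
#'
#' @param query A [gene_set]; its up and down genes together form the query.
#' @param pathways List of [gene_set] pathways (e.g. from [read_gmt()]).
#' @param universe Character vector of universe genes, or an integer
#'   universe size (in which case query and pathways are assumed to lie
#'   inside it).
#' @return Tibble of class `mm_enrichment`: `pathway`, `overlap`,
#'   `query_size`, `pathway_size`, `universe_size`, `p`, `odds_ratio`,
#'   `p_adj`, sorted by `p`.
#' @export
enrich <- function(query, pathways, universe) {
  stopifnot(inherits(query, "gene_set"))
  if (inherits(pathways, "gene_set")) pathways <- list(pathways)
  q <- unique(c(query$up, query$down))
  if (is.numeric(universe) && length(universe) == 1) {
    n_univ <- as.integer(universe)
    path_genes <- purrr::map(pathways, ~ unique(c(.x$up, .x$down)))
  } else {
    universe <- unique(as.character(universe))
    n_univ <- length(universe)
    outside <- setdiff(q, universe)
    if (length(outside)) {
      warning(length(outside), " query gene(s) outside the universe; excluded")
      q <- intersect(q, universe)
    }
    path_genes <- purrr::map(pathways, ~ intersect(unique(c(.x$up, .x$down)), universe))
  }
  if (n_univ < length(q)) stop("universe smaller than the query", call. = FALSE)
  rows <- purrr::imap(path_genes, function(pg, i) {
    K <- length(pg)
    if (n_univ < K) stop("universe smaller than a pathway", call. = FALSE)
    k <- length(intersect(q, pg))
    # upper tail including k
    p <- stats::phyper(k - 1, K, n_univ - K, length(q), lower.tail = FALSE)
    a <- k
    b <- length(q) - k
    cc <- K - k
    d <- n_univ - K - b
    if (min(a, b, cc, d) == 0) {
      a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5
    }
    nm <- if (!is.null(pathways[[i]]$name)) pathways[[i]]$name else as.character(i)
    tibble::tibble(
      pathway = nm, overlap = k, query_size = length(q), pathway_size = K,
      universe_size = n_univ, p = p, odds_ratio = (a * d) / (b * cc)
    )
  })
  out <- dplyr::bind_rows(rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out <- dplyr::arrange(out, .data$p)
  class(out) <- c("mm_enrichment", class(out))
  out
}
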