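logistic_lrt <- function(x, y, null_dev, maxit = 100) {
  # y is 0/1 group membership, x the gene's normalized expression
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(
      cbind(1, x), y,
      family = stats::binomial(),
      control = stats::glm.control(maxit = maxit)
    )),
    error = function(e) NULL
  )
  if (is.null(fit) || !isTRUE(fit$converged)) {
    return(list(p = NA_real_, converged = FALSE))
  }
  stat <- max(0, null_dev - fit$deviance)
  list(p = stats::pchisq(stat, df = 1, lower.tail = FALSE), converged = TRUE)
}

#' Differential expression by logistic regression
#'
#' For each gene detected in at least `min_pct` of either group, fits a
#' logistic model of group membership on the gene's normalized expression
#' and tests it against the intercept-only model by likelihood ratio
#' (chi-squared, 1 df). Fold changes are computed on de-logged group means
#' with a pseudocount, base-2 log. P-values are Bonferroni-adjusted over the
#' declared universe. Genes whose logistic fit fails to converge within 100
#' iterations fall back to the Wilcoxon rank-sum test and are flagged.
#'
#' @param norm An [sc_norm] object.
#' @param group1,group2 Barcode vectors of the two cell groups (each of size
#'   at least `n_min`). Fold changes are group1 over group2.
#' @param min_pct Detection filter: test genes expressed in at least this
#'   fraction of either group (default 0.10).
#' @param n_min Minimum cells per group (default 3).
#' @param pseudocount Added to de-logged group means in the fold change
#'   (default 1).
#' @param universe Bonferroni universe: `"all"` genes in the matrix (the
#'   default, matching the convention of single-cell toolchains) or
#'   `"tested"` genes only.
#' @return Tibble of class `mm_de`: `gene_id`, `l2fc`, `p`, `p_adj`,
#'   `pct_1`, `pct_2`, `direction` (`"up"`/`"down"`/`"flat"`), `fallback`
#'   (TRUE where the rank-sum fallback was used). Untested genes are absent.
#' @export
differential_expression <- function(norm, group1, group2, min_pct = 0.10,
                                    n_min = 3, pseudocount = 1,
                                    universe = c("all", "tested")) {
  stopifnot(inherits(norm, "sc_norm"))
  universe <- match.arg(universe)
  bc <- colnames(norm$values)
  if (!all(group1 %in% bc) || !all(group2 %in% bc)) {
    stop("unknown barcodes in group definitions", call. = FALSE)
  }
  if (length(intersect(group1, group2))) stop("groups overlap", call. = FALSE)
  if (length(group1) < n_min || length(group2) < n_min) {
    stop(sprintf("both groups need >= %d cells", n_min), call. = FALSE)
  }
  # cells x genes orientation for fast per-gene column access
  v <- Matrix::t(norm$values[, c(group1, group2), drop = FALSE])
  n1 <- length(group1)
  n2 <- length(group2)
  y <- rep(c(1, 0), c(n1, n2))
  idx1 <- seq_len(n1)
  idx2 <- n1 + seq_len(n2)

  pct1 <- Matrix::colMeans(v[idx1, , drop = FALSE] > 0)
  pct2 <- Matrix::colMeans(v[idx2, , drop = FALSE] > 0)
  tested <- which(pct1 >= min_pct | pct2 >= min_pct)
  m_universe <- if (universe == "all") ncol(v) else length(tested)

  mu <- mean(y)
  null_dev <- -2 * (sum(y) * log(mu) + sum(1 - y) * log(1 - mu))

  res <- purrr::map(tested, function(j) {
    x <- as.numeric(v[, j])
    expd1 <- mean(expm1(x[idx1]))
    expd2 <- mean(expm1(x[idx2]))
    l2fc <- log2((expd1 + pseudocount) / (expd2 + pseudocount))
    lrt <- logistic_lrt(x, y, null_dev)
    p <- lrt$p
    fallback <- !lrt$converged
    if (fallback) {
      p <- suppressWarnings(
        stats::wilcox.test(x[idx1], x[idx2], exact = FALSE)$p.value
      )
    }
    list(l2fc = l2fc, p = p, fallback = fallback)
  })
  out <- tibble::tibble(
    gene_id = colnames(v)[tested],
    l2fc = purrr::map_dbl(res, "l2fc"),
    p = purrr::map_dbl(res, "p"),
    pct_1 = pct1[tested],
    pct_2 = pct2[tested],
    fallback = purrr::map_lgl(res, "fallback")
  )
  out$p_adj <- pmin(1, out$p * m_universe)
  out$direction <- dplyr::case_when(
    out$l2fc > 0 ~ "up", out$l2fc < 0 ~ "down", .default = "flat"
  )
  out <- out[, c("gene_id", "l2fc", "p", "p_adj", "pct_1", "pct_2", "direction", "fallback")]
  attr(out, "n_cells") <- c(group1 = n1, group2 = n2)
  attr(out, "universe_size") <- m_universe
  class(out) <- c("mm_de", class(out))
  out
}

#' Derive a gene set from a differential-expression result
#'
#' Selects genes passing `|l2fc| > l2fc_min` and `p_adj < p_adj_max`. With
#' `up_only = TRUE` (the default, used for the LCE-MM signature) only the
#' up-regulated side is kept; otherwise up and down genes populate the two
#' sides of the set.
#'
#' @param de An `mm_de` tibble from [differential_expression()].
#' @param name Name for the resulting set.
#' @param l2fc_min Absolute log2-fold-change threshold (default 1.0, i.e.
#'   two-fold).
#' @param p_adj_max Adjusted-p threshold (default 0.05).
#' @param up_only Keep only up genes (default TRUE).
#' @return A [gene_set]; empty input yields an empty-set warning and `NULL`.
#' @export
define_gene_set <- function(de, name = "signature", l2fc_min = 1.0,
                            p_adj_max = 0.05, up_only = TRUE) {
  sig <- de[de$p_adj < p_adj_max, , drop = FALSE]
  up <- sig$gene_id[sig$l2fc > l2fc_min]
  down <- if (up_only) character() else sig$gene_id[sig$l2fc < -l2fc_min]
  if (!length(up) && !length(down)) {
    warning("no gene passes the thresholds; returning NULL")
    return(NULL)
  }
  gene_set(name, up, down)
}

#' Score cells against a gene signature
#'
#' Per-cell score is the mean normalized expression of the signature's up
#' genes minus the mean of its down genes (genes absent from the matrix are
#' dropped; at least one must be present).
#'
#' @param norm An [sc_norm] object.
#' @param sig A [gene_set].
#' @param group Optional per-cell grouping factor (e.g. the MM split); when
#'   given with exactly two levels, a Wilcoxon rank-sum comparison of the
#'   scores is attached as attribute `"test"`.
#' @return Tibble `barcode`, `score` and, if supplied, `group`.
#' @export
signature_score_cells <- function(norm, sig, group = NULL) {
  stopifnot(inherits(norm, "sc_norm"), inherits(sig, "gene_set"))
  v <- norm$values
  up <- intersect(sig$up, rownames(v))
  down <- intersect(sig$down, rownames(v))
  if (!length(up) && !length(down)) {
    stop("no signature gene present in the matrix", call. = FALSE)
  }
  score <- numeric(ncol(v))
  if (length(up)) score <- score + Matrix::colMeans(v[up, , drop = FALSE])
  if (length(down)) score <- score - Matrix::colMeans(v[down, , drop = FALSE])
  out <- tibble::tibble(barcode = colnames(v), score = as.numeric(score))
  if (!is.null(group)) {
    out$group <- group
    lv <- unique(group)
    if (length(lv) == 2) {
      attr(out, "test") <- suppressWarnings(stats::wilcox.test(score ~ factor(group)))
    }
  }
  out
}
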