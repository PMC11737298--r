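#' Summed z-score gene-set scoring of a bulk cohort
#'
#' For every signature gene present in the cohort, expression is
#' standardized to a cross-sample z-score (sample SD, n - 1); a sample's
#' gene-set score is the sum of z-scores over up genes minus the sum over
#' down genes. Genes with zero cross-sample SD contribute 0; signature genes
#' absent from the cohort are skipped with a message.
#'
#' @param cohort A [bulk_cohort] with at least 3 samples.
#' @param sig A [gene_set] with at least one gene present in the cohort.
#' @param verbose Log skipped genes.
#' @return Tibble of class `mm_scores`: `sample_id`, `score`. Attributes
#'   `"genes_used"` / `"genes_skipped"` record the overlap.
#' @export
geneset_score <- function(cohort, sig, verbose = TRUE) {
  stopifnot(inherits(cohort, "bulk_cohort"), inherits(sig, "gene_set"))
  if (nrow(cohort$expression) < 3) stop("need >= 3 samples", call. = FALSE)
  genes <- colnames(cohort$expression)
  up <- intersect(sig$up, genes)
  down <- intersect(sig$down, genes)
  skipped <- setdiff(c(sig$up, sig$down), genes)
  if (!length(up) && !length(down)) {
    stop("no signature gene present in the cohort", call. = FALSE)
  }
  if (length(skipped) && verbose) {
    message(length(skipped), " signature gene(s) absent from the cohort; skipped")
  }
  zmat <- function(gs) {
    if (!length(gs)) return(0)
    x <- cohort$expression[, gs, drop = FALSE]
    mu <- colMeans(x)
    sdv <- apply(x, 2, stats::sd)
    z <- sweep(x, 2, mu, `-`)
    z <- sweep(z, 2, ifelse(sdv > 0, sdv, Inf), `/`)  # SD = 0 contributes 0
    rowSums(z)
  }
  score <- zmat(up) - zmat(down)
  out <- tibble::tibble(sample_id = rownames(cohort$expression), score = as.numeric(score))
  attr(out, "genes_used") <- list(up = up, down = down)
  attr(out, "genes_skipped") <- skipped
  class(out) <- c("mm_scores", class(out))
  out
}

#' Stratify samples by gene-set score
#'
#' Samples scoring more than `m` standard deviations above the cohort mean
#' are `high`, more than `m` SD below are `low`, the rest `mid`.
#' Inequalities are strict: a score exactly at a cut is `mid`.
#'
#' @param scores An `mm_scores` tibble from [geneset_score()] (or any tibble
#'   with `sample_id` and `score`).
#' @param m SD multiplier for the cuts (default 1).
#' @return The input tibble with a `stratum` column
#'   (`"high"`/`"mid"`/`"low"`); attributes `"cuts"` hold the mean and SD
#'   used.
#' @export
stratify <- function(scores, m = 1.0) {
  stopifnot(all(c("sample_id", "score") %in% names(scores)))
  if (nrow(scores) < 3) stop("need >= 3 samples", call. = FALSE)
  mu <- mean(scores$score)
  sdv <- stats::sd(scores$score)
  if (sdv == 0) {
    warning("zero score SD; all samples mid")
    scores$stratum <- "mid"
  } else {
    scores$stratum <- dplyr::case_when(
      scores$score > mu + m * sdv ~ "high",
      scores$score < mu - m * sdv ~ "low",
      .default = "mid"
    )
  }
  attr(scores, "cuts") <- c(mean = mu, sd = sdv, m = m)
  scores
}

#' Osteolytic lesion association with score strata
#'
#' Cross-tabulates high vs low score strata against lesion burden
#' (three-or-more vs fewer lesions) and tests by two-sided Fisher exact
#' test; a continuous lesion count, when available, is compared by Welch
#' t-test. Mid-stratum samples are excluded.
#'
#' @param scores A stratified `mm_scores` tibble (see [stratify()]).
#' @param cohort The [bulk_cohort] holding `lesion_category` (levels
#'   `"0","1","2",">=3"`) and optionally `lesion_count`.
#' @return List of class `mm_lesions`: `table` (2x2 matrix), `fisher_p`,
#'   `odds_ratio`, and (when counts exist) `t_p`, `mean_high`, `mean_low`.
#' @export
lesion_association <- function(scores, cohort) {
  stopifnot(inherits(cohort, "bulk_cohort"), "stratum" %in% names(scores))
  df <- dplyr::inner_join(scores, cohort$clinical, by = "sample_id") |>
    dplyr::filter(.data$stratum %in% c("high", "low"), !is.na(.data$lesion_category))
  if (!any(df$stratum == "high") || !any(df$stratum == "low")) {
    stop("need lesion data in both the high and the low stratum", call. = FALSE)
  }
  df$many <- factor(df$lesion_category == ">=3", levels = c(TRUE, FALSE),
                    labels = c(">=3", "<3"))
  tab <- table(stratum = factor(df$stratum, levels = c("high", "low")), lesions = df$many)
  ft <- stats::fisher.test(tab)
  out <- list(table = tab, fisher_p = ft$p.value, odds_ratio = unname(ft$estimate))
  if ("lesion_count" %in% names(df) && !all(is.na(df$lesion_count))) {
    hi <- df$lesion_count[df$stratum == "high"]
    lo <- df$lesion_count[df$stratum == "low"]
    tt <- stats::t.test(hi, lo)
    out$t_p <- tt$p.value
    out$mean_high <- mean(hi, na.rm = TRUE)
    out$mean_low <- mean(lo, na.rm = TRUE)
  }
  structure(out, class = "mm_lesions")
}

#' @exportS3Method base::print
print.mm_lesions <- function(x, ...) {
  cat("<mm_lesions> high/low stratum vs lesion burden\n")
  print(x$table)
  cat(sprintf("Fisher exact p = %.3g, OR = %.3g\n", x$fisher_p, x$odds_ratio))
  if (!is.null(x$t_p)) {
    cat(sprintf(
      "lesion count: mean high %.2f vs low %.2f, Welch t p = %.3g\n",
      x$mean_high, x$mean_low, x$t_p
    ))
  }
  invisible(x)
}
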