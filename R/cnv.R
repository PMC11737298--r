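running_mean_rows <- function(mat, window) {
  # centered moving average down the rows, window shrinking at the edges
  n <- nrow(mat)
  h <- window %/% 2
  cs <- apply(mat, 2, cumsum)
  if (n == 1) return(mat)
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  upper <- cs[hi, , drop = FALSE]
  lower <- rbind(0, cs)[lo, , drop = FALSE]
  sweep(upper - lower, 1, hi - lo + 1, `/`)
}

#' Smoothed expression-based CNV signal
#'
#' An inferCNV-style estimate of chromosomal dosage: each gene's normalized
#' expression is centered on the mean over a reference (normal) cell set,
#' genes are laid out in genomic order, a moving average over `window` genes
#' is taken within each chromosome (shrinking at chromosome edges), each
#' cell is median-centered across windows, and values are clipped to
#' `[-clip, +clip]`. Mitochondrial genes and chromosomes carrying fewer than
#' five annotated genes are excluded.
#'
#' @param norm An [sc_norm] object.
#' @param ann A `gene_annotation` covering the genes of `norm`.
#' @param reference_cells Barcodes of the reference (non-malignant) cells;
#'   non-empty.
#' @param window Moving-average window in genes (default 101).
#' @param clip Clipping bound (default 1.0).
#' @return An object of class `cnv_matrix`: list with `signal` (cells x
#'   windows matrix; one window per gene position), `windows` (tibble
#'   `window`, `gene_id`, `chromosome`, `start_bp`), and
#'   `reference_cells`.
#' @export
smooth_cnv <- function(norm, ann, reference_cells, window = 101, clip = 1.0) {
  stopifnot(inherits(norm, "sc_norm"))
  if (!length(reference_cells)) stop("reference cell set is empty", call. = FALSE)
  if (!all(reference_cells %in% colnames(norm$values))) {
    stop("unknown reference barcode(s)", call. = FALSE)
  }
  ann_use <- ann[!ann$is_mitochondrial & ann$gene_id %in% rownames(norm$values), , drop = FALSE]
  chr_counts <- table(droplevels(ann_use$chromosome))
  small <- names(chr_counts)[chr_counts < 5]
  if (length(small)) {
    warning("excluding chromosome(s) with < 5 genes: ", paste(small, collapse = ", "))
    ann_use <- ann_use[!as.character(ann_use$chromosome) %in% small, , drop = FALSE]
  }
  ann_use <- dplyr::arrange(ann_use, .data$chromosome, .data$start_bp)
  genes <- ann_use$gene_id
  v <- as.matrix(norm$values[genes, , drop = FALSE])
  ref_mean <- rowMeans(v[, reference_cells, drop = FALSE])
  sig <- v - ref_mean

  smoothed <- matrix(0, nrow = length(genes), ncol = ncol(sig),
                     dimnames = dimnames(sig))
  for (chr in unique(as.character(ann_use$chromosome))) {
    idx <- which(as.character(ann_use$chromosome) == chr)
    smoothed[idx, ] <- running_mean_rows(sig[idx, , drop = FALSE], window)
  }
  cell_med <- apply(smoothed, 2, stats::median)
  smoothed <- sweep(smoothed, 2, cell_med, `-`)
  # second reference pass: remove residual per-window offsets (smoothing and
  # median-centering leave a small systematic shift even in reference cells)
  ref_window <- rowMeans(smoothed[, reference_cells, drop = FALSE])
  smoothed <- smoothed - ref_window
  smoothed <- pmin(pmax(smoothed, -clip), clip)

  structure(
    list(
      signal = t(smoothed),
      windows = tibble::tibble(
        window = seq_along(genes),
        gene_id = genes,
        chromosome = as.character(ann_use$chromosome),
        start_bp = ann_use$start_bp
      ),
      reference_cells = reference_cells
    ),
    class = "cnv_matrix"
  )
}

#' @exportS3Method base::print
print.cnv_matrix <- function(x, ...) {
  cat(sprintf(
    "<cnv_matrix> %d cells x %d windows over %d chromosomes (%d reference cells)\n",
    nrow(x$signal), ncol(x$signal),
    dplyr::n_distinct(x$windows$chromosome), length(x$reference_cells)
  ))
  invisible(x)
}

#' Per-cell chromosome-mean CNV profiles
#' @param cnv A `cnv_matrix`.
#' @return Cells x chromosomes matrix of mean window signal.
#' @export
chromosome_profiles <- function(cnv) {
  stopifnot(inherits(cnv, "cnv_matrix"))
  chrs <- unique(cnv$windows$chromosome)
  prof <- vapply(chrs, function(ch) {
    rowMeans(cnv$signal[, cnv$windows$chromosome == ch, drop = FALSE])
  }, numeric(nrow(cnv$signal)))
  rownames(prof) <- rownames(cnv$signal)
  prof
}

#' Chromosome-level gain/loss calls
#'
#' Calls a gain when a cell's mean window signal on a chromosome exceeds
#' `gain_thr`, a loss when it falls below `loss_thr`, neutral otherwise.
#'
#' @param cnv A `cnv_matrix`.
#' @param gain_thr,loss_thr Call thresholds (defaults +0.1 / -0.1).
#' @return Tibble of class `cnv_calls`: `barcode`, `chromosome`,
#'   `mean_signal`, `call` in `{"loss", "neutral", "gain"}`.
#' @export
call_events <- function(cnv, gain_thr = 0.1, loss_thr = -0.1) {
  prof <- chromosome_profiles(cnv)
  out <- tibble::as_tibble(prof) |>
    dplyr::mutate(barcode = rownames(prof), .before = 1) |>
    tidyr::pivot_longer(-"barcode", names_to = "chromosome", values_to = "mean_signal") |>
    dplyr::mutate(call = dplyr::case_when(
      .data$mean_signal > gain_thr ~ "gain",
      .data$mean_signal < loss_thr ~ "loss",
      .default = "neutral"
    ))
  class(out) <- c("cnv_calls", class(out))
  out
}

#' Cluster cells into CNV-defined subclones
#'
#' Hierarchical clustering (Ward minimum-variance linkage, Euclidean
#' distance; average linkage is available but chains on outlier cells) of
#' chromosome-mean CNV profiles. The number of subclones is chosen by
#' maximum mean silhouette width over `k = 2..k_max` (ties toward smaller
#' k) unless `k` is fixed; when the best silhouette is below
#' `silhouette_min` the cells are reported as a single subclone. Labels are
#' ordered by subclone size.
#'
#' @param cnv A `cnv_matrix`.
#' @param k Fixed number of subclones, or `NULL` for the silhouette search.
#' @param k_max Upper bound of the search (default 10).
#' @param linkage Agglomeration method passed to [stats::hclust()]
#'   (default `"ward.D2"`).
#' @param silhouette_min Silhouette floor under which k = 1 is reported
#'   (default 0.1).
#' @return An object of class `subclone_model`: list with `labels` (tibble
#'   `barcode`, `subclone`), `signatures` (subclones x chromosomes mean
#'   profile matrix), `k`, `silhouette`, `proportions` (tibble `subclone`,
#'   `n`, `proportion`).
#' @export
cluster_subclones <- function(cnv, k = NULL, k_max = 10, silhouette_min = 0.1,
                              linkage = "ward.D2") {
  prof <- chromosome_profiles(cnv)
  n <- nrow(prof)
  if (!is.null(k) && k > n) stop("k exceeds the number of cells", call. = FALSE)
  d <- stats::dist(prof)
  hc <- stats::hclust(d, method = linkage)
  sil_best <- NA_real_
  if (is.null(k)) {
    k_try <- seq(2, min(k_max, n - 1))
    sil <- vapply(k_try, function(kk) {
      cl <- stats::cutree(hc, kk)
      if (dplyr::n_distinct(cl) < 2) return(-Inf)
      mean(cluster::silhouette(cl, d)[, "sil_width"])
    }, numeric(1))
    best <- which.max(sil)  # which.max takes the first (smallest k) on ties
    sil_best <- sil[best]
    k <- if (is.finite(sil_best) && sil_best >= silhouette_min) k_try[best] else 1L
  } else if (k > 1) {
    cl <- stats::cutree(hc, k)
    if (dplyr::n_distinct(cl) > 1) {
      sil_best <- mean(cluster::silhouette(cl, d)[, "sil_width"])
    }
  }
  cl <- if (k == 1) rep(1L, n) else stats::cutree(hc, k)
  # relabel by decreasing size
  sizes <- sort(table(cl), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes), names(sizes))
  subclone <- sprintf("SC%d", relabel[as.character(cl)])
  labels <- tibble::tibble(barcode = rownames(prof), subclone = subclone)
  signatures <- do.call(rbind, lapply(split(seq_len(n), subclone), function(ix) {
    colMeans(prof[ix, , drop = FALSE])
  }))
  proportions <- labels |>
    dplyr::count(.data$subclone) |>
    dplyr::mutate(proportion = .data$n / sum(.data$n))
  structure(
    list(labels = labels, signatures = signatures, k = k,
         silhouette = sil_best, proportions = proportions),
    class = "subclone_model"
  )
}

#' @exportS3Method base::print
print.subclone_model <- function(x, ...) {
  cat(sprintf(
    "<subclone_model> k = %d subclone(s), mean silhouette %.3f\n",
    x$k, if (is.na(x$silhouette)) NA else x$silhouette
  ))
  print(x$proportions)
  invisible(x)
}

#' Track subclones across timepoints
#'
#' Greedily matches subclone chromosome signatures between consecutive
#' timepoints by Pearson correlation, accepting matches with correlation at least `match_min`; candidate pairs are visited in decreasing correlation, ties
#' broken toward the larger earlier subclone. Unmatched earlier subclones
#' are extinct, unmatched later ones emergent.
#'
#' @param models Ordered named list of `subclone_model`s, one per timepoint.
#' @param match_min Correlation floor for a match (default 0.8).
#' @param calls Optional list (same names) of `cnv_calls` tibbles; when
#'   given, per-timepoint carrier proportions of each chromosome gain/loss
#'   are reported.
#' @return List of class `subclone_tracking`: `mapping` (tibble
#'   `timepoint_from`, `subclone_from`, `timepoint_to`, `subclone_to`, `r`,
#'   `status`), `proportions` (tibble `timepoint`, `subclone`, `n`,
#'   `proportion`), and `event_proportions` (tibble `timepoint`,
#'   `chromosome`, `call`, `proportion`, or `NULL`).
#' @export
track_subclones <- function(models, match_min = 0.8, calls = NULL) {
  if (length(models) < 2) stop("need at least two timepoints", call. = FALSE)
  if (is.null(names(models))) names(models) <- sprintf("tp%d", seq_along(models))
  for (nm in names(models)) {
    if (!nrow(models[[nm]]$labels)) stop("timepoint with no cells: ", nm, call. = FALSE)
  }
  tps <- names(models)
  mapping <- list()
  for (i in seq_len(length(models) - 1)) {
    a <- models[[i]]
    b <- models[[i + 1]]
    size_a <- stats::setNames(a$proportions$n, a$proportions$subclone)
    pairs <- tidyr::expand_grid(
      subclone_from = rownames(a$signatures),
      subclone_to = rownames(b$signatures)
    )
    pairs$r <- purrr::map2_dbl(pairs$subclone_from, pairs$subclone_to, function(sa, sb) {
      va <- a$signatures[sa, ]
      vb <- b$signatures[sb, ]
      if (stats::sd(va) == 0 || stats::sd(vb) == 0) return(NA_real_)
      stats::cor(va, vb)
    })
    pairs <- pairs[!is.na(pairs$r) & pairs$r >= match_min, , drop = FALSE]
    pairs <- pairs[order(-pairs$r, -size_a[pairs$subclone_from]), , drop = FALSE]
    used_a <- used_b <- character()
    acc <- list()
    for (j in seq_len(nrow(pairs))) {
      sa <- pairs$subclone_from[j]
      sb <- pairs$subclone_to[j]
      if (sa %in% used_a || sb %in% used_b) next
      used_a <- c(used_a, sa)
      used_b <- c(used_b, sb)
      acc[[length(acc) + 1]] <- tibble::tibble(
        timepoint_from = tps[i], subclone_from = sa,
        timepoint_to = tps[i + 1], subclone_to = sb,
        r = pairs$r[j], status = "matched"
      )
    }
    extinct <- setdiff(rownames(a$signatures), used_a)
    emergent <- setdiff(rownames(b$signatures), used_b)
    if (length(extinct)) {
      acc[[length(acc) + 1]] <- tibble::tibble(
        timepoint_from = tps[i], subclone_from = extinct,
        timepoint_to = tps[i + 1], subclone_to = NA_character_,
        r = NA_real_, status = "extinct"
      )
    }
    if (length(emergent)) {
      acc[[length(acc) + 1]] <- tibble::tibble(
        timepoint_from = tps[i], subclone_from = NA_character_,
        timepoint_to = tps[i + 1], subclone_to = emergent,
        r = NA_real_, status = "emergent"
      )
    }
    mapping[[i]] <- dplyr::bind_rows(acc)
  }
  proportions <- purrr::imap(models, function(m, nm) {
    dplyr::mutate(m$proportions, timepoint = nm, .before = 1)
  }) |> dplyr::bind_rows()

  event_proportions <- NULL
  if (!is.null(calls)) {
    event_proportions <- purrr::imap(calls, function(cl, nm) {
      cl |>
        dplyr::group_by(.data$chromosome, .data$call) |>
        dplyr::summarise(n = dplyr::n(), .groups = "drop_last") |>
        dplyr::mutate(proportion = .data$n / sum(.data$n)) |>
        dplyr::ungroup() |>
        dplyr::filter(.data$call != "neutral") |>
        dplyr::mutate(timepoint = nm, .before = 1)
    }) |> dplyr::bind_rows()
  }
  structure(
    list(mapping = dplyr::bind_rows(mapping), proportions = proportions,
         event_proportions = event_proportions),
    class = "subclone_tracking"
  )
}

#' @exportS3Method base::print
print.subclone_tracking <- function(x, ...) {
  cat("<subclone_tracking>\n")
  print(x$mapping)
  invisible(x)
}
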