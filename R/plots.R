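#' Volcano plot of a differential-expression result
#'
#' @param de An `mm_de` tibble.
#' @param l2fc_min,p_adj_max Thresholds drawn as dashed guides and used to
#'   colour significant genes (defaults 0.25 and 0.05, the single-cell
#'   reporting thresholds).
#' @param label_top Number of top genes (by adjusted p) to label.
#' @return A ggplot object.
#' @export
plot_volcano <- function(de, l2fc_min = 0.25, p_adj_max = 0.05, label_top = 10) {
  df <- tibble::as_tibble(de) |>
    dplyr::mutate(
      neglog_p = -log10(pmax(.data$p_adj, 1e-300)),
      status = dplyr::case_when(
        .data$p_adj < p_adj_max & .data$l2fc > l2fc_min ~ "up",
        .data$p_adj < p_adj_max & .data$l2fc < -l2fc_min ~ "down",
        .default = "ns"
      )
    )
  top <- df |>
    dplyr::filter(.data$status != "ns") |>
    dplyr::slice_min(.data$p_adj, n = label_top, with_ties = FALSE)
  ggplot2::ggplot(df, ggplot2::aes(.data$l2fc, .data$neglog_p, colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_vline(xintercept = c(-l2fc_min, l2fc_min), linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(p_adj_max), linetype = "dashed") +
    ggplot2::geom_text(
      data = top, ggplot2::aes(label = .data$gene_id),
      size = 2.5, vjust = -0.6, show.legend = FALSE
    ) +
    ggplot2::scale_colour_manual(
      values = c(up = "#c0392b", down = "#2e6da4", ns = "grey70")
    ) +
    ggplot2::labs(
      x = "log2 fold change", y = "-log10 adjusted p", colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mm_de <- function(object, ...) plot_volcano(object, ...)

#' Gene-set score distribution with stratification cuts
#'
#' @param scores A stratified `mm_scores` tibble (see [stratify()]).
#' @param bins Histogram bins.
#' @return A ggplot object.
#' @export
plot_score_distribution <- function(scores, bins = 40) {
  cuts <- attr(scores, "cuts")
  p <- ggplot2::ggplot(
    tibble::as_tibble(scores),
    ggplot2::aes(.data$score, fill = .data$stratum)
  ) +
    ggplot2::geom_histogram(bins = bins, colour = "white", linewidth = 0.2) +
    ggplot2::scale_fill_manual(
      values = c(high = "#c0392b", mid = "grey75", low = "#2e6da4")
    ) +
    ggplot2::labs(x = "gene-set score (summed z-scores)", y = "samples") +
    ggplot2::theme_minimal()
  if (!is.null(cuts)) {
    p <- p + ggplot2::geom_vline(
      xintercept = cuts["mean"] + c(-1, 1) * cuts["m"] * cuts["sd"],
      linetype = "dashed"
    )
  }
  p
}

#' Serial M-spike and dFLC trajectories
#'
#' Plots each patient's M-spike (g/dL) and involved-minus-uninvolved light
#' chain difference (mg/dL) over time on free y scales — the visual
#' signature of light-chain escape is a rising dFLC panel against a flat
#' M-spike panel.
#'
#' @param series A [clinical_series] tibble.
#' @param patients Optional subset of patient ids.
#' @return A ggplot object.
#' @export
plot_clinical_series <- function(series, patients = NULL) {
  df <- tibble::as_tibble(series)
  if (!is.null(patients)) df <- df[df$patient_id %in% patients, , drop = FALSE]
  iso <- if ("affected_isotype" %in% names(df)) df$affected_isotype else {
    ifelse(df$kappa >= df$lambda, "kappa", "lambda")
  }
  df$dflc <- ifelse(iso == "kappa", df$kappa - df$lambda, df$lambda - df$kappa)
  long <- tidyr::pivot_longer(
    df[, c("patient_id", "t_days", "m_spike", "dflc")],
    c("m_spike", "dflc"), names_to = "analyte", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$t_days, .data$value, group = .data$patient_id)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::facet_wrap(~analyte, scales = "free_y",
                        labeller = ggplot2::as_labeller(c(
                          m_spike = "M-spike (g/dL)", dflc = "dFLC (mg/dL)"
                        ))) +
    ggplot2::labs(x = "days from diagnosis", y = NULL) +
    ggplot2::theme_minimal()
}

#' Subclone proportions across timepoints
#'
#' Stacked-bar view of per-timepoint subclone composition from a
#' [track_subclones()] result (the tabular form of an alluvial plot).
#'
#' @param tracking A `subclone_tracking` object.
#' @return A ggplot object.
#' @export
plot_subclone_proportions <- function(tracking) {
  stopifnot(inherits(tracking, "subclone_tracking"))
  df <- tracking$proportions
  df$timepoint <- factor(df$timepoint, levels = unique(df$timepoint))
  ggplot2::ggplot(df, ggplot2::aes(.data$timepoint, .data$proportion, fill = .data$subclone)) +
    ggplot2::geom_col(colour = "white", linewidth = 0.2) +
    ggplot2::labs(x = NULL, y = "proportion of cells", fill = "subclone") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.subclone_tracking <- function(object, ...) plot_subclone_proportions(object)

#' Kaplan-Meier curves for a two-group survival comparison
#'
#' @param fit An `mm_survfit` from [compare_survival()].
#' @return A ggplot object annotated with the hazard ratio and log-rank p.
#' @export
plot_survival <- function(fit) {
  stopifnot(inherits(fit, "mm_survfit"))
  km <- fit$km
  grp <- rep(sub("^group=", "", names(km$strata)), km$strata)
  df <- dplyr::bind_rows(purrr::map(unique(grp), function(g) {
    ix <- grp == g
    tibble::tibble(
      time = c(0, km$time[ix]), surv = c(1, km$surv[ix]), group = g
    )
  }))
  lab <- sprintf("HR %.2f (%.2f-%.2f), log-rank p = %.2g",
                 fit$hr, fit$ci_low, fit$ci_high, fit$logrank_p)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$surv, colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = if (fit$endpoint == "os") "years" else "days",
      y = if (fit$endpoint == "os") "overall survival" else "free of diffuse lytic lesions",
      colour = NULL, subtitle = lab
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mm_survfit <- function(object, ...) plot_survival(object)

#' CNV heatmap-style summary
#'
#' Mean smoothed signal per chromosome per subclone, as a tile plot — a
#' compact stand-in for a full cell-by-window heatmap.
#'
#' @param model A `subclone_model`.
#' @return A ggplot object.
#' @export
plot_cnv_profiles <- function(model) {
  stopifnot(inherits(model, "subclone_model"))
  sig <- model$signatures
  df <- tibble::as_tibble(sig) |>
    dplyr::mutate(subclone = rownames(sig), .before = 1) |>
    tidyr::pivot_longer(-"subclone", names_to = "chromosome", values_to = "signal")
  df$chromosome <- factor(df$chromosome, levels = colnames(sig))
  ggplot2::ggplot(df, ggplot2::aes(.data$chromosome, .data$subclone, fill = .data$signal)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2e6da4", mid = "white", high = "#c0392b") +
    ggplot2::labs(x = "chromosome", y = "subclone", fill = "mean signal") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
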