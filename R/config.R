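#' Pipeline configuration
#'
#' Collects every tunable used across the pipeline with its default. Values
#' round-trip unchanged through [write_config()] / [read_config()].
#'
#' @param ... Named overrides of the defaults listed below.
#' @return A named list of class `mmlce_config`.
#' @details Defaults:
#' \describe{
#'   \item{min_genes (250), max_mito (0.10)}{QC: keep cells with >= 250
#'     detected genes and <= 10\% mitochondrial reads.}
#'   \item{scale_factor (1e4)}{Per-cell normalization scale.}
#'   \item{pseudocount (1)}{Added to de-logged group means in the fold change.}
#'   \item{vargene_fdr (0.05)}{BH threshold for dropout-curve gene selection.}
#'   \item{tau_type (0.5), tau_igh (0.25), tau_lc (0.5), rho_lc (5)}{Marker
#'     score threshold for typing, IGH-score threshold for the MM split, and
#'     the light-chain restriction level/ratio thresholds.}
#'   \item{de_min_pct (0.10), de_n_min (3), bonferroni_universe ("all")}{DE
#'     detection filter, minimum group size, and whether Bonferroni divides by
#'     all matrix genes or only tested genes.}
#'   \item{l2fc_min (1.0), p_adj_max (0.05), signature_up_only (TRUE)}{Gene-set
#'     definition thresholds and direction.}
#'   \item{cnv_window (101), cnv_clip (1.0), gain_thr (0.1), loss_thr (-0.1),
#'     k_max (10), silhouette_min (0.1), match_min (0.8)}{CNV smoothing window
#'     (genes), clipping bound, per-chromosome call thresholds, subclone
#'     auto-k cap and silhouette floor, and the tracking correlation floor.}
#'   \item{strat_m (1.0)}{Stratification cut at mean +/- m * SD.}
#'   \item{dflc_min (10), mspike_low (1), mspike_dx (1), concord_dflc (5),
#'     concord_mspike (0.1), concord_cor (0.7)}{LCE classifier thresholds:
#'     dFLC > 10 mg/dL with M-spike < 1 g/dL, diagnosis M-spike > 1 g/dL, and
#'     the concordance-exclusion rule parameters.}
#'   \item{chromosomes}{Declared chromosome ordering.}
#'   \item{seed (1)}{Default simulation seed.}
#' }
#' @export
mmlce_config <- function(...) {
  defaults <- list(
    min_genes = 250L,
    max_mito = 0.10,
    scale_factor = 1e4,
    pseudocount = 1,
    vargene_fdr = 0.05,
    tau_type = 0.5,
    tau_igh = 0.25,
    tau_lc = 0.5,
    rho_lc = 5,
    de_min_pct = 0.10,
    de_n_min = 3L,
    bonferroni_universe = "all",
    l2fc_min = 1.0,
    p_adj_max = 0.05,
    signature_up_only = TRUE,
    cnv_window = 101L,
    cnv_clip = 1.0,
    gain_thr = 0.1,
    loss_thr = -0.1,
    k_max = 10L,
    silhouette_min = 0.1,
    match_min = 0.8,
    strat_m = 1.0,
    dflc_min = 10,
    mspike_low = 1,
    mspike_dx = 1,
    concord_dflc = 5,
    concord_mspike = 0.1,
    concord_cor = 0.7,
    chromosomes = default_chromosomes(),
    seed = 1L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "), call. = FALSE)
  defaults[names(over)] <- over
  structure(defaults, class = "mmlce_config")
}

#' @exportS3Method base::print
print.mmlce_config <- function(x, ...) {
  cat("<mmlce_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %s: %s\n", nm, paste(x[[nm]], collapse = ", ")))
  }
  invisible(x)
}

#' Write a configuration to YAML
#' @param config An [mmlce_config()] list.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a configuration from YAML
#' @param path YAML path written by [write_config()] (missing fields take
#'   their defaults).
#' @return An [mmlce_config()] list.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  int_fields <- c("min_genes", "de_n_min", "cnv_window", "k_max", "seed")
  for (f in intersect(int_fields, names(vals))) vals[[f]] <- as.integer(vals[[f]])
  do.call(mmlce_config, vals)
}
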