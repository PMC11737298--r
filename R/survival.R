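#' Two-group survival comparison
#'
#' Cox proportional-hazards fit with the group indicator as sole covariate
#' (Efron ties), Wald 95% confidence interval and p-value, Kaplan-Meier
#' per-group medians, and the log-rank test.
#'
#' @param cohort A [bulk_cohort] carrying the endpoint columns, or a data
#'   frame with `sample_id` plus `<endpoint>_time` / `<endpoint>_event`.
#' @param groups Tibble `sample_id`, `group` (two levels; the hazard ratio
#'   is for the second level relative to the first, so pass a factor with
#'   the reference level first, e.g. low then high). Samples missing the
#'   endpoint are dropped.
#' @param endpoint `"os"` (years) or `"lytic"` (days to diffuse osteolytic
#'   lesions).
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `mm_survfit`: list with `hr`, `ci_low`,
#'   `ci_high`, `p` (Wald), `logrank_stat`, `logrank_p`, `medians` (tibble
#'   `group`, `n`, `events`, `median`), `endpoint`, and the underlying
#'   `coxph` / `survfit` fits.
#' @export
compare_survival <- function(cohort, groups, endpoint = c("os", "lytic"),
                             conf_level = 0.95) {
  endpoint <- match.arg(endpoint)
  clin <- if (inherits(cohort, "bulk_cohort")) cohort$clinical else tibble::as_tibble(cohort)
  tcol <- paste0(endpoint, "_time")
  ecol <- paste0(endpoint, "_event")
  if (!all(c(tcol, ecol) %in% names(clin))) {
    stop("endpoint columns ", tcol, "/", ecol, " not found", call. = FALSE)
  }
  df <- dplyr::inner_join(
    tibble::as_tibble(groups), clin[, c("sample_id", tcol, ecol)], by = "sample_id"
  ) |>
    dplyr::rename(time = dplyr::all_of(tcol), event = dplyr::all_of(ecol)) |>
    dplyr::filter(!is.na(.data$time), !is.na(.data$event), !is.na(.data$group))
  if (!is.factor(df$group)) df$group <- factor(df$group)
  df$group <- droplevels(df$group)
  if (nlevels(df$group) != 2) stop("`groups` must define exactly two groups", call. = FALSE)
  ev <- tapply(df$event, df$group, sum)
  if (any(ev == 0)) {
    stop("no events in group ", paste(names(ev)[ev == 0], collapse = ", "),
         ": hazard ratio unestimable", call. = FALSE)
  }
  cox <- survival::coxph(
    survival::Surv(time, event) ~ group, data = df,
    ties = "efron"
  )
  sm <- summary(cox, conf.int = conf_level)
  km <- survival::survfit(survival::Surv(time, event) ~ group, data = df,
                          conf.int = conf_level)
  kt <- summary(km)$table
  medians <- tibble::tibble(
    group = levels(df$group),
    n = as.numeric(kt[, "records"]),
    events = as.numeric(kt[, "events"]),
    median = as.numeric(kt[, "median"])
  )
  lr <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  structure(
    list(
      hr = unname(sm$conf.int[1, "exp(coef)"]),
      ci_low = unname(sm$conf.int[1, 3]),
      ci_high = unname(sm$conf.int[1, 4]),
      p = unname(sm$coefficients[1, "Pr(>|z|)"]),
      logrank_stat = lr$chisq,
      logrank_p = stats::pchisq(lr$chisq, df = 1, lower.tail = FALSE),
      medians = medians,
      endpoint = endpoint,
      conf_level = conf_level,
      cox = cox,
      km = km
    ),
    class = "mm_survfit"
  )
}

#' @exportS3Method base::print
print.mm_survfit <- function(x, ...) {
  cat(sprintf(
    "<mm_survfit> endpoint %s: HR %.3g (%.0f%% CI %.3g-%.3g), Wald p %.3g; log-rank p %.3g\n",
    x$endpoint, x$hr, 100 * x$conf_level, x$ci_low, x$ci_high, x$p, x$logrank_p
  ))
  print(x$medians)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.mm_survfit <- function(x, ...) x$medians

#' @export
glance.mm_survfit <- function(x, ...) {
  tibble::tibble(
    endpoint = x$endpoint, hr = x$hr, ci_low = x$ci_low, ci_high = x$ci_high,
    p = x$p, logrank_stat = x$logrank_stat, logrank_p = x$logrank_p
  )
}

#' @export
tidy.subclone_model <- function(x, ...) x$labels

#' @export
glance.subclone_model <- function(x, ...) {
  tibble::tibble(k = x$k, silhouette = x$silhouette, n_cells = nrow(x$labels))
}

#' @export
tidy.mm_lesions <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x$table))
}

#' @export
glance.mm_lesions <- function(x, ...) {
  tibble::tibble(
    fisher_p = x$fisher_p, odds_ratio = x$odds_ratio,
    t_p = if (is.null(x$t_p)) NA_real_ else x$t_p,
    mean_high = if (is.null(x$mean_high)) NA_real_ else x$mean_high,
    mean_low = if (is.null(x$mean_low)) NA_real_ else x$mean_low
  )
}
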