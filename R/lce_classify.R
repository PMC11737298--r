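infer_isotype <- function(first_visit) {
  k <- first_visit$kappa
  l <- first_visit$lambda
  if (k == l) {
    stop(
      "isotype not inferable for patient ", first_visit$patient_id,
      ": equal kappa and lambda at diagnosis", call. = FALSE
    )
  }
  if (k > l) "kappa" else "lambda"
}

classify_one <- function(visits, dflc_min, mspike_low, mspike_dx,
                         concord_dflc, concord_mspike, concord_cor) {
  iso <- if ("affected_isotype" %in% names(visits) && !is.na(visits$affected_isotype[1])) {
    visits$affected_isotype[1]
  } else {
    infer_isotype(visits[1, ])
  }
  dflc <- if (iso == "kappa") visits$kappa - visits$lambda else visits$lambda - visits$kappa

  c1 <- any(dflc > dflc_min & visits$m_spike < mspike_low)
  c2 <- visits$m_spike[1] > mspike_dx

  d_dflc <- diff(dflc)
  d_m <- diff(visits$m_spike)
  rises <- which(d_dflc > concord_dflc)
  accompanied <- !length(rises) || all(d_m[rises] > concord_mspike)
  cc <- if (length(d_dflc) >= 2 && stats::sd(d_dflc) > 0 && stats::sd(d_m) > 0) {
    stats::cor(d_dflc, d_m)
  } else {
    NA_real_
  }
  c3 <- accompanied && !is.na(cc) && cc > concord_cor

  tibble::tibble(
    patient_id = visits$patient_id[1],
    affected_isotype = iso,
    c1 = c1, c2 = c2, c3_exclusion = c3,
    lce = c1 && c2 && !c3,
    max_dflc = max(dflc),
    dx_m_spike = visits$m_spike[1],
    change_cor = cc
  )
}

#' Classify light-chain escape from serial labs
#'
#' Applies the three-criterion rule per patient:
#' \enumerate{
#'   \item at one or more visits the involved-minus-uninvolved free light
#'     chain difference (dFLC) exceeds `dflc_min` (mg/dL) while the M-spike
#'     is below `mspike_low` (g/dL);
#'   \item the M-spike at diagnosis (the first visit) exceeds `mspike_dx`;
#'   \item exclusion when light-chain rises track M-spike rises: over
#'     consecutive-visit pairs, every dFLC increase above `concord_dflc` is
#'     accompanied by an M-spike increase above `concord_mspike` and the
#'     Pearson correlation of visit-to-visit changes exceeds `concord_cor`.
#' }
#' A patient is LCE when (1) and (2) hold and (3) does not. The affected
#' isotype is taken from an `affected_isotype` column when present,
#' otherwise inferred as the larger light chain at diagnosis (a tie is an
#' error).
#'
#' @param series A [clinical_series] tibble (>= 2 visits per patient).
#' @param dflc_min dFLC threshold, mg/dL (default 10).
#' @param mspike_low Concurrent M-spike ceiling, g/dL (default 1).
#' @param mspike_dx Diagnosis M-spike floor, g/dL (default 1).
#' @param concord_dflc,concord_mspike,concord_cor Concordance-exclusion
#'   parameters (defaults `dflc_min / 2`, 0.1 g/dL, 0.7).
#' @return Tibble of class `lce_calls`, one row per patient: `patient_id`,
#'   `affected_isotype`, criterion flags `c1`, `c2`, `c3_exclusion`, `lce`,
#'   plus `max_dflc`, `dx_m_spike`, `change_cor`.
#' @export
classify_lce <- function(series, dflc_min = 10, mspike_low = 1, mspike_dx = 1,
                         concord_dflc = dflc_min / 2, concord_mspike = 0.1,
                         concord_cor = 0.7) {
  stopifnot(inherits(series, "data.frame"))
  series <- clinical_series(series)
  n_visits <- table(series$patient_id)
  if (any(n_visits < 2)) {
    stop("every patient needs >= 2 visits; offending: ",
         paste(names(n_visits)[n_visits < 2], collapse = ", "), call. = FALSE)
  }
  out <- series |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::group_map(~ classify_one(
      .x |> dplyr::mutate(patient_id = .y$patient_id),
      dflc_min, mspike_low, mspike_dx,
      concord_dflc, concord_mspike, concord_cor
    )) |>
    dplyr::bind_rows()
  class(out) <- c("lce_calls", class(out))
  out
}
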