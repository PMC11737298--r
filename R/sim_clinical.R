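#' Specification for the serial-labs simulator
#'
#' Generates per-patient visit trajectories of M-spike (g/dL) and the
#' involved-minus-uninvolved free light chain difference (dFLC, mg/dL) under
#' three disease patterns:
#' \describe{
#'   \item{concordant}{M-spike and dFLC rise and fall together (dFLC is a
#'     fixed multiple of the M-spike), the usual intact-immunoglobulin
#'     relapse.}
#'   \item{lce}{A measurable M-spike at diagnosis, then relapse with rising
#'     dFLC while the M-spike stays suppressed — light-chain escape.}
#'   \item{light_chain_only}{No measurable M-spike at any point (light-chain
#'     disease from the outset; not escape).}
#' }
#'
#' @param seed Integer RNG seed.
#' @param n_patients Number of patients.
#' @param frac_lce Fraction with the LCE pattern.
#' @param frac_light_chain_only Fraction with light-chain-only disease; the
#'   remainder are concordant.
#' @param schedule Visit times in days, strictly increasing, first visit is
#'   diagnosis.
#' @param mspike_lce,dflc_lce Noiseless per-visit M-spike and dFLC for the
#'   LCE pattern (recycled/interpolated to the schedule length).
#' @param mspike_concordant Noiseless M-spike trajectory for concordant
#'   patients; their dFLC is `dflc_per_mspike` times it.
#' @param dflc_per_mspike dFLC (mg/dL) per g/dL of M-spike in concordant
#'   disease.
#' @param mspike_lco,dflc_lco Trajectories for light-chain-only patients.
#' @param mspike_noise_sd Measurement noise on M-spike, g/dL.
#' @param dflc_noise_sd Measurement noise on dFLC, mg/dL.
#' @param unaffected_level,unaffected_noise_sd Uninvolved light-chain level
#'   (mg/dL) and its noise.
#' @return A validated list of class `labs_sim_spec`.
#' @export
labs_sim_spec <- function(seed = 1,
                          n_patients = 40,
                          frac_lce = 0.5,
                          frac_light_chain_only = 0.1,
                          schedule = seq(0, 540, by = 90),
                          mspike_lce = c(2.0, 1.0, 0.4, 0.3, 0.3, 0.3, 0.3),
                          dflc_lce = c(25, 10, 5, 8, 25, 45, 70),
                          mspike_concordant = c(2.5, 1.2, 0.4, 0.3, 0.8, 1.8, 2.8),
                          dflc_per_mspike = 10,
                          mspike_lco = rep(0.2, 7),
                          dflc_lco = c(30, 15, 8, 12, 30, 50, 80),
                          mspike_noise_sd = 0.05,
                          dflc_noise_sd = 2,
                          unaffected_level = 1.2,
                          unaffected_noise_sd = 0.2) {
  if (frac_lce < 0 || frac_light_chain_only < 0 ||
      frac_lce + frac_light_chain_only > 1) {
    stop("pattern fractions must be non-negative and sum to at most 1", call. = FALSE)
  }
  if (any(diff(schedule) <= 0) || any(schedule < 0)) {
    stop("`schedule` must be non-negative and strictly increasing", call. = FALSE)
  }
  if (n_patients < 1) stop("`n_patients` must be >= 1", call. = FALSE)
  if (mspike_noise_sd < 0 || dflc_noise_sd < 0) stop("noise sds must be >= 0", call. = FALSE)
  structure(
    list(
      seed = seed, n_patients = n_patients, frac_lce = frac_lce,
      frac_light_chain_only = frac_light_chain_only, schedule = schedule,
      mspike_lce = mspike_lce, dflc_lce = dflc_lce,
      mspike_concordant = mspike_concordant, dflc_per_mspike = dflc_per_mspike,
      mspike_lco = mspike_lco, dflc_lco = dflc_lco,
      mspike_noise_sd = mspike_noise_sd, dflc_noise_sd = dflc_noise_sd,
      unaffected_level = unaffected_level, unaffected_noise_sd = unaffected_noise_sd
    ),
    class = "labs_sim_spec"
  )
}

fit_schedule <- function(values, n) {
  if (length(values) == n) return(values)
  stats::approx(seq_along(values), values, n = n)$y
}

#' Simulate serial clinical laboratory series
#'
#' Draws per-patient disease patterns, builds noiseless M-spike/dFLC
#' trajectories on the visit schedule, adds truncated Gaussian measurement
#' noise, and converts dFLC into kappa/lambda values around a constant
#' uninvolved level (the involved isotype is drawn per patient).
#'
#' @param spec A [labs_sim_spec()].
#' @return List with `labs` (a [clinical_series] tibble with columns
#'   `patient_id`, `t_days`, `m_spike`, `kappa`, `lambda`,
#'   `affected_isotype`) and `truth` (`patient_id`, `pattern`, `lce`).
#' @export
simulate_clinical_series <- function(spec) {
  stopifnot(inherits(spec, "labs_sim_spec"))
  with_preserved_seed(spec$seed, {
    n <- spec$n_patients
    n_lce <- round(n * spec$frac_lce)
    n_lco <- round(n * spec$frac_light_chain_only)
    pattern <- c(
      rep("lce", n_lce), rep("light_chain_only", n_lco),
      rep("concordant", n - n_lce - n_lco)
    )
    nv <- length(spec$schedule)
    ids <- sprintf("P%03d", seq_len(n))
    isotype <- sample(c("kappa", "lambda"), n, replace = TRUE)

    per_patient <- purrr::map(seq_len(n), function(i) {
      base <- switch(pattern[i],
        lce = list(
          m = fit_schedule(spec$mspike_lce, nv),
          d = fit_schedule(spec$dflc_lce, nv)
        ),
        concordant = {
          m <- fit_schedule(spec$mspike_concordant, nv)
          list(m = m, d = spec$dflc_per_mspike * m)
        },
        light_chain_only = list(
          m = fit_schedule(spec$mspike_lco, nv),
          d = fit_schedule(spec$dflc_lco, nv)
        )
      )
      m <- pmax(0, base$m + stats::rnorm(nv, 0, spec$mspike_noise_sd))
      d <- pmax(0, base$d + stats::rnorm(nv, 0, spec$dflc_noise_sd))
      unaff <- pmax(0, spec$unaffected_level + stats::rnorm(nv, 0, spec$unaffected_noise_sd))
      aff <- unaff + d
      tibble::tibble(
        patient_id = ids[i],
        t_days = spec$schedule,
        m_spike = m,
        kappa = if (isotype[i] == "kappa") aff else unaff,
        lambda = if (isotype[i] == "lambda") aff else unaff,
        affected_isotype = isotype[i]
      )
    })
    labs <- clinical_series(dplyr::bind_rows(per_patient))
    truth <- tibble::tibble(
      patient_id = ids, pattern = pattern, lce = pattern == "lce"
    )
    list(labs = labs, truth = truth)
  })
}
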