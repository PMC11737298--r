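mk_cohort <- function(expr_cols, clinical = NULL) {
  expr <- do.call(cbind, expr_cols)
  rownames(expr) <- sprintf("S%02d", seq_len(nrow(expr)))
  if (is.null(clinical)) clinical <- tibble::tibble(sample_id = rownames(expr))
  bulk_cohort(expr, clinical)
}

test_that("gene-set scores are summed cross-sample z-scores with the n-1 SD", {
  co <- mk_cohort(list(g1 = c(1, 2, 3)))
  sc <- geneset_score(co, gene_set("s", "g1"), verbose = FALSE)
  expect_equal(sc$score, c(-1, 0, 1))
  # a constant gene contributes zero everywhere
  co2 <- mk_cohort(list(g1 = c(1, 2, 3), flat = c(5, 5, 5)))
  sc2 <- geneset_score(co2, gene_set("s", c("g1", "flat")), verbose = FALSE)
  expect_equal(sc2$score, c(-1, 0, 1))
  # identical up and down expression columns cancel exactly
  co3 <- mk_cohort(list(a = c(1, 4, 9), b = c(1, 4, 9)))
  sc3 <- geneset_score(co3, gene_set("s", "a", "b"), verbose = FALSE)
  expect_equal(sc3$score, c(0, 0, 0))
  expect_error(
    geneset_score(co, gene_set("s", "missing"), verbose = FALSE),
    "no signature gene"
  )
})

test_that("scores are invariant to affine rescaling of cohort genes", {
  set.seed(81)
  expr <- matrix(rexp(200 * 30, 0.2), nrow = 200,
                 dimnames = list(sprintf("S%03d", 1:200), sprintf("g%02d", 1:30)))
  clin <- tibble::tibble(sample_id = rownames(expr))
  sig <- gene_set("s", sprintf("g%02d", 1:8), sprintf("g%02d", 9:12))
  base <- geneset_score(bulk_cohort(expr, clin), sig, verbose = FALSE)
  expr2 <- sweep(sweep(expr, 2, runif(30, 0.5, 3), `*`), 2, runif(30, 0, 10), `+`)
  rescaled <- geneset_score(bulk_cohort(expr2, clin), sig, verbose = FALSE)
  expect_equal(base$score, rescaled$score, tolerance = 1e-9)
})

test_that("stratification partitions samples with strict cuts and shrinks with m", {
  set.seed(82)
  sc <- tibble::tibble(sample_id = sprintf("S%05d", 1:10000), score = rnorm(10000))
  st1 <- stratify(sc, m = 1)
  counts <- table(st1$stratum)
  expect_equal(sum(counts), 10000)
  expect_lt(abs(counts[["high"]] / 10000 - 0.159), 0.01)
  st2 <- stratify(sc, m = 2)
  expect_lte(sum(st2$stratum == "high"), sum(st1$stratum == "high"))
  expect_lte(sum(st2$stratum == "low"), sum(st1$stratum == "low"))
  # m = 0: only exact-mean ties can be mid
  st0 <- stratify(sc, m = 0)
  expect_equal(sum(st0$stratum == "mid"), sum(sc$score == mean(sc$score)))
  # degenerate scores
  flat <- tibble::tibble(sample_id = c("a", "b", "c"), score = c(1, 1, 1))
  expect_warning(stf <- stratify(flat), "zero score SD")
  expect_true(all(stf$stratum == "mid"))
})

test_that("the three-criterion LCE rule reproduces its defining cases", {
  mk <- function(id, m, dflc) {
    tibble::tibble(
      patient_id = id, t_days = seq(0, by = 90, length.out = length(m)),
      m_spike = m, kappa = 1.2 + dflc, lambda = 1.2
    )
  }
  # escape at relapse: measurable M-spike at diagnosis, then dFLC rises alone
  esc <- mk("esc", c(1.5, 0.2), c(5, 59))
  # diagnosis M-spike too low: criterion (ii) fails
  lco <- mk("lco", c(0.5, 0.3), c(20, 80))
  # light-chain rises tracking M-spike rises: excluded by criterion (iii)
  conc <- mk("conc", c(1.5, 0.5, 2.5), c(20, 15, 80))
  calls <- classify_lce(dplyr::bind_rows(esc, lco, conc))
  expect_identical(calls$lce[calls$patient_id == "esc"], TRUE)
  expect_identical(calls$lce[calls$patient_id == "lco"], FALSE)
  expect_false(calls$c2[calls$patient_id == "lco"])
  expect_identical(calls$lce[calls$patient_id == "conc"], FALSE)
  expect_true(calls$c3_exclusion[calls$patient_id == "conc"])
  expect_true(calls$c1[calls$patient_id == "conc"])
})

test_that("the affected isotype is inferred from diagnosis and ties are an error", {
  la <- tibble::tibble(
    patient_id = "L", t_days = c(0, 90), m_spike = c(2, 0.3),
    kappa = c(1, 1), lambda = c(30, 60)
  )
  calls <- classify_lce(la)
  expect_identical(calls$affected_isotype, "lambda")
  tie <- tibble::tibble(
    patient_id = "T", t_days = c(0, 90), m_spike = c(2, 0.3),
    kappa = c(0, 10), lambda = c(0, 1)
  )
  expect_error(classify_lce(tie), "not inferable")
  single <- tibble::tibble(patient_id = "S", t_days = 0, m_spike = 2,
                           kappa = 10, lambda = 1)
  expect_error(classify_lce(single), ">= 2 visits")
})

test_that("the classifier is exact on noiseless trajectories and accurate under noise", {
  noisy <- simulate_clinical_series(labs_sim_spec(seed = 84, n_patients = 200))
  calls <- classify_lce(noisy$labs)
  truth <- noisy$truth$lce[match(calls$patient_id, noisy$truth$patient_id)]
  expect_gte(mean(calls$lce[truth]), 0.9)
  expect_gte(mean(!calls$lce[!truth]), 0.95)
})

test_that("identical survival groups give a unit hazard ratio and zero log-rank statistic", {
  times <- c(1, 2, 3, 4, 5, 6, 7, 8)
  events <- c(1, 1, 0, 1, 1, 0, 1, 1)
  clin <- tibble::tibble(
    sample_id = sprintf("S%02d", 1:16),
    os_time = rep(times, 2), os_event = rep(events, 2)
  )
  groups <- tibble::tibble(sample_id = clin$sample_id,
                           group = rep(c("a", "b"), each = 8))
  fit <- compare_survival(clin, groups, "os")
  expect_equal(fit$hr, 1, tolerance = 1e-8)
  expect_lt(fit$logrank_stat, 1e-10)
})

test_that("a planted hazard ratio of 3 is recovered at scale", {
  out <- simulate_bulk_cohort(cohort_sim_spec(
    seed = 86, n_samples = 2000, n_genes = 10, signature_genes = c("S1", "S2"),
    hr_os = 3, prevalence = 0.5
  ))
  groups <- tibble::tibble(
    sample_id = out$truth$sample_id,
    group = factor(ifelse(out$truth$latent_high, "high", "low"), c("low", "high"))
  )
  fit <- compare_survival(out$cohort, groups, "os")
  expect_gt(fit$hr, 2.6)
  expect_lt(fit$hr, 3.5)
})

test_that("an all-censored group is reported as unestimable", {
  clin <- tibble::tibble(
    sample_id = sprintf("S%02d", 1:10),
    os_time = 1:10, os_event = c(rep(1, 5), rep(0, 5))
  )
  groups <- tibble::tibble(sample_id = clin$sample_id,
                           group = rep(c("a", "b"), each = 5))
  expect_error(compare_survival(clin, groups, "os"), "unestimable")
})

test_that("lesion association matches the Fisher enumeration oracle", {
  mkscores <- function(strata) {
    tibble::tibble(sample_id = sprintf("S%02d", seq_along(strata)),
                   score = 0, stratum = strata)
  }
  clin <- tibble::tibble(
    sample_id = sprintf("S%02d", 1:10),
    lesion_category = rep(c(">=3", "0"), each = 5),
    lesion_count = c(5, 6, 4, 7, 5, 0, 1, 0, 2, 1)
  )
  expr <- matrix(1, nrow = 10, ncol = 1, dimnames = list(clin$sample_id, "g"))
  co <- bulk_cohort(expr, clin)
  la <- lesion_association(mkscores(rep(c("high", "low"), each = 5)), co)
  expect_equal(la$fisher_p, 2 / choose(10, 5))
  expect_equal(la$fisher_p, fisher_oracle(la$table))
  expect_lt(la$t_p, 0.05)
  # identical distributions: p = 1
  la2 <- lesion_association(mkscores(rep(c("high", "low"), 5)), co)
  expect_equal(la2$fisher_p, 1)

  # random small tables agree with the enumeration oracle
  set.seed(87)
  for (i in 1:10) {
    n <- sample(6:12, 1)
    strata <- sample(c("high", "low"), n, replace = TRUE)
    if (length(unique(strata)) < 2) strata[1:2] <- c("high", "low")
    lesions <- sample(c(">=3", "1"), n, replace = TRUE)
    clin_i <- tibble::tibble(
      sample_id = sprintf("S%02d", seq_len(n)), lesion_category = lesions
    )
    co_i <- bulk_cohort(
      matrix(1, nrow = n, ncol = 1, dimnames = list(clin_i$sample_id, "g")), clin_i
    )
    la_i <- lesion_association(mkscores(strata), co_i)
    expect_equal(la_i$fisher_p, fisher_oracle(la_i$table), tolerance = 1e-9)
  }
})

test_that("high-score strata are strongly enriched for the latent subgroup end to end", {
  out <- simulate_bulk_cohort(cohort_sim_spec(seed = 88, n_samples = 400))
  sig <- gene_set("LCE_MM_sig", sprintf("SIG%03d", 1:50))
  st <- stratify(geneset_score(out$cohort, sig, verbose = FALSE))
  latent <- out$truth$latent_high[match(st$sample_id, out$truth$sample_id)]
  p_high <- mean(latent[st$stratum == "high"])
  p_low <- if (any(st$stratum == "low")) mean(latent[st$stratum == "low"]) else 0
  expect_gte(p_high, 5 * p_low)
  expect_gte(p_high, 0.9)
})

test_that("survival and lesion results expose tidy and glance views", {
  out <- simulate_bulk_cohort(cohort_sim_spec(seed = 89, n_samples = 300, n_genes = 10,
                                              signature_genes = c("S1", "S2")))
  groups <- tibble::tibble(
    sample_id = out$truth$sample_id,
    group = factor(ifelse(out$truth$latent_high, "high", "low"), c("low", "high"))
  )
  fit <- compare_survival(out$cohort, groups, "os")
  g <- generics::glance(fit)
  expect_named(g, c("endpoint", "hr", "ci_low", "ci_high", "p", "logrank_stat", "logrank_p"))
  expect_true(g$ci_low <= g$hr && g$hr <= g$ci_high)
  expect_equal(nrow(generics::tidy(fit)), 2)
})
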