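# Shared fixtures, computed once per test run.

fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = fixture_env)) {
    assign(key, force(expr), envir = fixture_env)
  }
  get(key, envir = fixture_env)
}

# A moderate nine-population experiment used by typing/splitting/DE tests.
fix_sc <- function() {
  memo("sc", {
    spec <- sc_sim_spec(
      seed = 101,
      n_cells = c(
        LCE_MM = 600, IGH_MM = 300, T = 300, B = 120, NK = 120,
        monocyte = 200, RBC = 60, megakaryocyte = 40, progenitor = 60
      ),
      n_genes = 1200
    )
    sim <- simulate_single_cell(spec)
    norm <- normalize_counts(qc_filter(sim$counts, sim$annotation, verbose = FALSE))
    truth <- sim$truth[match(colnames(norm$values), sim$truth$barcode), ]
    list(sim = sim, norm = norm, truth = truth)
  })
}

# A CNV-oriented experiment at realistic expressed-gene density, with a
# subclonal chromosome 19 gain in 40% of LCE_MM cells.
fix_cnv <- function() {
  memo("cnv", {
    ev <- dplyr::bind_rows(
      default_cnv_events()[default_cnv_events()$event_id %in% c("gain_chr1", "loss_chr13"), ],
      tibble::tibble(
        event_id = "gain_chr19", population = "LCE_MM", chromosome = "19",
        multiplier = 1.5, carrier_fraction = 0.4
      )
    )
    spec <- sc_sim_spec(
      seed = 202,
      n_cells = c(LCE_MM = 800, IGH_MM = 200, T = 350, NK = 150, monocyte = 300),
      n_genes = 8000, cnv_events = ev
    )
    sim <- simulate_single_cell(spec)
    norm <- normalize_counts(qc_filter(sim$counts, sim$annotation, verbose = FALSE))
    truth <- sim$truth[match(colnames(norm$values), sim$truth$barcode), ]
    ref <- truth$barcode[!truth$population %in% c("LCE_MM", "IGH_MM")]
    cnv <- smooth_cnv(norm, sim$annotation, ref)
    list(sim = sim, norm = norm, truth = truth, ref = ref, cnv = cnv)
  })
}

subset_cnv <- function(cnv, barcodes) {
  out <- cnv
  out$signal <- cnv$signal[rownames(cnv$signal) %in% barcodes, , drop = FALSE]
  out
}

# Tiny hand-written sc_counts builder: `cols` is a named list of named count
# vectors (gene -> count), over the genes of `ann`.
tiny_counts <- function(cols, ann, sample = "s1") {
  m <- matrix(0L, nrow = nrow(ann), ncol = length(cols),
              dimnames = list(ann$gene_id, names(cols)))
  for (bc in names(cols)) {
    v <- cols[[bc]]
    m[names(v), bc] <- v
  }
  sc_counts(Matrix::Matrix(m, sparse = TRUE),
            tibble::tibble(barcode = names(cols), sample = sample))
}

# Exact hypergeometric enrichment oracle by subset enumeration: probability
# that a uniformly drawn query of size n from `universe_size` genes overlaps
# a fixed pathway of size K in at least k genes.
enrich_oracle <- function(k, K, n, universe_size) {
  genes <- seq_len(universe_size)
  hits <- utils::combn(genes, n, function(q) sum(q <= K) >= k)
  mean(hits)
}

# Exact two-sided Fisher oracle for a 2x2 table by enumeration over all
# tables with the same margins, summing probabilities <= observed.
fisher_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  prob <- function(a) {
    stats::dhyper(a, r1, r2, c1)
  }
  a_obs <- tab[1, 1]
  a_all <- max(0, c1 - r2):min(r1, c1)
  p_obs <- prob(a_obs)
  sum(vapply(a_all, prob, numeric(1))[vapply(a_all, prob, numeric(1)) <= p_obs * (1 + 1e-7)])
}
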