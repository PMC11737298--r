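test_that("qc_filter applies the detected-gene and mito-fraction rules with inclusive boundaries", {
  ann <- sim_gene_annotation(1200)
  nonmito <- ann$gene_id[!ann$is_mitochondrial]
  mito <- ann$gene_id[ann$is_mitochondrial]
  cols <- list(
    # 249 detected genes, no mito: removed (low RNA)
    low = setNames(rep(1L, 249), nonmito[1:249]),
    # 1000 genes, 25% mito reads: removed (high mito)
    himito = c(setNames(rep(1L, 987), nonmito[1:987]),
               setNames(c(317L, rep(1L, 12)), mito)),
    # exactly 250 genes and exactly 10% mito: retained
    boundary = c(setNames(rep(1L, 243), nonmito[1:243]),
                 setNames(c(21L, rep(1L, 6)), mito[1:7])),
    ok = setNames(rep(2L, 400), nonmito[1:400])
  )
  raw <- tiny_counts(cols, ann)
  qc <- qc_stats(raw, ann)
  expect_equal(qc$n_genes[qc$barcode == "boundary"], 250L)
  expect_equal(qc$mito_frac[qc$barcode == "boundary"], 0.10)
  filt <- qc_filter(raw, ann, verbose = FALSE)
  expect_setequal(colnames(filt$counts), c("boundary", "ok"))
  # genes unchanged
  expect_identical(rownames(filt$counts), rownames(raw$counts))
})

test_that("qc_filter is idempotent and errors when annotation misses genes", {
  fx <- fix_sc()
  once <- qc_filter(fx$sim$counts, fx$sim$annotation, verbose = FALSE)
  twice <- qc_filter(once, fx$sim$annotation, verbose = FALSE)
  expect_identical(colnames(once$counts), colnames(twice$counts))
  expect_error(
    qc_filter(fx$sim$counts, fx$sim$annotation[-1, ], verbose = FALSE),
    "annotation missing"
  )
})

test_that("normalization follows ln(1 + count/total * scale) exactly", {
  ann <- sim_gene_annotation(70)
  g <- ann$gene_id[!ann$is_mitochondrial][1:2]
  raw <- tiny_counts(list(
    c1 = setNames(c(2L, 0L), g),
    c2 = setNames(c(4L, 4L), g)
  ), ann)
  norm <- normalize_counts(raw, scale_factor = 10)
  expect_equal(norm$values[g[1], "c1"], log(1 + 2 / 2 * 10))
  expect_equal(norm$values[g[2], "c1"], 0)
  # doubling the scale factor strictly increases every nonzero value
  norm2 <- normalize_counts(raw, scale_factor = 20)
  nz <- as.matrix(norm$values) > 0
  expect_true(all(as.matrix(norm2$values)[nz] > as.matrix(norm$values)[nz]))
})

test_that("normalization refuses a zero-total cell by name", {
  ann <- sim_gene_annotation(70)
  g <- ann$gene_id[1]
  raw <- tiny_counts(list(full = setNames(1L, g), void = setNames(0L, g)), ann)
  expect_error(normalize_counts(raw), "void")
})

test_that("dropout-curve selection ignores ubiquitous genes and controls the null", {
  # genes lying exactly on a common Michaelis-Menten curve
  K <- 2
  set.seed(71)
  n_cells <- 400
  n_genes <- 300
  S <- runif(n_genes, 0.2, 8)
  d <- 1 - S / (K + S)
  on_value <- round(K + S)
  m <- sapply(seq_len(n_cells), function(i) {
    ifelse(runif(n_genes) < d, 0, on_value)
  })
  rownames(m) <- sprintf("g%03d", seq_len(n_genes))
  colnames(m) <- sprintf("c%03d", seq_len(n_cells))
  raw <- sc_counts(Matrix::Matrix(m, sparse = TRUE))
  res <- select_variable_genes(raw, fdr = 0.05)
  frac <- mean(res$variable)
  expect_lte(frac, 0.05 + 2 * sqrt(0.05 * 0.95 / n_genes))
  # a gene expressed in every cell can never be called variable
  allon <- res$variable[res$dropout == 0]
  expect_false(any(allon))

  # planted bimodal gene: on in 30% of cells at high mean
  m2 <- m
  m2[1, ] <- ifelse(runif(n_cells) < 0.3, 60L, 0L)
  res2 <- select_variable_genes(sc_counts(Matrix::Matrix(m2, sparse = TRUE)))
  expect_true(res2$variable[res2$gene_id == "g001"])
})

test_that("marker-rule typing recovers the planted populations", {
  fx <- fix_sc()
  ct <- assign_cell_types(fx$norm)
  truth_label <- ifelse(fx$truth$population %in% c("LCE_MM", "IGH_MM"), "MM",
                        fx$truth$population)
  expect_gte(mean(ct$label == truth_label), 0.95)
  expect_error(
    assign_cell_types(fx$norm, marker_map = list(T = "NOT_A_GENE")),
    "NOT_A_GENE"
  )
})

test_that("cells below the typing threshold stay unassigned", {
  ann <- sim_gene_annotation(70)
  raw <- tiny_counts(list(dull = setNames(1L, "G0005")), ann)
  norm <- normalize_counts(raw)
  ct <- assign_cell_types(norm)
  expect_identical(ct$label, "unassigned")
})

test_that("light-chain restriction follows the dominance-ratio contract", {
  ann <- sim_gene_annotation(70)
  mk <- function(k, l1) {
    raw <- tiny_counts(list(x = setNames(c(k, l1), c("IGKC", "IGLC1"))), ann)
    # scale-free check on the normalized values via direct construction
    normalize_counts(raw, scale_factor = 1)
  }
  r1 <- light_chain_restriction(mk(30L, 0L))
  expect_identical(r1$restriction, "kappa")
  ann2 <- sim_gene_annotation(70)
  raw0 <- tiny_counts(list(x = setNames(1L, "G0001")), ann2)
  r2 <- light_chain_restriction(normalize_counts(raw0))
  expect_identical(r2$restriction, "ambiguous")
  # near-equal scores fail the ratio test
  r3 <- light_chain_restriction(mk(10L, 9L), rho = 5)
  expect_identical(r3$restriction, "ambiguous")
})

test_that("the IGH split separates light-chain-only from intact-Ig myeloma", {
  fx <- fix_sc()
  mm <- fx$truth$barcode[fx$truth$population %in% c("LCE_MM", "IGH_MM")]
  sp <- split_mm(fx$norm, mm)
  truth <- fx$truth$population[match(mm, fx$truth$barcode)]
  expect_gte(mean(sp$label == truth), 0.98)
  # a cell with zero IGH constant expression must be LCE_MM
  zero_igh <- mm[Matrix::colSums(
    fx$norm$values[intersect(igh_constant_genes(), rownames(fx$norm$values)), mm]
  ) == 0]
  expect_true(all(sp$label[match(zero_igh, sp$barcode)] == "LCE_MM"))
  expect_error(split_mm(fx$norm, character()), "empty MM")
})

test_that("differential expression is null on identical groups and antisymmetric", {
  fx <- fix_sc()
  g1 <- fx$truth$barcode[fx$truth$population == "T"][1:60]
  # identical groups: copy the same cells under fresh barcodes
  v <- fx$norm$values[, c(g1, g1)]
  colnames(v) <- c(g1, paste0("copy_", g1))
  norm2 <- sc_norm(v, tibble::tibble(barcode = colnames(v), sample = "s"),
                   fx$norm$scale_factor)
  de0 <- differential_expression(norm2, g1, paste0("copy_", g1))
  expect_true(all(de0$l2fc == 0))
  expect_true(all(de0$p_adj == 1))

  g2 <- fx$truth$barcode[fx$truth$population == "NK"][1:60]
  de_ab <- differential_expression(fx$norm, g1, g2)
  de_ba <- differential_expression(fx$norm, g2, g1)
  expect_equal(de_ab$l2fc, -de_ba$l2fc, tolerance = 1e-9)
  expect_equal(de_ab$p, de_ba$p, tolerance = 1e-9)
})

test_that("Bonferroni adjustment dominates the raw p-value over the full universe", {
  fx <- fix_sc()
  g1 <- fx$truth$barcode[fx$truth$population == "T"][1:50]
  g2 <- fx$truth$barcode[fx$truth$population == "monocyte"][1:50]
  de <- differential_expression(fx$norm, g1, g2)
  m <- attr(de, "universe_size")
  expect_equal(m, nrow(fx$norm$values))
  expect_true(all(de$p_adj >= de$p))
  expect_true(all(de$p_adj[de$p >= 1 / m] == 1))
  expect_true(all(de$p_adj == pmin(1, de$p * m)))
})

test_that("a planted four-fold gene is recovered with accurate fold change", {
  progs <- list(LCE_MM = c(G0001 = 16, G0002 = 4), IGH_MM = c(G0001 = 4, G0002 = 4))
  spec <- sc_sim_spec(
    seed = 55, n_cells = c(LCE_MM = 500, IGH_MM = 500), n_genes = 400,
    marker_programs = progs, cnv_events = default_cnv_events()[0, ]
  )
  sim <- simulate_single_cell(spec)
  norm <- normalize_counts(sim$counts)
  pop <- sim$truth$population
  de <- differential_expression(norm, sim$truth$barcode[pop == "LCE_MM"],
                                sim$truth$barcode[pop == "IGH_MM"])
  hit <- de[de$gene_id == "G0001", ]
  expect_lt(hit$p_adj, 0.05)
  expect_lt(abs(hit$l2fc - 2), 0.3)
  null_gene <- de[de$gene_id == "G0002", ]
  expect_gt(null_gene$p_adj, 0.05)
})

test_that("gene-set definition applies the fold-change and significance thresholds", {
  de <- tibble::tibble(
    gene_id = c("LAMP5like", "weakfc", "weakp", "dn"),
    l2fc = c(1.68, 0.9, 1.5, -1.4),
    p = c(1e-140, 1e-12, 0.001, 1e-9),
    p_adj = c(6.68e-131, 1e-10, 0.06, 1e-6),
    pct_1 = 0.5, pct_2 = 0.5, direction = "up", fallback = FALSE
  )
  sig <- define_gene_set(de, "lce", l2fc_min = 1.0, p_adj_max = 0.05)
  expect_identical(sig$up, "LAMP5like")
  both <- define_gene_set(de, "lce", up_only = FALSE)
  expect_identical(both$down, "dn")
  empty <- de[de$p_adj > 0.5, ]
  expect_warning(out <- define_gene_set(empty), "no gene")
  expect_null(out)
})

test_that("hypergeometric enrichment matches closed forms and the null", {
  # universe 10, pathway 5, query 5, overlap 5: p = 1 / C(10,5)
  q <- gene_set("q", sprintf("g%d", 1:5))
  pw <- list(gene_set("hit", sprintf("g%d", 1:5)))
  res <- enrich(q, pw, universe = sprintf("g%d", 1:10))
  expect_equal(res$p, 1 / choose(10, 5))
  # zero overlap in a large universe: p ~ 1
  pw2 <- list(gene_set("miss", c("h1", "h2")))
  res2 <- enrich(q, pw2, universe = c(sprintf("g%d", 1:5), c("h1", "h2"), sprintf("x%d", 1:993)))
  expect_gt(res2$p, 0.99)
  # genes outside the universe are excluded with a warning
  expect_warning(
    enrich(gene_set("q", c("g1", "zz")), pw, universe = sprintf("g%d", 1:10)),
    "outside the universe"
  )
})

test_that("enrichment p-values agree with a subset-enumeration oracle", {
  for (cfg in list(c(8, 3, 4, 2), c(10, 4, 3, 1), c(12, 6, 5, 3))) {
    N <- cfg[1]; K <- cfg[2]; n <- cfg[3]; k <- cfg[4]
    q <- gene_set("q", c(sprintf("in%d", seq_len(k)), sprintf("out%d", seq_len(n - k))))
    pw <- list(gene_set("p", c(sprintf("in%d", seq_len(k)), sprintf("pw%d", seq_len(K - k)))))
    univ <- unique(c(q$up, pw[[1]]$up, sprintf("bg%d", seq_len(N))))[seq_len(N)]
    res <- enrich(q, pw, universe = univ)
    expect_equal(res$p, enrich_oracle(k, K, n, N), tolerance = 1e-12)
  }
})

test_that("per-cell signature scoring separates a planted program", {
  fx <- fix_sc()
  sig <- gene_set("lce", c("LAMP5", "MYC", "FABP5"))
  mm <- fx$truth$barcode[fx$truth$population %in% c("LCE_MM", "IGH_MM")]
  sc <- signature_score_cells(fx$norm, sig)
  scores <- sc$score[match(mm, sc$barcode)]
  pop <- fx$truth$population[match(mm, fx$truth$barcode)]
  expect_gt(median(scores[pop == "LCE_MM"]), median(scores[pop == "IGH_MM"]))
  expect_lt(stats::wilcox.test(scores[pop == "LCE_MM"], scores[pop == "IGH_MM"])$p.value, 0.01)
  # empty down list means the score is just the mean of up genes
  one <- gene_set("up1", "LAMP5")
  s1 <- signature_score_cells(fx$norm, one)
  expect_equal(s1$score, as.numeric(fx$norm$values["LAMP5", ]))
  expect_error(signature_score_cells(fx$norm, gene_set("none", "ABSENT")), "no signature gene")
})

test_that("end-to-end signature recovery finds the planted over-expressed genes", {
  planted <- sprintf("G%04d", 1:20)
  progs <- list(
    LCE_MM = setNames(rep(4 * 2^1.5, 20), planted),
    IGH_MM = setNames(rep(4, 20), planted)
  )
  spec <- sc_sim_spec(
    seed = 77, n_cells = c(LCE_MM = 600, IGH_MM = 500), n_genes = 600,
    marker_programs = progs, cnv_events = default_cnv_events()[0, ]
  )
  sim <- simulate_single_cell(spec)
  norm <- normalize_counts(sim$counts)
  pop <- sim$truth$population
  de <- differential_expression(norm, sim$truth$barcode[pop == "LCE_MM"],
                                sim$truth$barcode[pop == "IGH_MM"])
  sig <- define_gene_set(de, "recovered", l2fc_min = 1.0, p_adj_max = 0.05)
  sens <- length(intersect(sig$up, planted)) / length(planted)
  fdr <- length(setdiff(sig$up, planted)) / max(1, length(sig$up))
  expect_gte(sens, 0.9)
  expect_lte(fdr, 0.1)
})
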