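#' @keywords internal
with_preserved_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

sim_populations <- function() {
  c("LCE_MM", "IGH_MM", "T", "B", "NK", "monocyte", "RBC", "megakaryocyte", "progenitor")
}

#' Canonical marker gene map
#'
#' Cell-type markers used both by the simulator and as the default for
#' [assign_cell_types()]: CD3 for T cells, MS4A1 (CD20) for B cells, NKG7 for
#' NK, HBB/HBA1 for red cells, PPBP for megakaryocytes, CD14 for monocytes,
#' CD34 for progenitors, and CD38/SDC1 (CD138) plus IGKC for myeloma.
#'
#' @return Named list label -> character vector of marker genes.
#' @export
default_marker_map <- function() {
  list(
    T = c("CD3D", "CD3E"),
    B = "MS4A1",
    NK = "NKG7",
    RBC = c("HBB", "HBA1"),
    megakaryocyte = "PPBP",
    monocyte = "CD14",
    progenitor = "CD34",
    MM = c("CD38", "SDC1", "IGKC")
  )
}

#' Immunoglobulin heavy-chain constant-region genes
#' @return Character vector (IGHG1-4, IGHA1-2, IGHM, IGHD, IGHE).
#' @export
igh_constant_genes <- function() {
  c("IGHG1", "IGHG2", "IGHG3", "IGHG4", "IGHA1", "IGHA2", "IGHM", "IGHD", "IGHE")
}

#' Kappa / lambda light-chain genes
#' @return List with elements `kappa` and `lambda`.
#' @export
light_chain_genes <- function() {
  list(kappa = "IGKC", lambda = c("IGLC1", "IGLC2"))
}

mito_gene_names <- function() {
  paste0("MT-", c(
    "ND1", "ND2", "CO1", "CO2", "ATP8", "ATP6", "CO3",
    "ND3", "ND4L", "ND4", "ND5", "ND6", "CYB"
  ))
}

named_gene_chromosomes <- function() {
  c(
    CD3D = "11", CD3E = "11", MS4A1 = "11", NKG7 = "19", HBB = "11", HBA1 = "16",
    PPBP = "4", CD14 = "5", CD34 = "1", CD38 = "4", SDC1 = "2",
    IGKC = "2", IGLC1 = "22", IGLC2 = "22",
    IGHG1 = "14", IGHG2 = "14", IGHG3 = "14", IGHG4 = "14",
    IGHA1 = "14", IGHA2 = "14", IGHM = "14", IGHD = "14", IGHE = "14",
    LAMP5 = "20", MYC = "8", FABP5 = "8", ATF5 = "19"
  )
}

#' Build the simulator's gene annotation
#'
#' Places the named marker/immunoglobulin/mitochondrial genes on plausible
#' chromosomes and distributes filler genes evenly over autosomes 1-22, so
#' every autosome carries enough genes for CNV smoothing.
#'
#' @param n_genes Total number of genes (>= 60).
#' @return A `gene_annotation` tibble.
#' @export
sim_gene_annotation <- function(n_genes = 2000) {
  named <- named_gene_chromosomes()
  mito <- mito_gene_names()
  n_named <- length(named) + length(mito)
  if (n_genes < n_named + 22) stop("n_genes too small for the named gene layout", call. = FALSE)
  n_fill <- n_genes - n_named
  fill_chr <- as.character(rep_len(1:22, n_fill))
  df <- tibble::tibble(
    gene_id = c(names(named), mito, sprintf("G%04d", seq_len(n_fill))),
    chromosome = c(unname(named), rep("MT", length(mito)), fill_chr),
    is_mitochondrial = c(
      rep(FALSE, length(named)), rep(TRUE, length(mito)), rep(FALSE, n_fill)
    )
  )
  df <- df |>
    dplyr::group_by(.data$chromosome) |>
    dplyr::mutate(start_bp = 100000L * dplyr::row_number()) |>
    dplyr::ungroup()
  gene_annotation(df)
}

default_marker_programs <- function() {
  markers <- default_marker_map()
  lc <- light_chain_genes()
  igh <- igh_constant_genes()
  type_markers <- markers[setdiff(names(markers), "MM")]
  all_marked <- unique(c(unlist(markers), unlist(lc), igh))

  base_prog <- function() stats::setNames(rep(0.1, length(all_marked)), all_marked)

  progs <- list()
  for (pop in sim_populations()) {
    p <- base_prog()
    if (pop %in% names(type_markers)) p[type_markers[[pop]]] <- 40
    if (pop %in% c("LCE_MM", "IGH_MM")) {
      p[c("CD38", "SDC1")] <- 40
      p["IGKC"] <- 160                       # kappa-restricted clone
      p[unlist(lc["lambda"])] <- 0.1
      if (pop == "LCE_MM") {
        p[igh] <- 0                          # no detectable IGH expression
        p["LAMP5"] <- 2^1.68
        p["MYC"] <- 2^2.06
        p["FABP5"] <- 2^1.3
      } else {
        p["IGHG1"] <- 60
        p[setdiff(igh, "IGHG1")] <- 20
        p["MYC"] <- 2^1.0
      }
    }
    if (pop == "B") {
      p["IGKC"] <- 6
      p[unlist(lc["lambda"])] <- 6
      p[c("IGHM", "IGHD")] <- 8
    }
    progs[[pop]] <- p
  }
  progs
}

#' Default planted copy-number events
#'
#' Emulates the study's clonal chromosome 1 gain and chromosome 13 loss in
#' both myeloma subpopulations, plus subclonal chromosome 19 and 22 gains
#' largely confined to the light-chain-escape subpopulation.
#'
#' @return Tibble with columns `event_id`, `population`, `chromosome`,
#'   `multiplier`, `carrier_fraction`.
#' @export
default_cnv_events <- function() {
  tibble::tribble(
    ~event_id,    ~population, ~chromosome, ~multiplier, ~carrier_fraction,
    "gain_chr1",  "LCE_MM",    "1",         1.5,         1.0,
    "gain_chr1",  "IGH_MM",    "1",         1.5,         1.0,
    "loss_chr13", "LCE_MM",    "13",        0.5,         1.0,
    "loss_chr13", "IGH_MM",    "13",        0.5,         1.0,
    "gain_chr19", "LCE_MM",    "19",        1.5,         0.6,
    "gain_chr22", "LCE_MM",    "22",        1.5,         0.4
  )
}

#' Specification for the single-cell simulator
#'
#' Defaults reproduce the study conditions: 4,370 light-chain-escape and 281
#' intact-IGH myeloma cells among marker-defined normal bone-marrow
#' populations, negative-binomial UMI counts, Beta-distributed mitochondrial
#' fractions, and multiplicative chromosome-level CNV dosage (gain x1.5,
#' loss x0.5) defining subclones.
#'
#' @param seed Integer RNG seed.
#' @param n_cells Named integer vector of cells per population (names from
#'   `LCE_MM, IGH_MM, T, B, NK, monocyte, RBC, megakaryocyte, progenitor`;
#'   zero-cell populations may be omitted).
#' @param n_genes Total genes in the scaled transcriptome.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters for per-gene
#'   baseline mean counts.
#' @param nb_size Negative-binomial size (inverse dispersion), shared by all
#'   genes.
#' @param marker_programs Named list population -> named multiplier vector
#'   (gene -> fold change on the baseline mean). Defaults plant the marker
#'   map, the kappa-restricted IGKC program, absent IGH constant genes in
#'   LCE_MM, and LAMP5/MYC/FABP5 over-expression in LCE_MM.
#' @param mito_mean,mito_conc Beta mean/concentration of the per-cell target
#'   mitochondrial read fraction.
#' @param cnv_events Tibble of planted dosage events; see
#'   [default_cnv_events()].
#' @param lib_meanlog,lib_sdlog Log-normal per-cell library-size factor.
#' @param n_low_gene_cells,n_high_mito_cells Planted QC-failure cells:
#'   low-RNA cells (library scaled by `low_gene_factor`) and high-mito cells
#'   (target fraction Beta(`high_mito_mean`, `high_mito_conc`)).
#' @param low_gene_factor,high_mito_mean,high_mito_conc See above.
#' @param doublet_fraction Optional fraction of cells replaced by random
#'   same-sample cell-pair mixtures (off by default).
#' @param sample_label Sample/timepoint label stamped on every cell.
#' @return A validated list of class `sc_sim_spec`.
#' @export
sc_sim_spec <- function(seed = 1,
                        n_cells = c(
                          LCE_MM = 4370, IGH_MM = 281, T = 1500, B = 300,
                          NK = 400, monocyte = 800, RBC = 200,
                          megakaryocyte = 100, progenitor = 150
                        ),
                        n_genes = 2000,
                        baseline_meanlog = -1, baseline_sdlog = 1,
                        nb_size = 10,
                        marker_programs = default_marker_programs(),
                        mito_mean = 0.04, mito_conc = 600,
                        cnv_events = default_cnv_events(),
                        lib_meanlog = 0, lib_sdlog = 0.25,
                        n_low_gene_cells = 0, n_high_mito_cells = 0,
                        low_gene_factor = 0.05,
                        high_mito_mean = 0.30, high_mito_conc = 300,
                        doublet_fraction = 0,
                        sample_label = "tp1") {
  if (is.null(names(n_cells)) || !all(names(n_cells) %in% sim_populations())) {
    stop("`n_cells` must be named with populations from sim_populations()", call. = FALSE)
  }
  if (any(n_cells < 0) || any(n_cells != round(n_cells))) {
    stop("`n_cells` must be non-negative integers", call. = FALSE)
  }
  if (sum(n_cells) < 1) stop("at least one cell required", call. = FALSE)
  stopifnot(nb_size > 0, n_genes >= 60)
  if (mito_mean <= 0 || mito_mean >= 1 || high_mito_mean <= 0 || high_mito_mean >= 1) {
    stop("mitochondrial fraction means must lie in (0, 1)", call. = FALSE)
  }
  cnv_events <- tibble::as_tibble(cnv_events)
  if (nrow(cnv_events)) {
    need <- c("event_id", "population", "chromosome", "multiplier", "carrier_fraction")
    stopifnot(all(need %in% names(cnv_events)))
    if (any(cnv_events$multiplier <= 0)) stop("CNV dosage multiplier must be > 0", call. = FALSE)
    if (any(cnv_events$carrier_fraction < 0 | cnv_events$carrier_fraction > 1)) {
      stop("CNV carrier fraction must lie in [0, 1]", call. = FALSE)
    }
  }
  if (doublet_fraction < 0 || doublet_fraction > 0.5) {
    stop("`doublet_fraction` must lie in [0, 0.5]", call. = FALSE)
  }
  structure(
    list(
      seed = seed, n_cells = n_cells, n_genes = n_genes,
      baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog,
      nb_size = nb_size, marker_programs = marker_programs,
      mito_mean = mito_mean, mito_conc = mito_conc,
      cnv_events = cnv_events,
      lib_meanlog = lib_meanlog, lib_sdlog = lib_sdlog,
      n_low_gene_cells = n_low_gene_cells, n_high_mito_cells = n_high_mito_cells,
      low_gene_factor = low_gene_factor,
      high_mito_mean = high_mito_mean, high_mito_conc = high_mito_conc,
      doublet_fraction = doublet_fraction,
      sample_label = sample_label
    ),
    class = "sc_sim_spec"
  )
}

beta_shapes <- function(mean, conc) c(shape1 = mean * conc, shape2 = (1 - mean) * conc)

#' Simulate a single-cell RNA-seq experiment
#'
#' Draws gene-wise negative-binomial counts with mean
#' `baseline x population multiplier x CNV dosage x library factor`, then
#' rescales the mitochondrial genes of each cell so their expected share of
#' the library matches a Beta-distributed target fraction. Reproducible for a
#' fixed seed; the caller's RNG state is left untouched.
#'
#' @param spec An [sc_sim_spec()].
#' @return List with elements `counts` ([sc_counts]), `annotation`
#'   (`gene_annotation`), and `truth`: a tibble with `barcode`, `population`,
#'   `qc_class` (`"ok"`, `"low_gene"`, `"high_mito"`), `mito_target`, and one
#'   logical `carrier_<event_id>` column per planted CNV event.
#' @export
simulate_single_cell <- function(spec) {
  stopifnot(inherits(spec, "sc_sim_spec"))
  with_preserved_seed(spec$seed, {
    ann <- sim_gene_annotation(spec$n_genes)
    genes <- ann$gene_id
    n_genes <- length(genes)
    mito_idx <- which(ann$is_mitochondrial)

    base_mean <- stats::rlnorm(n_genes, spec$baseline_meanlog, spec$baseline_sdlog)
    names(base_mean) <- genes
    # Marked genes get a fixed, well-detected baseline so planted fold
    # changes are interpretable on the count scale.
    marked <- intersect(unique(unlist(lapply(spec$marker_programs, names))), genes)
    base_mean[marked] <- 0.5
    base_mean[mito_idx] <- 0.5

    n_cells <- spec$n_cells[spec$n_cells > 0]
    pops <- rep(names(n_cells), times = n_cells)
    n_main <- length(pops)
    n_low <- spec$n_low_gene_cells
    n_high <- spec$n_high_mito_cells
    if (n_low + n_high > 0) {
      planted_pops <- sample(names(n_cells), n_low + n_high, replace = TRUE)
      pops <- c(pops, planted_pops)
    }
    n_total <- length(pops)
    qc_class <- rep("ok", n_total)
    if (n_low) qc_class[n_main + seq_len(n_low)] <- "low_gene"
    if (n_high) qc_class[n_main + n_low + seq_len(n_high)] <- "high_mito"
    barcodes <- sprintf("%s_cell%05d", spec$sample_label, seq_len(n_total))

    lib <- stats::rlnorm(n_total, spec$lib_meanlog, spec$lib_sdlog)
    lib[qc_class == "low_gene"] <- lib[qc_class == "low_gene"] * spec$low_gene_factor

    sh_ok <- beta_shapes(spec$mito_mean, spec$mito_conc)
    mito_target <- stats::rbeta(n_total, sh_ok[1], sh_ok[2])
    if (n_high) {
      sh_hi <- beta_shapes(spec$high_mito_mean, spec$high_mito_conc)
      hi <- qc_class == "high_mito"
      mito_target[hi] <- stats::rbeta(sum(hi), sh_hi[1], sh_hi[2])
    }

    # population-specific expected means (genes x cells)
    mu <- matrix(base_mean, nrow = n_genes, ncol = n_total)
    for (pop in unique(pops)) {
      prog <- spec$marker_programs[[pop]]
      if (is.null(prog)) next
      hit <- intersect(names(prog), genes)
      if (length(hit)) {
        mu[match(hit, genes), pops == pop] <-
          mu[match(hit, genes), pops == pop, drop = FALSE] * prog[hit]
      }
    }

    # planted CNV dosage
    ev <- spec$cnv_events
    carrier <- matrix(FALSE, nrow = n_total, ncol = 0)
    if (nrow(ev)) {
      event_ids <- unique(ev$event_id)
      carrier <- matrix(FALSE, nrow = n_total, ncol = length(event_ids),
                        dimnames = list(NULL, event_ids))
      for (r in seq_len(nrow(ev))) {
        in_pop <- which(pops == ev$population[r])
        if (!length(in_pop)) next
        is_carrier <- in_pop[stats::runif(length(in_pop)) < ev$carrier_fraction[r]]
        if (!length(is_carrier)) next
        carrier[is_carrier, ev$event_id[r]] <- TRUE
        chr_genes <- which(as.character(ann$chromosome) == ev$chromosome[r])
        mu[chr_genes, is_carrier] <- mu[chr_genes, is_carrier, drop = FALSE] * ev$multiplier[r]
      }
    }

    mu <- sweep(mu, 2, lib, `*`)

    # rescale mitochondrial means to the per-cell target fraction
    nonmito_tot <- colSums(mu[-mito_idx, , drop = FALSE])
    mito_tot <- colSums(mu[mito_idx, , drop = FALSE])
    scale <- mito_target / (1 - mito_target) * nonmito_tot / pmax(mito_tot, 1e-12)
    mu[mito_idx, ] <- sweep(mu[mito_idx, , drop = FALSE], 2, scale, `*`)

    counts <- matrix(
      stats::rnbinom(length(mu), mu = mu, size = spec$nb_size),
      nrow = n_genes, dimnames = list(genes, barcodes)
    )

    if (spec$doublet_fraction > 0) {
      n_dbl <- floor(spec$doublet_fraction * n_total)
      if (n_dbl > 0) {
        tgt <- sample(n_total, n_dbl)
        src <- sample(n_total, n_dbl, replace = TRUE)
        counts[, tgt] <- counts[, tgt, drop = FALSE] + counts[, src, drop = FALSE]
        qc_class[tgt] <- "doublet"
      }
    }

    truth <- tibble::tibble(
      barcode = barcodes, population = pops, qc_class = qc_class,
      mito_target = mito_target
    )
    if (ncol(carrier)) {
      for (eid in colnames(carrier)) truth[[paste0("carrier_", eid)]] <- carrier[, eid]
    }

    cells <- tibble::tibble(barcode = barcodes, sample = spec$sample_label)
    list(
      counts = sc_counts(Matrix::Matrix(counts, sparse = TRUE), cells),
      annotation = ann,
      truth = truth
    )
  })
}
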