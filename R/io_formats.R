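#' Default chromosome ordering
#'
#' Autosomes 1..22 followed by X, Y and MT. Genome-ordered operations (CNV
#' smoothing) concatenate chromosomes in this order.
#'
#' @return Character vector of chromosome labels.
#' @export
default_chromosomes <- function() c(as.character(1:22), "X", "Y", "MT")

first_existing <- function(dir_path, stems) {
  for (s in stems) {
    p <- file.path(dir_path, s)
    if (file.exists(p)) return(p)
  }
  NA_character_
}

#' Read a 10x-style MatrixMarket count triple
#'
#' Reads `matrix.mtx`, `features.tsv` and `barcodes.tsv` (each optionally
#' `.gz`-compressed) from a directory, the plain-triple convention used by
#' feature-barcode pipelines.
#'
#' @param dir_path Directory holding the triple.
#' @param cell_sample Optional per-cell sample/timepoint labels, either a
#'   vector (one per barcode) or the name of a TSV file `cells.tsv` column.
#'   When a `cells.tsv` with columns barcode/sample exists in `dir_path` it is
#'   used automatically.
#' @return An [sc_counts] object.
#' @export
read_counts_mtx <- function(dir_path, cell_sample = NULL) {
  mtx <- first_existing(dir_path, c("matrix.mtx", "matrix.mtx.gz"))
  feat <- first_existing(dir_path, c("features.tsv", "features.tsv.gz", "genes.tsv", "genes.tsv.gz"))
  bc <- first_existing(dir_path, c("barcodes.tsv", "barcodes.tsv.gz"))
  missing <- c(matrix.mtx = mtx, features.tsv = feat, barcodes.tsv = bc)
  if (anyNA(missing)) {
    stop(
      "missing file(s) in MTX triple: ",
      paste(names(missing)[is.na(missing)], collapse = ", "),
      call. = FALSE
    )
  }
  m <- Matrix::readMM(mtx)
  features <- readr::read_tsv(feat, col_names = FALSE, show_col_types = FALSE, progress = FALSE)
  barcodes <- readr::read_tsv(bc, col_names = FALSE, show_col_types = FALSE, progress = FALSE)
  gene_ids <- as.character(features[[1]])
  bcs <- as.character(barcodes[[1]])
  if (nrow(m) != length(gene_ids)) {
    stop(sprintf(
      "matrix declares %d genes but features.tsv has %d rows", nrow(m), length(gene_ids)
    ), call. = FALSE)
  }
  if (ncol(m) != length(bcs)) {
    stop(sprintf(
      "matrix declares %d cells but barcodes.tsv has %d rows", ncol(m), length(bcs)
    ), call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) stop("duplicate gene id in features.tsv", call. = FALSE)
  if (anyDuplicated(bcs)) stop("duplicate barcode in barcodes.tsv", call. = FALSE)
  dimnames(m) <- list(gene_ids, bcs)

  cells <- NULL
  cells_path <- first_existing(dir_path, c("cells.tsv", "cells.tsv.gz"))
  if (!is.null(cell_sample)) {
    if (length(cell_sample) != length(bcs)) {
      stop("`cell_sample` must have one label per barcode", call. = FALSE)
    }
    cells <- tibble::tibble(barcode = bcs, sample = as.character(cell_sample))
  } else if (!is.na(cells_path)) {
    cells <- readr::read_tsv(cells_path, show_col_types = FALSE, progress = FALSE)
  }
  sc_counts(m, cells)
}

#' Write a 10x-style MatrixMarket count triple
#'
#' @param x An [sc_counts] object.
#' @param dir_path Output directory (created if needed). Writes `matrix.mtx`,
#'   `features.tsv`, `barcodes.tsv` and `cells.tsv` (barcode, sample).
#' @return `dir_path`, invisibly.
#' @export
write_counts_mtx <- function(x, dir_path) {
  stopifnot(inherits(x, "sc_counts"))
  dir.create(dir_path, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(x$counts, file.path(dir_path, "matrix.mtx"))
  writeLines(rownames(x$counts), file.path(dir_path, "features.tsv"))
  writeLines(colnames(x$counts), file.path(dir_path, "barcodes.tsv"))
  readr::write_tsv(x$cells, file.path(dir_path, "cells.tsv"), progress = FALSE)
  invisible(dir_path)
}

#' Read a gene annotation table
#'
#' Expects a TSV with columns `gene_id`, `chromosome`, `start` (1-based) and
#' optionally `mito_flag` (logical/0-1). Only the start coordinate is kept:
#' CNV smoothing needs genomic ordering, not spans. When `mito_flag` is
#' absent, mitochondrial genes are identified by the `"MT-"` prefix fallback
#' with a warning.
#'
#' @param path TSV path.
#' @param chromosomes Declared chromosome ordering; labels outside it are an
#'   error. Default [default_chromosomes()].
#' @return Tibble of class `gene_annotation` with columns `gene_id`,
#'   `chromosome` (factor in declared order), `start_bp`,
#'   `is_mitochondrial`, sorted by chromosome then start.
#' @export
read_gene_annotation <- function(path, chromosomes = default_chromosomes()) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("gene_id", "chromosome", "start") %in% names(raw))) {
    stop("annotation needs columns gene_id, chromosome, start", call. = FALSE)
  }
  if (!"mito_flag" %in% names(raw)) {
    warning("no `mito_flag` column; falling back to the 'MT-' gene-name prefix")
    raw$mito_flag <- startsWith(raw$gene_id, "MT-")
  }
  gene_annotation(
    tibble::tibble(
      gene_id = as.character(raw$gene_id),
      chromosome = as.character(raw$chromosome),
      start_bp = raw$start,
      is_mitochondrial = as.logical(raw$mito_flag)
    ),
    chromosomes = chromosomes
  )
}

#' Construct/validate a gene annotation
#'
#' @param df Data frame with columns `gene_id`, `chromosome`, `start_bp`,
#'   `is_mitochondrial`.
#' @inheritParams read_gene_annotation
#' @return Validated, genome-sorted `gene_annotation` tibble.
#' @export
gene_annotation <- function(df, chromosomes = default_chromosomes()) {
  df <- tibble::as_tibble(df)
  stopifnot(all(c("gene_id", "chromosome", "start_bp", "is_mitochondrial") %in% names(df)))
  if (anyDuplicated(df$gene_id)) stop("duplicate gene_id in annotation", call. = FALSE)
  bad <- setdiff(unique(as.character(df$chromosome)), chromosomes)
  if (length(bad)) {
    stop("unknown chromosome label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(df$start_bp < 1)) stop("gene starts are 1-based: start_bp must be >= 1", call. = FALSE)
  df$chromosome <- factor(as.character(df$chromosome), levels = chromosomes)
  df <- dplyr::arrange(df, .data$chromosome, .data$start_bp)
  class(df) <- c("gene_annotation", class(df))
  df
}

#' Write a gene annotation table
#' @param ann A `gene_annotation` tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(ann, path) {
  out <- tibble::tibble(
    gene_id = ann$gene_id,
    chromosome = as.character(ann$chromosome),
    start = ann$start_bp,
    mito_flag = ann$is_mitochondrial
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read serial clinical labs
#'
#' Long-format CSV with one row per visit: `patient_id`, `t_days`,
#' `m_spike` (g/dL), `kappa` (mg/dL), `lambda` (mg/dL), optional `calcium`
#' and optional per-patient `affected_isotype` ("kappa"/"lambda"). Units are
#' fixed by this schema; callers must convert before reading.
#'
#' @param path CSV path.
#' @return Tibble of class `clinical_series` sorted by patient then visit
#'   time; the first visit of each patient is taken as diagnosis.
#' @export
read_clinical_series <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  clinical_series(raw)
}

#' Construct/validate serial clinical labs
#' @param df Long-format visits data frame (see [read_clinical_series()]).
#' @return Validated `clinical_series` tibble.
#' @export
clinical_series <- function(df) {
  df <- tibble::as_tibble(df)
  need <- c("patient_id", "t_days", "m_spike", "kappa", "lambda")
  if (!all(need %in% names(df))) {
    stop("clinical series needs columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  labs <- c("t_days", "m_spike", "kappa", "lambda")
  for (col in labs) {
    if (any(df[[col]] < 0, na.rm = TRUE)) {
      stop(sprintf("negative value in `%s`", col), call. = FALSE)
    }
  }
  if (anyDuplicated(df[c("patient_id", "t_days")])) {
    stop("duplicate (patient_id, t_days) visit", call. = FALSE)
  }
  df <- dplyr::arrange(df, .data$patient_id, .data$t_days)
  class(df) <- c("clinical_series", class(df))
  df
}

#' Read gene sets from a GMT file
#'
#' Standard tab-delimited GMT: name, description, then member genes. Each
#' line becomes a [gene_set] with the members as up genes.
#'
#' @param path GMT path.
#' @return Named list of [gene_set] objects (empty list for an empty file).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(list())
  sets <- purrr::imap(lines, function(line, i) {
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop(sprintf("GMT line %d has fewer than 3 fields", i), call. = FALSE)
    }
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning(sprintf("duplicate gene(s) in set '%s'; deduplicated", fields[1]))
    }
    gene_set(fields[1], unique(genes))
  })
  stats::setNames(sets, purrr::map_chr(sets, "name"))
}

#' Write gene sets to a GMT file
#' @param sets A [gene_set] or list of them. Down genes, if any, are written
#'   as a companion `<name>_down` line so the format stays standard GMT.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  if (inherits(sets, "gene_set")) sets <- list(sets)
  lines <- unlist(purrr::map(sets, function(s) {
    out <- paste(c(s$name, "mmlce", s$up), collapse = "\t")
    if (length(s$down)) {
      out <- c(out, paste(c(paste0(s$name, "_down"), "mmlce", s$down), collapse = "\t"))
    }
    out
  }))
  writeLines(lines, path)
  invisible(path)
}
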