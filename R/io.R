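#' Read and validate a cell table
#'
#' Cell tables are tab-delimited with one row per segmented cell and at
#' least the columns `cell_id`, `sample_id`, `group`, `x_um`, `y_um`;
#' optional columns (`cell_type`, `n_genes`, `n_transcripts`, `pct_mito`,
#' anything else) are preserved.
#'
#' @param path Path to a tab-delimited cell table.
#' @return A validated `data.frame`.
#' @export
read_cell_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_cell_table(tab, source = path)
}

#' @rdname read_cell_table
#' @param cells Cell table to write.
#' @export
write_cell_table <- function(cells, path) {
  utils::write.table(cells, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_cell_table <- function(cells, source = "cell table") {
  required <- c("cell_id", "sample_id", "group", "x_um", "y_um")
  missing <- setdiff(required, names(cells))
  if (length(missing))
    stop(sprintf("%s: missing column %s", source, paste(missing, collapse = ", ")))
  for (col in c("x_um", "y_um")) {
    v <- suppressWarnings(as.numeric(cells[[col]]))
    bad <- which(!is.finite(v) & nrow(cells) > 0)
    if (length(bad))
      stop(sprintf("%s: non-numeric or non-finite %s at row %d", source, col, bad[1]))
    cells[[col]] <- v
  }
  if (nrow(cells) > 0) {
    dup <- duplicated(cells[, c("sample_id", "cell_id")])
    if (any(dup))
      stop(sprintf("%s: duplicated cell_id within sample (e.g. %s)",
                   source, cells$cell_id[which(dup)[1]]))
  }
  if ("pct_mito" %in% names(cells) && nrow(cells) > 0) {
    if (any(cells$pct_mito < 0 | cells$pct_mito > 1))
      stop(sprintf("%s: pct_mito outside [0,1]", source))
  }
  cells
}

#' Read a genes x cells sparse count matrix (MatrixMarket trio)
#'
#' @param mtx_path MatrixMarket coordinate file.
#' @param genes_path One gene id per line (row names).
#' @param barcodes_path One cell id per line (column names).
#' @return A `dgCMatrix` with genes as rows and cells as columns.
#' @export
read_counts <- function(mtx_path, genes_path, barcodes_path) {
  m <- Matrix::readMM(mtx_path)
  genes <- readLines(genes_path)
  barcodes <- readLines(barcodes_path)
  if (length(genes) != nrow(m))
    stop(sprintf("genes file has %d entries but matrix has %d rows",
                 length(genes), nrow(m)))
  if (length(barcodes) != ncol(m))
    stop(sprintf("barcodes file has %d entries but matrix has %d columns",
                 length(barcodes), ncol(m)))
  m <- as_csparse(m)
  if (length(m@x) && any(m@x < 0)) stop("negative count entry in matrix")
  if (length(m@x) && any(m@x != round(m@x))) stop("non-integer count entry in matrix")
  dimnames(m) <- list(genes, barcodes)
  m
}

#' @rdname read_counts
#' @param counts Sparse or dense genes x cells count matrix with dimnames.
#' @param dir Output directory; writes counts.mtx, genes.tsv, barcodes.tsv.
#' @export
write_counts <- function(counts, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(methods::as(as_csparse(counts), "TsparseMatrix"),
                  file.path(dir, "counts.mtx"))
  writeLines(rownames(counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read / write the sample-level clinical table
#'
#' Columns: `sample_id`, `group`, `serum_IgE` (IU/mL, must be positive),
#' `spt_wheal` (mm).
#' @param path Tab-delimited clinical table.
#' @return `data.frame` with one row per sample.
#' @export
read_clinical_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "group", "serum_IgE", "spt_wheal")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop(sprintf("clinical table: missing column %s", paste(missing, collapse = ", ")))
  if (anyDuplicated(tab$sample_id)) stop("clinical table: duplicated sample_id")
  if (any(tab$serum_IgE <= 0)) stop("clinical table: serum_IgE must be > 0")
  tab
}

#' @rdname read_clinical_table
#' @param clinical Clinical table to write.
#' @export
write_clinical_table <- function(clinical, path) {
  utils::write.table(clinical, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline run configuration
#'
#' The run configuration is a single YAML file collecting input paths,
#' thresholds (radius, QC cut-offs, permutation counts) and the master seed.
#' Missing fields fall back to the documented defaults.
#'
#' @param path YAML file.
#' @return Named list with classes filled in.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(
    radius = 20, min_genes = 50, max_mito = 0.20, min_transcripts = 100,
    min_cells = 3000, n_perm_proximity = 1000, n_perm_lr = 10000,
    positivity_threshold = 0, seed = 1L, out_dir = "results"
  )
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  cfg
}
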