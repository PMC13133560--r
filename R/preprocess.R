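#' Compute per-cell QC covariates from a count matrix
#'
#' Fills in `n_genes` (genes with >=1 count), `n_transcripts` (total counts)
#' and `pct_mito` (fraction of counts on mitochondrial genes, identified by
#' the `MT-` prefix) for cells lacking them.
#'
#' @param cells Cell table.
#' @param counts Genes x cells count matrix whose columns match
#'   `cells$cell_id` in order.
#' @return Cell table with QC covariate columns.
#' @export
compute_qc_covariates <- function(cells, counts) {
  check_cells_match(cells, counts)
  total <- Matrix::colSums(counts)
  mito <- grepl("^MT-", rownames(counts))
  cells$n_genes <- Matrix::colSums(counts > 0)
  cells$n_transcripts <- as.integer(total)
  cells$pct_mito <- ifelse(total > 0, Matrix::colSums(counts[mito, , drop = FALSE]) / total, 0)
  cells
}

check_cells_match <- function(cells, counts) {
  if (ncol(counts) != nrow(cells))
    stop(sprintf("matrix has %d cells but table has %d rows", ncol(counts), nrow(cells)))
  if (!is.null(colnames(counts)) && nrow(cells) > 0 &&
      !identical(colnames(counts), as.character(cells$cell_id)))
    stop("matrix column names do not match cell table cell_id order")
  invisible(TRUE)
}

#' Cell-level quality-control filter
#'
#' Removes cells failing any of three criteria, using strict inequalities:
#' fewer than `min_genes` detected genes, more than `max_mito` fraction of
#' mitochondrial transcripts, or fewer than `min_transcripts` total
#' transcripts. Cells exactly at a threshold are retained.
#'
#' @param cells Cell table with QC covariates (computed from `counts` when
#'   absent).
#' @param counts Genes x cells count matrix aligned to `cells`.
#' @param min_genes,max_mito,min_transcripts QC thresholds.
#' @return List with `cells`, `counts` (both filtered) and `log`, a named
#'   vector counting cells removed by each criterion (a cell can count
#'   towards several) plus totals.
#' @export
filter_cells <- function(cells, counts, min_genes = 50, max_mito = 0.20,
                         min_transcripts = 100) {
  check_cells_match(cells, counts)
  need <- c("n_genes", "n_transcripts", "pct_mito")
  if (!all(need %in% names(cells))) cells <- compute_qc_covariates(cells, counts)

  fail_genes <- cells$n_genes < min_genes
  fail_mito  <- cells$pct_mito > max_mito
  fail_depth <- cells$n_transcripts < min_transcripts
  keep <- !(fail_genes | fail_mito | fail_depth)

  list(
    cells = cells[keep, , drop = FALSE],
    counts = counts[, keep, drop = FALSE],
    log = c(n_input = nrow(cells),
            removed_low_genes = sum(fail_genes),
            removed_high_mito = sum(fail_mito),
            removed_low_transcripts = sum(fail_depth),
            n_removed = sum(!keep),
            n_retained = sum(keep))
  )
}

#' Sample-level quality control
#'
#' A sample passes when it retains at least `min_cells` cells after
#' cell-level filtering.
#'
#' @param cells Filtered cell table (all samples pooled).
#' @param min_cells Minimum retained cells per sample.
#' @return `data.frame` with `sample_id`, `n_cells`, `pass`.
#' @export
sample_qc <- function(cells, min_cells = 3000) {
  n <- table(cells$sample_id)
  data.frame(sample_id = names(n), n_cells = as.integer(n),
             pass = as.integer(n) >= min_cells, row.names = NULL)
}

#' Library-size log-normalization
#'
#' Computes `ln(1 + scale * count / cell_total)` per entry, the standard
#' log-normalization for targeted in-situ counts. Cells with zero total
#' counts get all-zero values (with a warning).
#'
#' @param counts Genes x cells count matrix (sparse or dense).
#' @param scale Scale factor (library size each cell is brought to).
#' @return Sparse `dgCMatrix` of normalized values; zeros stay zero.
#' @export
normalize_expression <- function(counts, scale = 10000) {
  m <- as_csparse(counts)
  total <- Matrix::colSums(m)
  zero <- total == 0
  if (any(zero)) {
    warning(sprintf("%d cell(s) with zero total counts: normalized values set to 0", sum(zero)))
    total[zero] <- 1
  }
  # operate on the non-zero slots only; column of each slot via pointer vector
  if (length(m@x)) {
    col_of <- rep.int(seq_len(ncol(m)), diff(m@p))
    m@x <- log1p(scale * m@x / total[col_of])
  }
  m
}

#' Marker-argmax cell-type annotation
#'
#' Assigns each cell the type whose marker genes have the highest mean
#' normalized expression; ties (including all-zero cells) are broken by
#' lexicographic type name and flagged.
#'
#' @param norm Normalized genes x cells matrix.
#' @param marker_map Named list of marker gene vectors per type; each type
#'   must have at least one marker present in the matrix.
#' @return `data.frame` with `cell_id`, `cell_type`, `tie` (logical flag).
#' @export
annotate_cells <- function(norm, marker_map = default_marker_map()) {
  if (length(marker_map) == 0) stop("empty marker_map")
  types <- sort(names(marker_map))
  score <- matrix(NA_real_, nrow = ncol(norm), ncol = length(types),
                  dimnames = list(NULL, types))
  for (ty in types) {
    mk <- intersect(marker_map[[ty]], rownames(norm))
    if (length(mk) == 0) stop(sprintf("no marker of type '%s' present in matrix", ty))
    score[, ty] <- Matrix::colMeans(norm[mk, , drop = FALSE])
  }
  best <- max.col(score, ties.method = "first")  # columns sorted -> lexicographic tie-break
  tie <- rowSums(score == score[cbind(seq_len(nrow(score)), best)]) > 1
  data.frame(cell_id = colnames(norm) %||% seq_len(ncol(norm)),
             cell_type = types[best], tie = tie)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# coerce dense or sparse input to a general numeric column-compressed
# sparse matrix (unpacking diagonal / symmetric storage)
as_csparse <- function(m) {
  if (is.matrix(m)) m <- Matrix::Matrix(m, sparse = TRUE)
  m <- methods::as(m, "CsparseMatrix")
  m <- methods::as(m, "generalMatrix")
  methods::as(m, "dMatrix")
}
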