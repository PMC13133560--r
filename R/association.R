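#' Adjacency-stratified expression contrast
#'
#' Compares expression of a gene (or any per-cell value) between cells of
#' one type that are fibroblast-adjacent (at least one partner cell within
#' the graph radius) and those that are not. The fold is the ratio of mean
#' back-transformed expression, `mean(expm1(norm))` adjacent over
#' non-adjacent; the p-value is a cell-level two-sided Wilcoxon rank-sum
#' test. Per-sample stratum means are also returned for group-level
#' aggregation, since cell-level pooling inflates significance.
#'
#' @param cells Cell table aligned to `norm`.
#' @param graph Radius graph built from `cells`.
#' @param norm Normalized genes x cells matrix.
#' @param gene Gene symbol.
#' @param t_type Stratified cell type (default CD4+ T cells).
#' @param partner Partner type defining adjacency (default fibroblasts).
#' @return List with `contrast` (one-row `data.frame`: stratum sizes and
#'   means, `fold` — `Inf` flagged via `degenerate` when the non-adjacent
#'   mean is 0 — and `p_wilcoxon`) and `per_sample` stratum means.
#' @export
adjacent_expression_contrast <- function(cells, graph, norm, gene,
                                         t_type = "CD4_T", partner = "fibroblast") {
  if (!gene %in% rownames(norm)) stop(sprintf("gene '%s' not in matrix", gene))
  labels <- cells$cell_type
  sel <- which(labels == t_type)
  if (length(sel) == 0) stop(sprintf("no cells of type '%s'", t_type))
  adj <- has_neighbor_of_type(graph, labels, partner)[sel]
  vals <- expm1(as.numeric(norm[gene, sel]))

  n_adj <- sum(adj); n_non <- sum(!adj)
  if (n_adj == 0 || n_non == 0) {
    contrast <- data.frame(gene = gene, n_adjacent = n_adj, n_nonadjacent = n_non,
                           mean_adjacent = NA_real_, mean_nonadjacent = NA_real_,
                           fold = NA_real_, degenerate = TRUE, p_wilcoxon = NA_real_)
  } else {
    m_adj <- mean(vals[adj]); m_non <- mean(vals[!adj])
    fold <- if (m_non == 0) Inf else m_adj / m_non
    contrast <- data.frame(gene = gene, n_adjacent = n_adj, n_nonadjacent = n_non,
                           mean_adjacent = m_adj, mean_nonadjacent = m_non,
                           fold = fold, degenerate = !is.finite(fold),
                           p_wilcoxon = wilcoxon_rank_sum(vals[adj], vals[!adj])$p)
  }
  per_sample <- stats::aggregate(
    vals, by = list(sample_id = cells$sample_id[sel], adjacent = adj),
    FUN = mean)
  names(per_sample)[3] <- "mean_expr"
  list(contrast = contrast, per_sample = per_sample)
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y Equal-length numeric vectors with `n >= 3` and non-zero
#'   variance in each.
#' @param x_name,y_name Labels carried into the result.
#' @return One-row `data.frame` with `x_name`, `y_name`, `n`, `pearson_r`,
#'   `p` (two-sided, from `t = r * sqrt((n - 2) / (1 - r^2))`).
#' @export
pearson_correlation <- function(x, y, x_name = "x", y_name = "y") {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance in x or y")
  ct <- stats::cor.test(x, y, method = "pearson")
  data.frame(x_name = x_name, y_name = y_name, n = length(x),
             pearson_r = unname(ct$estimate), p = ct$p.value)
}

#' Sample-level clinical association of the crosstalk score
#'
#' Pearson correlation of a sample-level crosstalk score against serum
#' total IgE and SPT wheal diameter.
#'
#' @param crosstalk `data.frame` with `sample_id` and a score column.
#' @param clinical Clinical table with `sample_id`, `serum_IgE`,
#'   `spt_wheal`; every crosstalk sample must be present.
#' @param score_col Name of the score column in `crosstalk`.
#' @return `data.frame`, one row per clinical metric.
#' @export
clinical_association <- function(crosstalk, clinical,
                                 score_col = "mean_ligand_score") {
  missing <- setdiff(crosstalk$sample_id, clinical$sample_id)
  if (length(missing))
    stop(sprintf("samples missing from clinical table: %s",
                 paste(missing, collapse = ", ")))
  m <- merge(crosstalk, clinical, by = "sample_id")
  rbind(
    pearson_correlation(m[[score_col]], m$serum_IgE, score_col, "serum_IgE"),
    pearson_correlation(m[[score_col]], m$spt_wheal, score_col, "spt_wheal")
  )
}
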