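#' Gene-module signature score with binned control genes
#'
#' Scores each cell for a gene set against expression-matched control
#' genes: panel genes are binned by their average normalized expression
#' across the scored pool (`n_bins` equal-frequency bins) and, for each set
#' gene, `n_ctrl` control genes are drawn from its bin (with replacement
#' when the bin is small). The raw score is the mean normalized expression
#' of the set genes minus the mean of the control genes; raw scores are
#' then min-max rescaled to `[0, 1]` over the scored cell pool (all cells
#' being compared in one analysis should be scored in one call so strata
#' share a scale). If every raw score is equal the normalized scores are
#' all 0.
#'
#' @param norm Normalized genes x cells matrix (the scored pool).
#' @param gene_set Character vector of set genes; at least one must be in
#'   the matrix (absent ones are dropped with a warning).
#' @param gene_set_name Label carried into the result.
#' @param n_bins Number of average-expression bins.
#' @param n_ctrl Control genes drawn per set gene.
#' @param seed Integer seed for the control draw.
#' @return `data.frame` with `cell_id`, `gene_set_name`, `raw_score`,
#'   `norm_score`.
#' @export
module_score <- function(norm, gene_set, gene_set_name = "custom",
                         n_bins = 25, n_ctrl = 100, seed = 1L) {
  present <- intersect(gene_set, rownames(norm))
  if (length(present) == 0) stop("no gene of the set is present in the matrix")
  if (length(present) < length(gene_set))
    warning(sprintf("%d set gene(s) absent from matrix, dropped",
                    length(gene_set) - length(present)))

  avg <- Matrix::rowMeans(norm)
  n_bins_eff <- min(n_bins, length(unique(avg)))
  # equal-frequency bins on the rank scale, ties kept together
  bin <- if (n_bins_eff < 2) rep(1L, nrow(norm)) else
    as.integer(cut(rank(avg, ties.method = "average"),
                   breaks = n_bins_eff, labels = FALSE, include.lowest = TRUE))
  names(bin) <- rownames(norm)

  ctrl_genes <- character(0)
  withr_seed(seed, {
    for (g in present) {
      # controls come from the gene's abundance bin, excluding the set
      # itself (unless the bin holds nothing else)
      pool <- setdiff(rownames(norm)[bin == bin[g]], present)
      if (length(pool) == 0) pool <- rownames(norm)[bin == bin[g]]
      ctrl_genes <- c(ctrl_genes, sample(pool, n_ctrl, replace = n_ctrl > length(pool)))
    }
  })
  set_mean <- Matrix::colMeans(norm[present, , drop = FALSE])
  ctrl_mean <- Matrix::colMeans(norm[ctrl_genes, , drop = FALSE])
  raw <- as.numeric(set_mean - ctrl_mean)

  rng <- range(raw)
  norm_score <- if (diff(rng) == 0) rep(0, length(raw)) else (raw - rng[1]) / diff(rng)
  data.frame(cell_id = colnames(norm) %||% seq_along(raw),
             gene_set_name = gene_set_name,
             raw_score = raw, norm_score = norm_score)
}

#' Per-cell fibroblast pro-Th2 ligand score
#'
#' For each CD4+ T cell with at least one fibroblast within the graph
#' radius, pairs it with its nearest fibroblast (ties broken by the smaller
#' cell index) and sums that fibroblast's normalized expression of the five
#' pro-Th2 ligands TSLP, ICOSL, OX40L, CCL17 and POSTN. T cells with no
#' fibroblast in range are excluded and counted.
#'
#' @param cells Cell table (one sample) with `cell_type`.
#' @param graph Radius graph built from `cells`.
#' @param norm Normalized genes x cells matrix aligned to `cells`.
#' @param t_type,fibro_type Cell-type labels of the scored and partner type.
#' @param ligands Ligand gene set (defaults to [pro_th2_ligands()]); all
#'   must be present in the matrix.
#' @return List with `records` (`data.frame`: `t_cell_id`,
#'   `paired_fibroblast_id`, `pair_distance`, `ligand_score`) and
#'   `n_unpaired`, the count of T cells with no fibroblast in range.
#' @export
fibroblast_ligand_score <- function(cells, graph, norm,
                                    t_type = "CD4_T", fibro_type = "fibroblast",
                                    ligands = pro_th2_ligands()) {
  missing <- setdiff(ligands, rownames(norm))
  if (length(missing))
    stop(sprintf("ligand gene(s) missing from panel: %s", paste(missing, collapse = ", ")))
  labels <- cells$cell_type
  e <- graph$edges

  # T-fibroblast edges, oriented T -> fibroblast
  t_i <- labels[e$i] == t_type & labels[e$j] == fibro_type
  t_j <- labels[e$j] == t_type & labels[e$i] == fibro_type
  t_idx <- c(e$i[t_i], e$j[t_j])
  f_idx <- c(e$j[t_i], e$i[t_j])
  d     <- c(e$dist[t_i], e$dist[t_j])

  n_t <- sum(labels == t_type)
  if (length(t_idx) == 0) {
    return(list(records = data.frame(t_cell_id = character(0),
                                     paired_fibroblast_id = character(0),
                                     pair_distance = numeric(0),
                                     ligand_score = numeric(0)),
                n_unpaired = n_t))
  }
  # nearest fibroblast per T cell; ties by smaller fibroblast index
  ord <- order(t_idx, d, f_idx)
  first <- !duplicated(t_idx[ord])
  ti <- t_idx[ord][first]; fi <- f_idx[ord][first]; di <- d[ord][first]

  lig_sum <- Matrix::colSums(norm[ligands, fi, drop = FALSE])
  list(records = data.frame(t_cell_id = as.character(cells$cell_id[ti]),
                            paired_fibroblast_id = as.character(cells$cell_id[fi]),
                            pair_distance = di,
                            ligand_score = as.numeric(lig_sum)),
       n_unpaired = n_t - length(ti))
}

#' Sample-level crosstalk score (mean ligand score)
#'
#' Arithmetic mean of the single-cell fibroblast ligand scores over all
#' CD4+ T cell-fibroblast pairs of one sample.
#'
#' @param records Ligand-score records from [fibroblast_ligand_score()].
#' @param sample_id Sample label carried into the result.
#' @return `data.frame` with `sample_id`, `mean_ligand_score` (`NA` and
#'   flagged `undefined` when there are no pairs) and `n_pairs`.
#' @export
sample_crosstalk_score <- function(records, sample_id) {
  n <- nrow(records)
  data.frame(sample_id = sample_id,
             mean_ligand_score = if (n > 0) mean(records$ligand_score) else NA_real_,
             n_pairs = n,
             undefined = n == 0)
}

#' Composite three-component crosstalk score
#'
#' Product of (1) the sample's CD4+ T-to-fibroblast adjacency fraction,
#' (2) the sample mean fibroblast type-2 mediator module score and (3) the
#' sample mean CD4+ T core-Th2 module score. All components must be finite
#' and non-negative.
#'
#' @param adjacency_component,mediator_component,th2_component Component
#'   values.
#' @return The product, a non-negative real.
#' @export
composite_crosstalk_score <- function(adjacency_component, mediator_component,
                                      th2_component) {
  comp <- c(adjacency_component, mediator_component, th2_component)
  if (any(!is.finite(comp))) stop("composite score: non-finite component")
  if (any(comp < 0)) stop("composite score: negative component")
  adjacency_component * mediator_component * th2_component
}
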