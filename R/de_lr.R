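#' Wilcoxon rank-sum test
#'
#' Two-sided rank-sum test between two groups of values: exact enumeration
#' when the combined sample size is at most 12 and there are no ties,
#' otherwise the tie-corrected normal approximation with continuity
#' correction. Identical multisets (zero rank variance) give p = 1.
#'
#' @param values_a,values_b Numeric vectors, both non-empty.
#' @return List with `statistic` (Mann-Whitney U of group a) and `p`.
#' @export
wilcoxon_rank_sum <- function(values_a, values_b) {
  if (length(values_a) == 0 || length(values_b) == 0)
    stop("both groups must be non-empty")
  pooled <- c(values_a, values_b)
  if (length(unique(pooled)) == 1) {
    return(list(statistic = length(values_a) * length(values_b) / 2, p = 1))
  }
  ties <- any(duplicated(pooled))
  use_exact <- (length(pooled) <= 12) && !ties
  res <- suppressWarnings(
    stats::wilcox.test(values_a, values_b, exact = use_exact, correct = TRUE)
  )
  p <- res$p.value
  if (!is.finite(p)) p <- 1
  list(statistic = unname(res$statistic), p = min(p, 1))
}

#' Differential expression between two groups within a cell type
#'
#' Per-gene Wilcoxon rank-sum test on normalized expression between groups
#' `group_a` and `group_b`, restricted to cells of `cell_type`. A gene is
#' tested only if detected (normalized expression > 0) in at least
#' `min_pct` of the cells of one of the groups. The log2 fold change is
#' computed on back-transformed means,
#' `log2((mean(expm1(a)) + eps) / (mean(expm1(b)) + eps))` with
#' `eps = 1e-9`. BH adjustment is applied over the tested genes; the
#' significant up-list uses `p_adj < 0.05` and `log2fc > logfc_threshold`.
#'
#' @param norm Normalized genes x cells matrix.
#' @param cells Cell table aligned to `norm` with `cell_type` and `group`.
#' @param cell_type Cell type tested.
#' @param group_a,group_b Group labels (fold change is a over b).
#' @param logfc_threshold,min_pct Seurat-convention thresholds.
#' @return `data.frame` with `gene`, `log2fc`, `pct_a`, `pct_b`, `p_raw`,
#'   `p_adj`, `significant`; empty (with a warning) if no gene passes
#'   `min_pct`.
#' @export
differential_expression <- function(norm, cells, cell_type, group_a, group_b,
                                    logfc_threshold = 0.25, min_pct = 0.1) {
  ia <- which(cells$cell_type == cell_type & cells$group == group_a)
  ib <- which(cells$cell_type == cell_type & cells$group == group_b)
  if (length(ia) == 0 || length(ib) == 0)
    stop(sprintf("both groups must contain '%s' cells", cell_type))
  ma <- norm[, ia, drop = FALSE]; mb <- norm[, ib, drop = FALSE]
  pct_a <- Matrix::rowMeans(ma > 0); pct_b <- Matrix::rowMeans(mb > 0)
  test_genes <- which(pct_a >= min_pct | pct_b >= min_pct)
  if (length(test_genes) == 0) {
    warning("no gene passes min_pct; empty result")
    return(data.frame(gene = character(0), log2fc = numeric(0),
                      pct_a = numeric(0), pct_b = numeric(0),
                      p_raw = numeric(0), p_adj = numeric(0),
                      significant = logical(0)))
  }
  eps <- 1e-9
  mean_a <- Matrix::rowMeans(expm1_sparse(ma))[test_genes]
  mean_b <- Matrix::rowMeans(expm1_sparse(mb))[test_genes]
  log2fc <- log2((mean_a + eps) / (mean_b + eps))
  da <- as.matrix(ma[test_genes, , drop = FALSE])
  db <- as.matrix(mb[test_genes, , drop = FALSE])
  p_raw <- vapply(seq_along(test_genes), function(k) {
    wilcoxon_rank_sum(da[k, ], db[k, ])$p
  }, numeric(1))
  p_adj <- bh_adjust(p_raw)
  data.frame(gene = rownames(norm)[test_genes],
             log2fc = as.numeric(log2fc),
             pct_a = as.numeric(pct_a[test_genes]),
             pct_b = as.numeric(pct_b[test_genes]),
             p_raw = p_raw, p_adj = p_adj,
             significant = p_adj < 0.05 & log2fc > logfc_threshold,
             row.names = NULL)
}

# expm1 on the non-zero slots of a sparse matrix (zeros map to zero)
expm1_sparse <- function(m) {
  m <- as_csparse(m)
  if (length(m@x)) m@x <- expm1(m@x)
  m
}

#' Hypergeometric pathway over-representation test
#'
#' Upper-tail hypergeometric test of the overlap between a hit list and a
#' pathway within a gene universe, with fold enrichment
#' `(overlap / n_hits) / (n_pathway / n_universe)`.
#'
#' @param hit_genes,pathway_genes,universe Character vectors; hits and
#'   pathway must be subsets of the universe.
#' @return `data.frame` (one row) with `overlap`, `n_hits`, `n_pathway`,
#'   `n_universe`, `fold_enrichment`, `p`.
#' @export
hypergeometric_enrichment <- function(hit_genes, pathway_genes, universe) {
  if (length(universe) == 0) stop("empty universe")
  if (!all(hit_genes %in% universe)) stop("hit genes must be a subset of the universe")
  if (!all(pathway_genes %in% universe)) stop("pathway genes must be a subset of the universe")
  k <- length(intersect(hit_genes, pathway_genes))
  n_h <- length(hit_genes); n_p <- length(pathway_genes); n_u <- length(universe)
  fold <- if (n_h == 0 || n_p == 0) 0 else (k / n_h) / (n_p / n_u)
  # P(X >= k) with X ~ Hypergeometric(white = n_p, black = n_u - n_p, drawn = n_h)
  p <- if (n_h == 0) 1 else stats::phyper(k - 1, n_p, n_u - n_p, n_h, lower.tail = FALSE)
  data.frame(overlap = k, n_hits = n_h, n_pathway = n_p, n_universe = n_u,
             fold_enrichment = fold, p = p)
}

#' Default ligand-receptor pair list
#'
#' The three headline fibroblast-to-T-cell axes: TSLP-IL7R, OX40L-OX40
#' (TNFRSF4) and ICOSL-ICOS.
#'
#' @return `data.frame` with `ligand`, `receptor`.
#' @export
default_lr_pairs <- function() {
  data.frame(ligand = c("TSLP", "OX40L", "ICOSL"),
             receptor = c("IL7R", "TNFRSF4", "ICOS"))
}

#' Ligand-receptor co-expression permutation test
#'
#' Scores each ligand-receptor pair as the mean of (i) the mean normalized
#' ligand expression in the sender type and (ii) the mean normalized
#' receptor expression in the receiver type. The null shuffles the
#' sender/receiver labels among the union of the two populations
#' (`n_perm` times); `p = (1 + #{null >= observed}) / (1 + n_perm)`, BH
#' adjusted across pairs.
#'
#' @param norm Normalized genes x cells matrix.
#' @param cells Cell table aligned to `norm`.
#' @param sender_type,receiver_type Cell-type labels.
#' @param pairs `data.frame` with `ligand`, `receptor` columns.
#' @param n_perm Number of label permutations.
#' @param seed Integer seed.
#' @return `data.frame` with one row per retained pair: `ligand`,
#'   `receptor`, `interaction_score`, `p_raw`, `p_adj`; pairs whose genes
#'   are absent are skipped with a warning.
#' @export
lr_permutation_test <- function(norm, cells, sender_type, receiver_type,
                                pairs = default_lr_pairs(), n_perm = 10000,
                                seed = 1L) {
  is_send <- cells$cell_type == sender_type
  is_recv <- cells$cell_type == receiver_type
  if (!any(is_send)) stop(sprintf("no cells of sender type '%s'", sender_type))
  if (!any(is_recv)) stop(sprintf("no cells of receiver type '%s'", receiver_type))
  keep <- pairs$ligand %in% rownames(norm) & pairs$receptor %in% rownames(norm)
  if (!all(keep))
    warning(sprintf("skipping %d pair(s) with genes absent from the panel", sum(!keep)))
  pairs <- pairs[keep, , drop = FALSE]
  if (nrow(pairs) == 0)
    return(data.frame(ligand = character(0), receptor = character(0),
                      interaction_score = numeric(0), p_raw = numeric(0),
                      p_adj = numeric(0)))

  idx <- which(is_send | is_recv)
  send_flag <- is_send[idx]
  n_pool <- length(idx); n_send <- sum(send_flag)
  # expression of all needed genes restricted to the pooled cells
  genes <- unique(c(pairs$ligand, pairs$receptor))
  expr <- as.matrix(norm[genes, idx, drop = FALSE])

  score_for <- function(flag) {
    lig <- rowMeans(expr[pairs$ligand, flag, drop = FALSE])
    rec <- rowMeans(expr[pairs$receptor, !flag, drop = FALSE])
    unname(lig + rec) / 2
  }
  observed <- score_for(send_flag)

  exceed <- integer(nrow(pairs))
  withr_seed(seed, {
    for (k in seq_len(n_perm)) {
      flag <- logical(n_pool)
      flag[sample.int(n_pool, n_send)] <- TRUE
      exceed <- exceed + (score_for(flag) >= observed)
    }
  })
  p_raw <- (1 + exceed) / (1 + n_perm)
  data.frame(ligand = pairs$ligand, receptor = pairs$receptor,
             interaction_score = observed, p_raw = p_raw,
             p_adj = bh_adjust(p_raw), row.names = NULL)
}
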