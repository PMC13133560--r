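#' Per-sample radius graphs for a pooled cell table
#'
#' Splits a pooled cell table by sample and builds one radius graph per
#' sample. When `types` is given, cells are first restricted to those
#' types: cross-type adjacency within the radius is identical on the
#' restricted graph, which is much cheaper for adjacency-only analyses.
#'
#' @param cells Pooled cell table.
#' @param radius Neighborhood radius (um).
#' @param types Optional cell types to restrict to.
#' @return List with `graphs` (named by sample) and `cells` (the possibly
#'   restricted table, row-aligned with the graphs sample by sample).
#' @export
sample_graphs <- function(cells, radius = 20, types = NULL) {
  if (!is.null(types)) cells <- cells[cells$cell_type %in% types, , drop = FALSE]
  split_cells <- split(cells, cells$sample_id)
  graphs <- lapply(split_cells, build_neighbor_graph, radius = radius)
  list(graphs = graphs, cells_by_sample = split_cells)
}

#' Per-sample adjacency and occupancy statistics
#'
#' Convenience wrapper computing, for every sample of a pooled cell table,
#' the fraction of `type_a` cells with a `type_b` neighbor within the
#' radius and the cell-count occupancy of `type_b`.
#'
#' @inheritParams sample_graphs
#' @param type_a,type_b Cell types (adjacency of a to b).
#' @return `data.frame` with one row per sample: `sample_id`, `group`,
#'   `adjacency_fraction`, `occupancy_pct`.
#' @export
cohort_adjacency <- function(cells, radius = 20, type_a = "CD4_T",
                             type_b = "fibroblast") {
  sg <- sample_graphs(cells, radius, types = c(type_a, type_b))
  occ <- vapply(split(cells, cells$sample_id),
                function(s) type_area_fraction(s, type_b), numeric(1))
  res <- lapply(names(sg$graphs), function(sid) {
    sc <- sg$cells_by_sample[[sid]]
    data.frame(sample_id = sid, group = sc$group[1],
               adjacency_fraction = adjacency_fraction(sg$graphs[[sid]], sc,
                                                       type_a, type_b),
               occupancy_pct = occ[[sid]])
  })
  do.call(rbind, res)
}

#' Per-cell fibroblast-adjacency flags across a pooled cohort
#'
#' @inheritParams cohort_adjacency
#' @param t_type,partner Types defining the flag (cells of `t_type` with a
#'   `partner` neighbor within radius).
#' @return Logical vector aligned to `cells` rows; `NA` for other types.
#' @export
adjacency_flags <- function(cells, radius = 20, t_type = "CD4_T",
                            partner = "fibroblast") {
  out <- rep(NA, nrow(cells))
  for (sid in unique(cells$sample_id)) {
    rows <- which(cells$sample_id == sid)
    sub <- rows[cells$cell_type[rows] %in% c(t_type, partner)]
    if (!length(sub)) next
    g <- build_neighbor_graph(cells[sub, , drop = FALSE], radius)
    adj <- has_neighbor_of_type(g, cells$cell_type[sub], partner)
    tt <- cells$cell_type[sub] == t_type
    out[sub[tt]] <- adj[tt]
  }
  out
}

#' Run the full crosstalk analysis pipeline
#'
#' Executes qc, spatial, score, de, lr, association and report stages over
#' a cohort on disk, writing tab-delimited result tables and a YAML run
#' manifest to `config$out_dir`. Re-running with the same configuration and
#' seed reproduces all stochastic outputs exactly. If the clinical table is
#' absent the association stage is skipped with a warning; any other stage
#' failure aborts with the stage name.
#'
#' @param config Run configuration list (see [read_run_config()]), with
#'   paths `cells_path`, `mtx_path`, `genes_path`, `barcodes_path` and
#'   optionally `clinical_path`, `pairs_path`.
#' @return Invisible list of stage outputs.
#' @export
run_pipeline <- function(config) {
  out_dir <- config$out_dir %||% "results"
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stages_run <- character(0)
  stage <- function(name, fun) {
    tryCatch(fun(), error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  radius <- config$radius %||% 20
  seed <- config$seed %||% 1L

  # ---- qc
  qc_out <- stage("qc", function() {
    cells <- read_cell_table(config$cells_path)
    counts <- read_counts(config$mtx_path, config$genes_path, config$barcodes_path)
    flt <- filter_cells(cells, counts, config$min_genes %||% 50,
                        config$max_mito %||% 0.20, config$min_transcripts %||% 100)
    sq <- sample_qc(flt$cells, config$min_cells %||% 3000)
    keep <- flt$cells$sample_id %in% sq$sample_id[sq$pass]
    list(cells = flt$cells[keep, , drop = FALSE],
         counts = flt$counts[, keep, drop = FALSE],
         log = flt$log, sample_qc = sq)
  })
  stages_run <- c(stages_run, "qc")
  cells <- qc_out$cells
  norm <- normalize_expression(qc_out$counts)
  groups <- unique(cells$group)

  # ---- spatial
  spatial_out <- stage("spatial", function() {
    adj <- cohort_adjacency(cells, radius)
    sg <- sample_graphs(cells, radius)
    prox <- do.call(rbind, lapply(names(sg$graphs), function(sid) {
      g <- sg$graphs[[sid]]
      sc <- sg$cells_by_sample[[sid]]
      cbind(sample_id = sid,
            neighborhood_enrichment(g, sc, "CD4_T", "fibroblast",
                                    n_perm = config$n_perm_proximity %||% 1000,
                                    seed = derive_seed(seed, match(sid, names(sg$graphs)))))
    }))
    prox$p_adj <- bh_adjust(prox$p_raw)
    utils::write.table(prox, file.path(out_dir, "proximity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(adjacency = adj, proximity = prox)
  })
  stages_run <- c(stages_run, "spatial")

  # ---- score
  score_out <- stage("score", function() {
    is_t <- cells$cell_type == "CD4_T"
    is_f <- cells$cell_type == "fibroblast"
    th2 <- module_score(norm[, is_t, drop = FALSE], core_th2_genes(),
                        "core_th2", seed = seed)
    med <- module_score(norm[, is_f, drop = FALSE], mediator_genes(),
                        "mediator", seed = seed)
    mod <- rbind(th2, med)
    utils::write.table(mod, file.path(out_dir, "module_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    sg <- sample_graphs(cells, radius, types = c("CD4_T", "fibroblast"))
    lig <- list(); ct <- list()
    for (sid in names(sg$graphs)) {
      sc <- sg$cells_by_sample[[sid]]
      ls <- fibroblast_ligand_score(sc, sg$graphs[[sid]],
                                    norm[, match(sc$cell_id, cells$cell_id), drop = FALSE])
      lig[[sid]] <- if (nrow(ls$records)) cbind(sample_id = sid, ls$records) else NULL
      ct[[sid]] <- sample_crosstalk_score(ls$records, sid)
    }
    lig <- do.call(rbind, lig)
    ct <- do.call(rbind, ct)
    # composite: per-sample adjacency x mean fibro mediator score x mean T th2 score
    th2_by <- tapply(th2$norm_score, cells$sample_id[is_t][match(th2$cell_id, cells$cell_id[is_t])], mean)
    med_by <- tapply(med$norm_score, cells$sample_id[is_f][match(med$cell_id, cells$cell_id[is_f])], mean)
    adj <- spatial_out$adjacency
    ct$composite_score <- vapply(seq_len(nrow(ct)), function(i) {
      sid <- ct$sample_id[i]
      composite_crosstalk_score(adj$adjacency_fraction[adj$sample_id == sid],
                                med_by[[sid]], th2_by[[sid]])
    }, numeric(1))
    ct$group <- adj$group[match(ct$sample_id, adj$sample_id)]
    utils::write.table(lig, file.path(out_dir, "ligand_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(ct, file.path(out_dir, "crosstalk.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(module = mod, ligand = lig, crosstalk = ct)
  })
  stages_run <- c(stages_run, "score")

  # ---- de
  de_out <- stage("de", function() {
    if (length(groups) < 2) return(NULL)
    de <- differential_expression(norm, cells, "fibroblast", groups[1], groups[2],
                                  config$logfc_threshold %||% 0.25,
                                  config$min_pct %||% 0.1)
    utils::write.table(de, file.path(out_dir, "de_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    de
  })
  stages_run <- c(stages_run, "de")

  # ---- lr
  lr_out <- stage("lr", function() {
    pairs <- if (!is.null(config$pairs_path)) utils::read.delim(config$pairs_path)
             else default_lr_pairs()
    sel <- cells$group == groups[1]
    lr <- lr_permutation_test(norm[, sel, drop = FALSE], cells[sel, , drop = FALSE],
                              "fibroblast", "CD4_T", pairs,
                              n_perm = config$n_perm_lr %||% 10000,
                              seed = derive_seed(seed, 777L))
    utils::write.table(lr, file.path(out_dir, "lr_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    lr
  })
  stages_run <- c(stages_run, "lr")

  # ---- association
  assoc_out <- NULL
  if (is.null(config$clinical_path) || !file.exists(config$clinical_path %||% "")) {
    warning("clinical table absent: association stage skipped")
  } else {
    assoc_out <- stage("association", function() {
      adj_flag <- adjacency_flags(cells, radius)
      sel <- cells$group == groups[1] & cells$cell_type == "CD4_T"
      contrasts <- do.call(rbind, lapply(c("IL4", "IL5", "IL13"), function(g) {
        vals <- expm1(as.numeric(norm[g, sel]))
        adj <- adj_flag[sel]
        fold <- if (mean(vals[!adj]) == 0) Inf else mean(vals[adj]) / mean(vals[!adj])
        data.frame(gene = g, mean_adjacent = mean(vals[adj]),
                   mean_nonadjacent = mean(vals[!adj]), fold = fold,
                   p_wilcoxon = wilcoxon_rank_sum(vals[adj], vals[!adj])$p)
      }))
      clinical <- read_clinical_table(config$clinical_path)
      ct <- score_out$crosstalk[!score_out$crosstalk$undefined, ]
      cors <- rbind(clinical_association(ct, clinical, "mean_ligand_score"),
                    clinical_association(ct, clinical, "composite_score"))
      utils::write.table(contrasts, file.path(out_dir, "contrasts.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(cors, file.path(out_dir, "correlations.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(contrasts = contrasts, correlations = cors)
    })
    stages_run <- c(stages_run, "association")
  }

  # ---- report
  stage("report", function() {
    manifest <- list(
      stages = c(stages_run, "report"),
      seed = seed, radius = radius,
      qc = as.list(qc_out$log),
      n_samples = length(unique(cells$sample_id)),
      package_version = as.character(utils::packageVersion("fibroTalk")),
      r_version = R.version.string)
    yaml::write_yaml(manifest, file.path(out_dir, "run_manifest.yaml"))
  })
  stages_run <- c(stages_run, "report")

  invisible(list(qc = qc_out, spatial = spatial_out, score = score_out,
                 de = de_out, lr = lr_out, association = assoc_out,
                 stages = stages_run))
}

#' Write a simulated cohort to disk in the pipeline's input formats
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if needed); writes cells.tsv, the
#'   MatrixMarket trio, clinical.tsv and panel.tsv.
#' @param panel Panel manifest to write alongside.
#' @return Invisible named list of written paths.
#' @export
write_cohort <- function(cohort, dir, panel = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_cell_table(cohort$cells, file.path(dir, "cells.tsv"))
  write_counts(cohort$counts, dir)
  write_clinical_table(cohort$clinical, file.path(dir, "clinical.tsv"))
  if (!is.null(panel))
    utils::write.table(panel, file.path(dir, "panel.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(cells = file.path(dir, "cells.tsv"),
                 mtx = file.path(dir, "counts.mtx"),
                 genes = file.path(dir, "genes.tsv"),
                 barcodes = file.path(dir, "barcodes.tsv"),
                 clinical = file.path(dir, "clinical.tsv")))
}
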