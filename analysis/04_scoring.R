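#!/usr/bin/env Rscript
# Signature and crosstalk scoring: core Th2 module scores for CD4 T cells,
# type-2 mediator module scores for fibroblasts, per-cell fibroblast
# ligand scores, sample-level mean-ligand crosstalk scores and the
# three-component composite score, with the AR/control fold.

library(fibroTalk)

seed <- 20260930L
cells <- read_cell_table("results/cells_filtered.tsv")
counts <- read_counts("results/filtered/counts.mtx", "results/filtered/genes.tsv",
                      "results/filtered/barcodes.tsv")
norm <- normalize_expression(counts)

is_t <- cells$cell_type == "CD4_T"
is_f <- cells$cell_type == "fibroblast"
th2 <- module_score(norm[, is_t], core_th2_genes(), "core_th2", seed = seed)
med <- module_score(norm[, is_f], mediator_genes(), "mediator", seed = seed)
utils::write.table(rbind(th2, med), "results/module_scores.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

sg <- sample_graphs(cells, 20, types = c("CD4_T", "fibroblast"))
lig <- list(); ct <- list()
for (sid in names(sg$graphs)) {
  sc <- sg$cells_by_sample[[sid]]
  ls <- fibroblast_ligand_score(sc, sg$graphs[[sid]],
                                norm[, match(sc$cell_id, cells$cell_id)])
  lig[[sid]] <- cbind(sample_id = sid, ls$records)
  ct[[sid]] <- sample_crosstalk_score(ls$records, sid)
}
lig <- do.call(rbind, lig); ct <- do.call(rbind, ct)

adj <- cohort_adjacency(cells, 20)
th2_by <- tapply(th2$norm_score, cells$sample_id[is_t], mean)
med_by <- tapply(med$norm_score, cells$sample_id[is_f], mean)
ct$composite_score <- vapply(ct$sample_id, function(sid)
  composite_crosstalk_score(adj$adjacency_fraction[adj$sample_id == sid],
                            med_by[[sid]], th2_by[[sid]]), numeric(1))
ct$group <- adj$group[match(ct$sample_id, adj$sample_id)]

utils::write.table(lig, "results/ligand_scores.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(ct, "results/crosstalk.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

ar <- ct$group == "AR"
message(sprintf("mean ligand crosstalk score: AR %.2f vs control %.2f (x%.1f)",
                mean(ct$mean_ligand_score[ar]), mean(ct$mean_ligand_score[!ar]),
                mean(ct$mean_ligand_score[ar]) / mean(ct$mean_ligand_score[!ar])))
message(sprintf("composite score: AR %.3f vs control %.3f (x%.1f)",
                mean(ct$composite_score[ar]), mean(ct$composite_score[!ar]),
                mean(ct$composite_score[ar]) / mean(ct$composite_score[!ar])))
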