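#!/usr/bin/env Rscript
# Ligand-receptor co-expression testing on AR cells: fibroblast-to-CD4 T
# scores for TSLP-IL7R, OX40L-OX40 (TNFRSF4) and ICOSL-ICOS, with a
# label-permutation null and BH correction.

library(fibroTalk)

seed <- 20260930L
cells <- read_cell_table("results/cells_filtered.tsv")
counts <- read_counts("results/filtered/counts.mtx", "results/filtered/genes.tsv",
                      "results/filtered/barcodes.tsv")
norm <- normalize_expression(counts)

sel <- cells$group == "AR"
lr <- lr_permutation_test(norm[, sel], cells[sel, ], "fibroblast", "CD4_T",
                          default_lr_pairs(), n_perm = 10000, seed = seed)
utils::write.table(lr, "results/lr_results.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

for (i in seq_len(nrow(lr)))
  message(sprintf("%s-%s: score %.3f, p_adj %.3g", lr$ligand[i], lr$receptor[i],
                  lr$interaction_score[i], lr$p_adj[i]))
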