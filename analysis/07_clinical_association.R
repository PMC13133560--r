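#!/usr/bin/env Rscript
# Association analyses: adjacency-stratified Th2 cytokine contrasts in AR
# CD4 T cells, single-cell ligand-score correlations with IL4 and GATA3,
# and sample-level correlation of the crosstalk score with serum IgE and
# SPT wheal diameter.

library(fibroTalk)

cells <- read_cell_table("results/cells_filtered.tsv")
counts <- read_counts("results/filtered/counts.mtx", "results/filtered/genes.tsv",
                      "results/filtered/barcodes.tsv")
norm <- normalize_expression(counts)
clinical <- read_clinical_table("results/data/clinical.tsv")
ct <- utils::read.delim("results/crosstalk.tsv")

# cytokine folds in fibroblast-adjacent vs non-adjacent AR CD4 T cells
ar <- cells$group == "AR"
adjf <- adjacency_flags(cells, 20)
contrasts <- do.call(rbind, lapply(c("IL4", "IL5", "IL13"), function(g) {
  sel <- ar & cells$cell_type == "CD4_T"
  vals <- expm1(as.numeric(norm[g, sel])); aa <- adjf[sel]
  data.frame(gene = g, fold = mean(vals[aa]) / mean(vals[!aa]),
             p_wilcoxon = wilcoxon_rank_sum(vals[aa], vals[!aa])$p)
}))
utils::write.table(contrasts, "results/contrasts.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
for (i in seq_len(nrow(contrasts)))
  message(sprintf("%s: %.1f-fold higher in fibroblast-adjacent CD4 T cells (p %.2g)",
                  contrasts$gene[i], contrasts$fold[i], contrasts$p_wilcoxon[i]))

# single-cell ligand-score correlations in AR samples
lig <- utils::read.delim("results/ligand_scores.tsv")
lig <- lig[lig$sample_id %in% cells$sample_id[ar], ]
idx <- match(lig$t_cell_id, cells$cell_id)
cors <- rbind(
  pearson_correlation(lig$ligand_score, as.numeric(norm["IL4", idx]),
                      "ligand_score", "IL4"),
  pearson_correlation(lig$ligand_score, as.numeric(norm["GATA3", idx]),
                      "ligand_score", "GATA3"),
  clinical_association(ct, clinical, "mean_ligand_score"),
  clinical_association(ct, clinical, "composite_score")
)
utils::write.table(cors, "results/correlations.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
for (i in seq_len(nrow(cors)))
  message(sprintf("r(%s, %s) = %.2f (n = %d, p %.2g)", cors$x_name[i],
                  cors$y_name[i], cors$pearson_r[i], cors$n[i], cors$p[i]))
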