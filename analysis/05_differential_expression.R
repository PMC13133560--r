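#!/usr/bin/env Rscript
# Fibroblast differential expression between AR and control (per-gene
# Wilcoxon, Seurat-style thresholds, BH correction), and hypergeometric
# over-representation of the type-2 mediator set among the upregulated
# genes.

library(fibroTalk)

cells <- read_cell_table("results/cells_filtered.tsv")
counts <- read_counts("results/filtered/counts.mtx", "results/filtered/genes.tsv",
                      "results/filtered/barcodes.tsv")
norm <- normalize_expression(counts)

de <- differential_expression(norm, cells, "fibroblast", "AR", "control",
                              logfc_threshold = 0.25, min_pct = 0.1)
utils::write.table(de, "results/de_results.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

up <- de$gene[de$significant]
message(sprintf("%d genes tested; %d significantly upregulated in AR fibroblasts",
                nrow(de), length(up)))
meds <- de[de$gene %in% mediator_genes(), c("gene", "log2fc", "p_adj")]
message("mediator log2FC estimates:")
for (i in seq_len(nrow(meds)))
  message(sprintf("  %-6s %.2f (p_adj %.2g)", meds$gene[i], meds$log2fc[i], meds$p_adj[i]))

enr <- hypergeometric_enrichment(up, intersect(mediator_genes(), de$gene), de$gene)
utils::write.table(enr, "results/pathway_enrichment.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
message(sprintf("mediator-set enrichment among upregulated genes: fold %.1f, p = %.2g",
                enr$fold_enrichment, enr$p))
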