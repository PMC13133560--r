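#!/usr/bin/env Rscript
# Cell- and sample-level quality control of the simulated cohort: drop
# cells with <50 detected genes, >20% mitochondrial content or <100
# transcripts; drop samples retaining <3,000 cells. Writes the filtered
# cell table plus a QC summary under results/.

library(fibroTalk)

cells <- read_cell_table("results/data/cells.tsv")
counts <- read_counts("results/data/counts.mtx", "results/data/genes.tsv",
                      "results/data/barcodes.tsv")

flt <- filter_cells(cells, counts)
sq <- sample_qc(flt$cells)
keep <- flt$cells$sample_id %in% sq$sample_id[sq$pass]

write_cell_table(flt$cells[keep, ], "results/cells_filtered.tsv")
write_counts(flt$counts[, keep], "results/filtered")
utils::write.table(sq, "results/sample_qc.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

message(sprintf("cells: %d in, %d removed (%d low-gene, %d high-mito, %d low-depth)",
                flt$log["n_input"], flt$log["n_removed"],
                flt$log["removed_low_genes"], flt$log["removed_high_mito"],
                flt$log["removed_low_transcripts"]))
message(sprintf("samples passing (>=3,000 cells): %d of %d",
                sum(sq$pass), nrow(sq)))
message(sprintf("retained cells: %.0f +/- %.0f genes, %.0f +/- %.0f transcripts",
                mean(flt$cells$n_genes), stats::sd(flt$cells$n_genes),
                mean(flt$cells$n_transcripts), stats::sd(flt$cells$n_transcripts)))
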