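#!/usr/bin/env Rscript
# Generate the synthetic study cohort: 5 AR + 5 control nasal-mucosa
# tissues (~4,800 cells each, 412-gene panel) with the study presets —
# expanded fibroblast niches, biased CD4 T placement, T-adjacent mediator
# upregulation, Th2 coupling and clinical coupling — and write the
# pipeline's input files under results/data/.

library(fibroTalk)

seed <- 20260930L
out <- "results/data"

panel <- generate_panel()
config <- sim_config(n_samples_per_group = 5L, seed = seed)
cohort <- generate_cohort(config, panel, seed = seed)

paths <- write_cohort(cohort, out, panel = panel)
yaml::write_yaml(list(seed = seed, n_samples_per_group = 5L,
                      groups = config$groups,
                      cells_per_sample = config$cells_per_sample),
                 file.path(out, "sim_manifest.yaml"))

n_by <- table(cohort$cells$sample_id)
message(sprintf("wrote %d samples (%d cells, %d genes) to %s",
                length(n_by), nrow(cohort$cells), nrow(cohort$counts), out))
message(sprintf("cells per sample: %d-%d (median %d)",
                min(n_by), max(n_by), as.integer(stats::median(n_by))))
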