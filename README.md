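# fibroTalk

Spatially resolved analysis of fibroblast–CD4⁺ T cell crosstalk in nasal
mucosa, for single-cell-resolution spatial transcriptomics (Xenium-class
targeted panels). Allergic rhinitis (AR) is driven by type 2 immunity, and
mucosal fibroblasts are increasingly seen not as passive scaffold but as
active organizers of Th2 polarization: they expand into dense stromal
niches, colocalize with CD4⁺ T cells within paracrine range, and express
pro-Th2 ligands (TSLP, ICOSL, OX40L, CCL17, POSTN) exactly where T cells
sit. fibroTalk implements the full quantitative workflow for testing that
picture in situ, for analysts working with segmented cell tables and
genes × cells count matrices.

## What it computes

All spatial statements are built on 20 µm radius neighbor graphs
(the physiological range of paracrine signalling):

- **QC and normalization** — cell filters (<50 genes, >20% mitochondrial,
  <100 transcripts), sample filter (<3,000 retained cells), log
  library-size normalization `ln(1 + 10⁴·c/total)`.
- **Neighborhood enrichment** — observed cross-type neighbor-pair
  frequency over its permutation null (cell-type labels shuffled over
  fixed positions, within sample); proximity score = observed/null mean;
  one-tailed add-one permutation p with BH correction.
- **Adjacency statistics** — fraction of CD4⁺ T cells with ≥1 fibroblast
  within 20 µm; marker⁺ vs marker⁻ adjacency enrichment ratios with
  Fisher's exact test; cell-count tissue occupancy.
- **Module scores** — binned-control gene-set scores (25 abundance bins,
  100 controls/gene), min–max normalized to [0, 1] over the compared pool;
  used for the core Th2 set (IL4, IL5, IL13, IL9) and a 42-gene
  GATA3-target set.
- **Ligand and crosstalk scores** — per CD4⁺ T cell, the summed normalized
  expression of the five pro-Th2 ligands in its *nearest* fibroblast
  within 20 µm; per sample, the mean over all pairs (crosstalk score) and
  a composite score = adjacency × mediator-expression × Th2-signature.
- **Differential expression** — per-gene Wilcoxon between groups within a
  cell type (min.pct 0.1, log2FC threshold 0.25, BH), with exact
  enumeration at small n; hypergeometric pathway over-representation.
- **Ligand–receptor testing** — permutation co-expression test for a
  supplied pair list (default TSLP–IL7R, OX40L–TNFRSF4, ICOSL–ICOS).
- **Clinical association** — Pearson correlation of sample crosstalk
  scores with serum total IgE and SPT wheal diameter.

Because no public dataset accompanies the analysis, the package ships a
**synthetic tissue generator** (`generate_tissue()`, `generate_cohort()`)
that plants all of the above effects at configurable sizes — zonated
9-type tissues, biased CD4 T placement at a target adjacency fraction,
T-adjacent mediator upregulation, ligand-score-coupled Th2 expression,
and clinical severity coupled to the crosstalk score. Its default presets
are calibrated to the reference cohort's reported group statistics
(fibroblast occupancy 34.2 ± 3.1% vs 15.6 ± 2.4%; adjacency 62.3 ± 4.5%
vs 28.7 ± 3.8%; mediator log2FCs 1.82/1.56/1.28/1.15/1.03/0.98; IL4 fold
2.7; ligand-score/IL4 r = 0.79; crosstalk/IgE r = 0.71). The methods
vignette (`vignettes/crosstalk-methods.Rmd`) documents every model and
calibration choice.

## Worked example

```r
library(fibroTalk)

panel  <- generate_panel()                      # 412-gene synthetic panel
config <- sim_config(n_samples_per_group = 2L, cells_per_sample = 2400L)
cohort <- generate_cohort(config, panel, seed = 7)

flt  <- filter_cells(cohort$cells, cohort$counts)
norm <- normalize_expression(flt$counts)
adj  <- cohort_adjacency(flt$cells, radius = 20)
adj
#>    sample_id   group adjacency_fraction occupancy_pct
#> 1      AR_01      AR              0.610          38.7
#> 2      AR_02      AR              0.585          34.4
#> 3 control_01 control              0.322          20.3
#> 4 control_02 control              0.301          12.7
```

AR samples show both the expanded fibroblast compartment (~37% of cells
vs ~17%) and the doubled CD4 T adjacency (~60% vs ~31%). Scoring each
CD4⁺ T cell against its nearest fibroblast and averaging per sample:

```r
sg <- sample_graphs(flt$cells, 20, types = c("CD4_T", "fibroblast"))
ct <- do.call(rbind, lapply(names(sg$graphs), function(sid) {
  sc <- sg$cells_by_sample[[sid]]
  ls <- fibroblast_ligand_score(sc, sg$graphs[[sid]],
                                norm[, match(sc$cell_id, flt$cells$cell_id)])
  sample_crosstalk_score(ls$records, sid)
}))
ct
#>    sample_id mean_ligand_score n_pairs undefined
#> 1      AR_01             15.20     152     FALSE
#> 2      AR_02             15.25     152     FALSE
#> 3 control_01              9.21      73     FALSE
#> 4 control_02              7.38      77     FALSE

clinical_association(ct, cohort$clinical)
#>              x_name    y_name n pearson_r    p
#> 1 mean_ligand_score serum_IgE 4      0.85 0.15
#> 2 mean_ligand_score spt_wheal 4      0.93 0.07
```

The crosstalk score separates the groups (~15.2 vs ~8.3) and tracks the
simulated clinical severity; at n = 4 samples the correlations are of
course only illustrative — the full analysis over the study-sized cohort
lives in `analysis/01_simulate_cohort.R` … `07_clinical_association.R`,
each a short driver that writes its tables under `results/`.

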