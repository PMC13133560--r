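---
title: "Quantifying fibroblast-CD4 T cell crosstalk in spatial transcriptomics: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying fibroblast-CD4 T cell crosstalk in spatial transcriptomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

fibroTalk quantifies stromal-immune crosstalk in single-cell-resolution
spatial transcriptomics of nasal mucosa, centred on the interaction between
fibroblasts and CD4+ T cells that drives Th2 polarization in allergic
rhinitis (AR). This vignette explains the statistical models behind each
step, the tunable parameters and their defaults, what the synthetic tissue
generator does and does not emulate, and the design decisions taken where
more than one reasonable construction existed.

## The analysis model

**Neighborhoods.** All spatial reasoning uses a radius graph: two cells are
neighbors when their Euclidean distance is at most 20 µm, the range over
which paracrine mediators (TSLP, IL-33, CCL17) and juxtacrine costimulation
(OX40L-OX40, ICOSL-ICOS) act in mucosal tissue. The radius query is exact
(grid-bucketed search, no approximate nearest-neighbor structure), distances
are stored per edge, and no edge correction is applied at tissue borders.

**Neighborhood enrichment.** For a pair of cell types $(a, b)$ the observed
enrichment is the number of $a$-$b$ neighbor pairs divided by the total
number of neighbor pairs in the sample. The null distribution comes from
shuffling cell-type labels over the fixed positions — tissue architecture
and density are preserved, identities are randomized — and the proximity
score is the ratio of observed enrichment to the null mean, so 1 means "as
expected by chance". The one-tailed p-value uses the add-one estimator
$(1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_{\text{perm}})$, which can
never be exactly zero and is valid under exchangeability; BH correction is
applied across tests. Labels are always shuffled within a sample, never
across samples, and group-level statements aggregate per-sample statistics
rather than pooled cells.

**Module scores.** A gene set's score per cell is its mean normalized
expression minus the mean of expression-matched control genes: panel genes
are binned into 25 equal-frequency bins of average expression, and 100
controls per set gene are drawn from the gene's bin, excluding the set
itself (a set gene among its own controls would shrink the score toward
zero by construction; the exclusion makes the small-panel behaviour exact,
and the draw falls back to the full bin only if nothing else is in it).
Raw scores are min-max rescaled to [0, 1] over the scored pool. The pool is
deliberately *all* cells compared in one analysis — both adjacency strata,
both groups — so that strata share one scale; rescaling strata separately
would erase the contrast being measured.

**Ligand and crosstalk scores.** Each CD4+ T cell with at least one
fibroblast within 20 µm is paired with its *nearest* fibroblast (ties go to
the smaller cell index, deterministically); its ligand score is the sum of
that fibroblast's normalized expression of TSLP, ICOSL, OX40L, CCL17 and
POSTN. The sample crosstalk score is the arithmetic mean of these ligand
scores over all pairs. The composite variant multiplies three sample-level
components: the CD4-to-fibroblast adjacency fraction, the mean fibroblast
mediator module score (the six-gene set adding IL33), and the mean CD4 core
Th2 module score. The mediator component's gene set is a package choice:
the six mediators are the documented upregulated set, and a module score
over them is the natural "type 2 mediator expression" summary.

**Differential expression.** Per-gene two-sided Wilcoxon rank-sum tests on
the normalized layer between groups within a cell type, testing only genes
detected in at least 10% of either group. The log2 fold change uses
back-transformed means, $\log_2((\bar{x}_a + \varepsilon)/(\bar{x}_b +
\varepsilon))$ with $\bar{x} = \text{mean}(\text{expm1}(\text{norm}))$ and
$\varepsilon = 10^{-9}$; the exact formula in the upstream ecosystem is not
published, so this conventional pseudo-count form is adopted and
documented. Significance: BH-adjusted p < 0.05 and log2FC > 0.25. The
Wilcoxon implementation switches to exact enumeration when the pooled
sample size is at most 12 and there are no ties; otherwise it uses the
tie-corrected normal approximation with continuity correction.

**Ligand-receptor testing.** A curated interaction database is out of
scope; instead a user-supplied pair list (default: TSLP-IL7R, OX40L-OX40,
ICOSL-ICOS) is scored as the mean of the ligand's mean expression in the
sender type and the receptor's mean in the receiver type, with a null built
by shuffling sender/receiver labels within the union of the two
populations. The score definition is a documented convention — the upstream
tool does not publish its internal formula — and the permutation p uses the
same add-one estimator as above.

**Associations.** Adjacency-stratified contrasts compare fibroblast-adjacent
(≥1 fibroblast within 20 µm) against non-adjacent cells; "fibroblast-poor"
is operationalized as the complement of adjacency. Cell-level Wilcoxon tests
are the headline (matching common practice), but per-sample stratum means
are always reported alongside, because pooled cell-level testing treats
cells as independent and inflates significance. Clinical association is the
sample-level Pearson correlation of the crosstalk score with serum total
IgE and SPT wheal diameter, with the t-distribution p-value.

## The synthetic tissue generator

No real dataset accompanies this package, so the generator is a first-class
module: it plants every effect the pipeline is supposed to detect, at
configurable sizes, and the default presets are the study conditions used
throughout the tests and the acceptance script.

**Geometry and composition.** Each sample is a 1,550 × 1,550 µm rectangle
(≈2,000 cells/mm² at the default 4,800 cells, a realistic segmentation
density for mucosal tissue). Epithelial cells are confined to a 200-µm
surface band sized so the band's cell density stays close to the stromal
density — a much thinner band would concentrate so many edges that the
neighbor graph, and with it every pair-fraction statistic, would be
dominated by epithelium. Fibroblasts are placed as a clustered (Thomas)
process in the stroma beneath — uniform cluster centres with on average
12 offspring scattered at 35 µm SD — reproducing the dense stromal
networks of inflamed mucosa; clustering also lowers the tissue fraction
within 20 µm of a fibroblast, which is what makes the planted adjacency
fractions genuinely *enriched* relative to random placement rather than
near the random baseline. Endothelial cells are uniform in the stroma;
immune cells are placed throughout. Per-sample cell counts are drawn around
the nominal size and clamped to the 3,500-6,000 range. Cell-type fractions:
fibroblasts 34.2 ± 3.1% of cells in AR and 15.6 ± 2.4% in control (the ±
values are *between-sample* SDs, planted as per-sample Gaussian draws);
CD4+ T cells 11%; the remainder is split among the other seven types at
fixed proportions.

**Planted adjacency.** CD4+ T placement uses thinning: uniform proposals
are accepted with weight $1 + b$ when within 20 µm of a fibroblast and 1
otherwise. Rather than fixing $b$, the presets specify the *target*
adjacency fraction (62.3 ± 4.5% AR, 28.7 ± 3.8% control) and derive $b$
per tissue from the empirically measured fibroblast coverage $q$ of that
tissue via $1 + b = \frac{t(1-q)}{q(1-t)}$, which makes the expected
adjacency equal the target irrespective of geometry, density or
fibroblast abundance. A fixed bias would drift with every one of those; a
self-calibrating target is the only way to plant the reference fractions
stably. A fixed-bias mode remains available (used by the null
configuration). Because the reference adjacency statistics describe the
*post-QC* cell population, each fibroblast's mitochondrial fraction is
decided at placement time and the planted adjacency (and the
nearest-fibroblast pairing that drives the Th2 coupling) targets
QC-viable fibroblasts only — those whose planted mito fraction is at or
below the 20% cut-off. Planting against all fibroblasts would let the
mito filter attenuate the realized adjacency by about one percentage
point in the control group, a systematic bias rather than noise.

**Counts.** Transcript counts are negative binomial with variance
$\mu + \phi\mu^2$. Structural genes (markers, background, mitochondrial)
use $\phi = 0.5$, the conventional dispersion for targeted in-situ counts.
The explicitly modelled program genes — mediators in fibroblasts, cytokines,
receptors, GATA3 and its targets in T cells — use a small residual
$\phi = 0.05$: their biological between-cell variation is injected
explicitly through the heterogeneity and coupling terms below, and giving
them the full dispersion on top would double-count that variation.
Background gene abundances follow a deterministic lognormal-quantile
profile (meanlog 0.05, sdlog 2.05, total 700), and per-cell depth is
lognormal (sdlog 0.22); together these were calibrated once so that
post-QC cells average ≈125 detected genes and ≈850 transcripts. Per-cell
mitochondrial fractions are Beta(2, 26), leaving a small tail above the
20% QC cut-off (≈3-4% of cells removed). The per-cell SDs of detected
genes and transcripts come out somewhat different from ±30/±150; the
calibration targets the means, which are the quantities the QC filters
act on.

**Planted effects.** In AR tissues, fibroblasts within 20 µm of a CD4+ T
cell scale their mediator means by $2^{\text{log2FC}}$ with the preset
effects TSLP 1.82, IL33 1.56, CCL17 1.28, ICOSL 1.15, OX40L 1.03, POSTN
0.98. Every fibroblast also carries a lognormal mediator factor (sdlog 1.2,
shared across the six genes) and every sample a lognormal multiplier
(sdlog 0.25) — the first creates the single-cell ligand-score spread that
the correlation analyses need, the second the between-patient spread that
the clinical correlations need. Each CD4+ T cell's program-gene means are
scaled by $\exp(s L + \eta)$ where $L$ is the ligand score of its nearest
fibroblast at generation time ($L = 0$ if none within 20 µm), $s = 0.070$
in AR and 0 in control, and $\eta \sim N(0, 0.10)$. The slope, baselines
and heterogeneity were calibrated once, jointly, so that the pipeline
recovers the planted study statistics: an IL4 adjacent/non-adjacent fold of
≈2.7, a TSLP+ fibroblast adjacency enrichment of ≈3.2, and a single-cell
ligand-score/IL4 correlation of ≈0.79.

**Clinical coupling.** Serum IgE is $120 + 40 \times \text{crosstalk score}
+ N(0, 62)$ IU/mL and SPT wheal $2.0 + 0.55 \times \text{score} + N(0,
1.0)$ mm, truncated positive. The noise SDs were calibrated against the
realized between-sample score SD in 30-patient cohorts so the measured
Pearson correlations centre on 0.71 (IgE) and 0.65 (SPT). Because the
per-cohort score SD is right-skewed (the lognormal sample multiplier),
the noise was solved against the *mean measured correlation* across
cohorts, not against a point estimate of the SD — a plug-in SD calibration
overshoots the correlation.

**The null configuration** (`null_config()`) switches every planted effect
off: no zonation, uniform (non-clustered) fibroblast placement, no
placement bias, equal group compositions, zero mediator upregulation,
zero coupling slopes. Under it, labels are
independent of positions and the groups are exchangeable, which is the
reference point for the calibration suite: proximity scores centre on 1,
permutation and Wilcoxon p-values are near-uniform, and BH yields no
discoveries.

**What the generator does not emulate.** Segmentation errors and transcript
misassignment between touching cells; spatial autocorrelation of expression
within a compartment beyond the planted adjacency effects; fibroblast
subtypes; anisotropic tissue architecture (crypts, vessels); batch effects
between samples (the analysis is per-sample throughout, so none are
planted). Passing the recovery suite therefore shows that the estimators
are unbiased and calibrated under the stated generative model — not that
they are robust to segmentation artefacts or batch structure in real
Xenium-class data.

## Numerical and interface choices

- **QC inclusivity** follows strict inequalities: a cell is removed iff
  genes < 50 *or* mito fraction > 0.20 *or* transcripts < 100; boundary
  cells are retained. Sample QC fails below 3,000 retained cells.
- **Normalization** is $\ln(1 + 10^4 \cdot c / \text{total})$; natural log
  (the upstream convention does not state the base). Zero-count cells get
  all-zero values with a warning rather than NaN.
- **Annotation** (optional; generator labels are normally used) is the
  argmax of mean normalized marker expression, ties broken
  lexicographically and flagged. On default synthetic tissues agreement
  with the generating labels exceeds 95%.
- **Tissue occupancy** is the cell-count fraction; the source quantity is
  an area fraction, but no area definition is given and at
  single-cell-resolution composition the two track each other. A
  Voronoi-area variant would be the natural extension.
- **Ordered vs unordered pairs** in the enrichment denominator: unordered
  is implemented; the choice cancels in the observed/null ratio.
- **Marker positivity** defaults to normalized expression > 0 (any
  detected transcript), configurable.
- **Degenerate inputs** are flagged, not silently dropped: empty strata
  give `NA`/`Inf` with a `degenerate` flag, zero-pair samples an
  `undefined` crosstalk score, an all-equal score pool gives all-zero
  normalized module scores.
- The composite-score fold reconstructed from the reported group means
  ((0.623 × 0.62)/(0.287 × 0.28) ≈ 4.8, mediator component equal between
  groups) is the anchor used in the reproduction checks; the reference
  material also quotes a much larger fold for the same quantity that is
  not reconstructible from any reported component combination — the
  discrepancy is surfaced here rather than resolved.
- The clinical-correlation cohort size is 30 patients, matching the figure
  legends of the source material even though the recruitment section
  describes fewer; the generator exposes `n_samples_per_group` rather than
  fixing it.

## Problem sizes

The test suite runs the full study cohort (10 + 10 samples at ~4,800
cells) once for the composition recovery check, five 2-sample AR cohorts
at 3,500 cells for the coupling recovery checks, five 12-sample clinical
cohorts at 2,400 cells for the clinical correlation, 200 small
(600-cell) null tissues for calibration, and enumeration-scale toys for
the oracle checks. The acceptance script uses the full-size presets: 10
samples per group for composition, five 3-sample cohorts for coupling,
and ten 30-patient cohorts at 3,600 cells per sample for the clinical
correlation. These sizes keep every Monte-Carlo standard error
comfortably below the corresponding acceptance tolerance.

## Known limitations

- Cell-level pooled Wilcoxon tests are anti-conservative under per-sample
  correlation (pseudoreplication); the per-sample aggregation outputs are
  provided and should be preferred for formal group inference.
- The permutation null conditions on the observed composition; it does not
  model between-sample composition variability.
- Min-max normalization of module scores makes the 0-1 scale pool-relative:
  scores are comparable within one call, not across datasets.
- The count-fraction occupancy proxy diverges from an area fraction when
  cell sizes differ systematically between types; that covariate is not
  modelled.
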