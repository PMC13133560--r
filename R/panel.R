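#' Gene sets used throughout the crosstalk analysis
#'
#' Accessors for the fixed gene sets the analysis is built around: the four
#' core Th2 cytokines, the five pro-Th2 fibroblast ligands summed into the
#' per-cell ligand score, and the six type-2 mediators upregulated in
#' T-adjacent fibroblasts (the five ligands plus IL33).
#'
#' @return Character vector of gene symbols.
#' @export
core_th2_genes <- function() c("IL4", "IL5", "IL13", "IL9")

#' @rdname core_th2_genes
#' @export
pro_th2_ligands <- function() c("TSLP", "ICOSL", "OX40L", "CCL17", "POSTN")

#' @rdname core_th2_genes
#' @export
mediator_genes <- function() c("TSLP", "IL33", "CCL17", "ICOSL", "OX40L", "POSTN")

#' Canonical marker genes for the nine mucosal cell types
#'
#' Marker sets used both by the synthetic panel and by the optional
#' marker-argmax annotator. CD3E is shared between the two T-cell types, as
#' is conventional; each type additionally carries lineage-restricted
#' markers.
#'
#' @return Named list, one character vector of gene symbols per cell type.
#' @export
default_marker_map <- function() {
  list(
    B_cell      = c("MS4A1", "CD79A", "IGHD"),
    CD4_T       = c("CD3E", "CD4", "FOXP3"),
    CD8_T       = c("CD3E", "CD8A", "GZMB"),
    dendritic   = c("LYZ", "CD1C", "CLEC9A"),
    endothelial = c("PECAM1", "VWF", "CDH5"),
    epithelial  = c("EPCAM", "KRT18", "MUC5AC"),
    fibroblast  = c("COL1A1", "PDGFRA", "DCN"),
    macrophage  = c("CD68", "CD163", "MRC1"),
    mast        = c("TPSAB1", "CMA1", "KIT")
  )
}

#' Cell types modelled by the generator and annotator
#' @return Character vector of the nine cell-type labels.
#' @export
cell_types <- function() names(default_marker_map())

# Genes that are required in every panel besides markers:
# Th2 cytokines, the 5 scored ligands, IL33 (6th mediator), the three
# T-cell receptors of the headline ligand-receptor axes, GATA3, and
# mitochondrial genes.
panel_required_genes <- function() {
  list(
    th2_cytokine   = core_th2_genes(),
    pro_th2_ligand = pro_th2_ligands(),
    mediator_extra = "IL33",
    receptor       = c("IL7R", "TNFRSF4", "ICOS"),
    tf             = "GATA3",
    mito           = c("MT-CO1", "MT-ND1", "MT-ATP6")
  )
}

#' Generate a targeted gene-panel manifest
#'
#' Builds the manifest of a synthetic in-situ gene panel mirroring a
#' ~400-gene targeted assay: >=3 canonical markers for each of the nine cell
#' types, the four core Th2 cytokines, the five pro-Th2 fibroblast ligands
#' (TSLP, ICOSL, OX40L, CCL17, POSTN), IL33, the receptors IL7R / TNFRSF4 /
#' ICOS, GATA3, a 42-member synthetic GATA3-target set (symbols G3T01..G3T42,
#' stand-ins for validated GATA3-binding genes), mitochondrial genes, and
#' `n_background` filler genes (BG001, BG002, ...).
#'
#' @param n_background Number of background (filler) genes; the default
#'   brings the panel to 412 genes total.
#' @param seed Unused at present (the manifest is deterministic); kept so a
#'   randomised panel variant stays call-compatible.
#' @return A `data.frame` with columns `gene_id`, `role` (one of `marker`,
#'   `th2_cytokine`, `pro_th2_ligand`, `gata3_target`, `mito`, `background`)
#'   and `marker_type` (cell type for marker genes, `NA` otherwise). Genes
#'   whose role in the analysis is finer than the role vocabulary (IL33,
#'   receptors, GATA3) carry role `background` and are picked up by name
#'   where needed.
#' @export
generate_panel <- function(n_background = NULL, seed = 1L) {
  mm  <- default_marker_map()
  req <- panel_required_genes()
  marker_genes <- unique(unlist(mm, use.names = FALSE))
  marker_type <- vapply(marker_genes, function(g) {
    types <- names(mm)[vapply(mm, function(v) g %in% v, logical(1))]
    types[[1]]  # CD3E maps to the lexicographically first T type
  }, character(1))

  gata3_targets <- sprintf("G3T%02d", seq_len(42))
  n_required <- length(marker_genes) + length(unlist(req)) + length(gata3_targets)
  if (is.null(n_background)) n_background <- 412L - n_required
  stopifnot(n_background >= 0)
  background <- if (n_background > 0) sprintf("BG%03d", seq_len(n_background)) else character(0)

  manifest <- rbind(
    data.frame(gene_id = marker_genes, role = "marker", marker_type = unname(marker_type)),
    data.frame(gene_id = req$th2_cytokine, role = "th2_cytokine", marker_type = NA_character_),
    data.frame(gene_id = req$pro_th2_ligand, role = "pro_th2_ligand", marker_type = NA_character_),
    data.frame(gene_id = gata3_targets, role = "gata3_target", marker_type = NA_character_),
    data.frame(gene_id = c(req$mediator_extra, req$receptor, req$tf),
               role = "background", marker_type = NA_character_),
    data.frame(gene_id = req$mito, role = "mito", marker_type = NA_character_),
    data.frame(gene_id = background,
               role = rep("background", length(background)),
               marker_type = rep(NA_character_, length(background)))
  )
  rownames(manifest) <- NULL
  stopifnot(!anyDuplicated(manifest$gene_id))
  manifest
}

#' GATA3-target gene set of a panel manifest
#' @param panel A panel manifest from [generate_panel()].
#' @return Character vector of gata3_target gene ids.
#' @export
gata3_target_genes <- function(panel) {
  panel$gene_id[panel$role == "gata3_target"]
}
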