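#' Simulation configuration for synthetic spatial tissue cohorts
#'
#' Builds the configuration of the synthetic spatial-tissue generator. The
#' defaults are the cohort presets used throughout: an AR (allergic
#' rhinitis) and a control group whose planted statistics reproduce the
#' reference cohort's group means — fibroblast occupancy 34.2 +/- 3.1% vs
#' 15.6 +/- 2.4% of cells, CD4+ T-cell-to-fibroblast 20-um adjacency
#' 62.3 +/- 4.5% vs 28.7 +/- 3.8%, T-adjacent fibroblast upregulation of
#' the six type-2 mediators at log2 fold changes 1.82 (TSLP), 1.56 (IL33),
#' 1.28 (CCL17), 1.15 (ICOSL), 1.03 (OX40L), 0.98 (POSTN), a Th2 coupling
#' of T-cell cytokine programs to the neighbouring fibroblast ligand score,
#' and clinical severity (serum IgE, SPT wheal) coupled to the sample
#' crosstalk score. Per-sample standard deviations plant between-patient
#' heterogeneity at the printed SDs.
#'
#' The adjacency preset is expressed as a target fraction
#' (`adjacency_target_by_group`): at generation time the CD4+ T placement
#' bias is derived per tissue from the empirically measured fibroblast
#' coverage so the expected adjacency fraction equals the target regardless
#' of tissue geometry. A fixed `adjacency_bias_by_group` (thinning weight
#' `1 + bias` within 20 um of a fibroblast) can be supplied instead by
#' setting the corresponding target to `NA`.
#'
#' @param n_samples_per_group Samples per group.
#' @param cells_per_sample Nominal cells per sample (per-sample counts are
#'   drawn around this and clamped to `cells_range`).
#' @param cells_sd,cells_range Between-sample spread and clamp of the cell
#'   count.
#' @param tissue_width,tissue_height Tissue extent in micrometres.
#' @param epithelial_band Depth of the mucosal-surface band (um) to which
#'   epithelial cells are confined; the default keeps the band's cell
#'   density close to the stromal density so compartment structure does
#'   not dominate the neighbor graph.
#' @param zonation When `FALSE`, compartment structure is switched off and
#'   every type is placed uniformly (the fully exchangeable null used for
#'   calibration studies).
#' @param radius Paracrine neighborhood radius (um) used for all planted
#'   adjacency effects.
#' @param groups Group labels; the first is the disease group.
#' @param fibroblast_fraction_by_group,fibroblast_sd_by_group Planted
#'   per-sample fibroblast cell fraction (mean, SD) per group.
#' @param adjacency_target_by_group,adjacency_sd_by_group Planted CD4-to-
#'   fibroblast adjacency fraction (mean, SD) per group.
#' @param adjacency_bias_by_group Fixed placement bias per group, used only
#'   where the target is `NA`.
#' @param cd4_fraction CD4+ T cell fraction of all cells.
#' @param fibro_cluster_size,fibro_cluster_sd Fibroblasts are placed as a
#'   clustered (Thomas) process: uniform cluster centres in the stroma
#'   with `fibro_cluster_size` offspring on average, scattered with an
#'   isotropic Gaussian of this SD (um) — the dense stromal networks seen
#'   in mucosa. Set `fibro_cluster_size` to `NA` for uniform placement
#'   (the exchangeable null).
#' @param ligand_upregulation Named log2 effects applied to mediator genes
#'   of T-adjacent fibroblasts in the disease group.
#' @param th2_coupling_slope_by_group Per-group slope of T-cell program
#'   means on the nearest-fibroblast ligand score (log scale).
#' @param th2_noise_sd SD of the per-cell lognormal noise on coupled T-cell
#'   programs.
#' @param dispersion Negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`) of structural/background genes.
#' @param program_dispersion Residual dispersion of the explicitly modelled
#'   program genes (mediators, cytokines, receptors, GATA3 and its
#'   targets), whose biological variation is injected through the coupling
#'   and heterogeneity terms instead.
#' @param depth_sdlog Per-cell lognormal library-depth spread.
#' @param mito_beta Beta(shape1, shape2) of the per-cell mitochondrial
#'   fraction; the default leaves a small tail above the 20% QC cut-off.
#' @param ligand_cell_sdlog Per-fibroblast lognormal heterogeneity of
#'   mediator expression (one factor per cell, shared across mediators).
#' @param ligand_sample_sdlog Per-sample lognormal mediator multiplier
#'   (between-patient heterogeneity driving the crosstalk-score spread).
#' @param clinical_coupling List with `ige_intercept`, `ige_slope`,
#'   `ige_noise_sd`, `spt_intercept`, `spt_slope`, `spt_noise_sd`; clinical
#'   values are `intercept + slope * sample crosstalk score + noise`,
#'   truncated positive.
#' @param expr Named list of baseline expression means (see
#'   [default_expression_params()]).
#' @param seed Default master seed.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(
    n_samples_per_group = 10L,
    cells_per_sample = 4800L,
    cells_sd = 500,
    cells_range = NULL,
    tissue_width = 1550,
    tissue_height = 1550,
    epithelial_band = 200,
    zonation = TRUE,
    radius = 20,
    groups = c("AR", "control"),
    fibroblast_fraction_by_group = c(AR = 0.342, control = 0.156),
    fibroblast_sd_by_group = c(AR = 0.031, control = 0.024),
    adjacency_target_by_group = c(AR = 0.623, control = 0.287),
    adjacency_sd_by_group = c(AR = 0.045, control = 0.038),
    adjacency_bias_by_group = c(AR = NA_real_, control = NA_real_),
    cd4_fraction = 0.11,
    fibro_cluster_size = 12,
    fibro_cluster_sd = 35,
    ligand_upregulation = c(TSLP = 1.82, IL33 = 1.56, CCL17 = 1.28,
                            ICOSL = 1.15, OX40L = 1.03, POSTN = 0.98),
    th2_coupling_slope_by_group = c(AR = 0.070, control = 0),
    th2_noise_sd = 0.10,
    dispersion = 0.5,
    program_dispersion = 0.05,
    depth_sdlog = 0.22,
    mito_beta = c(2, 26),
    ligand_cell_sdlog = 1.2,
    ligand_sample_sdlog = 0.25,
    clinical_coupling = list(ige_intercept = 120, ige_slope = 40, ige_noise_sd = 62,
                             spt_intercept = 2.0, spt_slope = 0.55, spt_noise_sd = 1.0),
    expr = default_expression_params(),
    seed = 1L) {
  cfg <- as.list(environment())
  # per-sample cell counts are clamped to this window (3,500-6,000 at the
  # default 4,800 nominal size)
  if (is.null(cfg$cells_range))
    cfg$cells_range <- round(cells_per_sample * c(3500, 6000) / 4800)
  stopifnot(cells_per_sample >= 0,
            all(fibroblast_fraction_by_group >= 0 & fibroblast_fraction_by_group <= 1),
            cd4_fraction >= 0 && cd4_fraction <= 1,
            all(is.na(adjacency_target_by_group) |
                  (adjacency_target_by_group > 0 & adjacency_target_by_group < 1)),
            tissue_width > 0, tissue_height > 0, radius > 0,
            n_samples_per_group >= 1)
  structure(cfg, class = "sim_config")
}

#' Baseline expression means of the synthetic panel
#'
#' Per-gene negative-binomial baseline means by cell type, chosen so that
#' post-QC cells average about 125 detected genes and 850 transcripts.
#' Marker genes are high in their own type with a small leak elsewhere;
#' background genes follow a deterministic lognormal-quantile abundance
#' profile shared by all types; program genes (mediators in fibroblasts,
#' cytokines / receptors / GATA3 and its targets in CD4+ T cells) have
#' explicit baselines.
#'
#' @return Named list of scalar parameters used by the generator.
#' @export
default_expression_params <- function() {
  list(
    marker_mean = 14,
    leak = 0.02,
    background_meanlog = 0.05,
    background_sdlog = 2.05,
    background_total = 700,    # background means are rescaled to this sum
    ligand_base = c(TSLP = 1.3, IL33 = 0.75, CCL17 = 0.65, ICOSL = 0.85,
                    OX40L = 0.65, POSTN = 2.2),
    th2_base = c(IL4 = 12, IL5 = 5, IL13 = 6, IL9 = 1.5),
    gata3_base = 4.0,
    gata3_target_base = 0.35,
    receptor_base = c(IL7R = 2.5, TNFRSF4 = 1.2, ICOS = 1.4),
    mito_share = c(0.5, 0.3, 0.2)  # split of mito mass over the 3 MT- genes
  )
}

# deterministic seed sub-stream (kept below 2^31)
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 100000) * 20011 + 7 * k) %% 2147483647L
}

# nearest q-point within `radius` of each p-point (grid-bucketed exact
# search); returns list(dist, idx) with Inf/NA where no q-point is in range
nearest_within <- function(px, py, qx, qy, radius) {
  np <- length(px)
  dist <- rep(Inf, np); idx <- rep(NA_integer_, np)
  if (np == 0 || length(qx) == 0) return(list(dist = dist, idx = idx))
  h <- radius
  qgx <- floor(qx / h); qgy <- floor(qy / h)
  qkey <- paste(qgx, qgy, sep = ",")
  qbuckets <- split(seq_along(qx), qkey)
  pgx <- floor(px / h); pgy <- floor(py / h)
  pkey <- paste(pgx, pgy, sep = ",")
  pbuckets <- split(seq_len(np), pkey)
  pcoord <- do.call(rbind, strsplit(names(pbuckets), ",", fixed = TRUE))
  pbx <- as.numeric(pcoord[, 1]); pby <- as.numeric(pcoord[, 2])
  for (b in seq_along(pbuckets)) {
    ip <- pbuckets[[b]]
    iq <- integer(0)
    for (dx in -1:1) for (dy in -1:1) {
      hit <- qbuckets[[paste(pbx[b] + dx, pby[b] + dy, sep = ",")]]
      if (!is.null(hit)) iq <- c(iq, hit)
    }
    if (length(iq) == 0) next
    dmat <- sqrt(outer(px[ip], qx[iq], "-")^2 + outer(py[ip], qy[iq], "-")^2)
    j <- max.col(-dmat, ties.method = "first")
    dmin <- dmat[cbind(seq_along(ip), j)]
    ok <- dmin <= radius
    dist[ip[ok]] <- dmin[ok]
    idx[ip[ok]] <- iq[j[ok]]
  }
  list(dist = dist, idx = idx)
}

# genes x types baseline mean matrix
build_base_means <- function(panel, expr) {
  types <- cell_types()
  genes <- panel$gene_id
  m <- matrix(expr$leak, nrow = length(genes), ncol = length(types),
              dimnames = list(genes, types))
  mm <- default_marker_map()
  for (ty in types) m[mm[[ty]], ty] <- expr$marker_mean
  # background genes: deterministic lognormal-quantile profile, all types
  bg <- genes[panel$role == "background" &
                !genes %in% c("IL33", "IL7R", "TNFRSF4", "ICOS", "GATA3")]
  if (length(bg)) {
    q <- stats::qlnorm((seq_along(bg) - 0.5) / length(bg),
                       expr$background_meanlog, expr$background_sdlog)
    q <- q * expr$background_total / sum(q)
    m[bg, ] <- matrix(q, nrow = length(bg), ncol = length(types))
  }
  m[names(expr$ligand_base), "fibroblast"] <- expr$ligand_base
  m[names(expr$th2_base), "CD4_T"] <- expr$th2_base
  m["GATA3", "CD4_T"] <- expr$gata3_base
  m[gata3_target_genes(panel), "CD4_T"] <- expr$gata3_target_base
  m[names(expr$receptor_base), "CD4_T"] <- expr$receptor_base
  m
}

# gene classes drawn with the lower residual (program) dispersion
program_genes <- function(panel) {
  unique(c(mediator_genes(), core_th2_genes(), "GATA3",
           gata3_target_genes(panel), "IL7R", "TNFRSF4", "ICOS"))
}

# NB draw for a dense mean matrix with per-gene size parameter
draw_counts <- function(mu, size_by_gene) {
  n <- length(mu)
  counts <- stats::rnbinom(n, mu = as.vector(mu), size = rep(size_by_gene, times = ncol(mu)))
  matrix(counts, nrow = nrow(mu), dimnames = dimnames(mu))
}

#' Generate one synthetic spatial tissue sample
#'
#' Places cells of nine types in a rectangular tissue (epithelial cells
#' confined to the surface band, fibroblasts and endothelial cells to the
#' stroma, immune cells throughout), plants the configured CD4+
#' T-to-fibroblast adjacency by thinning-based placement, then draws
#' negative-binomial counts: T-adjacent fibroblasts in the disease group
#' upregulate the six type-2 mediators by the configured log2 effects, and
#' each CD4+ T cell's cytokine / GATA3-program means are scaled by
#' `exp(slope * ligand score of its nearest fibroblast + noise)`.
#'
#' @param config A [sim_config()].
#' @param panel Panel manifest from [generate_panel()].
#' @param sample_id Sample label.
#' @param group Group label (must be one of `config$groups`).
#' @param seed Integer seed; identical seeds give identical output.
#' @return List with `cells` (cell table including QC covariates and truth
#'   columns `true_adjacent`, `true_ligand_score`), `counts` (sparse genes
#'   x cells), and `truth` (planted per-sample parameters and realized
#'   summaries, including the realized crosstalk score).
#' @export
generate_tissue <- function(config, panel, sample_id, group, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"), group %in% config$groups)
  W <- config$tissue_width; H <- config$tissue_height
  band <- if (isTRUE(config$zonation)) config$epithelial_band else 0
  r <- config$radius
  expr <- config$expr
  disease <- group == config$groups[1]

  if (config$cells_per_sample == 0) {
    empty <- data.frame(cell_id = character(0), sample_id = character(0),
                        group = character(0), x_um = numeric(0), y_um = numeric(0),
                        cell_type = character(0))
    return(list(cells = empty,
                counts = Matrix::Matrix(0, nrow = nrow(panel), ncol = 0,
                                        dimnames = list(panel$gene_id, NULL),
                                        sparse = TRUE),
                truth = list(n = 0L, group = group, crosstalk_score = NA_real_)))
  }

  out <- withr_seed(seed, {
    n <- {
      nn <- round(stats::rnorm(1, config$cells_per_sample, config$cells_sd))
      as.integer(min(max(nn, config$cells_range[1]), config$cells_range[2]))
    }
    if (W * H < n) stop("tissue too small to place the requested cells")

    # ---- per-sample planted parameters
    fib_frac <- min(max(stats::rnorm(1, config$fibroblast_fraction_by_group[group],
                                     config$fibroblast_sd_by_group[group]), 0.02), 0.8)
    adj_target <- config$adjacency_target_by_group[group]
    if (!is.na(adj_target))
      adj_target <- min(max(stats::rnorm(1, adj_target,
                                         config$adjacency_sd_by_group[group]), 0.02), 0.98)
    sample_ligand_mult <- exp(stats::rnorm(1, 0, config$ligand_sample_sdlog))

    # ---- cell-type counts
    n_fib <- round(n * fib_frac)
    n_cd4 <- round(n * config$cd4_fraction)
    other_w <- c(epithelial = 0.27, CD8_T = 0.12, endothelial = 0.16,
                 macrophage = 0.15, dendritic = 0.09, mast = 0.07, B_cell = 0.14)
    other_w <- other_w / sum(other_w)
    n_other <- round((n - n_fib - n_cd4) * other_w)
    n_other[1] <- n_other[1] + (n - n_fib - n_cd4 - sum(n_other))
    type_n <- c(fibroblast = n_fib, CD4_T = n_cd4, n_other)

    # ---- placement
    place_uniform <- function(k, ylim) {
      cbind(x = stats::runif(k, 0, W), y = stats::runif(k, ylim[1], ylim[2]))
    }
    # fibroblasts: clustered stromal network (uniform if cluster size NA)
    place_fibroblasts <- function(k) {
      cs <- config$fibro_cluster_size
      if (k == 0 || is.na(cs) || cs <= 1) return(place_uniform(k, c(0, H - band)))
      n_par <- max(1L, round(k / cs))
      par <- place_uniform(n_par, c(0, H - band))
      who <- sample.int(n_par, k, replace = TRUE)
      x <- par[who, 1] + stats::rnorm(k, 0, config$fibro_cluster_sd)
      y <- par[who, 2] + stats::rnorm(k, 0, config$fibro_cluster_sd)
      # reflect into the stromal compartment
      x <- abs(x); x <- W - abs(W - x)
      y <- abs(y); y <- (H - band) - abs((H - band) - y)
      cbind(x = x, y = y)
    }
    pos <- list(
      fibroblast  = place_fibroblasts(type_n["fibroblast"]),
      endothelial = place_uniform(type_n["endothelial"], c(0, H - band)),
      epithelial  = place_uniform(type_n["epithelial"],
                                  if (band > 0) c(H - band, H) else c(0, H)),
      CD8_T       = place_uniform(type_n["CD8_T"], c(0, H)),
      macrophage  = place_uniform(type_n["macrophage"], c(0, H)),
      dendritic   = place_uniform(type_n["dendritic"], c(0, H)),
      mast        = place_uniform(type_n["mast"], c(0, H)),
      B_cell      = place_uniform(type_n["B_cell"], c(0, H))
    )
    fx <- pos$fibroblast[, 1]; fy <- pos$fibroblast[, 2]

    # Per-fibroblast mitochondrial fractions are decided at placement time
    # so the planted adjacency can target QC-viable fibroblasts: the
    # reference adjacency statistics describe the post-QC cell population,
    # and the >20% mito rule is the only filter removing an appreciable
    # cell fraction under the default presets.
    fib_mito <- stats::rbeta(type_n["fibroblast"],
                             config$mito_beta[1], config$mito_beta[2])
    fib_ok <- fib_mito <= 0.20
    fxv <- fx[fib_ok]; fyv <- fy[fib_ok]

    # CD4 placement: thinning against (viable) fibroblast proximity
    n_t <- type_n["CD4_T"]
    acc_x <- numeric(0); acc_y <- numeric(0); acc_adj <- logical(0)
    if (n_t > 0) {
      bias <- config$adjacency_bias_by_group[group]
      q_hat <- NA_real_
      while (length(acc_x) < n_t) {
        m <- max(4 * n_t, 2000)
        prop <- place_uniform(m, c(0, H))
        near <- nearest_within(prop[, 1], prop[, 2], fxv, fyv, r)
        adj <- is.finite(near$dist)
        if (is.na(q_hat)) q_hat <- mean(adj)
        w1 <- if (!is.na(adj_target)) {
          if (q_hat <= 0 || q_hat >= 1) 1
          else (adj_target / (1 - adj_target)) * ((1 - q_hat) / q_hat)
        } else 1 + ifelse(is.na(bias), 0, bias)
        w <- ifelse(adj, w1, 1)
        keep <- stats::runif(m) < w / max(w1, 1)
        acc_x <- c(acc_x, prop[keep, 1]); acc_y <- c(acc_y, prop[keep, 2])
        acc_adj <- c(acc_adj, adj[keep])
      }
      acc_x <- acc_x[seq_len(n_t)]; acc_y <- acc_y[seq_len(n_t)]
    }
    pos$CD4_T <- cbind(x = acc_x, y = acc_y)

    cells <- data.frame(
      cell_type = rep(names(pos), vapply(pos, nrow, integer(1))),
      x_um = unlist(lapply(pos, function(p) p[, 1]), use.names = FALSE),
      y_um = unlist(lapply(pos, function(p) p[, 2]), use.names = FALSE),
      mito_f = c(fib_mito, stats::rbeta(n - type_n["fibroblast"],
                                        config$mito_beta[1], config$mito_beta[2]))
    )
    cells <- cells[sample.int(nrow(cells)), ]
    rownames(cells) <- NULL
    cells <- data.frame(cell_id = sprintf("%s_c%04d", sample_id, seq_len(nrow(cells))),
                        sample_id = sample_id, group = group, cells,
                        stringsAsFactors = FALSE)

    is_fib <- cells$cell_type == "fibroblast"
    is_t <- cells$cell_type == "CD4_T"
    # pairing and planted adjacency use QC-viable fibroblasts only
    vfib_idx <- which(is_fib & cells$mito_f <= 0.20)
    near_t_fib <- nearest_within(cells$x_um[is_t], cells$y_um[is_t],
                                 cells$x_um[vfib_idx], cells$y_um[vfib_idx], r)
    t_adj <- is.finite(near_t_fib$dist)
    fib_near_t <- nearest_within(cells$x_um[is_fib], cells$y_um[is_fib],
                                 cells$x_um[is_t], cells$y_um[is_t], r)
    fib_adj <- is.finite(fib_near_t$dist)

    # ---- expression means
    base <- build_base_means(panel, expr)
    genes <- panel$gene_id
    prog <- program_genes(panel)
    size_by_gene <- ifelse(genes %in% prog,
                           1 / config$program_dispersion, 1 / config$dispersion)
    mito_genes <- panel$gene_id[panel$role == "mito"]
    meds <- mediator_genes()

    depth <- exp(stats::rnorm(nrow(cells), 0, config$depth_sdlog))
    mito_f <- cells$mito_f

    mu <- base[, cells$cell_type, drop = FALSE]
    dimnames(mu) <- list(genes, cells$cell_id)

    # fibroblast mediator heterogeneity + adjacency-restricted upregulation
    fib_idx <- which(is_fib)
    if (length(fib_idx)) {
      het <- exp(stats::rnorm(length(fib_idx), 0, config$ligand_cell_sdlog))
      fac <- matrix(rep(sample_ligand_mult * het, each = length(meds)),
                    nrow = length(meds))
      if (disease) {
        up <- 2^config$ligand_upregulation[meds]
        fac <- fac * outer(up, as.numeric(fib_adj) , function(u, a) ifelse(a > 0, u, 1))
      }
      mu[meds, fib_idx] <- mu[meds, fib_idx] * fac
    }

    # depth scaling, then mitochondrial mass on top
    mu <- sweep(mu, 2, depth, `*`)
    non_mito_tot <- colSums(mu[setdiff(genes, mito_genes), , drop = FALSE])
    mu[mito_genes, ] <- outer(expr$mito_share, mito_f / (1 - mito_f) * non_mito_tot)

    # ---- draw counts: non-T cells first, then ligand-coupled T cells
    counts <- matrix(0L, nrow = length(genes), ncol = nrow(cells),
                     dimnames = list(genes, cells$cell_id))
    non_t <- which(!is_t)
    counts[, non_t] <- draw_counts(mu[, non_t, drop = FALSE], size_by_gene)

    lig_score <- rep(0, sum(is_t))
    if (sum(is_t)) {
      t_idx <- which(is_t)
      paired_fib <- vfib_idx[near_t_fib$idx]  # NA where unpaired
      paired_ok <- which(t_adj)
      if (length(paired_ok)) {
        fib_counts <- counts[, paired_fib[paired_ok], drop = FALSE]
        norm_fib <- normalize_expression(fib_counts)
        lig_score[paired_ok] <- Matrix::colSums(norm_fib[pro_th2_ligands(), , drop = FALSE])
      }
      slope <- config$th2_coupling_slope_by_group[group]
      coupled <- exp(slope * lig_score +
                       stats::rnorm(length(t_idx), 0, config$th2_noise_sd))
      cgenes <- unique(c(core_th2_genes(), "GATA3", gata3_target_genes(panel),
                         "IL7R", "TNFRSF4", "ICOS"))
      mu_t <- mu[, t_idx, drop = FALSE]
      mu_t[cgenes, ] <- sweep(mu_t[cgenes, , drop = FALSE], 2, coupled, `*`)
      counts[, t_idx] <- draw_counts(mu_t, size_by_gene)
    }

    cells$mito_f <- NULL
    cells$true_adjacent <- NA
    cells$true_adjacent[is_t] <- t_adj
    cells$true_ligand_score <- NA_real_
    cells$true_ligand_score[is_t] <- lig_score

    scounts <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
    cells <- compute_qc_covariates(cells, scounts)

    list(cells = cells, counts = scounts,
         truth = list(n = nrow(cells), group = group,
                      fibroblast_fraction = fib_frac,
                      adjacency_target = if (is.na(adj_target)) NA_real_ else adj_target,
                      realized_adjacency = if (sum(is_t)) mean(t_adj) else NA_real_,
                      fibro_adjacent_fraction = if (length(fib_idx)) mean(fib_adj) else NA_real_,
                      sample_ligand_mult = sample_ligand_mult,
                      crosstalk_score = if (any(t_adj)) mean(lig_score[t_adj]) else NA_real_))
  })
  out
}

#' Generate a full synthetic cohort with clinical records
#'
#' Generates `n_samples_per_group` tissues per group and a clinical table
#' whose serum IgE and SPT wheal diameter are linear in each sample's
#' realized crosstalk score (mean nearest-fibroblast ligand score over
#' paired CD4+ T cells) plus Gaussian noise, truncated positive.
#'
#' @param config A [sim_config()].
#' @param panel Panel manifest.
#' @param seed Master seed; per-sample seeds are derived deterministically.
#' @return List with `samples` (per-sample output of [generate_tissue()]),
#'   `cells` and `counts` (pooled), `clinical`, and `truth` (per-sample
#'   planted parameters).
#' @export
generate_cohort <- function(config, panel, seed = config$seed) {
  stopifnot(config$n_samples_per_group >= 1)
  samples <- list()
  k <- 0
  for (g in config$groups) {
    for (i in seq_len(config$n_samples_per_group)) {
      k <- k + 1
      sid <- sprintf("%s_%02d", g, i)
      samples[[sid]] <- generate_tissue(config, panel, sid, g,
                                        seed = derive_seed(seed, k))
    }
  }
  cells <- do.call(rbind, lapply(samples, `[[`, "cells"))
  rownames(cells) <- NULL
  counts <- do.call(cbind, lapply(samples, `[[`, "counts"))
  scores <- vapply(samples, function(s) s$truth$crosstalk_score %||% NA_real_, numeric(1))

  cc <- config$clinical_coupling
  clinical <- withr_seed(derive_seed(seed, 900001L), {
    data.frame(
      sample_id = names(samples),
      group = vapply(samples, function(s) s$truth$group %||% NA_character_, character(1)),
      serum_IgE = pmax(cc$ige_intercept + cc$ige_slope * scores +
                         stats::rnorm(length(scores), 0, cc$ige_noise_sd), 1),
      spt_wheal = pmax(cc$spt_intercept + cc$spt_slope * scores +
                         stats::rnorm(length(scores), 0, cc$spt_noise_sd), 0.5),
      row.names = NULL)
  })
  list(samples = samples, cells = cells, counts = counts, clinical = clinical,
       truth = lapply(samples, `[[`, "truth"))
}

#' Fully exchangeable null configuration
#'
#' A [sim_config()] with every planted effect switched off: no compartment
#' zonation, no placement bias, equal fibroblast fractions without
#' between-sample spread, no mediator upregulation, no Th2 coupling and no
#' clinical coupling. Under this configuration cell-type labels are
#' independent of position and the two groups are exchangeable, so every
#' downstream contrast is null — the reference point for calibration
#' studies of the permutation and rank tests.
#'
#' @param ... Overrides passed on to [sim_config()].
#' @return A `sim_config`.
#' @export
null_config <- function(...) {
  cfg <- sim_config(
    zonation = FALSE,
    fibro_cluster_size = NA,
    fibroblast_fraction_by_group = c(AR = 0.25, control = 0.25),
    fibroblast_sd_by_group = c(AR = 0, control = 0),
    adjacency_target_by_group = c(AR = NA_real_, control = NA_real_),
    adjacency_bias_by_group = c(AR = 0, control = 0),
    ligand_upregulation = c(TSLP = 0, IL33 = 0, CCL17 = 0,
                            ICOSL = 0, OX40L = 0, POSTN = 0),
    th2_coupling_slope_by_group = c(AR = 0, control = 0),
    ligand_sample_sdlog = 0,
    ...)
  cfg$clinical_coupling$ige_slope <- 0
  cfg$clinical_coupling$spt_slope <- 0
  cfg
}
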