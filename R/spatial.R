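#' Build an exact radius neighbor graph
#'
#' Connects every pair of cells of one sample whose Euclidean distance is at
#' most `radius` micrometres (20 um by default, the physiological range of
#' paracrine cell-cell signalling). The query is exact: cells are bucketed
#' on a grid of `radius`-sized cells and only adjacent buckets are compared,
#' so no approximation is involved. Coincident cells are connected by a
#' distance-0 edge; there are no self-edges.
#'
#' @param cells Cell table with `x_um`, `y_um` (one sample).
#' @param radius Neighborhood radius in micrometres.
#' @return An object of class `neighbor_graph`: list with `edges`
#'   (`data.frame` of 1-based indices `i < j` into `cells` and `dist`),
#'   `n_cells`, `radius` and `sample_id`.
#' @export
build_neighbor_graph <- function(cells, radius = 20) {
  n <- nrow(cells)
  if (n < 1) stop("build_neighbor_graph: need at least one cell")
  x <- cells$x_um; y <- cells$y_um
  h <- max(radius, 1e-9)
  gx <- floor(x / h); gy <- floor(y / h)
  key <- paste(gx, gy, sep = ",")
  buckets <- split(seq_len(n), key)
  coord <- do.call(rbind, strsplit(names(buckets), ",", fixed = TRUE))
  bx <- as.numeric(coord[, 1]); by <- as.numeric(coord[, 2])
  bkey <- names(buckets)
  lookup <- stats::setNames(seq_along(buckets), bkey)

  ei <- integer(0); ej <- integer(0); ed <- numeric(0)
  # offsets covering each unordered bucket pair once (plus within-bucket)
  offsets <- list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))
  for (b in seq_along(buckets)) {
    ia <- buckets[[b]]
    for (off in offsets) {
      if (off[1] == 0L && off[2] == 0L) {
        if (length(ia) > 1) {
          pr <- utils::combn(ia, 2)
          d <- sqrt((x[pr[1, ]] - x[pr[2, ]])^2 + (y[pr[1, ]] - y[pr[2, ]])^2)
          keep <- d <= radius
          ei <- c(ei, pr[1, keep]); ej <- c(ej, pr[2, keep]); ed <- c(ed, d[keep])
        }
      } else {
        nb <- lookup[paste(bx[b] + off[1], by[b] + off[2], sep = ",")]
        if (!is.na(nb)) {
          ib <- buckets[[nb]]
          dx <- outer(x[ia], x[ib], "-"); dy <- outer(y[ia], y[ib], "-")
          d <- sqrt(dx * dx + dy * dy)
          keep <- which(d <= radius, arr.ind = TRUE)
          if (nrow(keep)) {
            a <- ia[keep[, 1]]; bb <- ib[keep[, 2]]
            sw <- a > bb
            ei <- c(ei, ifelse(sw, bb, a)); ej <- c(ej, ifelse(sw, a, bb))
            ed <- c(ed, d[keep])
          }
        }
      }
    }
  }
  structure(list(edges = data.frame(i = ei, j = ej, dist = ed),
                 n_cells = n, radius = radius,
                 sample_id = if (nrow(cells)) cells$sample_id[1] else NA_character_),
            class = "neighbor_graph")
}

#' @export
print.neighbor_graph <- function(x, ...) {
  cat(sprintf("neighbor_graph: %d cells, %d edges, radius %.1f um (sample %s)\n",
              x$n_cells, nrow(x$edges), x$radius, x$sample_id))
  invisible(x)
}

# indicator: which cells have >=1 neighbor of the given type
has_neighbor_of_type <- function(graph, labels, type) {
  stopifnot(length(labels) == graph$n_cells)
  out <- logical(graph$n_cells)
  e <- graph$edges
  out[e$i[labels[e$j] == type]] <- TRUE
  out[e$j[labels[e$i] == type]] <- TRUE
  out
}

#' Fraction of one cell type adjacent to another
#'
#' Fraction of `type_a` cells with at least one `type_b` neighbor in the
#' radius graph (e.g. the fraction of CD4+ T cells within 20 um of a
#' fibroblast).
#'
#' @param graph A [build_neighbor_graph()] result.
#' @param cells The cell table the graph was built from.
#' @param type_a,type_b Cell-type labels.
#' @return Fraction in `[0, 1]`.
#' @export
adjacency_fraction <- function(graph, cells, type_a, type_b) {
  labels <- cells$cell_type
  ia <- labels == type_a
  if (!any(ia)) stop(sprintf("no cells of type '%s'", type_a))
  adj <- has_neighbor_of_type(graph, labels, type_b)
  mean(adj[ia])
}

#' Adjacent partner cells per 100 reference cells
#'
#' Number of `type_a` cells having at least one `type_b` neighbor, scaled
#' per 100 `type_b` cells (e.g. CD4+ T cells within 20 um of fibroblasts,
#' per 100 fibroblasts).
#'
#' @inheritParams adjacency_fraction
#' @return Non-negative real.
#' @export
adjacency_per_100 <- function(graph, cells, type_a, type_b) {
  labels <- cells$cell_type
  nb <- sum(labels == type_b)
  if (nb == 0) stop(sprintf("no cells of type '%s'", type_b))
  adj <- has_neighbor_of_type(graph, labels, type_b)
  100 * sum(adj & labels == type_a) / nb
}

#' Cell-count tissue occupancy of a type
#'
#' Count-based proxy for tissue area occupancy: percentage of all cells that
#' are of the given type.
#'
#' @param cells Cell table.
#' @param type Cell-type label.
#' @return Percentage in `[0, 100]`.
#' @export
type_area_fraction <- function(cells, type) {
  if (nrow(cells) == 0) stop("empty cell table")
  100 * mean(cells$cell_type == type)
}

#' Permutation-based neighborhood enrichment
#'
#' Tests whether two cell types are spatial neighbors more often than
#' expected by chance. The observed enrichment is the number of a-b
#' neighbor pairs divided by the total number of neighbor pairs in the
#' graph. The null distribution is built by shuffling cell-type labels over
#' the fixed cell positions (preserving spatial density, randomizing
#' identities only). The proximity score is observed / null mean; the raw
#' one-tailed p-value is `(1 + #{null >= observed}) / (1 + n_perm)`, which
#' can never be exactly zero.
#'
#' @inheritParams adjacency_fraction
#' @param n_perm Number of label permutations.
#' @param seed Integer seed for the permutation stream.
#' @return `data.frame` (one row) with `type_a`, `type_b`,
#'   `observed_enrichment`, `null_mean`, `null_sd`, `proximity_score`,
#'   `p_raw`, `n_perm`, `seed`.
#' @export
neighborhood_enrichment <- function(graph, cells, type_a, type_b,
                                    n_perm = 1000, seed = 1L) {
  stopifnot(n_perm >= 1)
  e <- graph$edges
  if (nrow(e) == 0) stop("neighborhood_enrichment: graph has no edges")
  labels <- cells$cell_type
  if (!any(labels == type_a)) stop(sprintf("no cells of type '%s'", type_a))
  if (!any(labels == type_b)) stop(sprintf("no cells of type '%s'", type_b))

  ab_count <- function(lab) {
    li <- lab[e$i]; lj <- lab[e$j]
    sum((li == type_a & lj == type_b) | (li == type_b & lj == type_a))
  }
  total <- nrow(e)
  observed <- ab_count(labels) / total

  null <- numeric(n_perm)
  withr_seed(seed, {
    for (k in seq_len(n_perm)) null[k] <- ab_count(sample(labels)) / total
  })
  null_mean <- mean(null)
  data.frame(type_a = type_a, type_b = type_b,
             observed_enrichment = observed,
             null_mean = null_mean, null_sd = stats::sd(null),
             proximity_score = if (null_mean > 0) observed / null_mean else NA_real_,
             p_raw = (1 + sum(null >= observed)) / (1 + n_perm),
             n_perm = n_perm, seed = seed)
}

# run expr under a local RNG state seeded with `seed`, restoring the
# caller's state afterwards
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH false-discovery-rate adjustment preserving input order
#' (thin wrapper over [stats::p.adjust()]).
#'
#' @param p Vector of raw p-values in `(0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  stats::p.adjust(p, method = "BH")
}

#' Marker-positive adjacency enrichment ratio
#'
#' Splits `source_type` cells into marker-positive (normalized expression
#' strictly above `positivity_threshold`) and marker-negative strata and
#' compares their probability of having at least one `target_type` cell
#' within the graph radius:
#' `ratio = P(adjacent | marker+) / P(adjacent | marker-)`, with a
#' Fisher's exact test on the 2x2 positivity x adjacency table.
#'
#' @inheritParams adjacency_fraction
#' @param norm Normalized genes x cells matrix aligned to `cells`.
#' @param source_type Type being stratified by marker expression.
#' @param marker Gene symbol.
#' @param target_type Partner type for adjacency.
#' @param positivity_threshold Normalized-expression cut-off (default 0,
#'   i.e. any detected transcript).
#' @param alternative Fisher-test alternative; `"greater"` tests positive
#'   association between positivity and adjacency.
#' @return `data.frame` (one row) with stratum sizes, adjacency
#'   probabilities, `ratio` (`Inf` flagged via `degenerate` when a
#'   denominator is 0 or a stratum is empty) and `p_fisher`.
#' @export
marker_adjacency_ratio <- function(graph, cells, norm, source_type, marker,
                                   target_type, positivity_threshold = 0,
                                   alternative = "greater") {
  if (!marker %in% rownames(norm)) stop(sprintf("marker '%s' not in matrix", marker))
  labels <- cells$cell_type
  src <- which(labels == source_type)
  if (length(src) == 0) stop(sprintf("no cells of type '%s'", source_type))
  pos <- as.numeric(norm[marker, src]) > positivity_threshold
  adj <- has_neighbor_of_type(graph, labels, target_type)[src]

  p_pos <- mean(adj[pos]); p_neg <- mean(adj[!pos])
  degenerate <- sum(pos) == 0 || sum(!pos) == 0 || isTRUE(p_neg == 0)
  ratio <- if (sum(pos) == 0 || sum(!pos) == 0) NA_real_
           else if (p_neg == 0) Inf else p_pos / p_neg
  tab <- matrix(c(sum(pos & adj), sum(pos & !adj),
                  sum(!pos & adj), sum(!pos & !adj)), nrow = 2, byrow = TRUE)
  p_fisher <- if (degenerate && is.na(ratio)) NA_real_
              else stats::fisher.test(tab, alternative = alternative)$p.value
  data.frame(source_type = source_type, marker = marker, target_type = target_type,
             n_pos = sum(pos), n_neg = sum(!pos),
             p_adj_pos = p_pos, p_adj_neg = p_neg,
             ratio = ratio, degenerate = degenerate, p_fisher = p_fisher)
}
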