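# Shared fixtures, built in code. Expensive simulated objects are memoised
# per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) assign(name, build(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# default panel (deterministic)
fx_panel <- function() fixture("panel", function() generate_panel())

# one mid-sized AR tissue with the study preset
fx_ar_tissue <- function() fixture("ar_tissue", function() {
  cfg <- sim_config(cells_per_sample = 2000L, cells_sd = 0)
  generate_tissue(cfg, fx_panel(), "AR_fx", "AR", seed = 101)
})

# QC'd + normalized view of the fixture tissue
fx_ar_norm <- function() fixture("ar_norm", function() {
  s <- fx_ar_tissue()
  f <- filter_cells(s$cells, s$counts)
  list(cells = f$cells, norm = normalize_expression(f$counts), counts = f$counts)
})

# tiny deterministic expression toy: genes x cells dense matrix
toy_matrix <- function(values, genes, cells) {
  matrix(values, nrow = length(genes), dimnames = list(genes, cells))
}

# exhaustive rank-sum enumeration oracle: two-sided p for group a vs b
enumerate_wilcoxon_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  r <- rank(pooled)
  obs <- sum(r[seq_len(na)])
  combos <- utils::combn(n, na)
  sums <- colSums(matrix(r[combos], nrow = na))
  mu <- mean(sums)
  # two-sided: probability of a rank sum at least as extreme (about the mean)
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
}

# exhaustive label-permutation oracle for neighborhood enrichment:
# exact P(null >= observed) over all distinct type assignments
enumerate_enrichment_p <- function(cells, radius, type_a, type_b) {
  g <- build_neighbor_graph(cells, radius)
  e <- g$edges
  labels <- cells$cell_type
  n <- nrow(cells)
  idx_a <- utils::combn(n, sum(labels == type_a))
  score <- function(lab) {
    li <- lab[e$i]; lj <- lab[e$j]
    sum((li == type_a & lj == type_b) | (li == type_b & lj == type_a)) / nrow(e)
  }
  obs <- score(labels)
  null <- apply(idx_a, 2, function(ia) {
    lab <- rep(type_b, n); lab[ia] <- type_a
    score(lab)
  })
  mean(null >= obs - 1e-12)
}
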