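toy_cells <- function(x, y, type = rep("A", length(x)), sample_id = "s1") {
  data.frame(cell_id = sprintf("c%d", seq_along(x)), sample_id = sample_id,
             group = "AR", x_um = x, y_um = y, cell_type = type)
}

test_that("radius graph matches hand-computed distances", {
  g <- build_neighbor_graph(toy_cells(c(0, 10, 50), c(0, 0, 0)), radius = 20)
  expect_equal(nrow(g$edges), 1)
  expect_equal(c(g$edges$i, g$edges$j), c(1, 2))
  expect_equal(g$edges$dist, 10)

  # radius 0: only coincident cells connect
  g0 <- build_neighbor_graph(toy_cells(c(0, 0, 5), c(0, 0, 0)), radius = 0)
  expect_equal(nrow(g0$edges), 1)
  expect_equal(g0$edges$dist, 0)

  # single cell: empty edge set
  g1 <- build_neighbor_graph(toy_cells(0, 0), radius = 20)
  expect_equal(nrow(g1$edges), 0)
})

test_that("grid-bucketed radius query equals the brute-force distance matrix", {
  set.seed(7)
  n <- 250
  cells <- toy_cells(runif(n, 0, 200), runif(n, 0, 200))
  for (r in c(8, 20, 33)) {
    g <- build_neighbor_graph(cells, radius = r)
    d <- as.matrix(dist(cbind(cells$x_um, cells$y_um)))
    expected <- which(upper.tri(d) & d <= r, arr.ind = TRUE)
    got <- g$edges[order(g$edges$i, g$edges$j), ]
    exp_ord <- expected[order(expected[, 1], expected[, 2]), , drop = FALSE]
    expect_equal(nrow(got), nrow(exp_ord))
    expect_equal(got$i, unname(exp_ord[, 1]))
    expect_equal(got$j, unname(exp_ord[, 2]))
    expect_true(all(g$edges$dist <= r))
  }
})

test_that("adjacency fraction and per-100 ratio follow their definitions", {
  cells <- toy_cells(c(0, 10, 100), c(0, 0, 0), c("CD4_T", "fibroblast", "fibroblast"))
  g <- build_neighbor_graph(cells, 20)
  expect_equal(adjacency_fraction(g, cells, "CD4_T", "fibroblast"), 1.0)
  expect_equal(adjacency_fraction(g, cells, "fibroblast", "CD4_T"), 0.5)
  expect_error(adjacency_fraction(g, cells, "mast", "fibroblast"), "mast")

  # 2 adjacent T cells, 50 fibroblasts -> 4.0
  x <- c(0, 1, seq(10, 500, length.out = 50))
  ty <- c("CD4_T", "CD4_T", rep("fibroblast", 50))
  cells2 <- toy_cells(x, rep(0, 52), ty)
  g2 <- build_neighbor_graph(cells2, 20)
  expect_equal(adjacency_per_100(g2, cells2, "CD4_T", "fibroblast"), 4.0)
})

test_that("type occupancy is the cell-count percentage", {
  cells <- toy_cells(seq_len(1000), rep(0, 1000),
                     rep(c("fibroblast", "other"), c(342, 658)))
  expect_equal(type_area_fraction(cells, "fibroblast"), 34.2)
  expect_equal(type_area_fraction(cells[cells$cell_type == "other", ], "other"), 100)
})

test_that("neighborhood enrichment p matches exhaustive label enumeration", {
  # 6-cell toy, 2 of type A clustered with one B
  cells <- toy_cells(c(0, 5, 8, 100, 104, 200), rep(0, 6),
                     c("A", "A", "B", "B", "B", "B"))
  res <- neighborhood_enrichment(build_neighbor_graph(cells, 20), cells,
                                 "A", "B", n_perm = 4000, seed = 3)
  exact <- enumerate_enrichment_p(cells, 20, "A", "B")
  expect_lt(abs(res$p_raw - exact), 0.02)
  expect_gt(res$p_raw, 0)

  # symmetry in the type pair
  res_ba <- neighborhood_enrichment(build_neighbor_graph(cells, 20), cells,
                                    "B", "A", n_perm = 500, seed = 11)
  res_ab <- neighborhood_enrichment(build_neighbor_graph(cells, 20), cells,
                                    "A", "B", n_perm = 500, seed = 11)
  expect_equal(res_ab$observed_enrichment, res_ba$observed_enrichment)
  expect_equal(res_ab$p_raw, res_ba$p_raw)
})

test_that("fully segregated types give zero enrichment and p near 1", {
  cells <- toy_cells(c(0, 5, 500, 505), rep(0, 4), c("A", "A", "B", "B"))
  res <- neighborhood_enrichment(build_neighbor_graph(cells, 20), cells,
                                 "A", "B", n_perm = 200, seed = 1)
  expect_equal(res$observed_enrichment, 0)
  expect_equal(res$proximity_score, 0)
  expect_gt(res$p_raw, 0.9)
})

test_that("BH adjustment matches hand computation and its invariants", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  set.seed(5)
  p <- runif(50)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p - 1e-12))
  expect_true(all(adj <= 1))
})

test_that("marker adjacency ratio uses the 2x2 Fisher table", {
  # 8/10 marker+ fibroblasts adjacent vs 3/10 marker-: each fibroblast is
  # 100 um from the next and has one dedicated T cell at 5 um (adjacent)
  # or 500 um (not)
  fx <- seq(0, 1900, by = 100)
  t_y <- c(rep(5, 8), rep(500, 2), rep(5, 3), rep(500, 7))
  cells <- toy_cells(c(fx, fx), c(rep(0, 20), t_y),
                     rep(c("fibroblast", "CD4_T"), each = 20))
  g <- build_neighbor_graph(cells, 20)
  norm <- matrix(c(rep(1, 10), rep(0, 10), rep(0, 20)), nrow = 1,
                 dimnames = list("TSLP", cells$cell_id))
  res <- marker_adjacency_ratio(g, cells, norm, "fibroblast", "TSLP", "CD4_T", 0)
  expect_equal(res$ratio, (8 / 10) / (3 / 10))
  # one-sided Fisher p equals the exact hypergeometric tail of the table
  p_exact <- sum(dhyper(8:10, 11, 9, 10))
  expect_equal(res$p_fisher, p_exact, tolerance = 1e-10)
})

test_that("degenerate marker strata are flagged", {
  cells <- toy_cells(c(0, 5, 1000, 2000), rep(0, 4),
                     c("fibroblast", "CD4_T", "fibroblast", "CD4_T"))
  g <- build_neighbor_graph(cells, 20)
  norm <- matrix(c(1, 0, 0, 0), nrow = 1, dimnames = list("TSLP", cells$cell_id))
  res <- marker_adjacency_ratio(g, cells, norm, "fibroblast", "TSLP", "CD4_T", 0)
  expect_true(res$degenerate)
  expect_true(is.infinite(res$ratio))
})
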