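test_that("module score cancels under uniform expression and rescales to [0,1]", {
  genes <- sprintf("G%02d", 1:20)
  m <- Matrix::Matrix(1, nrow = 20, ncol = 5,
                      dimnames = list(genes, sprintf("c%d", 1:5)), sparse = TRUE)
  res <- module_score(m, genes, n_bins = 5, n_ctrl = 10, seed = 2)
  expect_equal(res$raw_score, rep(0, 5))
  expect_equal(res$norm_score, rep(0, 5))  # all-equal raw -> all 0

  fx <- fx_ar_norm()
  sc <- module_score(fx$norm, core_th2_genes(), "core_th2", seed = 4)
  expect_true(all(sc$norm_score >= 0 & sc$norm_score <= 1))
  expect_equal(min(sc$norm_score), 0)
  expect_equal(max(sc$norm_score), 1)
})

test_that("module raw score matches hand arithmetic when controls are forced", {
  # one bin; all non-set genes share identical per-cell values, so any
  # control draw has a deterministic mean
  genes <- c("S", "B1", "B2", "B3")
  vals <- rbind(S = c(2, 5), B1 = c(1, 3), B2 = c(1, 3), B3 = c(1, 3))
  m <- Matrix::Matrix(vals, dimnames = list(genes, c("c1", "c2")), sparse = TRUE)
  res <- module_score(m, "S", n_bins = 1, n_ctrl = 50, seed = 9)
  expect_equal(res$raw_score, c(2 - 1, 5 - 3))
  expect_equal(res$norm_score, c(0, 1))
})

test_that("ligand score pairs each T cell with its nearest fibroblast", {
  cells <- data.frame(cell_id = c("t1", "f_near", "f_far", "t_alone"),
                      sample_id = "s1", group = "AR",
                      x_um = c(0, 5, 15, 500), y_um = 0,
                      cell_type = c("CD4_T", "fibroblast", "fibroblast", "CD4_T"))
  g <- build_neighbor_graph(cells, 20)
  lig <- pro_th2_ligands()
  norm <- matrix(0, nrow = 5, ncol = 4, dimnames = list(lig, cells$cell_id))
  norm["TSLP", "f_near"] <- 1.7
  norm["POSTN", "f_near"] <- 0.3
  norm["TSLP", "f_far"] <- 99  # further away, must not be chosen
  res <- fibroblast_ligand_score(cells, g, norm)
  expect_equal(nrow(res$records), 1)
  expect_equal(res$records$paired_fibroblast_id, "f_near")
  expect_equal(res$records$pair_distance, 5)
  expect_equal(res$records$ligand_score, 2.0)
  expect_equal(res$n_unpaired, 1)

  # zero-expression fibroblast scores 0; raising any one ligand raises it
  norm2 <- norm; norm2[, "f_near"] <- 0
  expect_equal(fibroblast_ligand_score(cells, g, norm2)$records$ligand_score, 0)
  for (gene in lig) {
    bumped <- norm; bumped[gene, "f_near"] <- bumped[gene, "f_near"] + 0.5
    expect_equal(fibroblast_ligand_score(cells, g, bumped)$records$ligand_score,
                 res$records$ligand_score + 0.5)
  }

  expect_error(fibroblast_ligand_score(cells, g, norm[-1, , drop = FALSE]), "TSLP")
})

test_that("sample crosstalk score is the order-invariant mean with N flag", {
  rec <- data.frame(t_cell_id = c("a", "b"), paired_fibroblast_id = c("f", "g"),
                    pair_distance = c(5, 10), ligand_score = c(1, 3))
  expect_equal(sample_crosstalk_score(rec, "s")$mean_ligand_score, 2)
  expect_equal(sample_crosstalk_score(rec[2:1, ], "s")$mean_ligand_score, 2)
  expect_equal(sample_crosstalk_score(rec[1, ], "s")$mean_ligand_score, 1)
  empty <- sample_crosstalk_score(rec[0, ], "s")
  expect_true(empty$undefined)
  expect_true(is.na(empty$mean_ligand_score))
})

test_that("composite crosstalk score is the three-component product", {
  expect_equal(composite_crosstalk_score(1, 1, 1), 1)
  expect_equal(composite_crosstalk_score(0, 5, 2), 0)
  expect_error(composite_crosstalk_score(-0.1, 1, 1), "negative")
  # group-mean reconstruction: adjacency and Th2 components differ,
  # mediator component held equal -> AR/control fold
  fold <- composite_crosstalk_score(0.623, 1, 0.62) /
    composite_crosstalk_score(0.287, 1, 0.28)
  expect_equal(fold, (0.623 * 0.62) / (0.287 * 0.28), tolerance = 1e-12)
  expect_equal(round(fold, 1), 4.8)
})
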