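test_that("generation is deterministic given the seed", {
  p <- fx_panel()
  cfg <- sim_config(cells_per_sample = 600L, cells_sd = 0)
  a <- generate_tissue(cfg, p, "s1", "AR", seed = 77)
  b <- generate_tissue(cfg, p, "s1", "AR", seed = 77)
  expect_identical(a$cells, b$cells)
  expect_identical(as.matrix(a$counts), as.matrix(b$counts))
  c2 <- generate_tissue(cfg, p, "s1", "AR", seed = 78)
  expect_false(identical(a$cells$x_um, c2$cells$x_um))

  cfg2 <- sim_config(cells_per_sample = 400L, cells_sd = 0, n_samples_per_group = 2)
  co1 <- generate_cohort(cfg2, p, seed = 5)
  co2 <- generate_cohort(cfg2, p, seed = 5)
  expect_identical(co1$cells, co2$cells)
  expect_identical(co1$clinical, co2$clinical)
})

test_that("degenerate tissue requests are handled", {
  p <- fx_panel()
  cfg <- sim_config(cells_per_sample = 0L)
  s <- generate_tissue(cfg, p, "s0", "AR", seed = 1)
  expect_equal(nrow(s$cells), 0)
  expect_equal(ncol(s$counts), 0)
  expect_equal(nrow(s$counts), 412)

  tiny <- sim_config(cells_per_sample = 500L, cells_sd = 0,
                     tissue_width = 10, tissue_height = 10)
  expect_error(generate_tissue(tiny, p, "s", "AR", seed = 1), "too small")
})

test_that("tissue respects compartment zonation and composition presets", {
  s <- fx_ar_tissue()
  cfg <- sim_config()
  epi <- s$cells[s$cells$cell_type == "epithelial", ]
  expect_true(all(epi$y_um >= cfg$tissue_height - cfg$epithelial_band))
  fib <- s$cells[s$cells$cell_type == "fibroblast", ]
  expect_true(all(fib$y_um <= cfg$tissue_height - cfg$epithelial_band))
  # per-sample planted fraction is realized in the cell counts
  expect_equal(nrow(fib) / nrow(s$cells), s$truth$fibroblast_fraction,
               tolerance = 0.02)
})

test_that("planted composition and adjacency are recovered across seeds", {
  p <- fx_panel()
  occ <- adj <- numeric(0)
  for (sd0 in 1:5) {
    cfg <- sim_config(cells_per_sample = 2400L, cells_sd = 0)
    s <- generate_tissue(cfg, p, "s", "AR", seed = 200 + sd0)
    f <- filter_cells(s$cells, s$counts)
    occ <- c(occ, type_area_fraction(f$cells, "fibroblast"))
    ca <- cohort_adjacency(f$cells, 20)
    adj <- c(adj, ca$adjacency_fraction)
  }
  # group means within 2 planted SD of the preset
  expect_lt(abs(mean(occ) - 34.2), 2 * 3.1)
  expect_lt(abs(mean(adj) - 0.623), 2 * 0.045)
})

test_that("unbiased placement yields unit proximity scores", {
  p <- fx_panel()
  cfg <- null_config(cells_per_sample = 1500L, cells_sd = 0)
  scores <- numeric(0)
  for (sd0 in 1:6) {
    s <- generate_tissue(cfg, p, "s", "AR", seed = 300 + sd0)
    g <- build_neighbor_graph(s$cells, 20)
    ne <- neighborhood_enrichment(g, s$cells, "CD4_T", "fibroblast",
                                  n_perm = 300, seed = sd0)
    scores <- c(scores, ne$proximity_score)
  }
  expect_lt(abs(mean(scores) - 1), 0.1)
})

test_that("noiseless clinical coupling gives exact linearity", {
  p <- fx_panel()
  cfg <- sim_config(cells_per_sample = 900L, cells_sd = 0, n_samples_per_group = 4,
                    groups = "AR")
  cfg$clinical_coupling$ige_noise_sd <- 0
  cfg$clinical_coupling$spt_noise_sd <- 0
  co <- generate_cohort(cfg, p, seed = 9)
  sc <- vapply(co$truth, `[[`, numeric(1), "crosstalk_score")
  expect_equal(cor(sc, co$clinical$serum_IgE), 1, tolerance = 1e-9)
  expect_equal(co$clinical$serum_IgE, unname(120 + 40 * sc), tolerance = 1e-9)
})

test_that("null clinical coupling leaves correlations centred at zero", {
  p <- fx_panel()
  rs <- numeric(0)
  for (sd0 in 1:8) {
    cfg <- sim_config(cells_per_sample = 700L, cells_sd = 0, n_samples_per_group = 6,
                      groups = "AR")
    cfg$clinical_coupling$ige_slope <- 0
    co <- generate_cohort(cfg, p, seed = 400 + sd0)
    sc <- vapply(co$truth, `[[`, numeric(1), "crosstalk_score")
    rs <- c(rs, cor(sc, co$clinical$serum_IgE))
  }
  expect_lt(abs(mean(rs)), 0.35)  # mean of 8 null correlations at n = 6
})
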