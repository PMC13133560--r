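test_that("rank-sum test: degenerate, exact and enumerated cases agree", {
  expect_equal(wilcoxon_rank_sum(c(1, 1, 2), c(2, 1, 1))$p, 1)
  expect_equal(wilcoxon_rank_sum(rep(3, 4), rep(3, 4))$p, 1)
  # complete separation of 3 vs 3: one-tailed 1/20, two-sided 0.1
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p, 0.1, tolerance = 1e-12)

  # exact (n <= 12) and tie-corrected approximate branches both track the
  # enumeration oracle
  set.seed(31)
  for (rep in 1:5) {
    a <- round(rnorm(5), 3); b <- round(rnorm(6, 0.5), 3)
    expect_equal(wilcoxon_rank_sum(a, b)$p, enumerate_wilcoxon_p(a, b),
                 tolerance = 1e-9)
    a13 <- rnorm(6); b13 <- rnorm(7)  # n = 13 forces the normal approximation
    expect_lt(abs(wilcoxon_rank_sum(a13, b13)$p - enumerate_wilcoxon_p(a13, b13)),
              0.02)
  }
})

test_that("differential expression respects min.pct and finds nothing under the null", {
  set.seed(11)
  genes <- c("RARE", sprintf("G%02d", 1:9))
  n <- 60
  counts <- matrix(rpois(10 * 2 * n, 3), nrow = 10,
                   dimnames = list(genes, sprintf("c%d", 1:(2 * n))))
  counts["RARE", ] <- rbinom(2 * n, 1, 0.05)  # ~5% detection in both groups
  cells <- data.frame(cell_id = colnames(counts), sample_id = "s",
                      group = rep(c("A", "B"), each = n), cell_type = "fibroblast")
  norm <- normalize_expression(counts)
  de <- differential_expression(norm, cells, "fibroblast", "A", "B")
  expect_false("RARE" %in% de$gene)          # excluded by min.pct
  expect_false(any(de$significant))          # identical generative process

  # swap antisymmetry: log2fc flips sign, p unchanged
  de_rev <- differential_expression(norm, cells, "fibroblast", "B", "A")
  m <- match(de$gene, de_rev$gene)
  expect_equal(de$log2fc, -de_rev$log2fc[m], tolerance = 1e-9)
  expect_equal(de$p_raw, de_rev$p_raw[m], tolerance = 1e-12)
})

test_that("planted mediator upregulation is recovered by fibroblast DE", {
  p <- fx_panel()
  folds <- numeric(0); sig <- logical(0)
  for (sd0 in 1:5) {
    cfg <- sim_config(cells_per_sample = 2400L, cells_sd = 0, n_samples_per_group = 3,
                      ligand_sample_sdlog = 0)  # isolate the planted log2FC
    co <- generate_cohort(cfg, p, seed = sd0)
    f <- filter_cells(co$cells, co$counts)
    de <- differential_expression(normalize_expression(f$counts), f$cells,
                                  "fibroblast", "AR", "control")
    # expected population log2FC: upregulation only in T-adjacent AR fibroblasts
    p_a <- mean(vapply(co$truth[1:3], `[[`, numeric(1), "fibro_adjacent_fraction"))
    expected <- log2(p_a * 2^1.82 + (1 - p_a))
    row <- de[de$gene == "TSLP", ]
    folds <- c(folds, row$log2fc - expected)
    sig <- c(sig, row$significant)
  }
  expect_lt(abs(mean(folds)), 0.3)
  # per-cell mediator heterogeneity is heavy-tailed, so a single scaled-down
  # cohort can miss the BH cut-off; the planted effect must still reach
  # significance in nearly every replicate
  expect_gte(sum(sig), 4)
})

test_that("hypergeometric enrichment matches the closed-form tail", {
  uni <- sprintf("u%03d", 1:100)
  path <- uni[1:10]
  hits <- c(uni[1:5], uni[90:94])  # overlap 5
  res <- hypergeometric_enrichment(hits, path, uni)
  expect_equal(res$fold_enrichment, (5 / 10) / (10 / 100))
  expect_equal(res$p, sum(dhyper(5:10, 10, 90, 10)), tolerance = 1e-12)

  all_eq <- hypergeometric_enrichment(uni, uni, uni)
  expect_equal(all_eq$fold_enrichment, 1)
  expect_equal(all_eq$p, 1)
  none <- hypergeometric_enrichment(uni[1:5], uni[96:100], uni)
  expect_equal(none$fold_enrichment, 0)
  expect_gt(none$p, 0.7)
  expect_error(hypergeometric_enrichment("x", "y", character(0)), "universe")
  # monotone in overlap at fixed margins
  p_less <- hypergeometric_enrichment(c(uni[1:4], uni[90:95]), path, uni)$p
  expect_gt(p_less, res$p)
})

test_that("ligand-receptor permutation p matches 4-cell enumeration", {
  cells <- data.frame(cell_id = c("s1", "s2", "r1", "r2"), sample_id = "s",
                      group = "AR",
                      cell_type = c("fibroblast", "fibroblast", "CD4_T", "CD4_T"))
  norm <- matrix(c(2, 1, 0, 0,    # TSLP: high in senders
                   0, 0, 3, 1),   # IL7R: high in receivers
                 nrow = 2, byrow = TRUE, dimnames = list(c("TSLP", "IL7R"), cells$cell_id))
  pairs <- data.frame(ligand = "TSLP", receptor = "IL7R")
  res <- lr_permutation_test(norm, cells, "fibroblast", "CD4_T", pairs,
                             n_perm = 6000, seed = 5)
  # enumeration over the C(4,2)=6 sender assignments
  combos <- utils::combn(4, 2)
  obs <- (mean(norm["TSLP", 1:2]) + mean(norm["IL7R", 3:4])) / 2
  null <- apply(combos, 2, function(s)
    (mean(norm["TSLP", s]) + mean(norm["IL7R", -s])) / 2)
  exact <- mean(null >= obs - 1e-12)
  expect_lt(abs(res$p_raw - exact), 0.02)

  # extreme separation with many cells attains the permutation minimum
  cells2 <- data.frame(cell_id = sprintf("c%d", 1:40), sample_id = "s", group = "AR",
                       cell_type = rep(c("fibroblast", "CD4_T"), each = 20))
  norm2 <- matrix(0, nrow = 2, ncol = 40, dimnames = list(c("TSLP", "IL7R"), cells2$cell_id))
  norm2["TSLP", 1:20] <- 5; norm2["IL7R", 21:40] <- 5
  res2 <- lr_permutation_test(norm2, cells2, "fibroblast", "CD4_T", pairs,
                              n_perm = 400, seed = 2)
  expect_equal(res2$p_raw, 1 / 401)

  # absent genes are skipped with a warning
  pairs2 <- rbind(pairs, data.frame(ligand = "NOPE", receptor = "IL7R"))
  expect_warning(res3 <- lr_permutation_test(norm, cells, "fibroblast", "CD4_T",
                                             pairs2, n_perm = 10, seed = 1),
                 "skipping")
  expect_equal(nrow(res3), 1)
})
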