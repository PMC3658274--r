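test_that("standardization produces unit rows/columns and matches the hand
           2x2 case", {
  set.seed(3)
  E <- matrix(rnorm(200), 20, dimnames = list(sprintf("g%02d", 1:20),
                                              sprintf("d%02d", 1:10)))
  inp <- isa_standardize(E)
  expect_lt(max(abs(rowMeans(inp$E_G))), 1e-10)
  expect_lt(max(abs(apply(inp$E_G, 1, sd) - 1)), 1e-10)
  expect_lt(max(abs(colMeans(inp$E_C))), 1e-10)
  expect_lt(max(abs(apply(inp$E_C, 2, sd) - 1)), 1e-10)
  E2 <- matrix(c(1, 2, 3, 5), 2, dimnames = list(c("a", "b"),
                                                 c("x", "y")))
  inp2 <- isa_standardize(E2)
  expect_equal(unname(inp2$E_G["a", ]),
               (c(1, 3) - 2) / sd(c(1, 3)))
  expect_error(isa_standardize(E[, 1, drop = FALSE]), "at least 2")
  E3 <- E; E3[1, ] <- 7
  expect_warning(isa_standardize(E3), "constant")
})

test_that("ISA converges to the planted bicluster from an inside seed and
           is a fixed point of itself", {
  fx <- small_planted(seed = 5)
  inp <- isa_standardize(fx$ds$values)
  m <- isa_iterate(inp, fx$truth$genes[1:8], t_gene = 3, t_drug = 2)
  expect_false(is.null(m))
  expect_gte(jaccard(module_genes(m), fx$truth$genes), 0.9)
  # drug members are profiles of the planted drugs
  prof_drugs <- fx$ds$profile_meta$drug[
    match(module_drugs(m), fx$ds$profile_meta$profile)]
  expect_gte(jaccard(unique(prof_drugs), fx$truth$drugs), 0.9)
  # re-feeding a converged module yields the same module (identical
  # membership; scores equal up to the convergence tolerance)
  m2 <- isa_iterate(inp, m$gene_scores, t_gene = 3, t_drug = 2)
  expect_setequal(module_genes(m2), module_genes(m))
  expect_setequal(module_drugs(m2), module_drugs(m))
  expect_equal(m2$gene_scores[module_genes(m)], m$gene_scores,
               tolerance = 1e-3)
  expect_equal(m2$drug_scores[module_drugs(m)], m$drug_scores,
               tolerance = 1e-3)
})

test_that("flipping the seed sign flips the module sign (antisymmetry)", {
  fx <- small_planted(seed = 6)
  inp <- isa_standardize(fx$ds$values)
  seed_scores <- stats::setNames(rep(1, 8), fx$truth$genes[1:8])
  m_pos <- isa_iterate(inp, seed_scores, t_gene = 3, t_drug = 2)
  m_neg <- isa_iterate(inp, -seed_scores, t_gene = 3, t_drug = 2)
  expect_equal(m_neg$gene_scores, -m_pos$gene_scores, tolerance = 1e-8)
  expect_equal(m_neg$drug_scores, -m_pos$drug_scores, tolerance = 1e-8)
})

test_that("on pure noise at high thresholds almost no seed converges to a
           module", {
  comp <- generate_compendium(n_genes = 400, n_drugs = 60,
                              n_cell_lines = 1, liver = FALSE, seed = 41)
  inp <- isa_standardize(comp$datasets$CL1$values)
  set.seed(99)
  found <- 0
  for (i in 1:40) {
    sg <- sample(inp$genes, 5)
    if (!is.null(isa_iterate(inp, sg, t_gene = 4, t_drug = 3))) {
      found <- found + 1
    }
  }
  expect_lte(found / 40, 0.05)
})

test_that("the threshold sweep is deterministic and recovers the planted
           module", {
  fx <- small_planted(seed = 7)
  inp <- isa_standardize(fx$ds$values)
  cfg <- isa_config(gene_thresholds = seq(4, 3, by = -0.5),
                    drug_thresholds = seq(2.5, 1.5, by = -0.5),
                    n_seeds = 40, seed = 17)
  mods <- isa_sweep(inp, cfg)
  expect_gt(length(mods), 0)
  best <- max(vapply(mods, function(m)
    jaccard(module_genes(m), fx$truth$genes), 0))
  expect_gte(best, 0.8)
  mods2 <- isa_sweep(inp, cfg)
  expect_identical(lapply(mods, `[[`, "gene_scores"),
                   lapply(mods2, `[[`, "gene_scores"))
})

test_that("a sweep with a single seed equals one isa_iterate call from the
           same start", {
  fx <- small_planted(seed = 8)
  inp <- isa_standardize(fx$ds$values)
  cfg <- isa_config(gene_thresholds = 3, drug_thresholds = 2, n_seeds = 1,
                    seed = 23)
  mods <- isa_sweep(inp, cfg)
  # rebuild the same sparse seed the sweep drew
  set.seed(codimr:::stage_seed(23, sprintf("sweep:%.4f:%.4f", 3, 2)))
  k <- max(5L, round(0.01 * length(inp$genes)))
  sg <- inp$genes[sample.int(length(inp$genes), k)]
  m <- isa_iterate(inp, sg, t_gene = 3, t_drug = 2)
  if (is.null(m)) {
    expect_length(mods, 0)
  } else {
    expect_length(mods, 1)
    expect_equal(mods[[1]]$gene_scores, m$gene_scores, tolerance = 1e-10)
  }
})

test_that("raising the gene threshold does not grow modules
           (statistically over seeds)", {
  fx <- small_planted(seed = 9)
  inp <- isa_standardize(fx$ds$values)
  sizes <- vapply(c(2.5, 3.5, 4.5), function(tg) {
    set.seed(77)
    ns <- vapply(1:15, function(i) {
      m <- isa_iterate(inp, sample(inp$genes, 8), t_gene = tg, t_drug = 2)
      if (is.null(m)) NA_real_ else length(m$gene_scores)
    }, 0)
    mean(ns, na.rm = TRUE)
  }, 0)
  sizes <- sizes[!is.nan(sizes)]
  expect_true(all(diff(sizes) <= 1e-9))
})

test_that("planted-module recovery is non-decreasing in effect size", {
  rec <- vapply(c(1, 2, 3, 4), function(eff) {
    fx <- small_planted(seed = 13, effect = eff)
    inp <- isa_standardize(fx$ds$values)
    cfg <- isa_config(gene_thresholds = c(4, 3.5, 3),
                      drug_thresholds = c(2.5, 2), n_seeds = 25, seed = 29)
    mods <- isa_sweep(inp, cfg)
    if (length(mods) == 0) return(0)
    max(vapply(mods, function(m)
      jaccard(module_genes(m), fx$truth$genes), 0))
  }, 0)
  expect_true(all(diff(rec) >= -1e-9))
  expect_gte(rec[3], 0.8)
})

test_that("robustness filtering removes noise modules but keeps strongly
           planted ones", {
  # pure noise: most sweep output must die
  comp <- generate_compendium(n_genes = 300, n_drugs = 50,
                              n_cell_lines = 1, liver = FALSE, seed = 51)
  inp <- isa_standardize(comp$datasets$CL1$values)
  cfg <- isa_config(gene_thresholds = c(2.5, 2), drug_thresholds = c(1.5, 1),
                    n_seeds = 30, seed = 31)
  mods <- isa_sweep(inp, cfg)
  kept <- robustness_filter(mods, inp, cfg)
  expect_lte(length(kept), max(1, 0.1 * length(mods)))
  # strong planted module: retained
  fx <- small_planted(seed = 15, effect = 5)
  inp2 <- isa_standardize(fx$ds$values)
  cfg2 <- isa_config(gene_thresholds = 3.5, drug_thresholds = 2,
                     n_seeds = 30, seed = 33)
  mods2 <- isa_sweep(inp2, cfg2)
  kept2 <- robustness_filter(mods2, inp2, cfg2)
  best <- max(vapply(kept2, function(m)
    jaccard(module_genes(m), fx$truth$genes), 0))
  expect_gte(best, 0.8)
  # disabled filter is the identity
  expect_identical(robustness_filter(mods2, inp2, cfg2, enabled = FALSE),
                   mods2)
})
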