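mk_ds <- function(values, drug = colnames(values), control = FALSE,
                  id = "X", ...) {
  expression_dataset(values,
                     profile_meta = data.frame(profile = colnames(values),
                                               drug = drug,
                                               control = control, ...),
                     scale = "raw", dataset_id = id)
}

test_that("replicate selection maximizes cross-cell-line consistency", {
  set.seed(21)
  genes <- sprintf("g%02d", 1:50)
  base <- rnorm(50)
  mk <- function(id, good, bad) {
    v <- cbind(good, bad)
    rownames(v) <- genes
    colnames(v) <- paste0(id, c("_r1", "_r2"))
    mk_ds(v, drug = c("dA", "dA"), id = id)
  }
  # replicate 1 identical across cell lines (r = 1), replicate 2 pure noise
  dss <- list(CL1 = mk("CL1", base, rnorm(50)),
              CL2 = mk("CL2", base, rnorm(50)),
              CL3 = mk("CL3", base, rnorm(50)))
  sel <- select_replicates(dss)
  for (cl in names(sel)) {
    expect_equal(ncol(sel[[cl]]$values), 1L)
    expect_equal(colnames(sel[[cl]]$values), paste0(cl, "_r1"))
  }
  # brute-force oracle over all 8 combinations on random data
  set.seed(22)
  dss2 <- list(CL1 = mk("CL1", rnorm(50), rnorm(50)),
               CL2 = mk("CL2", rnorm(50), rnorm(50)),
               CL3 = mk("CL3", rnorm(50), rnorm(50)))
  combos <- expand.grid(1:2, 1:2, 1:2)
  sc <- apply(combos, 1, function(co) {
    cols <- mapply(function(d, i) d$values[, i], dss2, co)
    cm <- cor(cols)
    mean(cm[upper.tri(cm)])
  })
  best <- unlist(combos[which.max(sc), ])
  sel2 <- select_replicates(dss2)
  got <- vapply(names(sel2), function(cl)
    match(colnames(sel2[[cl]]$values), colnames(dss2[[cl]]$values)), 1L)
  expect_equal(unname(got), unname(best))
  # single replicate everywhere: identity
  one <- lapply(dss, function(d) {
    d$values <- d$values[, 1, drop = FALSE]
    d$profile_meta <- d$profile_meta[1, , drop = FALSE]
    d
  })
  expect_equal(select_replicates(one), one)
})

test_that("present-call filtering keeps genes expressed in any cell line", {
  genes <- c("g1", "g2", "g3")
  mkp <- function(p1, p2, p3, n = 100) {
    m <- rbind(g1 = rep(c(TRUE, FALSE), c(p1, n - p1)),
               g2 = rep(c(TRUE, FALSE), c(p2, n - p2)),
               g3 = rep(c(TRUE, FALSE), c(p3, n - p3)))
    colnames(m) <- sprintf("p%03d", 1:n)
    ds <- mk_ds(matrix(0, 3, n, dimnames = list(genes, colnames(m))))
    ds$present <- m
    ds
  }
  dss <- list(CL1 = mkp(0, 11, 10), CL2 = mkp(0, 0, 10))
  keep <- present_call_filter(dss, threshold = 0.10)
  expect_equal(keep, c("g2"))        # 11% in one cell line is enough; 10% is not (strict >)
  dss$CL1$present <- NULL
  expect_error(present_call_filter(dss), "present-call")
})

test_that("probe collapse: random is seeded-uniform, maxvar takes the
           argmax with lexicographic ties", {
  v <- rbind(p1 = c(1, 2, 3, 4), p2 = c(1, 1, 1, 9), p3 = c(0, 0, 1, 0))
  colnames(v) <- sprintf("s%d", 1:4)
  ds <- mk_ds(v)
  ds$gene_meta <- data.frame(probe = c("p1", "p2", "p3"),
                             gene = c("gA", "gA", "gB"))
  # gB has a single probe
  r1 <- collapse_probes_random(ds, seed = 1)
  expect_true(all(rownames(r1$values) == c("gA", "gB")))
  expect_equal(unname(r1$values["gB", ]), unname(v["p3", ]))
  expect_identical(collapse_probes_random(ds, seed = 1)$gene_meta,
                   r1$gene_meta)
  # maxvar: var(p2) > var(p1)
  mv <- collapse_probes_maxvar(ds)
  expect_equal(mv$gene_meta$probe[mv$gene_meta$gene == "gA"], "p2")
  # tie broken lexicographically
  v2 <- rbind(pB = c(0, 1), pA = c(1, 0), pC = c(5, 5))
  colnames(v2) <- c("s1", "s2")
  ds2 <- mk_ds(v2)
  ds2$gene_meta <- data.frame(probe = c("pB", "pA", "pC"),
                              gene = c("g1", "g1", "g2"))
  expect_equal(collapse_probes_maxvar(ds2)$gene_meta$probe[1], "pA")
  # selection frequencies approximately uniform across seeds
  picks <- vapply(1:300, function(s)
    collapse_probes_random(ds, seed = s)$gene_meta$probe[1], "")
  expect_gt(stats::chisq.test(table(picks))$p.value, 1e-4)
})

test_that("quantile normalization equalizes column distributions", {
  m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  qn <- quantile_normalize(m)
  expect_equal(unname(qn[, "a"]), c(2.5, 3.5, 4.5))
  expect_equal(unname(qn[, "b"]), c(2.5, 3.5, 4.5))
  m2 <- cbind(a = c(3, 1, 2), b = c(3, 1, 2))
  expect_equal(quantile_normalize(m2), m2)
  set.seed(5)
  m3 <- matrix(rnorm(60), 20)
  qn3 <- quantile_normalize(m3)
  expect_equal(sort(qn3[, 1]), sort(qn3[, 2]))
  expect_equal(sort(qn3[, 2]), sort(qn3[, 3]))
  expect_warning(quantile_normalize(m[, 1, drop = FALSE]), "single")
})

test_that("missing-value handling drops >10% rows and mean-imputes the
           rest", {
  m <- rbind(a = c(1, NA, 3, 4, 5, 6, 7, 8, 9, 10),       # 10%: kept
             b = c(1, NA, NA, 4, 5, 6, 7, 8, 9, 10),      # 20%: dropped
             c = c(1, NA, 3, rep(1, 7)))
  out <- impute_missing(m)
  expect_equal(rownames(out), c("a", "c"))
  expect_equal(unname(out["a", 2]), mean(m["a", -2]))
  expect_equal(unname(out["c", 2]), mean(m["c", -2]))
  full <- matrix(1:6 + 0, 2, dimnames = list(c("x", "y"), NULL))
  expect_equal(impute_missing(full), full)
  allna <- rbind(ok = 1:10 + 0, bad = rep(NA_real_, 10))
  expect_equal(rownames(impute_missing(allna, max_missing_fraction = 1)),
               "ok")
})

test_that("regularized z-scores match the hand computation", {
  v <- rbind(g1 = c(2, 4, 6, 8), g2 = c(1, 1, 2, 2), g3 = c(5, 5, 5, 5))
  colnames(v) <- sprintf("t%d", 1:4)
  ctl <- rbind(g1 = c(3, 5), g2 = c(1, 2), g3 = c(5, 5))
  colnames(ctl) <- c("c1", "c2")
  z <- zscore_vs_controls(v, ctl, sd_quantile = 0.10)
  sd_g <- apply(cbind(v, ctl), 1, sd)
  q <- quantile(sd_g, 0.1, names = FALSE)
  expect_equal(z["g1", 1], (2 - 4) / (sd_g["g1"] + q),
               ignore_attr = TRUE)
  # constant gene: denominator is the quantile regularizer, z stays finite
  expect_true(all(is.finite(z["g3", ])))
  expect_equal(unname(z["g3", ]), rep(0, 4))
  # x equal to its control mean gives z = 0
  expect_equal(z["g2", 1], (1 - 1.5) / (sd_g["g2"] + q),
               ignore_attr = TRUE)
  expect_error(zscore_vs_controls(v, ctl[, 0]), "control")
})

test_that("replicate averaging means within (drug, dose, time) groups", {
  v <- cbind(a1 = c(1, 2), a2 = c(3, 4), b1 = c(5, 6), b2 = c(-5, -6))
  rownames(v) <- c("g1", "g2")
  ds <- expression_dataset(
    v, profile_meta = data.frame(profile = colnames(v),
                                 drug = c("A", "A", "B", "B"),
                                 dose = 1, time = 6,
                                 replicate = c(1, 2, 1, 2),
                                 control = FALSE),
    scale = "raw")
  avg <- average_replicates(ds)
  expect_equal(ncol(avg$values), 2)
  expect_equal(unname(avg$values[, 1]), c(2, 3))     # mean oracle
  expect_equal(unname(avg$values[, 2]), c(0, 0))     # z and -z cancel
  # distinct doses remain independent profiles
  ds$profile_meta$dose <- c(1, 2, 1, 1)
  expect_equal(ncol(average_replicates(ds)$values), 3)
})

test_that("ortholog restriction keeps one-to-one partners and translates
           ids", {
  v <- matrix(rnorm(12), 4, dimnames = list(c("r1", "r2", "r3", "r4"),
                                            c("s1", "s2", "s3")))
  ds <- mk_ds(v)
  omap <- data.frame(rat = c("r1", "r3", "r9"),
                     human = c("h1", "h3", "h9"))
  out <- restrict_to_orthologs(ds, omap, reference_genes = c("h1", "h3"))
  expect_equal(rownames(out$values), c("h1", "h3"))
  expect_equal(unname(out$values["h3", ]), unname(v["r3", ]))
  bad <- rbind(omap, data.frame(rat = "r1", human = "hX"))
  expect_error(restrict_to_orthologs(ds, bad, "h1"), "one-to-one")
  expect_warning(
    restrict_to_orthologs(ds, omap[0, ], reference_genes = "h1"),
    "no genes")
})

test_that("raw-mode data survive the liver preprocessing branch with sign
           and most of the effect retained", {
  pm <- planted_module("M", sprintf("g%05d", 1:40), sprintf("d%04d", 1:8),
                       3, datasets = "CL1")
  comp <- generate_compendium(n_genes = 400, n_drugs = 50,
                              n_cell_lines = 1, planted = list(pm),
                              liver = FALSE, mode = "raw",
                              replicate_count = 2, missing_rate = 0.02,
                              seed = 31)
  z <- preprocess_liver(comp$datasets$CL1)
  expect_equal(z$scale, "zscore")
  expect_true(all(is.finite(z$values)))
  # recovered effect per planted gene, in units of that gene's background
  # z-noise: mean over planted cells / sd over non-planted cells
  planted_cols <- z$profile_meta$drug %in% pm$drugs
  genes_in <- intersect(pm$genes, rownames(z$values))
  expect_gt(length(genes_in), 30)
  eff <- vapply(genes_in, function(g) {
    mean(z$values[g, planted_cols]) / sd(z$values[g, !planted_cols])
  }, 0)
  expect_true(all(eff > 0))                     # sign retained
  expect_gt(median(eff) / sqrt(2), 0.7 * 3)     # replicates averaged: /sqrt(2)
})
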