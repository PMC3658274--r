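universe <- sprintf("g%04d", 1:800)

test_that("identical catalogs link every module to its own copy with
           minimal q", {
  sets <- list(universe[1:40], universe[101:135], universe[301:330])
  a <- mk_catalog(sets, universe, "A")
  b <- mk_catalog(sets, universe, "B")
  links <- gene_overlap_links(a, b)
  expect_equal(nrow(links), 9)
  self <- links[links$module_a == "A-1" & links$module_b == "B-1", ]
  expect_equal(self$overlap, 40)
  expect_true(self$significant)
  links <- reciprocal_best_hits(links)
  expect_equal(sum(links$reciprocal_best), 3)
  expect_true(all(links$reciprocal_best ==
                    (sub("A", "", links$module_a) ==
                       sub("B", "", links$module_b))))
})

test_that("disjoint modules give P = 1 and no significant links", {
  a <- mk_catalog(list(universe[1:30]), universe, "A")
  b <- mk_catalog(list(universe[201:230]), universe, "B")
  links <- gene_overlap_links(a, b)
  expect_equal(links$p_gene, 1)
  expect_false(any(links$significant))
})

test_that("link p-values are symmetric in the catalog order", {
  set.seed(91)
  sa <- list(sample(universe, 35), sample(universe, 50))
  sb <- list(sample(universe, 40), sample(universe, 25))
  a <- mk_catalog(sa, universe, "A"); b <- mk_catalog(sb, universe, "B")
  ab <- gene_overlap_links(a, b)
  ba <- gene_overlap_links(b, a)
  m <- match(paste(ab$module_a, ab$module_b),
             paste(ba$module_b, ba$module_a))
  expect_equal(ab$p_gene, ba$p_gene[m])
  expect_equal(ab$q_gene, ba$q_gene[m])
})

test_that("best-hit selection keeps only the stronger of two competing
           partners", {
  a <- mk_catalog(list(universe[1:40]), universe, "A")
  b <- mk_catalog(list(universe[1:38],          # strong partner
                       c(universe[1:20], universe[501:520])),  # weaker
                  universe, "B")
  links <- reciprocal_best_hits(gene_overlap_links(a, b))
  best <- links[links$reciprocal_best, ]
  expect_equal(nrow(best), 1)
  expect_equal(best$module_b, "B-1")
})

test_that("random catalogs essentially never produce reciprocal
           significant links", {
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    a <- mk_catalog(replicate(4, sample(universe, 30), simplify = FALSE),
                    universe, "A")
    b <- mk_catalog(replicate(4, sample(universe, 30), simplify = FALSE),
                    universe, "B")
    sum(reciprocal_best_hits(gene_overlap_links(a, b))$reciprocal_best)
  }, 1L)
  expect_lte(mean(hits > 0), 0.05)
})

test_that("CODIMs are connected components of cell-line reciprocal best
           hits with union members", {
  sets <- list(universe[1:40], universe[201:240])
  cats <- list(A = mk_catalog(sets, universe, "A"),
               B = mk_catalog(sets, universe, "B"),
               C = mk_catalog(sets[1], universe, "C"))
  links <- rbind(gene_overlap_links(cats$A, cats$B),
                 gene_overlap_links(cats$A, cats$C),
                 gene_overlap_links(cats$B, cats$C))
  links <- reciprocal_best_hits(links)
  codims <- build_codims(links, cats)
  expect_length(codims, 2)
  n_members <- vapply(codims, function(cd) nrow(cd$members), 1L)
  expect_setequal(n_members, c(3L, 2L))
  big <- codims[[which(n_members == 3)]]
  expect_equal(big$genes, sort(universe[1:40]))
  # no links, no CODIMs
  none <- links; none$reciprocal_best <- FALSE
  expect_length(build_codims(none, cats), 0)
})

test_that("liver links annotate conservation but contribute no members", {
  sets <- list(universe[1:40])
  cats <- list(A = mk_catalog(sets, universe, "A"),
               B = mk_catalog(sets, universe, "B"),
               LIV = mk_catalog(sets, universe, "LIV", kind = "liver"))
  links <- rbind(gene_overlap_links(cats$A, cats$B),
                 gene_overlap_links(cats$A, cats$LIV),
                 gene_overlap_links(cats$B, cats$LIV))
  links <- reciprocal_best_hits(links)
  codims <- build_codims(links, cats)
  expect_length(codims, 1)
  expect_true(codims[[1]]$liver_conserved)
  expect_false("LIV" %in% codims[[1]]$members$dataset)
})

test_that("drug-overlap Fisher testing flags shared drug sets and refuses
           liver data", {
  drugs <- sprintf("d%03d", 1:100)
  shared_drugs <- drugs[1:10]
  a <- mk_catalog(list(universe[1:40]), universe, "A", drugs = drugs,
                  drug_sets = list(shared_drugs))
  b <- mk_catalog(list(universe[1:40]), universe, "B", drugs = drugs,
                  drug_sets = list(shared_drugs))
  links <- gene_overlap_links(a, b)
  out <- drug_overlap_links(links, list(A = a, B = b))
  expect_true(out$drug_significant[1])
  expect_equal(out$p_drug[1],
               hypergeom_overlap_p(10, 10, 10, 100), tolerance = 1e-12)
  disj <- mk_catalog(list(universe[1:40]), universe, "B", drugs = drugs,
                     drug_sets = list(drugs[50:59]))
  out2 <- drug_overlap_links(gene_overlap_links(a, disj),
                             list(A = a, B = disj))
  expect_false(out2$drug_significant[1])
  liv <- mk_catalog(list(universe[1:40]), universe, "LIV", kind = "liver")
  expect_error(drug_overlap_links(gene_overlap_links(a, liv),
                                  list(A = a, LIV = liv)), "liver")
})

test_that("the conservation permutation test is maximal for identical
           catalogs and calibrated-ish under the null", {
  sets <- list(universe[1:40], universe[101:140], universe[301:340])
  a <- mk_catalog(sets, universe, "A")
  b <- mk_catalog(sets, universe, "B")
  res <- conservation_permutation_test(a, b, n_perm = 99, seed = 4)
  expect_equal(res$observed, 3)
  expect_equal(res$p, 1 / 100)
  expect_error(conservation_permutation_test(a, b, n_perm = 0), "n_perm")
  # under the null (random a), p is not systematically small
  set.seed(17)
  ps <- vapply(1:10, function(s) {
    ra <- mk_catalog(replicate(3, sample(universe, 40), simplify = FALSE),
                     universe, "A")
    conservation_permutation_test(ra, b, n_perm = 49, seed = s)$p
  }, 0)
  expect_gt(mean(ps), 0.3)
})

test_that("orthology translation projects liver modules into the shared
           universe", {
  rat <- sprintf("r%04d", 1:300)
  omap <- data.frame(rat = rat, human = universe[1:300])
  a <- mk_catalog(list(universe[1:40]), universe[1:400], "A")
  b_rat <- mk_catalog(list(rat[1:40]), rat, "LIV", kind = "liver")
  links <- gene_overlap_links(a, b_rat, omap = omap)
  expect_equal(links$universe, 300)
  expect_equal(links$overlap, 40)
  expect_true(links$significant)
  no_omap <- data.frame(rat = rat, human = sprintf("z%04d", 1:300))
  expect_error(gene_overlap_links(a, mk_catalog(list(rat[1:40]), rat,
                                                "LIV", kind = "liver"),
                                  omap = no_omap), "empty shared")
})
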