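# Shared fixture builders: everything is generated in code at test time.

# Jaccard index of two id sets
jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# a small single-cell-line dataset with one planted bicluster that ISA can
# recover comfortably (module covers ~12% of drugs, ~5% of genes)
small_planted <- function(seed = 5, effect = 3) {
  truth <- planted_module("P1", sprintf("g%05d", 1:40),
                          sprintf("d%04d", 1:10), effect,
                          datasets = "CL1")
  comp <- generate_compendium(n_genes = 800, n_drugs = 80,
                              n_cell_lines = 1, planted = list(truth),
                              liver = FALSE, seed = seed)
  list(truth = truth, ds = comp$datasets$CL1)
}

# build an isa_module directly from member id vectors (unit scores)
mk_module <- function(genes, drugs, t_gene = 3.5, t_drug = 2.5,
                      gene_scores = NULL, id = NA_character_) {
  isa_module(gene_scores = stats::setNames(gene_scores %||%
                                             rep(1, length(genes)), genes),
             drug_scores = stats::setNames(rep(1, length(drugs)), drugs),
             t_gene = t_gene, t_drug = t_drug, id = id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# catalog over an explicit universe from a list of gene-set modules
mk_catalog <- function(gene_sets, universe, dataset_id = "A",
                       kind = "cellline", drugs = sprintf("d%03d", 1:50),
                       drug_sets = NULL) {
  mods <- lapply(seq_along(gene_sets), function(i) {
    mk_module(gene_sets[[i]],
              if (is.null(drug_sets)) drugs[1:5] else drug_sets[[i]])
  })
  module_catalog(mods, dataset_id = dataset_id, universe_genes = universe,
                 universe_drugs = drugs, kind = kind)
}

# independent enumeration oracle for the upper-tail hypergeometric:
# P(X >= q) computed by summing the pmf written out with choose()
hyper_tail_oracle <- function(q, K, n, N) {
  ks <- max(0, K + n - N):min(K, n)
  ks <- ks[ks >= q]
  if (length(ks) == 0) return(0)
  sum(exp(lchoose(K, ks) + lchoose(N - K, n - ks) - lchoose(N, n)))
}

# hand step-up BH oracle
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}
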