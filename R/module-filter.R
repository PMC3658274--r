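## Post-ISA module filters: removal of constitutive coexpression modules
## (apparent already in untreated samples), a minimum-size filter, and
## prioritized redundancy removal across the threshold sweep.

#' Filter configuration for the post-ISA stage
#'
#' Defaults: a module is constitutive when at
#' least 10% of its gene pairs show Pearson r > 0.6 in untreated samples;
#' minimum size 20 genes and 5 drugs (10 for liver); redundancy removal at
#' a module-correlation threshold of 0.3 and a gene-overlap hypergeometric
#' P < 1e-5.
#'
#' @param constitutive_pair_fraction,constitutive_r Constitutive-filter
#'   parameters.
#' @param min_genes,min_drugs Size-filter parameters.
#' @param redundancy_corr,overlap_p_cut Redundancy-removal parameters.
#' @param kind `"cellline"` or `"liver"` (selects `min_drugs` and the
#'   priority bands when not given explicitly).
#' @return Object of class `filter_config`.
#' @export
filter_config <- function(constitutive_pair_fraction = 0.10,
                          constitutive_r = 0.60, min_genes = 20L,
                          min_drugs = NULL, redundancy_corr = 0.30,
                          overlap_p_cut = 1e-5,
                          kind = c("cellline", "liver")) {
  kind <- match.arg(kind)
  if (is.null(min_drugs)) min_drugs <- if (kind == "liver") 10L else 5L
  structure(list(constitutive_pair_fraction = constitutive_pair_fraction,
                 constitutive_r = constitutive_r,
                 min_genes = as.integer(min_genes),
                 min_drugs = as.integer(min_drugs),
                 redundancy_corr = redundancy_corr,
                 overlap_p_cut = overlap_p_cut, kind = kind),
            class = "filter_config")
}

#' Remove constitutive coexpression modules
#'
#' Discards a module when at least `constitutive_pair_fraction` of its gene
#' pairs are strongly coexpressed (Pearson r > `constitutive_r`) in the
#' untreated samples as well — such modules reflect intrinsic cellular
#' programs rather than drug responses. Pairs involving genes absent from
#' the untreated matrix, or with undefined correlation (constant gene),
#' count as not coexpressed.
#'
#' @param modules List of [isa_module()] objects.
#' @param untreated Genes x untreated-profiles matrix (>= 3 profiles).
#' @param cfg [filter_config()].
#' @return Filtered module list.
#' @export
constitutive_filter <- function(modules, untreated, cfg = filter_config()) {
  if (ncol(untreated) < 3L) stop("need at least 3 untreated profiles")
  keep <- vapply(modules, function(m) {
    genes <- module_genes(m)
    total_pairs <- n_pairs(length(genes))
    if (total_pairs == 0) return(TRUE)
    present <- intersect(genes, rownames(untreated))
    if (length(present) < length(genes)) {
      warning("module gene(s) absent from untreated matrix; their pairs ",
              "count as not coexpressed")
    }
    n_hot <- 0
    if (length(present) >= 2) {
      cm <- suppressWarnings(stats::cor(t(untreated[present, ,
                                                    drop = FALSE])))
      cm[is.na(cm)] <- 0
      n_hot <- sum(cm[upper.tri(cm)] > cfg$constitutive_r)
    }
    (n_hot / total_pairs) < cfg$constitutive_pair_fraction
  }, TRUE)
  modules[keep]
}

#' Remove small modules
#'
#' Retains modules with at least `min_genes` genes and `min_drugs` drugs
#' (boundaries inclusive).
#'
#' @inheritParams constitutive_filter
#' @return Filtered module list.
#' @export
size_filter <- function(modules, cfg = filter_config()) {
  Filter(function(m) {
    length(m$gene_scores) >= cfg$min_genes &&
      length(m$drug_scores) >= cfg$min_drugs
  }, modules)
}

## threshold-band rank; lower rank = higher priority. Bands are checked in
## priority order because they overlap (e.g. 4..3 lies inside 5..3.2).
.band_rank <- function(t, bands) {
  for (i in seq_along(bands)) {
    b <- bands[[i]]
    if (t >= b[1] - 1e-9 && t <= b[2] + 1e-9) return(i)
  }
  NA_integer_
}

#' Order modules for redundancy removal
#'
#' Stable sort by threshold-of-origin priority bands so that medium-sized
#' modules are preferentially retained. For cell-line data, gene thresholds
#' in 4..3 rank above 5..3.2 and finally 2.8..2; for liver data, 3..2 above
#' 5..3.2. Drug thresholds in 3..2 rank above 4..3.2 in both, followed by
#' 1.8..1 for cell-line data. Ties keep sweep order; thresholds outside all
#' bands get lowest priority with a warning.
#'
#' @inheritParams constitutive_filter
#' @return The reordered module list.
#' @export
prioritize_modules <- function(modules, cfg = filter_config()) {
  if (length(modules) == 0L) return(modules)
  if (cfg$kind == "liver") {
    gene_bands <- list(c(2, 3), c(3.2, 5))
    drug_bands <- list(c(2, 3), c(3.2, 4))
  } else {
    gene_bands <- list(c(3, 4), c(3.2, 5), c(2, 2.8))
    drug_bands <- list(c(2, 3), c(3.2, 4), c(1, 1.8))
  }
  gr <- vapply(modules, function(m) .band_rank(m$t_gene, gene_bands), 1L)
  dr <- vapply(modules, function(m) .band_rank(m$t_drug, drug_bands), 1L)
  if (anyNA(gr) || anyNA(dr)) {
    warning("module threshold(s) outside all priority bands; ranked last")
    gr[is.na(gr)] <- length(gene_bands) + 1L
    dr[is.na(dr)] <- length(drug_bands) + 1L
  }
  modules[order(gr, dr)]   # stable
}

## signed membership-score correlation of two modules over the full gene
## universe (absent genes scored 0), computed sparsely; absolute value.
## Using the universe (not the union of members) keeps disjoint modules
## uncorrelated instead of artifactually anti-correlated.
.module_score_cor <- function(m1, m2, n_universe) {
  s1 <- m1$gene_scores; s2 <- m2$gene_scores
  common <- intersect(names(s1), names(s2))
  dot <- sum(s1[common] * s2[common])
  mu1 <- sum(s1) / n_universe; mu2 <- sum(s2) / n_universe
  ss1 <- sum(s1^2) - n_universe * mu1^2
  ss2 <- sum(s2^2) - n_universe * mu2^2
  if (ss1 <= 0 || ss2 <= 0) return(1)
  abs((dot - n_universe * mu1 * mu2) / sqrt(ss1 * ss2))
}

#' Sequentially remove redundant modules
#'
#' Two passes over the priority-ordered list. Pass 1: a module is kept only
#' if the absolute Pearson correlation between its signed gene
#' membership-score vector and that of every already-kept module (both
#' vectors laid out over the dataset's gene universe, absent genes scored
#' 0) is at most `redundancy_corr`. Pass 2: a module is kept only if its gene-overlap
#' hypergeometric P against every kept module is at least `overlap_p_cut`.
#'
#' @param modules Module list ordered by [prioritize_modules()].
#' @param cfg [filter_config()].
#' @param universe Gene count of the dataset (hypergeometric universe).
#' @return Non-redundant module list (subset of the input, in order).
#' @export
remove_redundant <- function(modules, cfg = filter_config(), universe) {
  kept <- list()
  for (m in modules) {
    redundant <- any(vapply(kept, function(km)
      .module_score_cor(m, km, universe) > cfg$redundancy_corr, TRUE))
    if (!redundant) kept <- c(kept, list(m))
  }
  kept2 <- list()
  for (m in kept) {
    redundant <- any(vapply(kept2, function(km) {
      ov <- length(intersect(module_genes(m), module_genes(km)))
      hypergeom_overlap_p(ov, length(m$gene_scores),
                          length(km$gene_scores),
                          universe) < cfg$overlap_p_cut
    }, TRUE))
    if (!redundant) kept2 <- c(kept2, list(m))
  }
  kept2
}

#' Apply the full post-ISA filter chain
#'
#' constitutive filter -> size filter -> prioritization -> redundancy
#' removal, returning a [module_catalog()].
#'
#' @param modules Output of [isa_sweep()] (optionally robustness-filtered).
#' @param ds The [expression_dataset()] the modules were discovered in
#'   (provides the untreated matrix and the universes).
#' @param cfg [filter_config()].
#' @return A [module_catalog()].
#' @export
filter_modules <- function(modules, ds, cfg = filter_config()) {
  if (!is.null(ds$untreated)) {
    modules <- constitutive_filter(modules, ds$untreated, cfg)
  }
  modules <- size_filter(modules, cfg)
  modules <- prioritize_modules(modules, cfg)
  modules <- remove_redundant(modules, cfg, universe = nrow(ds$values))
  module_catalog(modules, dataset_id = ds$dataset_id,
                 universe_genes = rownames(ds$values),
                 universe_drugs = unique(ds$profile_meta$drug),
                 kind = ds$kind)
}
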