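## Drug-set enrichment over annotation catalogs (targets, ATC classes, side
## effects, chemical fragments or any custom category) and Tanimoto-based
## selection of structurally novel repositioning candidates. Fragment x drug
## matrices and fingerprints are accepted as inputs; fragment generation
## itself is upstream cheminformatics.

#' Drop rarely-annotated terms from a catalog
#'
#' Retains only terms linked with at least `min_drugs` drugs within the
#' given drug universe.
#'
#' @param catalog [generate_annotations()]-style `annotation_catalog` (or
#'   any list with a `categories` field: category -> term -> drug vector).
#' @param drug_universe Drug universe the counts refer to; defaults to the
#'   catalog's own drug set.
#' @param min_drugs Minimum drug count per term (default 5, inclusive).
#' @return The catalog with sparse terms removed.
#' @export
filter_terms <- function(catalog, drug_universe = NULL, min_drugs = 5L) {
  drug_universe <- drug_universe %||% catalog$drugs
  catalog$categories <- lapply(catalog$categories, function(terms) {
    keep <- vapply(terms, function(d)
      length(intersect(d, drug_universe)) >= min_drugs, TRUE)
    terms[keep]
  })
  catalog
}

#' Drug-set enrichment of a module against an annotation catalog
#'
#' One-sided Fisher exact test per term, comparing the module's drug set
#' against the drug universe; BH-FDR within each category; the significance
#' flag applies a category-specific cutoff on q (`q_cut_fragment` for the
#' `fragment` category, `q_cut_default` elsewhere).
#'
#' @param module_drugs Non-empty character vector of the module's drugs
#'   (subset of `drug_universe`).
#' @param catalog Annotation catalog (see [filter_terms()]).
#' @param drug_universe Character vector of all drugs in the dataset.
#' @param q_cut_default FDR cutoff for target/ATC/side-effect/custom terms
#'   (default 0.1).
#' @param q_cut_fragment FDR cutoff for chemical fragments (default 0.01).
#' @return `data.frame` with one row per (category, term): counts `k`
#'   (module drugs with term), `K` (universe drugs with term), `n`, `N`,
#'   `p`, `q`, `significant`.
#' @export
enrich_terms <- function(module_drugs, catalog, drug_universe,
                         q_cut_default = 0.1, q_cut_fragment = 0.01) {
  module_drugs <- unique(module_drugs)
  if (length(module_drugs) == 0L) stop("empty module drug set")
  if (!all(module_drugs %in% drug_universe)) {
    stop("`module_drugs` must be a subset of `drug_universe`")
  }
  N <- length(drug_universe); n <- length(module_drugs)
  res <- list()
  for (cat_name in names(catalog$categories)) {
    terms <- catalog$categories[[cat_name]]
    if (length(terms) == 0L) next
    k <- vapply(terms, function(d)
      length(intersect(d, module_drugs)), 1L)
    K <- vapply(terms, function(d)
      length(intersect(d, drug_universe)), 1L)
    p <- fisher_exact_greater(k, n - k, K - k, N - n - K + k)
    q <- bh_fdr(p)
    cut <- if (cat_name == "fragment") q_cut_fragment else q_cut_default
    res[[cat_name]] <- data.frame(
      category = cat_name, term = names(terms), k = k, K = K, n = n, N = N,
      p = p, q = q, significant = q < cut, row.names = NULL,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Tanimoto similarity of two fingerprint bit-vectors
#'
#' `|a AND b| / |a OR b|` for equal-length logical (or 0/1) vectors.
#'
#' @param fp_a,fp_b Fingerprint bit-vectors of equal length, not both
#'   all-zero.
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto <- function(fp_a, fp_b) {
  if (length(fp_a) != length(fp_b)) stop("fingerprint lengths differ")
  a <- as.logical(fp_a); b <- as.logical(fp_b)
  denom <- sum(a | b)
  if (denom == 0L) stop("similarity undefined for two all-zero fingerprints")
  sum(a & b) / denom
}

#' Structurally novel repositioning candidates within a module
#'
#' Module drugs NOT annotated with `target_term` whose maximum Tanimoto
#' similarity to any module drug that IS annotated with the term is below
#' `max_sim` — i.e. drugs sharing the module's transcriptional response but
#' structurally dissimilar to the known binders, hence candidates for a new
#' mechanism of action.
#'
#' @param module_drugs Character vector of the module's drugs.
#' @param target_term Term name (searched across the catalog's categories).
#' @param catalog Annotation catalog with `fingerprints` (drugs x bits).
#' @param max_sim Tanimoto cutoff (default 0.5, strict "<").
#' @return Character vector of candidate drugs (possibly empty, with a
#'   warning when the module contains no annotated drug).
#' @export
repositioning_candidates <- function(module_drugs, target_term, catalog,
                                     max_sim = 0.5) {
  annotated_with <- unique(unlist(lapply(catalog$categories, function(tt)
    tt[[target_term]])))
  if (is.null(annotated_with)) {
    stop(sprintf("term '%s' not found in catalog", target_term))
  }
  known <- intersect(module_drugs, annotated_with)
  if (length(known) == 0L) {
    warning("no module drug is annotated with the target term")
    return(character(0))
  }
  cands <- setdiff(module_drugs, annotated_with)
  fp <- catalog$fingerprints
  keep <- vapply(cands, function(d) {
    sims <- vapply(known, function(kd) tanimoto(fp[d, ], fp[kd, ]), 0)
    max(sims) < max_sim
  }, TRUE)
  cands[keep]
}
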