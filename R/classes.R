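## Lightweight S3 containers. Expression data are plain genes x profiles
## matrices with a profile metadata data.frame, in the style of the
## biclustering literature; modules are signed score vectors over their
## members.

#' Construct an expression dataset
#'
#' A genes x profiles numeric matrix plus per-profile metadata (drug, batch,
#' dose, time, replicate, control flag) and optional companions: an
#' untreated/control matrix and a present-call matrix. The substrate of all
#' module discovery.
#'
#' @param values Numeric matrix, genes as rows (rownames = gene ids),
#'   profiles as columns (colnames = profile ids).
#' @param profile_meta `data.frame` with one row per column of `values`;
#'   recognised columns: `profile`, `drug`, `batch`, `dose`, `time`,
#'   `replicate`, `control`.
#' @param untreated Optional genes x untreated-profiles matrix.
#' @param present Optional logical genes x profiles present-call matrix.
#' @param gene_meta Optional `data.frame` with columns `probe`, `gene`.
#' @param scale Either `"zscore"` or `"raw"`.
#' @param dataset_id Identifier, e.g. a cell line name.
#' @param kind `"cellline"` or `"liver"`.
#' @return An object of class `expression_dataset`.
#' @export
expression_dataset <- function(values, profile_meta = NULL, untreated = NULL,
                               present = NULL, gene_meta = NULL,
                               scale = c("zscore", "raw"),
                               dataset_id = "dataset", kind = "cellline") {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (is.null(rownames(values))) {
    stop("`values` must have gene ids as rownames")
  }
  if (anyDuplicated(colnames(values))) stop("duplicate profile ids")
  if (is.null(profile_meta)) {
    profile_meta <- data.frame(profile = colnames(values),
                               drug = colnames(values))
  }
  if (nrow(profile_meta) != ncol(values)) {
    stop("`profile_meta` must have one row per profile")
  }
  if (scale == "zscore" && any(!is.finite(values))) {
    stop("z-score matrices must have finite entries")
  }
  structure(list(values = values, profile_meta = profile_meta,
                 untreated = untreated, present = present,
                 gene_meta = gene_meta, scale = scale,
                 dataset_id = dataset_id, kind = kind),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset '%s' (%s)> %d genes x %d profiles [%s]\n",
              x$dataset_id, x$kind, nrow(x$values), ncol(x$values), x$scale))
  if (!is.null(x$untreated)) {
    cat(sprintf("  untreated companion: %d profiles\n", ncol(x$untreated)))
  }
  invisible(x)
}

#' Construct a transcriptional module (bicluster)
#'
#' A subset of genes with signed scores plus the subset of drug treatments
#' that coherently regulate them, tagged with the (gene, drug) threshold
#' pair it was discovered at.
#'
#' @param gene_scores Named numeric vector of signed gene scores; names are
#'   the member gene ids.
#' @param drug_scores Named numeric vector of signed condition scores; names
#'   are the member drug/treatment ids.
#' @param t_gene,t_drug Thresholds of origin.
#' @param dataset Dataset id the module was found in.
#' @param id Module id (assigned by sweeps/catalogs when `NA`).
#' @param provenance Free-form list (seed count, iterations, ...).
#' @return Object of class `isa_module`.
#' @export
isa_module <- function(gene_scores, drug_scores, t_gene = NA_real_,
                       t_drug = NA_real_, dataset = NA_character_,
                       id = NA_character_, provenance = list()) {
  if (length(gene_scores) < 1L || length(drug_scores) < 1L) {
    stop("a module needs at least one gene and one drug")
  }
  if (is.null(names(gene_scores)) || is.null(names(drug_scores))) {
    stop("scores must be named by gene/drug ids")
  }
  if (any(!is.finite(gene_scores)) || any(!is.finite(drug_scores))) {
    stop("scores must be finite")
  }
  structure(list(gene_scores = gene_scores, drug_scores = drug_scores,
                 t_gene = t_gene, t_drug = t_drug, dataset = dataset,
                 id = id, provenance = provenance),
            class = "isa_module")
}

#' @export
print.isa_module <- function(x, ...) {
  cat(sprintf("<isa_module %s@%s> %d genes, %d drugs (t_gene=%.2g, t_drug=%.2g)\n",
              x$id %||% "?", x$dataset, length(x$gene_scores),
              length(x$drug_scores), x$t_gene, x$t_drug))
  invisible(x)
}

#' Member gene ids of a module
#' @param m An `isa_module`.
#' @return Character vector of gene ids.
#' @export
module_genes <- function(m) names(m$gene_scores)

#' Member drug ids of a module
#' @param m An `isa_module`.
#' @return Character vector of drug ids.
#' @export
module_drugs <- function(m) names(m$drug_scores)

#' Construct a module catalog
#'
#' The set of modules discovered in one dataset, together with the gene and
#' drug universes that define the background for all overlap and enrichment
#' tests.
#'
#' @param modules List of [isa_module()] objects.
#' @param dataset_id Dataset identifier.
#' @param universe_genes Character vector: all genes input to discovery.
#' @param universe_drugs Character vector: all drugs in the dataset.
#' @param kind `"cellline"` or `"liver"`.
#' @return Object of class `module_catalog`.
#' @export
module_catalog <- function(modules, dataset_id, universe_genes,
                           universe_drugs, kind = "cellline") {
  modules <- unname(modules)
  for (i in seq_along(modules)) {
    modules[[i]]$dataset <- dataset_id
    if (is.na(modules[[i]]$id)) {
      modules[[i]]$id <- sprintf("%s-%d", dataset_id, i)
    }
  }
  names(modules) <- vapply(modules, `[[`, "", "id")
  structure(list(modules = modules, dataset_id = dataset_id,
                 universe_genes = unique(universe_genes),
                 universe_drugs = unique(universe_drugs), kind = kind),
            class = "module_catalog")
}

#' @export
print.module_catalog <- function(x, ...) {
  cat(sprintf("<module_catalog '%s' (%s)> %d modules; %d genes, %d drugs in universe\n",
              x$dataset_id, x$kind, length(x$modules),
              length(x$universe_genes), length(x$universe_drugs)))
  invisible(x)
}
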