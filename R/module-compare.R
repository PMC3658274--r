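## Cross-dataset module matching and conservation analysis: hypergeometric
## gene-overlap links with per-dataset-pair FDR, reciprocal best hits,
## construction of conserved drug-induced modules (CODIMs) as connected
## components of the reciprocal-best-hit graph, drug-overlap Fisher tests
## between linked cell-line modules, and a permutation test for the number
## of conserved modules.

## translate a character vector via a 2-column map (NA where unmapped)
.translate <- function(x, omap, from, to) {
  if (is.null(omap)) return(x)
  tr <- stats::setNames(omap[[to]], omap[[from]])
  out <- unname(tr[x])
  out[!is.na(out)]
}

## membership matrix (modules x shared-universe)
.membership <- function(gene_sets, shared) {
  M <- matrix(FALSE, length(gene_sets), length(shared))
  for (i in seq_along(gene_sets)) {
    M[i, match(intersect(gene_sets[[i]], shared), shared)] <- TRUE
  }
  M
}

## all-pairs overlap p-values between two lists of gene sets in a shared
## universe; returns list(overlap, size_a, size_b, p) as matrices/vectors
.overlap_grid <- function(sets_a, sets_b, shared) {
  A <- .membership(sets_a, shared)
  B <- .membership(sets_b, shared)
  O <- A %*% t(B)                       # overlap counts
  na <- rowSums(A); nb <- rowSums(B)
  grid <- expand.grid(i = seq_along(sets_a), j = seq_along(sets_b))
  p <- hypergeom_overlap_p(O[cbind(grid$i, grid$j)], na[grid$i],
                           nb[grid$j], length(shared))
  list(grid = grid, overlap = O[cbind(grid$i, grid$j)],
       size_a = na[grid$i], size_b = nb[grid$j], p = p)
}

#' Gene-overlap links between two module catalogs
#'
#' Projects both catalogs' gene memberships into the shared universe (the
#' intersection of the two datasets' gene universes, after orthology
#' translation when `omap` is given), computes the upper-tail
#' hypergeometric overlap P for every module pair, applies BH-FDR across
#' all pairs of this dataset pair, and flags links with q below `q_cut`.
#'
#' @param catalog_a,catalog_b [module_catalog()] objects.
#' @param omap Optional one-to-one orthology `data.frame`; column `from`
#'   holds ids in catalog_b's namespace, column `to` ids in catalog_a's.
#' @param q_cut FDR cutoff for a significant link (default 0.01).
#' @param from,to Column names of `omap`.
#' @return `data.frame` (class `module_links`) with one row per module
#'   pair: ids, datasets, overlap, `p_gene`, `q_gene`, `significant`.
#' @export
gene_overlap_links <- function(catalog_a, catalog_b, omap = NULL,
                               q_cut = 0.01, from = "rat", to = "human") {
  ua <- catalog_a$universe_genes
  ub <- .translate(catalog_b$universe_genes, omap, from, to)
  shared <- intersect(ua, ub)
  if (length(shared) == 0L) stop("empty shared gene universe")
  sets_a <- lapply(catalog_a$modules, module_genes)
  sets_b <- lapply(catalog_b$modules, function(m)
    .translate(module_genes(m), omap, from, to))
  og <- .overlap_grid(sets_a, sets_b, shared)
  q <- bh_fdr(og$p)
  links <- data.frame(
    module_a = names(catalog_a$modules)[og$grid$i],
    dataset_a = catalog_a$dataset_id,
    module_b = names(catalog_b$modules)[og$grid$j],
    dataset_b = catalog_b$dataset_id,
    overlap = og$overlap, size_a = og$size_a, size_b = og$size_b,
    universe = length(shared), p_gene = og$p, q_gene = q,
    significant = q < q_cut,
    stringsAsFactors = FALSE)
  class(links) <- c("module_links", "data.frame")
  links
}

## order used to pick the "best" partner: smallest p, then largest overlap,
## then lexicographic partner id
.best_partner <- function(p, overlap, partner_id) {
  o <- order(p, -overlap, partner_id)
  o[1]
}

#' Mark reciprocal best hits among module links
#'
#' A link is a reciprocal best hit iff module A is module B's minimum-P
#' partner within A's dataset and vice versa, and the link is significant.
#' P-value ties are broken by larger overlap, then lexicographic module id.
#'
#' @param links Output of [gene_overlap_links()] (one dataset pair, or
#'   several row-bound pairs).
#' @return `links` with a logical `reciprocal_best` column added.
#' @export
reciprocal_best_hits <- function(links) {
  links$reciprocal_best <- FALSE
  pair_key <- paste(links$dataset_a, links$dataset_b)
  for (pk in unique(pair_key)) {
    rows <- which(pair_key == pk)
    sub <- links[rows, , drop = FALSE]
    best_ab <- tapply(seq_len(nrow(sub)), sub$module_a, function(idx) {
      idx[.best_partner(sub$p_gene[idx], sub$overlap[idx],
                        sub$module_b[idx])]
    })
    best_ba <- tapply(seq_len(nrow(sub)), sub$module_b, function(idx) {
      idx[.best_partner(sub$p_gene[idx], sub$overlap[idx],
                        sub$module_a[idx])]
    })
    rbh <- intersect(unlist(best_ab), unlist(best_ba))
    rbh <- rbh[sub$significant[rbh]]
    links$reciprocal_best[rows[rbh]] <- TRUE
  }
  links
}

#' Build conserved drug-induced modules (CODIMs)
#'
#' Connected components of the reciprocal-best-hit graph over cell-line
#' modules; every component with at least two member modules becomes a
#' CODIM whose gene and drug sets are the unions over its member modules.
#' Links to liver modules do not contribute members but annotate the CODIM
#' (and the individual modules) as conserved across species.
#'
#' @param links Links with a `reciprocal_best` column
#'   (see [reciprocal_best_hits()]); may row-bind several dataset pairs.
#' @param catalogs Named list of [module_catalog()] objects keyed by
#'   dataset id.
#' @return List of `codim` objects: `id`, `members` (data.frame with
#'   `dataset`, `module`), `genes`, `drugs`, `liver_conserved`.
#' @export
build_codims <- function(links, catalogs) {
  kind_of <- vapply(catalogs, `[[`, "", "kind")
  rbh <- links[links$reciprocal_best, , drop = FALSE]
  cell <- rbh[kind_of[rbh$dataset_a] == "cellline" &
              kind_of[rbh$dataset_b] == "cellline", , drop = FALSE]
  if (nrow(cell) == 0L) return(list())
  va <- paste(cell$dataset_a, cell$module_a, sep = "\r")
  vb <- paste(cell$dataset_b, cell$module_b, sep = "\r")
  g <- igraph::graph_from_edgelist(cbind(va, vb), directed = FALSE)
  comp <- igraph::components(g)
  liver_linked <- unique(c(
    paste(rbh$dataset_a, rbh$module_a, sep = "\r")[
      kind_of[rbh$dataset_b] == "liver"],
    paste(rbh$dataset_b, rbh$module_b, sep = "\r")[
      kind_of[rbh$dataset_a] == "liver"]))
  out <- list()
  for (ci in seq_len(comp$no)) {
    vids <- names(comp$membership)[comp$membership == ci]
    if (length(vids) < 2L) next
    parts <- do.call(rbind, strsplit(vids, "\r", fixed = TRUE))
    members <- data.frame(dataset = parts[, 1], module = parts[, 2],
                          stringsAsFactors = FALSE)
    members <- members[order(members$dataset, members$module), ,
                       drop = FALSE]
    genes <- character(0); drugs <- character(0)
    for (r in seq_len(nrow(members))) {
      m <- catalogs[[members$dataset[r]]]$modules[[members$module[r]]]
      genes <- union(genes, module_genes(m))
      drugs <- union(drugs, module_drugs(m))
    }
    out[[length(out) + 1L]] <- structure(
      list(id = sprintf("CODIM%d", length(out) + 1L), members = members,
           genes = sort(genes), drugs = sort(drugs),
           liver_conserved = any(vids %in% liver_linked)),
      class = "codim")
  }
  out
}

#' @export
print.codim <- function(x, ...) {
  cat(sprintf("<%s> %d member modules (%s)%s; %d genes, %d drugs\n",
              x$id, nrow(x$members),
              paste(x$members$module, collapse = ", "),
              if (x$liver_conserved) ", liver-conserved" else "",
              length(x$genes), length(x$drugs)))
  invisible(x)
}

#' Drug-overlap Fisher tests for linked cell-line modules
#'
#' For every link, tests the overlap of the two modules' drug sets over the
#' intersection of the two datasets' drug universes (one-sided Fisher exact
#' test), with BH-FDR per dataset pair. Liver catalogs are refused: the
#' number of drugs shared with the liver dataset is too low for a solid
#' drug-overlap comparison.
#'
#' @param links Output of [gene_overlap_links()].
#' @param catalogs Named list of [module_catalog()] objects.
#' @param q_cut FDR cutoff (default 0.01).
#' @return `links` with `p_drug`, `q_drug`, `drug_significant` columns.
#' @export
drug_overlap_links <- function(links, catalogs, q_cut = 0.01) {
  kinds <- vapply(catalogs, `[[`, "", "kind")
  used <- unique(c(links$dataset_a, links$dataset_b))
  if (any(kinds[used] == "liver")) {
    stop("drug-overlap testing is only defined between cell-line ",
         "datasets (too few drugs in common with liver data)")
  }
  p <- numeric(nrow(links))
  for (r in seq_len(nrow(links))) {
    ca <- catalogs[[links$dataset_a[r]]]
    cb <- catalogs[[links$dataset_b[r]]]
    uni <- intersect(ca$universe_drugs, cb$universe_drugs)
    da <- intersect(module_drugs(ca$modules[[links$module_a[r]]]), uni)
    db <- intersect(module_drugs(cb$modules[[links$module_b[r]]]), uni)
    k <- length(intersect(da, db))
    p[r] <- fisher_exact_greater(k, length(da) - k, length(db) - k,
                                 length(uni) - length(da) - length(db) + k)
  }
  links$p_drug <- p
  pair_key <- paste(links$dataset_a, links$dataset_b)
  links$q_drug <- NA_real_
  for (pk in unique(pair_key)) {
    rows <- pair_key == pk
    links$q_drug[rows] <- bh_fdr(links$p_drug[rows])
  }
  links$drug_significant <- links$q_drug < q_cut
  links
}

## count of catalog-a gene sets with a significant reciprocal best hit
## among catalog-b gene sets; the statistic of the conservation test
.rbh_count <- function(sets_a, sets_b, shared, q_cut) {
  og <- .overlap_grid(sets_a, sets_b, shared)
  q <- bh_fdr(og$p)
  P <- matrix(og$p, length(sets_a), length(sets_b))
  O <- matrix(og$overlap, length(sets_a), length(sets_b))
  sig <- matrix(q < q_cut, length(sets_a), length(sets_b))
  n <- 0L
  best_for_b <- vapply(seq_along(sets_b), function(j)
    .best_partner(P[, j], O[, j], seq_along(sets_a)), 1L)
  for (i in seq_along(sets_a)) {
    j <- .best_partner(P[i, ], O[i, ], seq_along(sets_b))
    if (sig[i, j] && best_for_b[j] == i) n <- n + 1L
  }
  n
}

#' Permutation test for cross-dataset module conservation
#'
#' Observed statistic: the number of catalog-a modules with a significant
#' reciprocal best hit in catalog b. Null: each catalog-a module's gene set
#' is replaced by a uniformly drawn gene set of identical size from
#' catalog a's universe and the statistic recomputed; the p-value follows
#' the add-one permutation convention of [empirical_p()].
#'
#' @inheritParams gene_overlap_links
#' @param n_perm Number of permutations (>= 1; default 1000).
#' @param seed Integer seed.
#' @return List with `observed`, `null` (vector) and `p`.
#' @export
conservation_permutation_test <- function(catalog_a, catalog_b, omap = NULL,
                                          n_perm = 1000, seed = 1,
                                          q_cut = 0.01, from = "rat",
                                          to = "human") {
  if (n_perm < 1) stop("`n_perm` must be >= 1")
  ua <- catalog_a$universe_genes
  ub <- .translate(catalog_b$universe_genes, omap, from, to)
  shared <- intersect(ua, ub)
  if (length(shared) == 0L) stop("empty shared gene universe")
  sets_a <- lapply(catalog_a$modules, module_genes)
  sets_b <- lapply(catalog_b$modules, function(m)
    .translate(module_genes(m), omap, from, to))
  observed <- .rbh_count(sets_a, sets_b, shared, q_cut)
  sizes <- vapply(sets_a, length, 1L)
  set.seed(stage_seed(seed, "conservation-null"))
  null <- vapply(seq_len(n_perm), function(b) {
    rand_sets <- lapply(sizes, function(k) sample(ua, min(k, length(ua))))
    .rbh_count(rand_sets, sets_b, shared, q_cut)
  }, 1L)
  list(observed = observed, null = null, p = empirical_p(observed, null))
}
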