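## Functional coherence of modules against a gene-gene association network:
## the proportion of functionally associated gene pairs within a module is
## compared against the distribution of that proportion in random gene sets
## of matched size.

#' Filter a raw scored edge list into an association network
#'
#' Drops edges from excluded evidence channels (by default coexpression,
#' which is methodologically analogous to the expression data the modules
#' come from), combines the remaining channels per gene pair by their
#' maximum score, retains pairs with score strictly above `min_score`, and
#' removes self-relations.
#'
#' @param raw_edges `data.frame` with columns `gene_a`, `gene_b`, `score`
#'   and optionally `channel`.
#' @param min_score Minimum retained score (default 0.4, the conventional
#'   intermediate-confidence cutoff).
#' @param excluded_channels Channels to drop (default `"coexpression"`).
#' @return Object of class `association_network` with a deduplicated edge
#'   `data.frame` and the covered gene set.
#' @export
filter_network <- function(raw_edges, min_score = 0.4,
                           excluded_channels = "coexpression") {
  e <- raw_edges
  if (length(excluded_channels) && !is.null(e$channel)) {
    e <- e[!(e$channel %in% excluded_channels), , drop = FALSE]
  } else if (length(excluded_channels) && is.null(e$channel) &&
             !identical(excluded_channels, "coexpression")) {
    stop("channel labels required to exclude channels")
  }
  e <- e[e$gene_a != e$gene_b, , drop = FALSE]
  a <- pmin(e$gene_a, e$gene_b); b <- pmax(e$gene_a, e$gene_b)
  key <- paste(a, b, sep = "\r")
  score <- tapply(e$score, key, max)
  first <- !duplicated(key)
  edges <- data.frame(gene_a = a[first], gene_b = b[first],
                      score = unname(score[key[first]]),
                      stringsAsFactors = FALSE)
  edges <- edges[edges$score > min_score, , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges,
                 genes = sort(unique(c(edges$gene_a, edges$gene_b)))),
            class = "association_network")
}

#' @export
print.association_network <- function(x, ...) {
  cat(sprintf("<association_network> %d edges over %d genes\n",
              nrow(x$edges), length(x$genes)))
  invisible(x)
}

## dense logical adjacency over the network's gene set (cached)
.net_adjacency <- function(net) {
  n <- length(net$genes)
  A <- matrix(FALSE, n, n)
  ia <- match(net$edges$gene_a, net$genes)
  ib <- match(net$edges$gene_b, net$genes)
  A[cbind(ia, ib)] <- TRUE
  A[cbind(ib, ia)] <- TRUE
  A
}

#' Permutation test for the functional coherence of a module
#'
#' Computes the proportion of gene pairs within `module_genes` that are
#' linked in the association network (self-relations excluded) and compares
#' it against the same proportion in `n_random` gene sets of matched size
#' drawn uniformly without replacement from `universe`. Random sets are
#' drawn from the full expression universe, not from network nodes only;
#' genes absent from the network contribute no edges. One-sided test
#' (enrichment only).
#'
#' @param module_genes Character vector of >= 2 gene ids.
#' @param net [filter_network()] output.
#' @param universe Character vector containing `module_genes`.
#' @param n_random Number of random sets (default 1000).
#' @param seed Integer seed.
#' @return List with `proportion`, `null` (vector of null proportions) and
#'   `p` (add-one permutation p-value).
#' @export
coherence_test <- function(module_genes, net, universe, n_random = 1000,
                           seed = 1) {
  module_genes <- unique(module_genes)
  if (length(module_genes) < 2L) stop("module must have at least 2 genes")
  if (!all(module_genes %in% universe)) {
    stop("`universe` must contain all module genes")
  }
  A <- .net_adjacency(net)
  prop_of <- function(genes) {
    idx <- match(genes, net$genes)
    idx <- idx[!is.na(idx)]
    hits <- if (length(idx) >= 2) sum(A[idx, idx]) / 2 else 0
    hits / n_pairs(length(genes))
  }
  observed <- prop_of(module_genes)
  k <- length(module_genes)
  set.seed(stage_seed(seed, "coherence-null"))
  null <- vapply(seq_len(n_random), function(b)
    prop_of(sample(universe, k)), 0)
  list(proportion = observed, null = null,
       p = empirical_p(observed, null))
}
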