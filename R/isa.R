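## Iterative Signature Algorithm (ISA) biclustering.
##
## ISA alternates between scoring drug treatments given a gene signature and
## scoring genes given the treatment signature, thresholding each score
## vector at a multiple of its standard deviation, until a fixed point.
## Conventions pinned here for reproducibility: score normalization by the
## L1 norm of the current membership vector; thresholding |score| >
## t * sd(score) with the sd computed over ALL genes/conditions at that
## iteration; signed membership retained (up- and down-regulated genes can
## coexist in one module); convergence when the Pearson correlation of
## consecutive gene-score vectors exceeds 1 - eps for two consecutive
## iterations. Many random sparse seeds per threshold pair are iterated as
## one matrix so that the full threshold sweep stays fast on one CPU.

#' Prepare a matrix for ISA
#'
#' Builds the row-standardized (`E_G`) and column-standardized (`E_C`)
#' copies of a z-score matrix. Constant rows are dropped with a warning.
#'
#' @param E Genes x treatments numeric matrix (no missing entries).
#' @return Object of class `isa_input` with `E`, `E_G`, `E_C`.
#' @export
isa_standardize <- function(E) {
  E <- as.matrix(E)
  if (nrow(E) < 2L || ncol(E) < 2L) stop("need at least 2 rows and columns")
  if (any(!is.finite(E))) stop("missing or non-finite entries not allowed")
  rs <- apply(E, 1, stats::sd)
  if (any(rs == 0)) {
    warning(sprintf("dropping %d constant gene row(s)", sum(rs == 0)))
    E <- E[rs > 0, , drop = FALSE]
    rs <- rs[rs > 0]
  }
  cs <- apply(E, 2, stats::sd)
  if (any(cs == 0)) stop("constant treatment column(s) present")
  E_G <- (E - rowMeans(E)) / rs
  E_C <- sweep(sweep(E, 2, colMeans(E), "-"), 2, cs, "/")
  structure(list(E = E, E_G = E_G, E_C = E_C,
                 genes = rownames(E), drugs = colnames(E)),
            class = "isa_input")
}

#' @export
print.isa_input <- function(x, ...) {
  cat(sprintf("<isa_input> %d genes x %d treatments\n",
              nrow(x$E), ncol(x$E)))
  invisible(x)
}

## column-wise sd of a matrix, fast
.col_sds <- function(M) {
  n <- nrow(M)
  if (n < 2) return(rep(0, ncol(M)))
  mu <- colMeans(M)
  sqrt(pmax(0, (colSums(M^2) - n * mu^2) / (n - 1)))
}

## threshold each column of M at t * its sd; entries at or below -> 0
.threshold_cols <- function(M, t) {
  thr <- t * .col_sds(M)
  M * (abs(M) > rep(thr, each = nrow(M)))
}

## column-wise correlation between matched columns of A and B; NA when a
## column is constant (e.g. all zero)
.col_cors <- function(A, B) {
  a <- sweep(A, 2, colMeans(A)); b <- sweep(B, 2, colMeans(B))
  num <- colSums(a * b)
  den <- sqrt(colSums(a^2) * colSums(b^2))
  ifelse(den > 0, num / den, NA_real_)
}

## Core batched fixed-point iteration. G0: genes x n_seeds signed seed
## matrix. Returns list(G, C, converged, iterations).
.isa_batch <- function(input, G0, t_gene, t_drug, eps = 1e-2,
                       max_iter = 100L) {
  E_G <- input$E_G; E_C <- input$E_C
  G <- G0
  m <- ncol(G)
  conv_streak <- integer(m)
  status <- integer(m)            # 0 running, 1 converged, -1 dead
  iters <- integer(m)
  C_out <- matrix(0, ncol(E_G), m)
  active <- seq_len(m)
  for (it in seq_len(max_iter)) {
    Ga <- G[, active, drop = FALSE]
    l1g <- colSums(abs(Ga))
    dead <- l1g == 0
    C <- crossprod(E_G, Ga)
    C[, !dead] <- sweep(C[, !dead, drop = FALSE], 2, l1g[!dead], "/")
    C <- .threshold_cols(C, t_drug)
    l1c <- colSums(abs(C))
    dead <- dead | l1c == 0
    Gn <- E_C %*% C
    ok <- !dead
    Gn[, ok] <- sweep(Gn[, ok, drop = FALSE], 2, l1c[ok], "/")
    Gn <- .threshold_cols(Gn, t_gene)
    dead <- dead | colSums(abs(Gn)) == 0
    cc <- .col_cors(Ga, Gn)
    hit <- !dead & !is.na(cc) & cc > 1 - eps
    conv_streak[active] <- ifelse(hit, conv_streak[active] + 1L, 0L)
    G[, active] <- Gn
    C_out[, active] <- C
    iters[active] <- it
    status[active[dead]] <- -1L
    status[active[conv_streak[active] >= 2L]] <- 1L
    active <- which(status == 0L)
    if (length(active) == 0L) break
  }
  list(G = G, C = C_out, converged = status == 1L, iterations = iters)
}

## ISA robustness score of a module signature against a (normalized) input:
## geometric mean of the gene- and condition-side signature strengths.
.robustness_score <- function(input, g, c) {
  gn <- g / sqrt(sum(g^2)); cn <- c / sqrt(sum(c^2))
  a <- as.numeric(crossprod(gn, input$E_C %*% cn))
  b <- as.numeric(crossprod(cn, crossprod(input$E_G, gn)))
  sqrt(abs(a * b))
}

.modules_from_batch <- function(res, input, t_gene, t_drug, provenance) {
  out <- list()
  idx <- which(res$converged)
  for (j in idx) {
    g <- res$G[, j]; c <- res$C[, j]
    gi <- which(g != 0); ci <- which(c != 0)
    if (length(gi) == 0L || length(ci) == 0L) next
    prov <- provenance
    prov$iterations <- res$iterations[j]
    prov$robustness <- .robustness_score(input, g, c)
    out[[length(out) + 1L]] <- isa_module(
      gene_scores = stats::setNames(g[gi], input$genes[gi]),
      drug_scores = stats::setNames(c[ci], input$drugs[ci]),
      t_gene = t_gene, t_drug = t_drug, provenance = prov)
  }
  out
}

## canonical signature of a module up to a global sign flip
.module_signature <- function(m) {
  s <- if (m$gene_scores[[which.max(abs(m$gene_scores))]] < 0) -1 else 1
  o <- order(names(m$gene_scores))
  od <- order(names(m$drug_scores))
  paste(paste(names(m$gene_scores)[o],
              sign(m$gene_scores)[o] * s, collapse = ";"),
        paste(names(m$drug_scores)[od],
              sign(m$drug_scores)[od] * s, collapse = ";"),
        sep = "|")
}

.dedupe_modules <- function(modules) {
  if (length(modules) <= 1L) return(modules)
  sig <- vapply(modules, .module_signature, "")
  modules[!duplicated(sig)]
}

#' Run a single ISA iteration to convergence from one seed
#'
#' @param input [isa_standardize()] output.
#' @param seed_genes Character vector of seed gene ids, or a named signed
#'   numeric vector of initial gene scores.
#' @param t_gene,t_drug Gene and condition thresholds (> 0).
#' @param eps Convergence tolerance on the correlation of consecutive score
#'   vectors (default 1e-2).
#' @param max_iter Iteration cap (default 100).
#' @return An [isa_module()], or `NULL` if the gene or condition set
#'   empties or convergence is not reached.
#' @export
isa_iterate <- function(input, seed_genes, t_gene, t_drug, eps = 1e-2,
                        max_iter = 100L) {
  stopifnot(t_gene > 0, t_drug > 0)
  g0 <- numeric(length(input$genes))
  if (is.character(seed_genes)) {
    g0[match(seed_genes, input$genes)] <- 1
  } else {
    g0[match(names(seed_genes), input$genes)] <- unname(seed_genes)
  }
  if (all(g0 == 0)) stop("seed gene set does not intersect the input genes")
  res <- .isa_batch(input, matrix(g0, ncol = 1), t_gene, t_drug, eps,
                    max_iter)
  mods <- .modules_from_batch(res, input, t_gene, t_drug,
                              provenance = list(n_seeds = 1L))
  if (length(mods)) mods[[1]] else NULL
}

#' ISA configuration
#'
#' Default threshold grids: gene thresholds
#' span 5 to 2 in steps of 0.2; drug thresholds 4 to 1 (to 2 for liver
#' data) in steps of 0.2. The sweep enumerates each grid in ascending
#' order (the isa2 convention), which also fixes the tie order inside the
#' prioritization bands of [prioritize_modules()]: among equal-priority
#' threshold pairs the lowest-threshold (largest, least truncated) variant
#' of a module is encountered first. `n_seeds` random sparse starting
#' points are iterated per threshold pair (full-compendium analyses want
#' 20 000 or more; the desk-scale default is 2 000 since recovery on synthetic data
#' saturates far below that).
#'
#' @param gene_thresholds,drug_thresholds Positive threshold grids (stored
#'   sorted ascending).
#' @param n_seeds Random restarts per threshold pair.
#' @param eps,max_iter Convergence controls.
#' @param seed Integer seed; sweep randomness derives from it.
#' @param kind `"cellline"` or `"liver"` (selects the drug grid default).
#' @return Object of class `isa_config`.
#' @export
isa_config <- function(gene_thresholds = NULL, drug_thresholds = NULL,
                       n_seeds = 2000L, eps = 1e-2, max_iter = 100L,
                       seed = 1L, kind = c("cellline", "liver")) {
  kind <- match.arg(kind)
  if (is.null(gene_thresholds)) gene_thresholds <- seq(5, 2, by = -0.2)
  if (is.null(drug_thresholds)) {
    drug_thresholds <- seq(4, if (kind == "liver") 2 else 1, by = -0.2)
  }
  stopifnot(all(gene_thresholds > 0), all(drug_thresholds > 0),
            n_seeds >= 1L)
  structure(list(gene_thresholds = sort(gene_thresholds),
                 drug_thresholds = sort(drug_thresholds),
                 n_seeds = as.integer(n_seeds), eps = eps,
                 max_iter = as.integer(max_iter), seed = seed, kind = kind),
            class = "isa_config")
}

## random sparse seed matrix: each column has k genes set to +1
.seed_matrix <- function(n_genes, n_seeds, k) {
  G0 <- matrix(0, n_genes, n_seeds)
  for (j in seq_len(n_seeds)) {
    G0[sample.int(n_genes, k), j] <- 1
  }
  G0
}

#' Sweep ISA over the full threshold grid
#'
#' For every (gene threshold, drug threshold) pair, `cfg$n_seeds` random
#' sparse gene seeds (size `max(5, 1%)` of genes, signs +1) are iterated to
#' convergence; converged modules are pooled with their threshold of origin
#' and provenance, deduplicated up to a global sign flip within each pair.
#' Deterministic given `cfg$seed`.
#'
#' @param input [isa_standardize()] output.
#' @param cfg [isa_config()].
#' @return List of [isa_module()] objects.
#' @export
isa_sweep <- function(input, cfg) {
  n_genes <- length(input$genes)
  k <- max(5L, round(0.01 * n_genes))
  out <- list()
  for (tg in cfg$gene_thresholds) {
    for (td in cfg$drug_thresholds) {
      set.seed(stage_seed(cfg$seed, sprintf("sweep:%.4f:%.4f", tg, td)))
      G0 <- .seed_matrix(n_genes, cfg$n_seeds, k)
      res <- .isa_batch(input, G0, tg, td, cfg$eps, cfg$max_iter)
      mods <- .modules_from_batch(res, input, tg, td,
                                  provenance = list(n_seeds = cfg$n_seeds))
      out <- c(out, .dedupe_modules(mods))
    }
  }
  out
}

#' Filter modules by robustness against a permuted matrix
#'
#' A module's robustness score (the geometric mean of its gene- and
#' condition-side signature strengths on the real matrix) must exceed the
#' highest score obtained by running ISA at the same thresholds on a fully
#' permuted copy of the matrix. Removes modules that are no stronger than
#' what pure noise at those thresholds produces.
#'
#' @param modules Output of [isa_sweep()].
#' @param input The [isa_standardize()] input the modules came from.
#' @param cfg The [isa_config()] used for the sweep.
#' @param enabled Set `FALSE` to return `modules` unchanged.
#' @return Filtered module list.
#' @export
robustness_filter <- function(modules, input, cfg, enabled = TRUE) {
  if (!enabled || length(modules) == 0L) return(modules)
  pairs <- unique(t(vapply(modules, function(m) c(m$t_gene, m$t_drug),
                           numeric(2))))
  n_genes <- length(input$genes)
  k <- max(5L, round(0.01 * n_genes))
  null_max <- numeric(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    tg <- pairs[i, 1]; td <- pairs[i, 2]
    set.seed(stage_seed(cfg$seed, sprintf("robust:%.4f:%.4f", tg, td)))
    ## permute the raw matrix once and re-standardize, so the null input is
    ## internally consistent (its E_G/E_C describe the same scrambled data)
    Ep <- matrix(sample(input$E), nrow(input$E),
                 dimnames = dimnames(input$E))
    perm <- suppressWarnings(isa_standardize(Ep))
    G0 <- .seed_matrix(n_genes, cfg$n_seeds, k)
    res <- .isa_batch(perm, G0, tg, td, cfg$eps, cfg$max_iter)
    nm <- .modules_from_batch(res, perm, tg, td, provenance = list())
    null_max[i] <- if (length(nm))
      max(vapply(nm, function(m) m$provenance$robustness, 0)) else 0
  }
  keep <- vapply(modules, function(m) {
    i <- which(pairs[, 1] == m$t_gene & pairs[, 2] == m$t_drug)[1]
    rob <- m$provenance$robustness %||%
      .robustness_score(input, .full_gene_scores(m, input),
                        .full_drug_scores(m, input))
    rob > null_max[i]
  }, TRUE)
  modules[keep]
}

.full_gene_scores <- function(m, input) {
  g <- numeric(length(input$genes))
  g[match(names(m$gene_scores), input$genes)] <- m$gene_scores
  g
}

.full_drug_scores <- function(m, input) {
  c <- numeric(length(input$drugs))
  c[match(names(m$drug_scores), input$drugs)] <- m$drug_scores
  c
}
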