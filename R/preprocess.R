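## Preprocessing of drug-treatment expression compendia.
##
## Two branches are supported, mirroring the two kinds of source data:
## - cell-line screens arrive as batch-adjusted z-scores and go through
##   replicate selection (maximizing cross-cell-line consistency),
##   present-call filtering, and random probe collapse;
## - liver-style raw data go through quantile normalization, missing-value
##   imputation, max-variance probe collapse, regularized z-scoring against
##   control samples, replicate averaging, and ortholog restriction.

#' Select one representative replicate per drug and cell line
#'
#' When a drug was profiled multiple times in a cell line, keeps the single
#' replicate per cell line such that the mean pairwise Pearson correlation
#' of the drug's retained profiles across cell lines is maximized
#' (exhaustively when the number of replicate combinations is at most
#' `exhaustive_limit`, otherwise by greedy coordinate ascent seeded from the
#' best single pair). Drugs absent from a cell line simply contribute no
#' profile there.
#'
#' @param ds_by_cellline Named list of [expression_dataset()] objects on a
#'   shared gene space.
#' @param exhaustive_limit Combination count up to which the search is
#'   exhaustive (default 64).
#' @return The same list with exactly one profile per (drug, cell line).
#' @export
select_replicates <- function(ds_by_cellline, exhaustive_limit = 64) {
  stopifnot(length(ds_by_cellline) >= 1)
  all_drugs <- unique(unlist(lapply(ds_by_cellline,
                                    function(d) d$profile_meta$drug)))
  keep_cols <- lapply(ds_by_cellline, function(d) integer(0))
  for (drug in all_drugs) {
    cand <- lapply(ds_by_cellline, function(d)
      which(d$profile_meta$drug == drug & !d$profile_meta$control))
    cand <- cand[vapply(cand, length, 1L) > 0]
    if (length(cand) == 0L) next
    if (length(cand) == 1L || all(vapply(cand, length, 1L) == 1L)) {
      choice <- vapply(cand, `[[`, 1L, 1L)
    } else {
      profs <- lapply(names(cand), function(cl)
        ds_by_cellline[[cl]]$values[, cand[[cl]], drop = FALSE])
      names(profs) <- names(cand)
      choice <- .pick_consistent(profs, cand, exhaustive_limit)
    }
    for (cl in names(choice)) {
      keep_cols[[cl]] <- c(keep_cols[[cl]], choice[[cl]])
    }
  }
  out <- ds_by_cellline
  for (cl in names(ds_by_cellline)) {
    idx <- sort(keep_cols[[cl]])
    out[[cl]]$values <- ds_by_cellline[[cl]]$values[, idx, drop = FALSE]
    out[[cl]]$profile_meta <- ds_by_cellline[[cl]]$profile_meta[idx, ,
                                                                drop = FALSE]
    if (!is.null(out[[cl]]$present)) {
      out[[cl]]$present <- ds_by_cellline[[cl]]$present[, idx, drop = FALSE]
    }
  }
  out
}

## profs: named list (cell line -> genes x replicates matrix)
## returns named integer vector of chosen column indices (into cand)
.pick_consistent <- function(profs, cand, exhaustive_limit) {
  cls <- names(profs)
  k <- vapply(profs, ncol, 1L)
  mean_pairwise <- function(sel) {
    cols <- lapply(cls, function(cl) profs[[cl]][, sel[[cl]]])
    rs <- 0; m <- 0
    for (i in seq_along(cols)) for (j in seq_len(i - 1)) {
      rs <- rs + stats::cor(cols[[i]], cols[[j]]); m <- m + 1
    }
    if (m == 0) 0 else rs / m
  }
  if (prod(k) <= exhaustive_limit) {
    combos <- expand.grid(lapply(k, seq_len))
    scores <- apply(combos, 1, function(row)
      mean_pairwise(as.list(stats::setNames(row, cls))))
    best <- as.list(combos[which.max(scores), , drop = TRUE])
  } else {
    ## seed from the best single cross-cell-line pair, then coordinate ascent
    best <- as.list(stats::setNames(rep(1L, length(cls)), cls))
    best_pair <- -Inf
    for (i in seq_along(cls)) for (j in seq_len(i - 1)) {
      cm <- stats::cor(profs[[cls[i]]], profs[[cls[j]]])
      w <- which(cm == max(cm), arr.ind = TRUE)[1, ]
      if (max(cm) > best_pair) {
        best_pair <- max(cm)
        best[[cls[i]]] <- unname(w["row"]); best[[cls[j]]] <- unname(w["col"])
      }
    }
    repeat {
      improved <- FALSE
      for (cl in cls) {
        sc <- vapply(seq_len(k[[cl]]), function(r) {
          trial <- best; trial[[cl]] <- r; mean_pairwise(trial)
        }, 0)
        if (max(sc) > mean_pairwise(best) + 1e-12) {
          best[[cl]] <- which.max(sc); improved <- TRUE
        }
      }
      if (!improved) break
    }
  }
  stats::setNames(vapply(cls, function(cl) cand[[cl]][best[[cl]]], 1L), cls)
}

#' Filter genes by present-call ratio
#'
#' Keeps genes whose fraction of "present" calls exceeds `threshold` in at
#' least one cell line. Present calls are inputs (the call algorithm itself
#' is upstream).
#'
#' @param ds_by_cellline Named list of [expression_dataset()] objects, each
#'   carrying a logical `present` matrix.
#' @param threshold Present-call ratio that must be exceeded (default 0.10).
#' @return Character vector of retained gene ids.
#' @export
present_call_filter <- function(ds_by_cellline, threshold = 0.10) {
  mats <- lapply(ds_by_cellline, `[[`, "present")
  if (any(vapply(mats, is.null, TRUE))) {
    stop("every dataset must carry a present-call matrix")
  }
  genes <- rownames(mats[[1]])
  keep <- rep(FALSE, length(genes))
  for (m in mats) {
    keep <- keep | (rowMeans(m[genes, , drop = FALSE]) > threshold)
  }
  genes[keep]
}

#' Collapse probes to genes by seeded random choice
#'
#' One probe per gene, chosen uniformly at random with a fixed seed (avoids
#' bias towards genes represented by many probes).
#'
#' @param ds [expression_dataset()] whose `gene_meta` maps `probe` to
#'   `gene`; rownames of `values` are probe ids.
#' @param seed Integer seed.
#' @return Dataset with one row per gene (rownames = gene ids).
#' @export
collapse_probes_random <- function(ds, seed = 1) {
  gm <- ds$gene_meta
  if (is.null(gm)) stop("`gene_meta` with probe -> gene mapping required")
  set.seed(stage_seed(seed, "collapse-random"))
  genes <- unique(gm$gene)
  pick <- vapply(genes, function(g) {
    probes <- gm$probe[gm$gene == g]
    if (length(probes) == 1L) probes else sample(probes, 1L)
  }, "")
  .collapse_to(ds, pick, genes)
}

#' Collapse probes to genes by maximal variance
#'
#' Per gene, retains the probe with the highest sample variance across
#' profiles; ties are broken by lexicographically smaller probe id.
#'
#' @inheritParams collapse_probes_random
#' @return Dataset with one row per gene.
#' @export
collapse_probes_maxvar <- function(ds) {
  gm <- ds$gene_meta
  if (is.null(gm)) stop("`gene_meta` with probe -> gene mapping required")
  v <- apply(ds$values, 1, stats::var, na.rm = TRUE)
  genes <- unique(gm$gene)
  pick <- vapply(genes, function(g) {
    probes <- sort(gm$probe[gm$gene == g])
    probes[which.max(v[probes])]
  }, "")
  .collapse_to(ds, pick, genes)
}

.collapse_to <- function(ds, pick, genes) {
  out <- ds
  out$values <- ds$values[pick, , drop = FALSE]
  rownames(out$values) <- genes
  if (!is.null(ds$present)) {
    out$present <- ds$present[pick, , drop = FALSE]
    rownames(out$present) <- genes
  }
  if (!is.null(ds$untreated) && all(pick %in% rownames(ds$untreated))) {
    out$untreated <- ds$untreated[pick, , drop = FALSE]
    rownames(out$untreated) <- genes
  }
  out$gene_meta <- data.frame(probe = unname(pick), gene = genes,
                              stringsAsFactors = FALSE)
  out
}

#' Quantile-normalize expression columns
#'
#' Makes all column distributions identical (the cross-column mean order
#' statistics); ties receive the mean of their target quantiles, and
#' missing entries are excluded from rank pooling and restored as missing.
#'
#' @param values Numeric matrix with >= 2 columns (missing values allowed).
#' @return Quantile-normalized matrix of the same shape.
#' @export
quantile_normalize <- function(values) {
  if (ncol(values) < 2L) {
    warning("single column: quantile normalization is the identity")
    return(values)
  }
  out <- limma::normalizeQuantiles(values, ties = TRUE)
  dimnames(out) <- dimnames(values)
  out
}

#' Drop high-missingness rows and mean-impute the rest
#'
#' Rows with strictly more than `max_missing_fraction` missing values are
#' excluded; remaining missing entries are replaced by the row-wise mean of
#' observed values.
#'
#' @param values Numeric matrix (NAs mark missing entries).
#' @param max_missing_fraction Maximum tolerated missing fraction (strict
#'   ">" comparison; a row at exactly the threshold is kept). Default 0.10.
#' @return Imputed matrix, possibly with fewer rows.
#' @export
impute_missing <- function(values, max_missing_fraction = 0.10) {
  frac <- rowMeans(is.na(values))
  keep <- frac <= max_missing_fraction & frac < 1
  out <- values[keep, , drop = FALSE]
  na_idx <- which(is.na(out), arr.ind = TRUE)
  if (nrow(na_idx)) {
    rm <- rowMeans(out, na.rm = TRUE)
    out[na_idx] <- rm[na_idx[, 1]]
  }
  out
}

#' Regularized z-scores relative to control samples
#'
#' Converts expression values to fold changes by subtracting the per-gene
#' mean of the controls, then divides by the per-gene s.d. across all
#' samples (treated and control) regularized by the 0.1 quantile of all
#' per-gene s.d. values: `z_gi = (x_gi - mean_g(controls)) / (sd_g + q)`.
#' The additive quantile keeps z finite for near-constant genes.
#'
#' @param values Genes x treated-profiles matrix.
#' @param control_profiles Genes x control-profiles matrix (same genes).
#' @param sd_quantile Quantile of the per-gene s.d. distribution used as
#'   regularizer (default 0.10).
#' @return Matrix of z-scores, same shape as `values`.
#' @export
zscore_vs_controls <- function(values, control_profiles, sd_quantile = 0.10) {
  if (is.null(control_profiles) || ncol(control_profiles) == 0L) {
    stop("control profiles are required")
  }
  if (!identical(rownames(values), rownames(control_profiles))) {
    stop("gene spaces of `values` and `control_profiles` must match")
  }
  all_samples <- cbind(values, control_profiles)
  sd_g <- apply(all_samples, 1, stats::sd)
  q <- stats::quantile(sd_g, sd_quantile, names = FALSE)
  ctl_mean <- rowMeans(control_profiles)
  sweep(values, 1, ctl_mean, "-") / (sd_g + q)
}

#' Average replicate profiles
#'
#' Collapses profiles sharing the same (drug, dose, time) to their
#' arithmetic mean; different doses and time points of the same drug remain
#' distinct profiles (they are treated as independent experiments).
#'
#' @param ds [expression_dataset()] with replicate metadata.
#' @param group_keys Metadata columns defining a replicate group.
#' @return Dataset with one profile per group.
#' @export
average_replicates <- function(ds, group_keys = c("drug", "dose", "time")) {
  meta <- ds$profile_meta
  keys <- do.call(paste, c(meta[intersect(group_keys, names(meta))],
                           sep = "\r"))
  groups <- split(seq_len(ncol(ds$values)), keys)
  groups <- groups[order(vapply(groups, min, 1L))]  # keep first-seen order
  avg <- vapply(groups, function(idx)
    rowMeans(ds$values[, idx, drop = FALSE]), numeric(nrow(ds$values)))
  first <- vapply(groups, min, 1L)
  out <- ds
  out$values <- avg
  colnames(out$values) <- meta$profile[first]
  out$profile_meta <- meta[first, , drop = FALSE]
  out$profile_meta$replicate <- 1L
  out$present <- NULL
  out
}

#' Restrict a dataset to genes with a one-to-one ortholog
#'
#' Keeps only genes having a one-to-one partner (per `omap`) among
#' `reference_genes`, optionally translating gene ids into the reference
#' namespace.
#'
#' @param ds [expression_dataset()].
#' @param omap `data.frame` with two columns (gene ids in the dataset's
#'   namespace in column `from`, reference ids in column `to`); must be
#'   one-to-one.
#' @param reference_genes Character vector of reference-namespace gene ids.
#' @param from,to Column names of `omap` (defaults `"rat"`, `"human"`).
#' @param translate Rename retained genes to the reference namespace
#'   (default `TRUE`).
#' @return Restricted (and possibly renamed) dataset.
#' @export
restrict_to_orthologs <- function(ds, omap, reference_genes,
                                  from = "rat", to = "human",
                                  translate = TRUE) {
  if (anyDuplicated(omap[[from]]) || anyDuplicated(omap[[to]])) {
    stop("orthology map must be one-to-one")
  }
  omap <- omap[omap[[to]] %in% reference_genes, , drop = FALSE]
  keep <- rownames(ds$values) %in% omap[[from]]
  if (!any(keep)) warning("no genes retained by ortholog restriction")
  out <- ds
  out$values <- ds$values[keep, , drop = FALSE]
  if (!is.null(ds$untreated)) {
    ukeep <- rownames(ds$untreated) %in% omap[[from]]
    out$untreated <- ds$untreated[ukeep, , drop = FALSE]
  }
  if (!is.null(ds$present)) out$present <- ds$present[keep, , drop = FALSE]
  if (translate) {
    trans <- stats::setNames(omap[[to]], omap[[from]])
    rownames(out$values) <- unname(trans[rownames(out$values)])
    if (!is.null(out$untreated)) {
      rownames(out$untreated) <- unname(trans[rownames(out$untreated)])
    }
    if (!is.null(out$present)) {
      rownames(out$present) <- unname(trans[rownames(out$present)])
    }
  }
  out
}

#' Run the liver-style preprocessing branch end to end
#'
#' quantile normalization -> missing-value handling -> max-variance probe
#' collapse -> regularized z-scores against controls -> replicate averaging
#' -> ortholog restriction (optional).
#'
#' @param ds Raw-scale [expression_dataset()] with control profiles flagged
#'   in `profile_meta$control`.
#' @param omap,reference_genes Passed to [restrict_to_orthologs()]; both
#'   `NULL` to skip.
#' @param sd_quantile,max_missing_fraction Stage parameters.
#' @param ... Passed to [restrict_to_orthologs()].
#' @return z-score-scale [expression_dataset()].
#' @export
preprocess_liver <- function(ds, omap = NULL, reference_genes = NULL,
                             sd_quantile = 0.10,
                             max_missing_fraction = 0.10, ...) {
  v <- quantile_normalize(ds$values)
  v <- impute_missing(v, max_missing_fraction)
  ds$values <- v
  if (!is.null(ds$present)) {
    ds$present <- ds$present[rownames(v), , drop = FALSE]
  }
  if (!is.null(ds$gene_meta)) {
    ds$gene_meta <- ds$gene_meta[ds$gene_meta$probe %in% rownames(v), ,
                                 drop = FALSE]
    ds <- collapse_probes_maxvar(ds)
  }
  ctl <- ds$profile_meta$control
  z <- zscore_vs_controls(ds$values[, !ctl, drop = FALSE],
                          ds$values[, ctl, drop = FALSE], sd_quantile)
  ds$values <- z
  ds$profile_meta <- ds$profile_meta[!ctl, , drop = FALSE]
  ds$present <- NULL
  ds$scale <- "zscore"
  ds <- average_replicates(ds)
  if (!is.null(omap) && !is.null(reference_genes)) {
    ds <- restrict_to_orthologs(ds, omap, reference_genes, ...)
  }
  ds
}
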