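## Synthetic drug-treatment compendia with planted ground truth.
##
## The generator emulates the statistical structure of multi-cell-line drug
## perturbation screens plus a reduced-gene-space in-vivo liver dataset:
## batch-structured treatment profiles with planted gene x drug biclusters
## (optionally shared across datasets), constitutive coexpression blocks that
## are also present in untreated samples, replicate noise, missing values,
## one-to-one orthology between the "human" and "rat" gene spaces, and
## annotation catalogs / association networks with planted enrichments.

#' Describe a planted module (ground truth for recovery tests)
#'
#' @param id Identifier of the planted module.
#' @param genes Character vector of member gene ids (human namespace).
#' @param drugs Character vector of member drug ids.
#' @param effect_size Expression shift in units of the background s.d. (> 0).
#' @param sign Per-gene sign pattern (+1/-1), recycled; mixed signs model
#'   modules with inverse expression patterns.
#' @param datasets Character vector of dataset ids where the module is
#'   planted (cell-line ids and/or `"LIV"`).
#' @param constitutive If `TRUE` the module's genes are additionally
#'   coexpressed in untreated samples (a shared latent factor), i.e. it is a
#'   generic coexpression module rather than a drug response.
#' @return Object of class `planted_module`.
#' @export
planted_module <- function(id, genes, drugs, effect_size = 3, sign = 1,
                           datasets, constitutive = FALSE) {
  stopifnot(length(genes) >= 1, length(drugs) >= 1, effect_size > 0)
  sign <- rep_len(sign, length(genes))
  if (!all(sign %in% c(-1, 1))) stop("`sign` entries must be +1 or -1")
  structure(list(id = id, genes = genes, drugs = drugs,
                 effect_size = effect_size, sign = sign,
                 datasets = datasets, constitutive = constitutive),
            class = "planted_module")
}

## latent-factor loading used for constitutive coexpression; with unit noise
## it yields pairwise Pearson r of lambda^2/(lambda^2+1) ~ 0.8, comfortably
## above the 0.6 coexpression cutoff targeted by the constitutive filter
.CONSTITUTIVE_LOADING <- 2

.plant_effects <- function(values, planted, dataset_id, noise_sd,
                           gene_map = NULL) {
  for (pm in planted) {
    if (!dataset_id %in% pm$datasets) next
    genes <- pm$genes
    if (!is.null(gene_map)) genes <- unname(gene_map[genes])
    keep <- genes %in% rownames(values)
    drugs_cols <- which(attr(values, "drug_of") %in% pm$drugs)
    if (!any(keep) || length(drugs_cols) == 0L) next
    shift <- pm$sign[keep] * pm$effect_size * noise_sd
    values[genes[keep], drugs_cols] <-
      values[genes[keep], drugs_cols] + shift
  }
  values
}

.make_untreated <- function(genes, n_untreated, noise_sd, planted,
                            dataset_id, seed, gene_map = NULL) {
  set.seed(stage_seed(seed, paste0("untreated:", dataset_id)))
  u <- matrix(stats::rnorm(length(genes) * n_untreated, 0, noise_sd),
              nrow = length(genes), dimnames = list(
                genes, sprintf("%s_untr%03d", dataset_id,
                               seq_len(n_untreated))))
  for (pm in planted) {
    if (!pm$constitutive || !dataset_id %in% pm$datasets) next
    g <- pm$genes
    if (!is.null(gene_map)) g <- unname(gene_map[g])
    keep <- g %in% genes
    if (!any(keep)) next
    f <- stats::rnorm(n_untreated)
    u[g[keep], ] <- u[g[keep], ] +
      (.CONSTITUTIVE_LOADING * noise_sd) * outer(pm$sign[keep], f)
  }
  u
}

#' Generate a synthetic multi-dataset expression compendium
#'
#' Builds `n_cell_lines` "human" cell-line datasets plus (optionally) one
#' "rat liver" dataset (`"LIV"`) restricted to an orthologous subset of the
#' gene space, with planted biclusters as specified. By default profiles are
#' generated directly on the z-score scale (the post-preprocessing scale);
#' `mode = "raw"` instead emits raw-intensity profiles with batches,
#' replicates, control samples, present calls and missing values so the
#' preprocessing stage can be exercised end to end.
#'
#' @param n_genes Number of genes in the human space.
#' @param n_drugs Number of drugs per cell line.
#' @param n_cell_lines Number of cell-line datasets (`CL1`, `CL2`, ...).
#' @param planted List of [planted_module()] specs.
#' @param noise_sd Background noise s.d.
#' @param batch_count Number of batches (metadata; raw mode adds batch
#'   offsets).
#' @param replicate_count Replicates per treatment (raw mode; z-score mode
#'   emits one profile per drug as replicate selection is a preprocessing
#'   concern).
#' @param missing_rate Fraction of missing entries (raw mode only; z-score
#'   matrices are finite by contract).
#' @param n_untreated Untreated profiles per dataset.
#' @param liver If `TRUE`, generate the `"LIV"` dataset.
#' @param liver_gene_fraction Fraction of the human gene space with a
#'   one-to-one rat ortholog (default 0.4, mirroring 3618 of 8964).
#' @param liver_n_drugs Drugs profiled in the liver dataset.
#' @param liver_profiles_per_drug Dose/time profiles per liver drug (treated
#'   as independent experiments), default 4.
#' @param mode `"zscore"` (default) or `"raw"`.
#' @param seed Integer seed; all randomness derives from it.
#' @return Object of class `synthetic_compendium`: a list with `datasets`
#'   (named list of [expression_dataset()]), `orthology`
#'   (`data.frame(human, rat)`) and `truth` (the planted modules).
#' @export
generate_compendium <- function(n_genes = 1500, n_drugs = 120,
                                n_cell_lines = 3, planted = list(),
                                noise_sd = 1, batch_count = 6,
                                replicate_count = 2, missing_rate = 0,
                                n_untreated = 30, liver = TRUE,
                                liver_gene_fraction = 0.4,
                                liver_n_drugs = 40,
                                liver_profiles_per_drug = 4,
                                mode = c("zscore", "raw"), seed = 1) {
  mode <- match.arg(mode)
  genes <- sprintf("g%05d", seq_len(n_genes))
  drugs <- sprintf("d%04d", seq_len(n_drugs))
  cls <- sprintf("CL%d", seq_len(n_cell_lines))
  for (pm in planted) {
    if (!all(pm$genes %in% genes) || !all(pm$drugs %in% drugs)) {
      stop(sprintf("planted module '%s' exceeds compendium dimensions",
                   pm$id))
    }
    ## datasets not generated here are allowed (the module is simply not
    ## planted anywhere it cannot be)
  }

  ## orthology: rat space covers all LIV-planted genes plus a random fill
  liv_genes_needed <- unique(unlist(lapply(planted, function(pm)
    if ("LIV" %in% pm$datasets) pm$genes else character(0))))
  n_rat <- round(liver_gene_fraction * n_genes)
  if (length(liv_genes_needed) > n_rat) {
    stop("liver-planted genes exceed the orthologous gene space")
  }
  set.seed(stage_seed(seed, "orthology"))
  fill <- sample(setdiff(genes, liv_genes_needed),
                 n_rat - length(liv_genes_needed))
  human_orth <- sort(c(liv_genes_needed, fill))
  orthology <- data.frame(human = human_orth,
                          rat = sprintf("r%05d", seq_along(human_orth)),
                          stringsAsFactors = FALSE)
  h2r <- stats::setNames(orthology$rat, orthology$human)

  liv_drugs_needed <- unique(unlist(lapply(planted, function(pm)
    if ("LIV" %in% pm$datasets) pm$drugs else character(0))))
  if (length(liv_drugs_needed) > liver_n_drugs) {
    stop("liver-planted drugs exceed liver_n_drugs")
  }
  if (liver_n_drugs > n_drugs) {
    stop("`liver_n_drugs` cannot exceed `n_drugs`")
  }
  set.seed(stage_seed(seed, "liver-drugs"))
  liv_drugs <- sort(c(liv_drugs_needed,
                      sample(setdiff(drugs, liv_drugs_needed),
                             liver_n_drugs - length(liv_drugs_needed))))

  datasets <- list()
  for (cl in cls) {
    datasets[[cl]] <- .generate_one_dataset(
      genes, drugs, cl, "cellline", planted, noise_sd, batch_count,
      replicate_count, missing_rate, n_untreated, mode, seed,
      profiles_per_drug = 1L, gene_map = NULL)
  }
  if (liver) {
    datasets[["LIV"]] <- .generate_one_dataset(
      orthology$rat, liv_drugs, "LIV", "liver", planted, noise_sd,
      batch_count, replicate_count, missing_rate, n_untreated, mode, seed,
      profiles_per_drug = liver_profiles_per_drug, gene_map = h2r)
  }

  structure(list(datasets = datasets, orthology = orthology,
                 truth = planted,
                 params = list(n_genes = n_genes, n_drugs = n_drugs,
                               noise_sd = noise_sd, seed = seed,
                               mode = mode)),
            class = "synthetic_compendium")
}

.generate_one_dataset <- function(genes, drugs, dataset_id, kind, planted,
                                  noise_sd, batch_count, replicate_count,
                                  missing_rate, n_untreated, mode, seed,
                                  profiles_per_drug, gene_map) {
  n_rep <- if (mode == "raw") replicate_count else 1L
  grid <- expand.grid(replicate = seq_len(n_rep),
                      dose_time = seq_len(profiles_per_drug),
                      drug = drugs, stringsAsFactors = FALSE)
  doses <- c(0.1, 0.1, 1, 1)
  times <- c(6, 24, 6, 24)
  pm_meta <- data.frame(
    profile = sprintf("%s_%s_dt%d_r%d", dataset_id, grid$drug,
                      grid$dose_time, grid$replicate),
    drug = grid$drug,
    dose = doses[(grid$dose_time - 1) %% 4 + 1],
    time = times[(grid$dose_time - 1) %% 4 + 1],
    replicate = grid$replicate,
    control = FALSE,
    stringsAsFactors = FALSE)
  pm_meta$batch <- rep_len(seq_len(batch_count), nrow(pm_meta))

  set.seed(stage_seed(seed, paste0("treated:", dataset_id)))
  np <- nrow(pm_meta)
  values <- matrix(stats::rnorm(length(genes) * np, 0, noise_sd),
                   nrow = length(genes),
                   dimnames = list(genes, pm_meta$profile))
  attr(values, "drug_of") <- pm_meta$drug
  values <- .plant_effects(values, planted, dataset_id, noise_sd, gene_map)
  attr(values, "drug_of") <- NULL

  untreated <- .make_untreated(genes, n_untreated, noise_sd, planted,
                               dataset_id, seed, gene_map)

  if (mode == "raw") {
    set.seed(stage_seed(seed, paste0("raw:", dataset_id)))
    baseline <- stats::rnorm(length(genes), 8, 1.5)
    batch_off <- stats::rnorm(batch_count, 0, 0.2)
    n_ctl <- max(6L, 2L * batch_count)
    ctl_meta <- data.frame(
      profile = sprintf("%s_ctl%03d", dataset_id, seq_len(n_ctl)),
      drug = "control", dose = 0, time = 0, replicate = 1L,
      control = TRUE, batch = rep_len(seq_len(batch_count), n_ctl),
      stringsAsFactors = FALSE)
    ctl <- matrix(stats::rnorm(length(genes) * n_ctl, 0, noise_sd),
                  nrow = length(genes),
                  dimnames = list(genes, ctl_meta$profile))
    values <- baseline + sweep(values, 2, batch_off[pm_meta$batch], "+")
    ctl <- baseline + sweep(ctl, 2, batch_off[ctl_meta$batch], "+")
    values <- cbind(values, ctl)
    pm_meta <- rbind(pm_meta, ctl_meta)
    if (missing_rate > 0) {
      miss <- stats::runif(length(values)) < missing_rate
      values[miss] <- NA_real_
    }
    present <- matrix(stats::runif(length(values)) < 0.6,
                      nrow = nrow(values), dimnames = dimnames(values))
    return(expression_dataset(values, pm_meta, untreated = untreated,
                              present = present, scale = "raw",
                              dataset_id = dataset_id, kind = kind))
  }

  set.seed(stage_seed(seed, paste0("present:", dataset_id)))
  present <- matrix(stats::runif(length(values)) < 0.6,
                    nrow = nrow(values), dimnames = dimnames(values))
  expression_dataset(values, pm_meta, untreated = untreated,
                     present = present, scale = "zscore",
                     dataset_id = dataset_id, kind = kind)
}

#' @export
print.synthetic_compendium <- function(x, ...) {
  cat(sprintf("<synthetic_compendium> %d datasets, %d planted modules, seed %s\n",
              length(x$datasets), length(x$truth), x$params$seed))
  for (d in x$datasets) print(d)
  invisible(x)
}

#' Generate a drug-annotation catalog with planted enrichments
#'
#' Emulates target / ATC-class / side-effect / chemical-fragment catalogs:
#' each term gets a random background drug membership, and each planted
#' enrichment additionally assigns its term to at least `fraction` of the
#' given drug set. Fingerprints are random bit-vectors; drug sets flagged
#' `share_fingerprint` receive a common planted sub-pattern (so they are
#' mutually Tanimoto-similar).
#'
#' @param drugs Character vector: the drug universe.
#' @param categories Named integer vector: number of terms per category.
#' @param planted_enrichments List of lists with fields `drugs`, `category`,
#'   `term`, `fraction` (in (0, 1]) and optional `share_fingerprint`.
#' @param fingerprint_bits Fingerprint length (default 1024, the standard
#'   hashed-fingerprint length).
#' @param background_rate Probability that a random drug carries a term.
#' @param seed Integer seed.
#' @return Object of class `annotation_catalog`: list with `categories`
#'   (category -> term -> drug vector), `fingerprints` (logical drugs x bits
#'   matrix) and `drugs`.
#' @export
generate_annotations <- function(drugs,
                                 categories = c(target = 40, atc = 20,
                                                side_effect = 60,
                                                fragment = 80),
                                 planted_enrichments = list(),
                                 fingerprint_bits = 1024,
                                 background_rate = 0.05, seed = 1) {
  for (pe in planted_enrichments) {
    if (is.null(pe$fraction) || pe$fraction <= 0 || pe$fraction > 1) {
      stop("planted enrichment fractions must lie in (0, 1]")
    }
    if (!pe$category %in% names(categories)) {
      stop(sprintf("unknown category '%s' in planted enrichment",
                   pe$category))
    }
    if (!all(pe$drugs %in% drugs)) {
      stop("planted enrichment references drugs outside the universe")
    }
  }
  set.seed(stage_seed(seed, "annotations"))
  cats <- list()
  for (cat_name in names(categories)) {
    n_terms <- categories[[cat_name]]
    terms <- sprintf("%s_T%03d", cat_name, seq_len(n_terms))
    cats[[cat_name]] <- stats::setNames(lapply(terms, function(t) {
      drugs[stats::runif(length(drugs)) < background_rate]
    }), terms)
  }
  for (pe in planted_enrichments) {
    term <- pe$term
    if (!term %in% names(cats[[pe$category]])) {
      cats[[pe$category]][[term]] <- character(0)
    }
    k <- ceiling(pe$fraction * length(pe$drugs))
    members <- if (k >= length(pe$drugs)) pe$drugs else
      sample(pe$drugs, k)
    cats[[pe$category]][[term]] <-
      sort(unique(c(cats[[pe$category]][[term]], members)))
  }
  set.seed(stage_seed(seed, "fingerprints"))
  fp <- matrix(stats::runif(length(drugs) * fingerprint_bits) < 0.1,
               nrow = length(drugs), dimnames = list(drugs, NULL))
  for (pe in planted_enrichments) {
    if (isTRUE(pe$share_fingerprint)) {
      pattern <- sample(fingerprint_bits, max(64L, fingerprint_bits %/% 10))
      fp[pe$drugs, pattern] <- TRUE
    }
  }
  structure(list(categories = cats, fingerprints = fp, drugs = drugs),
            class = "annotation_catalog")
}

#' Generate a scored gene-gene association network
#'
#' Erdős–Rényi background edges plus denser edges among the gene pairs of
#' planted modules; undirected, self-loop free, scores in (0, 1], each edge
#' labeled with an evidence channel.
#'
#' @param genes Character vector of gene ids.
#' @param within_module_density Edge probability within planted modules.
#' @param background_density Background edge probability.
#' @param planted List of [planted_module()] specs (only gene sets used).
#' @param channels Evidence channels sampled per edge.
#' @param coexpression_density Extra edges labeled `"coexpression"` (the
#'   channel the coherence stage excludes), default 0.
#' @param seed Integer seed.
#' @return `data.frame` with columns `gene_a`, `gene_b`, `score`, `channel`.
#' @export
generate_network <- function(genes, within_module_density = 0.3,
                             background_density = 0.01, planted = list(),
                             channels = c("experimental", "database"),
                             coexpression_density = 0, seed = 1) {
  stopifnot(within_module_density >= 0, within_module_density <= 1,
            background_density >= 0, background_density <= 1)
  n <- length(genes)
  set.seed(stage_seed(seed, "network"))
  ia <- rep.int(seq_len(n - 1), (n - 1):1)
  ib <- unlist(lapply(seq_len(n - 1), function(i) (i + 1):n),
               use.names = FALSE)
  draw_edges <- function(p, idx_a, idx_b) {
    keep <- stats::runif(length(idx_a)) < p
    cbind(idx_a[keep], idx_b[keep])
  }
  bg <- draw_edges(background_density, ia, ib)
  co <- if (coexpression_density > 0)
    draw_edges(coexpression_density, ia, ib) else
    matrix(integer(0), ncol = 2)
  within <- matrix(integer(0), ncol = 2)
  for (pm in planted) {
    gi <- match(intersect(pm$genes, genes), genes)
    if (length(gi) < 2) next
    pa <- utils::combn(sort(gi), 2)
    keep <- stats::runif(ncol(pa)) < within_module_density
    within <- rbind(within, t(pa[, keep, drop = FALSE]))
  }
  main <- unique(rbind(bg, within))
  edges <- data.frame(
    gene_a = genes[main[, 1]], gene_b = genes[main[, 2]],
    score = stats::runif(nrow(main), 0.41, 1),
    channel = if (nrow(main)) sample(channels, nrow(main), replace = TRUE)
              else character(0),
    stringsAsFactors = FALSE)
  if (nrow(co)) {
    co <- co[!duplicated(co), , drop = FALSE]
    edges <- rbind(edges, data.frame(
      gene_a = genes[co[, 1]], gene_b = genes[co[, 2]],
      score = stats::runif(nrow(co), 0.41, 1),
      channel = "coexpression", stringsAsFactors = FALSE))
  }
  edges
}
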