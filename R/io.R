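## Plain-text serialization: TSV for matrices, module catalogs, links and
## networks; JSON for CODIMs and run manifests. Writers are deterministic
## (fixed column order, fixed numeric formatting) so that same-seed runs
## are byte-identical.

.fmt_num <- function(x) sprintf("%.10g", x)

#' Write / read a genes x profiles matrix as TSV
#'
#' Genes as rows (first column `gene`), profiles as columns.
#'
#' @param mat Numeric matrix with dimnames.
#' @param path File path.
#' @return `write_matrix_tsv`: the path, invisibly. `read_matrix_tsv`: the
#'   matrix.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(gene = rownames(mat),
                   apply(mat, 2, .fmt_num),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}

.pack_scores <- function(scores) {
  paste(names(scores), .fmt_num(scores), sep = ":", collapse = ";")
}

.unpack_scores <- function(s) {
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  stats::setNames(vapply(parts, function(p) as.numeric(p[2]), 0),
                  vapply(parts, `[[`, "", 1))
}

#' Write / read a module catalog as TSV
#'
#' One row per module: id, dataset, thresholds, sizes, and the gene / drug
#' members with their signed scores packed as `id:score;id:score;...`.
#' The universes are kept in a `#` header line so catalogs round-trip.
#'
#' @param catalog A [module_catalog()].
#' @param path File path.
#' @return `write_modules_tsv`: the path, invisibly; `read_modules_tsv`:
#'   a [module_catalog()].
#' @export
write_modules_tsv <- function(catalog, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dataset=%s kind=%s", catalog$dataset_id,
                     catalog$kind), con)
  writeLines(paste0("# universe_genes=",
                    paste(catalog$universe_genes, collapse = ",")), con)
  writeLines(paste0("# universe_drugs=",
                    paste(catalog$universe_drugs, collapse = ",")), con)
  rows <- vapply(catalog$modules, function(m) {
    paste(m$id, m$dataset, .fmt_num(m$t_gene), .fmt_num(m$t_drug),
          length(m$gene_scores), length(m$drug_scores),
          .pack_scores(m$gene_scores), .pack_scores(m$drug_scores),
          sep = "\t")
  }, "")
  writeLines(paste("id", "dataset", "t_gene", "t_drug", "n_genes",
                   "n_drugs", "gene_scores", "drug_scores", sep = "\t"),
             con)
  writeLines(rows, con)
  invisible(path)
}

#' @rdname write_modules_tsv
#' @export
read_modules_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  meta1 <- sub("^# dataset=(\\S+) kind=(\\S+)$", "\\1\r\\2", hdr[1])
  ds <- strsplit(meta1, "\r")[[1]]
  ug <- strsplit(sub("^# universe_genes=", "", hdr[2]), ",")[[1]]
  ud <- strsplit(sub("^# universe_drugs=", "", hdr[3]), ",")[[1]]
  body <- lines[!startsWith(lines, "#")]
  mods <- list()
  if (length(body) > 1) {
    for (ln in body[-1]) {
      f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      mods[[length(mods) + 1L]] <- isa_module(
        gene_scores = .unpack_scores(f[7]),
        drug_scores = .unpack_scores(f[8]),
        t_gene = as.numeric(f[3]), t_drug = as.numeric(f[4]),
        dataset = f[2], id = f[1])
    }
  }
  module_catalog(mods, dataset_id = ds[1], universe_genes = ug,
                 universe_drugs = ud, kind = ds[2])
}

#' Write module links as TSV
#' @param links [gene_overlap_links()] output (possibly augmented).
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_links_tsv <- function(links, path) {
  df <- as.data.frame(links)
  num <- vapply(df, is.numeric, TRUE) &
    !vapply(df, is.integer, TRUE)
  df[num] <- lapply(df[num], .fmt_num)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write CODIMs as JSON
#' @param codims List of `codim` objects from [build_codims()].
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_codims_json <- function(codims, path) {
  x <- lapply(codims, function(cd) {
    list(id = cd$id, members = cd$members, genes = cd$genes,
         drugs = cd$drugs, liver_conserved = cd$liver_conserved)
  })
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write / read a scored edge list as TSV
#' @param edges `data.frame` with `gene_a`, `gene_b`, `score` and optional
#'   `channel`.
#' @param path File path.
#' @return `write_network_tsv`: the path, invisibly; `read_network_tsv`:
#'   the `data.frame`.
#' @export
write_network_tsv <- function(edges, path) {
  edges$score <- .fmt_num(edges$score)
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_network_tsv
#' @export
read_network_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
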