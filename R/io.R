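# Readers and writers for the on-disk formats: MatrixMarket triplets
# with ID sidecar files for sparse matrices, dense TSV for toy inputs,
# and plain TSV/JSON for tables and results.

read_tsv_checked <- function(path, required, what = "table") {
  if (!file.exists(path)) stop("missing file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("malformed %s '%s': missing column(s) %s",
                 what, path, paste(missing, collapse = ", ")))
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read an expression matrix
#'
#' Sparse matrices go to a MatrixMarket triplet `<prefix>.mtx` with
#' one-column sidecars `<prefix>.genes.tsv` and `<prefix>.cells.tsv`;
#' dense matrices to a TSV whose header row holds the cell IDs and whose
#' first column (`gene_id`) holds the gene IDs.
#'
#' @param x An [expression_matrix()].
#' @param prefix Output path prefix (sparse) or `.tsv` path (dense).
#' @param sparse Write the MTX triplet (default if `values` is a
#'   `Matrix`), else dense TSV.
#' @return The main file path, invisibly.
#' @export
write_expression <- function(x, prefix, sparse = methods::is(x$values, "Matrix")) {
  if (sparse) {
    path <- if (endsWith(prefix, ".mtx")) prefix else paste0(prefix, ".mtx")
    base <- sub("\\.mtx$", "", path)
    Matrix::writeMM(methods::as(methods::as(x$values, "generalMatrix"), "CsparseMatrix"), path)
    writeLines(x$gene_ids, paste0(base, ".genes.tsv"))
    writeLines(x$cell_ids, paste0(base, ".cells.tsv"))
  } else {
    path <- if (endsWith(prefix, ".tsv")) prefix else paste0(prefix, ".tsv")
    df <- data.frame(gene_id = x$gene_ids, as.matrix(x$values), check.names = FALSE)
    colnames(df) <- c("gene_id", x$cell_ids)
    write_tsv(df, path)
  }
  invisible(path)
}

#' @rdname write_expression
#' @param path `.mtx` or `.tsv` path written by [write_expression()].
#' @param normalized Flag recorded on the returned object.
#' @export
read_expression <- function(path, normalized = FALSE) {
  if (!file.exists(path)) stop("missing file: ", path)
  if (endsWith(path, ".mtx")) {
    base <- sub("\\.mtx$", "", path)
    values <- methods::as(Matrix::readMM(path), "CsparseMatrix")
    gene_ids <- readLines(paste0(base, ".genes.tsv"))
    cell_ids <- readLines(paste0(base, ".cells.tsv"))
    expression_matrix(values, gene_ids, cell_ids, normalized = normalized)
  } else {
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (names(df)[1] != "gene_id")
      stop("malformed dense matrix '", path, "': first column must be gene_id")
    values <- as.matrix(df[, -1, drop = FALSE])
    expression_matrix(values, df$gene_id, colnames(df)[-1], normalized = normalized)
  }
}

#' Write / read an APA (polyA-site) matrix
#'
#' The matrix itself uses the same MTX-or-dense convention as
#' [write_expression()]; per-site metadata goes to
#' `<prefix>.sites.tsv` with columns `gene_id`, `site_id`, `cleavage_pos`.
#'
#' @param apa An [apa_matrix()].
#' @param prefix Output path prefix.
#' @param sparse Write MTX (default if sparse storage).
#' @return The matrix path, invisibly.
#' @export
write_apa <- function(apa, prefix, sparse = methods::is(apa$values, "Matrix")) {
  prefix <- sub("\\.mtx$|\\.tsv$", "", prefix)
  write_tsv(apa$site_meta, paste0(prefix, ".sites.tsv"))
  if (sparse) {
    Matrix::writeMM(methods::as(methods::as(apa$values, "generalMatrix"), "CsparseMatrix"),
                    paste0(prefix, ".mtx"))
    writeLines(apa$cell_ids, paste0(prefix, ".cells.tsv"))
    invisible(paste0(prefix, ".mtx"))
  } else {
    df <- data.frame(site_key = rownames(apa$values), as.matrix(apa$values),
                     check.names = FALSE)
    colnames(df) <- c("site_key", apa$cell_ids)
    write_tsv(df, paste0(prefix, ".tsv"))
    invisible(paste0(prefix, ".tsv"))
  }
}

#' @rdname write_apa
#' @param path `.mtx` or `.tsv` matrix path written by [write_apa()].
#' @export
read_apa <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  prefix <- sub("\\.mtx$|\\.tsv$", "", path)
  site_meta <- read_tsv_checked(paste0(prefix, ".sites.tsv"),
                                c("gene_id", "site_id", "cleavage_pos"),
                                "APA site metadata")
  if (endsWith(path, ".mtx")) {
    values <- methods::as(Matrix::readMM(path), "CsparseMatrix")
    cell_ids <- readLines(paste0(prefix, ".cells.tsv"))
  } else {
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    values <- as.matrix(df[, -1, drop = FALSE])
    cell_ids <- colnames(df)[-1]
  }
  apa_matrix(values, site_meta, cell_ids)
}

#' Write / read a cell-to-cluster assignment TSV
#' @param clusters A [cluster_assignment()].
#' @param path TSV path (columns `cell_id`, `cluster`).
#' @export
write_clusters <- function(clusters, path) write_tsv(clusters, path)

#' @rdname write_clusters
#' @export
read_clusters <- function(path) {
  cluster_assignment(read_tsv_checked(path, c("cell_id", "cluster"), "cluster table"))
}

#' Write / read a binding-site TSV
#'
#' BED-like column order `gene_id`, `start`, `end`, `family_id`;
#' coordinates 0-based half-open relative to the 3'UTR start.
#'
#' @param sites A [binding_site_table()].
#' @param path TSV path.
#' @export
write_binding_sites <- function(sites, path) {
  write_tsv(sites[, c("gene_id", "start", "end", "family_id")], path)
}

#' @rdname write_binding_sites
#' @export
read_binding_sites <- function(path) {
  binding_site_table(read_tsv_checked(path, c("gene_id", "start", "end", "family_id"),
                                      "binding-site table"))
}

#' Write / read a directed interaction TSV
#' @param interactions An [interaction_table()].
#' @param path TSV path (columns `source_id`, `source_type`, `target_id`,
#'   `target_type`).
#' @export
write_interactions <- function(interactions, path) write_tsv(interactions, path)

#' @rdname write_interactions
#' @export
read_interactions <- function(path) {
  interaction_table(read_tsv_checked(
    path, c("source_id", "source_type", "target_id", "target_type"),
    "interaction table"))
}

#' Write / read a cells x dimensions embedding TSV
#' @param embedding Numeric matrix, cells in rows (row names = cell IDs).
#' @param path TSV path; first column `cell_id`.
#' @export
write_embedding <- function(embedding, path) {
  df <- data.frame(cell_id = rownames(embedding), embedding, check.names = FALSE)
  write_tsv(df, path)
}

#' @rdname write_embedding
#' @export
read_embedding <- function(path) {
  df <- read_tsv_checked(path, "cell_id", "embedding")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$cell_id
  m
}

#' Load and cross-validate a full input bundle
#'
#' @param paths Named list of file paths: `expression`, `apa`,
#'   `clusters`, `binding_sites`, `interactions` (one or more paths),
#'   and optionally `embedding`.
#' @param config A [pipeline_config()] (currently only carried through).
#' @return A list with elements `expr`, `apa`, `clusters`, `sites`,
#'   `interactions` (single merged [interaction_table()]), `embedding`
#'   (or `NULL`).
#' @export
load_dataset <- function(paths, config = pipeline_config()) {
  req <- c("expression", "apa", "clusters", "binding_sites", "interactions")
  missing <- setdiff(req, names(paths))
  if (length(missing)) stop("paths missing entries: ", paste(missing, collapse = ", "))
  expr <- read_expression(paths$expression)
  apa <- read_apa(paths$apa)
  clusters <- read_clusters(paths$clusters)
  sites <- read_binding_sites(paths$binding_sites)
  tabs <- lapply(paths$interactions, read_interactions)
  interactions <- interaction_table(do.call(rbind, tabs))
  if (!identical(expr$cell_ids, apa$cell_ids))
    stop("cell IDs of expression and APA matrices differ in content or order")
  unknown <- setdiff(clusters$cell_id, expr$cell_ids)
  if (length(unknown))
    stop("cluster table '", paths$clusters, "' references unknown cell(s): ",
         paste(utils::head(unknown, 5), collapse = ", "))
  unlabeled <- setdiff(expr$cell_ids, clusters$cell_id)
  if (length(unlabeled))
    stop("cells without a cluster label: ",
         paste(utils::head(unlabeled, 5), collapse = ", "))
  embedding <- NULL
  if (!is.null(paths$embedding)) {
    embedding <- read_embedding(paths$embedding)
    if (!all(expr$cell_ids %in% rownames(embedding)))
      stop("embedding is missing coordinates for some cells")
    embedding <- embedding[expr$cell_ids, , drop = FALSE]
  }
  list(expr = expr, apa = apa, clusters = clusters, sites = sites,
       interactions = interactions, embedding = embedding)
}

#' Write / read avoidance test results
#'
#' One row per (cluster, family), sorted by cluster then family, with
#' columns `cluster`, `family`, `lost`, `retained`, `statistic`, `p`,
#' `p_adj`.
#'
#' @param results An avoidance result data frame
#'   (see [avoidance_permutation_test()]).
#' @param out_dir Output directory.
#' @return The TSV path, invisibly.
#' @export
write_avoidance_results <- function(results, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cols <- c("cluster", "family", "lost", "retained", "statistic", "p", "p_adj")
  if (nrow(results) == 0) {
    df <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
  } else {
    df <- as.data.frame(results)[, cols]
    df <- df[order(df$cluster, df$family), ]
  }
  write_tsv(df, file.path(out_dir, "avoidance_results.tsv"))
}

#' @rdname write_avoidance_results
#' @param path TSV written by [write_avoidance_results()].
#' @export
read_avoidance_results <- function(path) {
  read_tsv_checked(path, c("cluster", "family", "lost", "retained",
                           "statistic", "p", "p_adj"), "avoidance results")
}

#' Write network (SFFL / MFFL) results
#'
#' SFFLs go to `sffl_results.tsv` (columns `cluster`, `family`, `tf`,
#' `gene`, `class`, `score`, `p`, `p_adj`, `mirna_sites_lost_flag`);
#' MFFLs to `mffl_results.json`, one record per module with its center
#' node, center type, member SFFL triples and the merged node set.
#'
#' @param sffls Scored SFFL data frame (see [sffl_permutation_test()]).
#' @param mffls MFFL list (see [merge_mffls()]).
#' @param out_dir Output directory.
#' @return Named character vector of the two file paths, invisibly.
#' @export
write_network_results <- function(sffls, mffls, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cols <- c("cluster", "family", "tf", "gene", "class", "score", "p", "p_adj",
            "mirna_sites_lost_flag")
  df <- as.data.frame(sffls)
  if (!"family" %in% names(df) && "mirna" %in% names(df)) df$family <- df$mirna
  for (cl in setdiff(cols, names(df))) df[[cl]] <- rep(NA, nrow(df))
  df <- df[, cols]
  if (nrow(df)) df <- df[order(df$cluster, df$family, df$tf, df$gene), ]
  tsv <- write_tsv(df, file.path(out_dir, "sffl_results.tsv"))
  json_path <- file.path(out_dir, "mffl_results.json")
  records <- lapply(mffls, function(m) {
    list(cluster = m$cluster, center = m$center, center_type = m$center_type,
         members = lapply(m$members, function(mem)
           mem[c("mirna", "tf", "gene", "class")]),
         nodes = as.list(m$nodes))
  })
  jsonlite::write_json(records, json_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(sffl = tsv, mffl = json_path))
}

#' @rdname write_network_results
#' @param path JSON written by [write_network_results()].
#' @export
read_mffl_results <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(recs, function(r) {
    list(cluster = r$cluster, center = r$center, center_type = r$center_type,
         members = lapply(r$members, function(m)
           lapply(m, as.character)),
         nodes = vapply(r$nodes, as.character, character(1)))
  })
}
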