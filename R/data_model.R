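# Domain types shared by all stages.  All containers are validated S3
# objects: plain matrices/data frames with a class attribute, in the
# style of limma's list-based containers.

#' Construct a genes x cells expression matrix
#'
#' @param values Non-negative numeric matrix (base or `Matrix` sparse),
#'   genes in rows, cells in columns.
#' @param gene_ids,cell_ids Unique row/column identifiers; default to the
#'   dimnames of `values`.
#' @param normalized Logical flag: `FALSE` for raw counts, `TRUE` for
#'   log-normalized values.
#' @return An `ExpressionMatrix` object (list with `values`, `gene_ids`,
#'   `cell_ids`, `normalized`).
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              cell_ids = colnames(values), normalized = FALSE) {
  if (is.null(gene_ids) || is.null(cell_ids))
    stop("gene_ids and cell_ids are required (or set dimnames on 'values')")
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (nrow(values) != length(gene_ids) || ncol(values) != length(cell_ids))
    stop("matrix dimensions do not match the ID list lengths")
  if (anyDuplicated(gene_ids)) stop("duplicate gene_ids: ",
    paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(cell_ids)) stop("duplicate cell_ids: ",
    paste(unique(cell_ids[duplicated(cell_ids)]), collapse = ", "))
  if (min(values) < 0) stop("expression values must be non-negative")
  dimnames(values) <- list(gene_ids, cell_ids)
  structure(list(values = values, gene_ids = gene_ids, cell_ids = cell_ids,
                 normalized = isTRUE(normalized)),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d cells (%s)\n",
              length(x$gene_ids), length(x$cell_ids),
              if (x$normalized) "log-normalized" else "raw counts"))
  invisible(x)
}

#' Construct a polyA-site x cells APA expression matrix
#'
#' Rows are individual polyadenylation-site isoforms.  `cleavage_pos` is
#' the number of 3'UTR bases retained by the isoform, in mRNA-sense
#' 3'UTR-relative coordinates, so a binding site `[start, end)` is
#' physically present on the isoform iff `end <= cleavage_pos`.
#'
#' @param values Non-negative matrix, polyA sites x cells.
#' @param site_meta Data frame with one row per matrix row and columns
#'   `gene_id`, `site_id`, `cleavage_pos` (integer >= 0).
#' @param cell_ids Unique cell identifiers; when the matrix is paired
#'   with an [expression_matrix()], content and order must match.
#' @return An `ApaMatrix` object.
#' @export
apa_matrix <- function(values, site_meta, cell_ids = colnames(values)) {
  stopifnot(is.data.frame(site_meta))
  req <- c("gene_id", "site_id", "cleavage_pos")
  if (!all(req %in% names(site_meta)))
    stop("site_meta needs columns: ", paste(req, collapse = ", "))
  if (nrow(values) != nrow(site_meta))
    stop("site_meta rows must match matrix rows")
  cell_ids <- as.character(cell_ids)
  if (ncol(values) != length(cell_ids)) stop("cell_ids length mismatch")
  if (anyDuplicated(cell_ids)) stop("duplicate cell_ids")
  if (min(values) < 0) stop("APA values must be non-negative")
  site_meta$gene_id <- as.character(site_meta$gene_id)
  site_meta$site_id <- as.character(site_meta$site_id)
  site_meta$cleavage_pos <- as.integer(site_meta$cleavage_pos)
  if (any(site_meta$cleavage_pos < 0)) stop("cleavage_pos must be >= 0")
  key <- paste(site_meta$gene_id, site_meta$site_id, sep = ":")
  if (anyDuplicated(key)) stop("duplicate (gene_id, site_id) pairs: ",
    paste(unique(key[duplicated(key)]), collapse = ", "))
  dup_pos <- stats::aggregate(cleavage_pos ~ gene_id, site_meta,
                              function(v) anyDuplicated(v) > 0)
  if (any(dup_pos$cleavage_pos))
    stop("duplicate cleavage_pos within gene(s): ",
         paste(dup_pos$gene_id[dup_pos$cleavage_pos], collapse = ", "))
  rownames(site_meta) <- key
  dimnames(values) <- list(key, cell_ids)
  structure(list(values = values, site_meta = site_meta, cell_ids = cell_ids),
            class = "ApaMatrix")
}

#' @export
print.ApaMatrix <- function(x, ...) {
  cat(sprintf("ApaMatrix: %d polyA sites in %d genes x %d cells\n",
              nrow(x$site_meta), length(unique(x$site_meta$gene_id)),
              length(x$cell_ids)))
  invisible(x)
}

#' Genes with more than one annotated polyA site
#' @param apa An [apa_matrix()].
#' @return Character vector of gene IDs.
#' @export
multi_apa_genes <- function(apa) {
  tab <- table(apa$site_meta$gene_id)
  names(tab)[tab >= 2]
}

#' Construct a cell-to-cluster assignment
#'
#' @param df Data frame with columns `cell_id` and `cluster`, or a named
#'   character vector (names = cell IDs).
#' @return A `ClusterAssignment` data frame.
#' @export
cluster_assignment <- function(df) {
  if (is.vector(df) && !is.null(names(df)))
    df <- data.frame(cell_id = names(df), cluster = unname(df))
  stopifnot(all(c("cell_id", "cluster") %in% names(df)))
  df$cell_id <- as.character(df$cell_id)
  df$cluster <- as.character(df$cluster)
  if (anyDuplicated(df$cell_id))
    stop("cells assigned more than once: ",
         paste(unique(df$cell_id[duplicated(df$cell_id)]), collapse = ", "))
  structure(df[, c("cell_id", "cluster")], class = c("ClusterAssignment", "data.frame"))
}

#' Cells belonging to one cluster
#' @param clusters A [cluster_assignment()].
#' @param label Cluster label.
#' @return Character vector of cell IDs.
#' @export
cells_in_cluster <- function(clusters, label) {
  if (!label %in% clusters$cluster) stop("unknown cluster label: ", label)
  clusters$cell_id[clusters$cluster == label]
}

#' Construct a microRNA-family binding-site table
#'
#' Coordinates are 0-based half-open, relative to the gene's 3'UTR start
#' on the mRNA sense strand.
#'
#' @param df Data frame with columns `family_id`, `gene_id`, `start`, `end`.
#' @return A `BindingSiteTable` data frame.
#' @export
binding_site_table <- function(df) {
  req <- c("family_id", "gene_id", "start", "end")
  if (!all(req %in% names(df)))
    stop("binding-site table needs columns: ", paste(req, collapse = ", "))
  df <- df[, req]
  df$family_id <- as.character(df$family_id)
  df$gene_id <- as.character(df$gene_id)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (any(is.na(df$start) | is.na(df$end))) stop("non-integer site coordinates")
  bad <- df$start < 0 | df$end <= df$start
  if (any(bad))
    stop("invalid site intervals (need 0 <= start < end) at rows: ",
         paste(utils::head(which(bad), 5), collapse = ", "))
  df <- unique(df)
  rownames(df) <- NULL
  structure(df, class = c("BindingSiteTable", "data.frame"))
}

ALLOWED_EDGE_KINDS <- c("miRNA->TF", "miRNA->gene", "TF->gene", "TF->miRNA")

#' Construct a directed regulatory interaction table
#'
#' Exactly four edge kinds are allowed: miRNA->TF, miRNA->gene, TF->gene
#' and TF->miRNA.  Rows are deduplicated; self-edges are rejected.
#'
#' @param df Data frame with columns `source_id`, `source_type`,
#'   `target_id`, `target_type` (types in `miRNA`, `TF`, `gene`).
#' @return An `InteractionTable` data frame.
#' @export
interaction_table <- function(df) {
  req <- c("source_id", "source_type", "target_id", "target_type")
  if (!all(req %in% names(df)))
    stop("interaction table needs columns: ", paste(req, collapse = ", "))
  df <- df[, req]
  for (cl in req) df[[cl]] <- as.character(df[[cl]])
  kind <- paste0(df$source_type, "->", df$target_type)
  bad <- !(kind %in% ALLOWED_EDGE_KINDS)
  if (any(bad))
    stop("disallowed interaction kind(s): ",
         paste(unique(kind[bad]), collapse = ", "))
  if (any(df$source_id == df$target_id))
    stop("self-edges are not allowed: ",
         paste(unique(df$source_id[df$source_id == df$target_id]), collapse = ", "))
  df <- unique(df)
  rownames(df) <- NULL
  structure(df, class = c("InteractionTable", "data.frame"))
}

#' Pipeline configuration
#'
#' Houses the analysis constants: number of label permutations, the
#' significance threshold for BH-adjusted p-values, and the per-cluster
#' expression prevalence filter.
#'
#' @param n_permutations Number of permutations `B` (default 10000).
#' @param alpha BH significance threshold (default 0.05).
#' @param min_expr_frac Minimum fraction of a cluster's cells in which a
#'   gene must be detected (value > 0) to count as expressed (default 0.10).
#' @param count_mode `"weighted"` (expression-mass) or `"binary"`
#'   (used-isoform counting) for the lost/retained tallies.
#' @param smooth_permutation_p Use the add-one-smoothed permutation
#'   p-value `(1 + #\{null >= obs\}) / (B + 1)` (default).  When `FALSE`
#'   the literal counting estimators are used instead (strictly-greater
#'   count / B for avoidance; greater-or-equal count / B for SFFLs).
#' @param binary_used_frac Prevalence at which an isoform counts as
#'   "used" in binary mode (default 0.05).
#' @param signed_edges Use signed Fisher-z edge scores instead of the
#'   default absolute value.
#' @param scale_factor Library-size target for [log_normalize()].
#' @param seed Root RNG seed.
#' @param out_dir Output directory for pipeline runs.
#' @param paths Named list of input file paths (see [load_dataset()]).
#' @param simulate Optional list of [synthetic_config()] overrides; when
#'   present the pipeline generates its inputs.
#' @param centroid_ref Optional reference cluster label for
#'   [centroid_distances()].
#' @return A `PipelineConfig` list.
#' @export
pipeline_config <- function(n_permutations = 10000L, alpha = 0.05,
                            min_expr_frac = 0.10, count_mode = c("weighted", "binary"),
                            smooth_permutation_p = TRUE, binary_used_frac = 0.05,
                            signed_edges = FALSE, scale_factor = 1e4,
                            seed = 1L, out_dir = NULL, paths = NULL,
                            simulate = NULL, centroid_ref = NULL) {
  count_mode <- match.arg(count_mode)
  cfg <- list(n_permutations = as.integer(n_permutations), alpha = alpha,
              min_expr_frac = min_expr_frac, count_mode = count_mode,
              smooth_permutation_p = isTRUE(smooth_permutation_p),
              binary_used_frac = binary_used_frac,
              signed_edges = isTRUE(signed_edges), scale_factor = scale_factor,
              seed = as.integer(seed), out_dir = out_dir, paths = paths,
              simulate = simulate, centroid_ref = centroid_ref)
  problems <- character()
  if (is.na(cfg$n_permutations) || cfg$n_permutations < 1)
    problems <- c(problems, "n_permutations: must be an integer >= 1")
  if (!is.numeric(cfg$alpha) || cfg$alpha < 0 || cfg$alpha >= 1)
    problems <- c(problems, "alpha: must lie in [0, 1)")
  if (!is.numeric(cfg$min_expr_frac) || cfg$min_expr_frac < 0 || cfg$min_expr_frac > 1)
    problems <- c(problems, "min_expr_frac: must lie in [0, 1]")
  if (!is.numeric(cfg$binary_used_frac) || cfg$binary_used_frac < 0 || cfg$binary_used_frac > 1)
    problems <- c(problems, "binary_used_frac: must lie in [0, 1]")
  if (length(problems)) stop("invalid configuration:\n  ",
                             paste(problems, collapse = "\n  "))
  structure(cfg, class = "PipelineConfig")
}
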