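# Per-cluster expression prevalence filter, one-vs-rest Wilcoxon
# differential expression, Benjamini-Hochberg correction, and centroid
# distance summaries.

#' Genes expressed in a minimum fraction of a cluster's cells
#'
#' A gene counts as expressed in a cell when its value is > 0; it passes
#' the filter when its detection fraction within the cluster is at least
#' `min_frac` (boundary inclusive).
#'
#' @param expr An [expression_matrix()].
#' @param clusters A [cluster_assignment()].
#' @param cluster Cluster label.
#' @param min_frac Minimum detection fraction in `[0, 1]` (default 0.10).
#' @return Character vector of gene IDs.
#' @export
expressed_genes <- function(expr, clusters, cluster, min_frac = 0.10) {
  stopifnot(min_frac >= 0, min_frac <= 1)
  cells <- cells_in_cluster(clusters, cluster)
  v <- expr$values[, cells, drop = FALSE]
  frac <- Matrix::rowSums(v > 0) / length(cells)
  expr$gene_ids[frac >= min_frac]
}

#' One-vs-rest Wilcoxon rank-sum differential expression
#'
#' Tests every gene for a two-sided location difference between the
#' cells of one cluster and all remaining cells.  `stats::wilcox.test`
#' supplies exact p-values for small tie-free groups and the
#' normal approximation otherwise; a constant gene gets p = 1.
#' P-values are BH-adjusted across all tested genes of the cluster.
#'
#' @param expr An [expression_matrix()].
#' @param clusters A [cluster_assignment()].
#' @param cluster Cluster label (needs >= 2 cells in and out).
#' @param genes Optional subset of genes to test (default all).
#' @return Data frame with columns `cluster`, `gene_id`, `p`, `p_adj`,
#'   `mean_in`, `mean_out`.
#' @export
wilcoxon_de <- function(expr, clusters, cluster, genes = NULL) {
  cells_in <- cells_in_cluster(clusters, cluster)
  cells_out <- setdiff(intersect(clusters$cell_id, expr$cell_ids), cells_in)
  if (length(cells_in) < 2 || length(cells_out) < 2)
    stop("cluster and complement must each have >= 2 cells")
  genes <- genes %||% expr$gene_ids
  v <- as.matrix(expr$values[genes, c(cells_in, cells_out), drop = FALSE])
  n_in <- length(cells_in)
  idx_in <- seq_len(n_in)
  p <- vapply(seq_along(genes), function(g) {
    x <- v[g, idx_in]
    y <- v[g, -idx_in]
    if (max(v[g, ]) == min(v[g, ])) return(1)
    suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided")$p.value)
  }, numeric(1))
  data.frame(cluster = cluster, gene_id = genes, p = p,
             p_adj = benjamini_hochberg(p),
             mean_in = rowMeans(v[, idx_in, drop = FALSE]),
             mean_out = rowMeans(v[, -idx_in, drop = FALSE]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard FDR step-up: sorted p-values are scaled by `m / rank`, a
#' running minimum is taken from the largest rank down, and the result
#' is capped at 1.  Input order is preserved.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
benjamini_hochberg <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(pvals)
  o <- order(pvals, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * pvals[o]))[ro]
}

#' Mean Euclidean distance from a reference-cluster centroid
#'
#' The centroid is the coordinate-wise mean of the reference cluster's
#' cells; for every other cluster the mean and population standard
#' deviation (divide by n) of the per-cell distances to that centroid
#' are reported.
#'
#' @param embedding Numeric matrix, cells x dimensions, row names =
#'   cell IDs.
#' @param clusters A [cluster_assignment()].
#' @param ref_cluster Reference cluster label (non-empty).
#' @return Data frame with columns `target_cluster`, `mean_dist`, `sd_dist`.
#' @export
centroid_distances <- function(embedding, clusters, ref_cluster) {
  ref_cells <- cells_in_cluster(clusters, ref_cluster)
  missing <- setdiff(clusters$cell_id, rownames(embedding))
  if (length(missing))
    stop("embedding lacks coordinates for: ",
         paste(utils::head(missing, 5), collapse = ", "))
  centroid <- colMeans(embedding[ref_cells, , drop = FALSE])
  targets <- sort(setdiff(unique(clusters$cluster), ref_cluster))
  rows <- lapply(targets, function(tc) {
    cells <- cells_in_cluster(clusters, tc)
    d2 <- sweep(embedding[cells, , drop = FALSE], 2, centroid)
    d <- sqrt(rowSums(d2^2))
    data.frame(target_cluster = tc, mean_dist = mean(d),
               sd_dist = sqrt(mean((d - mean(d))^2)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
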