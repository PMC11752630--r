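# Per-cluster microRNA binding-site avoidance: lost vs retained site
# mass under observed APA usage, tested by shuffling cluster labels.
#
# A binding site is "retained" on an isoform only when it lies wholly
# upstream of the isoform's cleavage position (end <= cleavage_pos): a
# truncated seed match cannot function.  Only genes with >= 2 annotated
# polyA sites can exhibit APA-driven loss and enter the statistic.

#' Fate of a binding site on an isoform
#'
#' @param start,end Site interval, 0-based half-open, 3'UTR-relative.
#' @param cleavage_pos Number of 3'UTR bases retained by the isoform.
#' @return `"retained"` when `end <= cleavage_pos`, else `"lost"`.
#' @export
site_fate <- function(start, end, cleavage_pos) {
  stopifnot(all(start >= 0), all(end > start), all(cleavage_pos >= 0))
  ifelse(end <= cleavage_pos, "retained", "lost")
}

# All (binding site x isoform) pairs for the eligible genes, with the
# lost/retained call per pair and an APA-sensitivity flag per site
# (fate differs across the gene's isoforms).
site_isoform_pairs <- function(apa, sites, eligible_genes) {
  meta <- apa$site_meta
  meta$row <- seq_len(nrow(meta))
  meta <- meta[meta$gene_id %in% eligible_genes, c("gene_id", "row", "cleavage_pos")]
  s <- sites[sites$gene_id %in% eligible_genes, , drop = FALSE]
  if (nrow(s) == 0 || nrow(meta) == 0) return(NULL)
  s$site_key <- paste(s$family_id, s$gene_id, s$start, s$end, sep = "|")
  pairs <- merge(s, meta, by = "gene_id")
  pairs$lost <- pairs$end > pairs$cleavage_pos
  sens <- tapply(pairs$lost, pairs$site_key, function(l) any(l) && !all(l))
  pairs$sensitive <- as.vector(sens[pairs$site_key])
  pairs
}

# Sparse family x isoform-row weight matrices: number of lost (WL) and
# retained (WR) sites of each family on each isoform.
family_site_weights <- function(pairs, n_rows) {
  families <- sort(unique(pairs$family_id))
  fi <- match(pairs$family_id, families)
  make <- function(keep) {
    Matrix::sparseMatrix(i = fi[keep], j = pairs$row[keep],
                         x = rep(1, sum(keep)),
                         dims = c(length(families), n_rows),
                         dimnames = list(families, NULL))
  }
  list(families = families, WL = make(pairs$lost), WR = make(!pairs$lost))
}

#' Lost and retained binding-site mass per microRNA family
#'
#' In `weighted` mode every (eligible gene, isoform, binding site)
#' combination contributes the isoform's summed expression over the
#' cell set to the family's lost or retained mass according to
#' [site_fate()].  In `binary` mode the contribution is 1 per isoform
#' that is "used" in the cell set (detected in at least `used_frac` of
#' its cells), 0 otherwise.
#'
#' @param apa An [apa_matrix()].
#' @param sites A [binding_site_table()].
#' @param cells Non-empty character vector of cell IDs.
#' @param eligible_genes Genes entering the statistic (normally the
#'   multi-APA genes passing the cluster's expression filter).
#' @param mode `"weighted"` or `"binary"`.
#' @param used_frac Binary-mode prevalence threshold (default 0.05).
#' @return Data frame with columns `family_id`, `lost`, `retained`.
#' @export
family_lost_retained <- function(apa, sites, cells, eligible_genes,
                                 mode = c("weighted", "binary"),
                                 used_frac = 0.05) {
  mode <- match.arg(mode)
  if (length(cells) == 0) stop("empty cell set")
  pairs <- site_isoform_pairs(apa, sites, eligible_genes)
  if (is.null(pairs))
    return(data.frame(family_id = character(0), lost = numeric(0),
                      retained = numeric(0)))
  w <- family_site_weights(pairs, nrow(apa$values))
  v <- apa$values[, cells, drop = FALSE]
  mass <- if (mode == "weighted") {
    Matrix::rowSums(v)
  } else {
    as.numeric(Matrix::rowSums(v > 0) / length(cells) >= used_frac)
  }
  data.frame(family_id = w$families,
             lost = as.numeric(w$WL %*% mass),
             retained = as.numeric(w$WR %*% mass))
}

#' Lost-fraction avoidance statistic
#'
#' The monotone reparameterization `L / (L + R)` of the lost-to-retained
#' ratio `L / R`: same ordering, no division by zero for fully lost
#' families.
#'
#' @param lost,retained Non-negative masses `L` and `R`.
#' @return `L / (L + R)`; `NA` where `L + R = 0` (untestable).
#' @export
avoidance_statistic <- function(lost, retained) {
  tot <- lost + retained
  ifelse(tot > 0, lost / tot, NA_real_)
}

# Eligible genes for one cluster: multi-APA genes whose gene-level APA
# expression is detected in >= min_expr_frac of the cluster's cells.
eligible_avoidance_genes <- function(apa, cells, min_expr_frac) {
  genes <- multi_apa_genes(apa)
  if (min_expr_frac > 0 && length(genes)) {
    v <- apa$values[, cells, drop = FALSE] > 0
    # gene-level detection: any isoform of the gene detected in the cell
    detmat <- rowsum(as.matrix(v) * 1, apa$site_meta$gene_id) > 0
    frac <- rowSums(detmat) / length(cells)
    genes <- intersect(genes, rownames(detmat)[frac >= min_expr_frac])
  }
  genes
}

#' Permutation test for APA-driven binding-site avoidance in a cluster
#'
#' Computes the observed lost fraction per microRNA family for the focal
#' cluster, then shuffles all cells' cluster labels `B` times (cluster
#' sizes preserved) and recomputes the statistic on the permuted focal
#' cell set.  The default p-value is the add-one-smoothed
#' `(1 + #\{perm >= obs\}) / (B + 1)`; with
#' `smooth_permutation_p = FALSE` the literal strictly-greater count
#' divided by `B` is reported.  BH correction is applied across the
#' cluster's testable families.
#'
#' Families are testable only when they carry at least one
#' APA-sensitive site (a site retained on some isoform and lost on
#' another) on an eligible gene; families whose statistic cannot vary
#' with isoform choice carry no information about APA-driven loss and
#' are excluded from testing and BH.
#'
#' @param apa An [apa_matrix()].
#' @param sites A [binding_site_table()].
#' @param clusters A [cluster_assignment()] with >= 2 clusters.
#' @param cluster Focal cluster label (>= 2 cells).
#' @param config A [pipeline_config()]; uses `n_permutations`, `alpha`,
#'   `min_expr_frac`, `count_mode`, `binary_used_frac`,
#'   `smooth_permutation_p` and `seed`.
#' @param seed RNG seed for this test; defaults to a substream derived
#'   from `config$seed` and the focal cluster's cell-ID set, so results
#'   depend neither on the order in which clusters are tested nor on
#'   how clusters are named.
#' @return Data frame, one row per family with >= 1 site on an eligible
#'   gene: `cluster`, `family`, `lost`, `retained`, `statistic`,
#'   `ratio`, `testable`, `p`, `p_adj`, `significant`, `n_genes`, and a
#'   list column `contributing_genes` (genes contributing lost mass).
#' @export
avoidance_permutation_test <- function(apa, sites, clusters, cluster,
                                       config = pipeline_config(),
                                       seed = NULL) {
  B <- config$n_permutations
  if (B < 1) stop("n_permutations must be >= 1")
  if (length(unique(clusters$cluster)) < 2) stop("need >= 2 clusters")
  focal <- cells_in_cluster(clusters, cluster)
  if (length(focal) < 2) stop("cluster '", cluster, "' has fewer than 2 cells")
  if (is.null(seed)) seed <- derive_seed(config$seed, "avoidance", sort(focal))
  all_cells <- intersect(apa$cell_ids, clusters$cell_id)
  eligible <- eligible_avoidance_genes(apa, focal, config$min_expr_frac)
  pairs <- site_isoform_pairs(apa, sites, eligible)
  empty <- data.frame(cluster = character(0), family = character(0),
                      lost = numeric(0), retained = numeric(0),
                      statistic = numeric(0), ratio = numeric(0),
                      testable = logical(0), p = numeric(0), p_adj = numeric(0),
                      significant = logical(0), n_genes = integer(0))
  if (is.null(pairs)) {
    empty$contributing_genes <- list()
    return(empty)
  }
  w <- family_site_weights(pairs, nrow(apa$values))
  nF <- length(w$families)
  ci <- match(all_cells, apa$cell_ids)
  v <- apa$values[, ci, drop = FALSE]
  n_focal <- length(focal)
  n_cells <- length(all_cells)

  binary <- config$count_mode == "binary"
  ML <- as.matrix(w$WL %*% v)  # family x cell lost mass (weighted mode)
  MR <- as.matrix(w$WR %*% v)
  if (binary) {
    NZ <- as.matrix(v > 0) * 1
    thresh <- config$binary_used_frac * n_focal
    binary_lr <- function(f, ind) {  # ind: cells x k indicator
      rows_f <- which(w$WL[f, ] > 0 | w$WR[f, ] > 0)
      used <- (NZ[rows_f, , drop = FALSE] %*% ind >= thresh) * 1
      list(L = as.vector(w$WL[f, rows_f, drop = FALSE] %*% used),
           R = as.vector(w$WR[f, rows_f, drop = FALSE] %*% used))
    }
  }

  obs_ind <- matrix(as.numeric(all_cells %in% focal), ncol = 1)
  if (binary) {
    obs_lr <- lapply(seq_len(nF), function(f) binary_lr(f, obs_ind))
    obs <- list(L = vapply(obs_lr, `[[`, numeric(1), "L"),
                R = vapply(obs_lr, `[[`, numeric(1), "R"))
  } else {
    obs <- list(L = as.vector(ML %*% obs_ind), R = as.vector(MR %*% obs_ind))
  }
  obs$stat <- obs$L / (obs$L + obs$R)

  # testability: >= 1 APA-sensitive site on an eligible gene
  sens_fam <- unique(pairs$family_id[pairs$sensitive])
  testable <- w$families %in% sens_fam &
    !is.na(obs$stat) & (obs$L + obs$R) > 0

  # Each family draws its own independent permutation substream: the
  # marginal p is identical to recomputing every family on one shared
  # set of shuffles, but the number of families called significant is
  # not inflated by shared shuffle noise.
  p <- rep(NA_real_, nF)
  for (f in which(testable)) {
    idx <- withr::with_seed(derive_seed(seed, w$families[f]), {
      vapply(seq_len(B), function(b) sample.int(n_cells, n_focal),
             integer(n_focal))
    })
    if (binary) {
      Pf <- Matrix::sparseMatrix(i = as.vector(idx),
                                 j = rep(seq_len(B), each = n_focal),
                                 x = 1, dims = c(n_cells, B))
      lr <- binary_lr(f, Pf)
      stat_perm <- lr$L / (lr$L + lr$R)
    } else {
      Lp <- colSums(matrix(ML[f, idx], n_focal, B))
      Rp <- colSums(matrix(MR[f, idx], n_focal, B))
      stat_perm <- Lp / (Lp + Rp)
    }
    p[f] <- permutation_pvalue(stat_perm, obs$stat[f],
                               smooth = config$smooth_permutation_p,
                               strict = TRUE)
  }
  p_adj <- rep(NA_real_, nF)
  p_adj[testable] <- benjamini_hochberg(p[testable])

  lost_pairs <- pairs[pairs$lost, , drop = FALSE]
  row_mass <- Matrix::rowSums(v[, which(all_cells %in% focal), drop = FALSE])
  contrib <- tapply(lost_pairs$gene_id[row_mass[lost_pairs$row] > 0],
                    lost_pairs$family_id[row_mass[lost_pairs$row] > 0],
                    function(g) sort(unique(g)), simplify = FALSE)
  contributing <- lapply(w$families, function(f) contrib[[f]] %||% character(0))

  res <- data.frame(cluster = cluster, family = w$families,
                    lost = obs$L, retained = obs$R,
                    statistic = obs$stat,
                    ratio = ifelse(obs$R > 0, obs$L / obs$R,
                                   ifelse(obs$L > 0, Inf, NA_real_)),
                    testable = testable, p = p, p_adj = p_adj,
                    significant = !is.na(p_adj) & p_adj < config$alpha,
                    n_genes = vapply(contributing, length, integer(1)),
                    row.names = NULL, stringsAsFactors = FALSE)
  res$contributing_genes <- contributing
  res[order(res$family), , drop = FALSE]
}

#' Run the avoidance test for every cluster
#'
#' @inheritParams avoidance_permutation_test
#' @return Row-bound per-cluster results of
#'   [avoidance_permutation_test()], clusters in sorted label order.
#' @export
avoidance_test_all <- function(apa, sites, clusters, config = pipeline_config()) {
  labs <- sort(unique(clusters$cluster))
  do.call(rbind, lapply(labs, function(lab)
    avoidance_permutation_test(apa, sites, clusters, lab, config)))
}

#' Per-cluster gene sets behind significant avoidance families
#'
#' @param results Output of [avoidance_test_all()].
#' @return Named list (cluster -> character vector) of the union of
#'   contributing genes over the cluster's significant families.
#' @export
avoidance_gene_sets <- function(results) {
  labs <- sort(unique(results$cluster))
  sets <- lapply(labs, function(lab) {
    keep <- results$cluster == lab & results$significant
    sort(unique(unlist(results$contributing_genes[keep])))
  })
  names(sets) <- labs
  sets
}

#' Venn-region counts of gene sets across clusters
#'
#' Every gene is assigned to exactly one region: the combination of
#' clusters whose sets contain it.  Counts are reported for each
#' non-empty region.
#'
#' @param gene_sets Named list of character vectors (cluster -> genes).
#' @return Data frame with columns `clusters` (labels joined by `&`),
#'   `n_clusters`, `count`.
#' @export
gene_loss_overlap <- function(gene_sets) {
  genes <- sort(unique(unlist(gene_sets)))
  if (length(genes) == 0)
    return(data.frame(clusters = character(0), n_clusters = integer(0),
                      count = integer(0)))
  labs <- names(gene_sets)
  membership <- vapply(gene_sets, function(s) genes %in% s,
                       logical(length(genes)))
  membership <- matrix(membership, nrow = length(genes),
                       dimnames = list(genes, labs))
  region <- apply(membership, 1, function(row) paste(labs[row], collapse = "&"))
  tab <- table(region)
  df <- data.frame(clusters = names(tab),
                   n_clusters = lengths(strsplit(names(tab), "&", fixed = TRUE)),
                   count = as.integer(tab), stringsAsFactors = FALSE)
  df[order(-df$n_clusters, df$clusters), , drop = FALSE]
}
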