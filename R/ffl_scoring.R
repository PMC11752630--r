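# SFFL scoring and significance: inverse-normal node scores from
# differential-expression adjusted p-values, Fisher-z correlation edge
# scores over the cluster's cells, the averaged overall score, and a
# random-triple permutation test with BH correction.

P_CLIP <- 1e-12
R_CLIP <- 1 - 1e-7

#' Inverse-normal node score
#'
#' `qnorm(1 - p_adj)` with the adjusted p-value clipped to
#' `[1e-12, 1 - 1e-12]`: smaller p-values (stronger differential
#' expression) give strictly larger scores.
#'
#' @param p_adj BH-adjusted p-value(s) in `[0, 1]`.
#' @return Numeric score(s).
#' @export
node_score <- function(p_adj) {
  if (any(is.na(p_adj)) || any(p_adj < 0 | p_adj > 1))
    stop("adjusted p-values must lie in [0, 1]")
  stats::qnorm(1 - clip(p_adj, P_CLIP, 1 - P_CLIP))
}

edge_score_from_r <- function(r, n, signed = FALSE) {
  z <- atanh(clip(r, -R_CLIP, R_CLIP)) * sqrt(n - 3)
  if (signed) z else abs(z)
}

#' Fisher-z correlation edge score
#'
#' Pearson correlation `r` between the two expression vectors over a
#' cluster's cells, Fisher-transformed and scaled to an approximate
#' standard-normal z: `|atanh(r)| * sqrt(n - 3)` (`r` clipped to
#' `+/-(1 - 1e-7)`).  The absolute value treats repression and
#' activation as equally coherent; `signed = TRUE` keeps the sign.
#' A zero-variance vector yields score 0 with a warning.
#'
#' @param x,y Equal-length numeric vectors, `n >= 4`.
#' @param signed Keep the sign of the transformed correlation.
#' @return A non-negative score (or signed z).
#' @export
edge_score <- function(x, y, signed = FALSE) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  n <- length(x)
  if (n < 4) stop("edge scores need n >= 4 cells")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero-variance vector; edge score set to 0")
    return(0)
  }
  edge_score_from_r(stats::cor(x, y), n, signed)
}

# Precompute everything scoring needs for one cluster: standardized
# log-normalized rows, node scores, and the three pairwise correlation
# blocks (miRNA x gene, TF x gene, miRNA x TF) restricted to the pools.
sffl_cluster_context <- function(expr, clusters, cluster, de, pools, config) {
  cells <- cells_in_cluster(clusters, cluster)
  n <- length(cells)
  if (n < 4) stop("cluster '", cluster, "' has fewer than 4 cells")
  ln <- if (expr$normalized) as.matrix(expr$values) else
    log_normalize(expr$values, config$scale_factor)
  pool_m <- pools$mirnas; pool_t <- pools$tfs; pool_g <- pools$genes
  if (length(pool_t) == 0 || length(pool_g) == 0 || length(pool_m) == 0)
    stop("empty candidate pool")
  miss <- setdiff(c(pool_t, pool_g), expr$gene_ids)
  if (length(miss))
    stop("pool members without expression rows: ",
         paste(utils::head(miss, 5), collapse = ", "))
  ns <- stats::setNames(node_score(de$p_adj), de$gene_id)
  miss_de <- setdiff(c(pool_t, pool_g), names(ns))
  if (length(miss_de))
    stop("pool members without DE results: ",
         paste(utils::head(miss_de, 5), collapse = ", "))
  m_expr <- pool_m[pool_m %in% expr$gene_ids]
  miss_de_m <- setdiff(m_expr, names(ns))
  if (length(miss_de_m))
    stop("expressed miRNAs without DE results: ",
         paste(utils::head(miss_de_m, 5), collapse = ", "))
  Z <- standardize_rows(ln[unique(c(m_expr, pool_t, pool_g)), , drop = FALSE],
                        match(cells, expr$cell_ids))
  if (length(attr(Z, "degenerate")))
    warning("zero-variance expression in cluster '", cluster, "' for: ",
            paste(utils::head(attr(Z, "degenerate"), 5), collapse = ", "),
            "; their edge scores are 0")
  cor_block <- function(a, b)
    if (length(a) && length(b))
      tcrossprod(Z[a, , drop = FALSE], Z[b, , drop = FALSE]) / n
    else matrix(0, length(a), length(b))
  list(cluster = cluster, n = n,
       pool_m = pool_m, pool_t = pool_t, pool_g = pool_g,
       m_expressed = pool_m %in% m_expr,
       me_index = match(pool_m, m_expr),    # row into miRNA cor blocks
       ns_m = ifelse(pool_m %in% names(ns), ns[pool_m], NA_real_),
       ns_t = ns[pool_t], ns_g = ns[pool_g],
       C_mg = cor_block(m_expr, pool_g),
       C_tg = cor_block(pool_t, pool_g),
       C_mt = cor_block(m_expr, pool_t),
       signed = config$signed_edges)
}

# Score triples given pool indices and one edge-presence pattern.
# Terms: TF node + gene node + TF->gene edge always; when the miRNA has
# an expression row it adds its node score, the miRNA->gene edge, and
# one miRNA-TF correlation term per cross edge present (feedback loops
# count it twice, once per directed edge).
score_triples <- function(ctx, mi, ti, gi, has_mt, has_tm) {
  es <- function(r) edge_score_from_r(r, ctx$n, ctx$signed)
  base <- ctx$ns_t[ti] + ctx$ns_g[gi] + es(ctx$C_tg[cbind(ti, gi)])
  n_terms <- rep(3, length(ti))
  m_in <- ctx$m_expressed[mi]
  if (any(m_in)) {
    me <- ctx$me_index[mi[m_in]]
    k_cross <- as.numeric(has_mt) + as.numeric(has_tm)
    add <- ctx$ns_m[mi[m_in]] + es(ctx$C_mg[cbind(me, gi[m_in])]) +
      k_cross * es(ctx$C_mt[cbind(me, ti[m_in])])
    base[m_in] <- base[m_in] + add
    n_terms[m_in] <- 3 + 2 + k_cross
  }
  base / n_terms
}

#' Score a single SFFL in a cluster
#'
#' The overall score is the arithmetic mean of the available node and
#' edge scores: inverse-normal node scores for every node with a DE
#' adjusted p-value, and Fisher-z correlation scores for every loop
#' edge whose endpoints both have expression rows.  A miRNA without an
#' expression row contributes no terms; the TF and gene node scores and
#' the TF->gene edge must always remain (otherwise the loop is
#' unscorable and `NA` is returned).
#'
#' @param sffl One-row data frame or list with `mirna`, `tf`, `gene`,
#'   `has_mt`, `has_tm` (see [enumerate_sffls()]).
#' @param expr An [expression_matrix()].
#' @param clusters A [cluster_assignment()].
#' @param cluster Cluster label (>= 4 cells).
#' @param de Output of [wilcoxon_de()] for this cluster.
#' @param config A [pipeline_config()].
#' @return A list with `node_scores`, `edge_scores`, `score`,
#'   `n_terms`, `n_cells`.
#' @export
sffl_score <- function(sffl, expr, clusters, cluster, de,
                       config = pipeline_config()) {
  sffl <- as.list(sffl)
  pools <- list(mirnas = sffl$mirna, tfs = sffl$tf, genes = sffl$gene)
  ctx <- sffl_cluster_context(expr, clusters, cluster, de, pools, config)
  s <- score_triples(ctx, 1L, 1L, 1L, isTRUE(sffl$has_mt), isTRUE(sffl$has_tm))
  es <- function(r) edge_score_from_r(r, ctx$n, ctx$signed)
  nodes <- c(tf = unname(ctx$ns_t[1]), gene = unname(ctx$ns_g[1]))
  edges <- c(tf_gene = es(ctx$C_tg[1, 1]))
  if (ctx$m_expressed[1]) {
    nodes <- c(mirna = unname(ctx$ns_m[1]), nodes)
    edges <- c(mirna_gene = es(ctx$C_mg[1, 1]), edges)
    if (isTRUE(sffl$has_mt)) edges <- c(edges, mirna_tf = es(ctx$C_mt[1, 1]))
    if (isTRUE(sffl$has_tm)) edges <- c(edges, tf_mirna = es(ctx$C_mt[1, 1]))
  }
  list(node_scores = nodes, edge_scores = edges, score = unname(s),
       n_terms = length(nodes) + length(edges), n_cells = ctx$n)
}

#' Random-triple permutation significance of SFFLs in a cluster
#'
#' Every candidate loop's observed score is compared to `B` random
#' triples (one miRNA, one TF, one gene, drawn uniformly with
#' replacement from the cluster's candidate pools) scored under the
#' observed loop's edge-presence pattern and the same absent-miRNA drop
#' rules, so observed and null scores average comparable terms.  The
#' default p-value is the add-one-smoothed
#' `(1 + #\{S_rand >= S_obs\}) / (B + 1)`; with
#' `smooth_permutation_p = FALSE` the literal greater-or-equal count
#' divided by `B`.  BH correction runs across the cluster's candidates.
#'
#' @param sffls Candidate loops for this cluster
#'   (see [apply_expression_filter()]).
#' @param expr An [expression_matrix()].
#' @param clusters A [cluster_assignment()].
#' @param cluster Cluster label.
#' @param de Output of [wilcoxon_de()] for this cluster.
#' @param pools List with `mirnas`, `tfs`, `genes`: the cluster's
#'   candidate node pools (expression-filtered; miRNAs without
#'   expression rows included).
#' @param config A [pipeline_config()].
#' @param seed RNG seed; defaults to a substream of `config$seed` keyed
#'   by the cluster's cell-ID set, independent of candidate processing
#'   order and of cluster naming.
#' @return `sffls` sorted by (mirna, tf, gene) with columns `score`,
#'   `p`, `p_adj`, `significant`, `n_cells` added.
#' @export
sffl_permutation_test <- function(sffls, expr, clusters, cluster, de, pools,
                                  config = pipeline_config(),
                                  seed = NULL) {
  B <- config$n_permutations
  if (B < 1) stop("n_permutations must be >= 1")
  if (is.null(seed))
    seed <- derive_seed(config$seed, "sffl", sort(cells_in_cluster(clusters, cluster)))
  sffls <- sffls[order(sffls$mirna, sffls$tf, sffls$gene), , drop = FALSE]
  rownames(sffls) <- NULL
  nS <- nrow(sffls)
  out <- sffls
  out$score <- numeric(nS); out$p <- numeric(nS); out$p_adj <- numeric(nS)
  if (nS == 0) {
    out$significant <- logical(0); out$n_cells <- integer(0)
    return(out)
  }
  ctx <- sffl_cluster_context(expr, clusters, cluster, de, pools, config)
  mi <- match(sffls$mirna, ctx$pool_m)
  ti <- match(sffls$tf, ctx$pool_t)
  gi <- match(sffls$gene, ctx$pool_g)
  if (any(is.na(mi) | is.na(ti) | is.na(gi)))
    stop("candidate SFFL nodes missing from the pools")
  obs <- vapply(seq_len(nS), function(i)
    score_triples(ctx, mi[i], ti[i], gi[i], sffls$has_mt[i], sffls$has_tm[i]),
    numeric(1))
  p <- withr::with_seed(seed, {
    vapply(seq_len(nS), function(i) {
      rm_ <- sample.int(length(ctx$pool_m), B, replace = TRUE)
      rt_ <- sample.int(length(ctx$pool_t), B, replace = TRUE)
      rg_ <- sample.int(length(ctx$pool_g), B, replace = TRUE)
      s_rand <- score_triples(ctx, rm_, rt_, rg_, sffls$has_mt[i], sffls$has_tm[i])
      permutation_pvalue(s_rand, obs[i],
                         smooth = config$smooth_permutation_p, strict = FALSE)
    }, numeric(1))
  })
  out$score <- obs
  out$p <- p
  out$p_adj <- benjamini_hochberg(p)
  out$significant <- out$p_adj < config$alpha
  out$n_cells <- ctx$n
  out
}

#' Annotate loops with APA-driven binding-site loss
#'
#' An SFFL's flag is `TRUE` iff its (cluster, miRNA family) pair is
#' significantly avoided in the avoidance results (BH-adjusted
#' p < alpha).  Clusters without any avoidance rows get all-`FALSE`
#' flags with a warning.
#'
#' @param sffls SFFL data frame with `cluster` and `mirna` columns.
#' @param avoidance Output of [avoidance_test_all()].
#' @param alpha Significance threshold (default 0.05).
#' @return `sffls` with a logical `mirna_sites_lost_flag` column.
#' @export
annotate_apa_loss <- function(sffls, avoidance, alpha = 0.05) {
  if (!all(c("cluster", "family") %in% names(avoidance)))
    stop("avoidance results need 'cluster' and 'family' columns")
  sig <- avoidance[!is.na(avoidance$p_adj) & avoidance$p_adj < alpha, ]
  missing <- setdiff(unique(sffls$cluster), unique(avoidance$cluster))
  if (length(missing))
    warning("no avoidance results for cluster(s): ",
            paste(missing, collapse = ", "), "; flags set to FALSE")
  sffls$mirna_sites_lost_flag <-
    paste(sffls$cluster, sffls$mirna) %in% paste(sig$cluster, sig$family)
  sffls
}

#' @rdname annotate_apa_loss
#' @param mffls MFFL list from [merge_mffls()].
#' @return For MFFLs: the list with `apa_loss_center` (center miRNA
#'   family significant; `FALSE` for TF centers) and `apa_loss_any`
#'   (any member miRNA significant) added per module.
#' @export
annotate_mffl_apa_loss <- function(mffls, avoidance, alpha = 0.05) {
  sig <- avoidance[!is.na(avoidance$p_adj) & avoidance$p_adj < alpha, ]
  sig_key <- paste(sig$cluster, sig$family)
  lapply(mffls, function(m) {
    member_m <- vapply(m$members, function(x) x$mirna, character(1))
    m$apa_loss_center <- m$center_type == "miRNA" &&
      paste(m$cluster, m$center) %in% sig_key
    m$apa_loss_any <- any(paste(m$cluster, member_m) %in% sig_key)
    m
  })
}
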