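# Tiny in-code fixtures shared across test files.

# One two-isoform gene (cleavages 100 and 300) plus a single-site gene,
# four cells in two clusters of two.  Family FAMA has one site (150,157)
# lost on the proximal isoform only; FAMB one site (50,57) upstream of
# both cleavages (always retained).
toy_apa_bundle <- function(values = NULL) {
  meta <- data.frame(gene_id = c("GA", "GA", "GB"),
                     site_id = c("s1", "s2", "s1"),
                     cleavage_pos = c(100L, 300L, 500L))
  if (is.null(values))
    values <- rbind(c(10, 20, 1, 2),    # GA proximal
                    c(2, 3, 9, 7),      # GA distal
                    c(5, 5, 5, 5))      # GB single site
  colnames(values) <- paste0("c", 1:4)
  apa <- apa_matrix(values, meta, colnames(values))
  sites <- binding_site_table(data.frame(
    family_id = c("FAMA", "FAMB"), gene_id = "GA",
    start = c(150L, 50L), end = c(157L, 57L)))
  clusters <- cluster_assignment(data.frame(
    cell_id = paste0("c", 1:4), cluster = rep(c("A", "B"), each = 2)))
  list(apa = apa, sites = sites, clusters = clusters)
}

# Exhaustive avoidance permutation oracle: lost fraction of one family
# for every size-k cell subset (the permutation null with cluster sizes
# preserved and two clusters is uniform over subsets).
exact_avoidance_stats <- function(apa, sites, family, eligible, k) {
  cells <- apa$cell_ids
  combos <- utils::combn(cells, k, simplify = FALSE)
  vapply(combos, function(cs) {
    lr <- family_lost_retained(apa, sites, cs, eligible)
    row <- lr[lr$family_id == family, ]
    avoidance_statistic(row$lost, row$retained)
  }, numeric(1))
}

# Brute-force SFFL scan over all (miRNA, TF, gene) triples.
brute_force_sffls <- function(graph) {
  e <- graph$edges
  key <- paste(e$source_id, e$target_id, sep = "\r")
  has <- function(a, b) paste(a, b, sep = "\r") %in% key
  out <- list()
  for (m in graph$mirnas) for (t in graph$tfs) for (g in graph$genes) {
    if (!has(m, g) || !has(t, g)) next
    mt <- has(m, t); tm <- has(t, m)
    if (!mt && !tm) next
    cls <- if (mt && tm) "feedback" else if (mt) "mirna_centric" else "tf_centric"
    out[[length(out) + 1]] <- data.frame(mirna = m, tf = t, gene = g,
                                         class = cls, has_mt = mt, has_tm = tm)
  }
  if (length(out) == 0)
    return(data.frame(mirna = character(0), tf = character(0),
                      gene = character(0), class = character(0),
                      has_mt = logical(0), has_tm = logical(0)))
  df <- do.call(rbind, out)
  df <- df[order(df$mirna, df$tf, df$gene), ]
  rownames(df) <- NULL
  df
}

random_graph_config <- function(seed) {
  synthetic_config(n_genes = sample(5:30, 1), n_tfs = sample(2:10, 1),
                   n_mirna_families = sample(2:10, 1),
                   edge_prob = c(mirna_gene = 0.3, mirna_tf = 0.3,
                                 tf_gene = 0.3, tf_mirna = 0.2),
                   seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
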