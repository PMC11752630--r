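# Synthetic single-cell bundles with known ground truth: cluster-
# structured negative-binomial expression, multi-polyA-site genes with
# Dirichlet isoform usage, a random four-kind regulatory graph, and
# planted effects (avoided microRNA families, coherent FFL triples) for
# recovery testing.

#' Configuration of the synthetic-data generator
#'
#' Defaults emulate a compact two-cluster single-cell experiment:
#' negative-binomial counts with moderate overdispersion, 16.6% of
#' genes carrying multiple polyA sites, and sparse Bernoulli
#' regulatory edges.
#'
#' @param n_clusters,cells_per_cluster,n_genes,n_tfs,n_mirna_families
#'   Problem sizes (all >= 1).
#' @param frac_multi_apa Fraction of genes with 2+ polyA sites
#'   (default 0.166).
#' @param utr_length_range Integer pair: 3'UTR length bounds.
#' @param sites_per_multi_gene Integer pair: polyA sites per multi-APA
#'   gene (default 2-4).
#' @param mean_binding_sites_per_family Poisson mean of the number of
#'   binding sites placed per microRNA family.
#' @param site_width Binding-site width in nt (default 7, a seed match).
#' @param nb_mean,nb_dispersion Negative-binomial mean of the per-gene
#'   expression means and the NB size parameter.
#' @param gene_mean_sdlog Log-normal sd of per-gene mean variation.
#' @param edge_prob Named numeric: independent Bernoulli edge
#'   probabilities for `mirna_gene`, `mirna_tf`, `tf_gene`, `tf_mirna`.
#' @param planted_avoidance `NULL` or data frame (`cluster`, `family`,
#'   `delta`): in that cluster, usage mass `delta` of the affected
#'   genes moves to the most proximal polyA site, deleting the family's
#'   distal sites.
#' @param genes_per_planted_family Multi-APA genes seeded with each
#'   planted family's APA-sensitive sites.
#' @param planted_ffls `NULL` or data frame (`cluster`, `mirna`, `tf`,
#'   `gene`, `rho`, `de_effect`, optional `class`): coherent triples
#'   whose edges are force-inserted and whose expression shares a
#'   latent factor (target pairwise correlation `rho`) plus a
#'   log-fold mean shift `de_effect` in the named cluster.
#' @param latent_sigma Log-scale sd of the planted latent factor.
#' @param mirna_expression Include microRNA families as expression
#'   rows; set `FALSE` to exercise the missing-miRNA path.
#' @param embedding_dim,embedding_separation Dimensions of the
#'   synthetic embedding and sd of the cluster centers (`embedding_dim
#'   = 0` disables it).
#' @param cluster_labels Optional label vector (default `cluster1..k`).
#' @param seed Root RNG seed.
#' @return A validated `SyntheticConfig` list.
#' @export
synthetic_config <- function(n_clusters = 2L, cells_per_cluster = 200L,
                             n_genes = 300L, n_tfs = 30L,
                             n_mirna_families = 150L,
                             frac_multi_apa = 0.166,
                             utr_length_range = c(600L, 2000L),
                             sites_per_multi_gene = c(2L, 4L),
                             mean_binding_sites_per_family = 30,
                             site_width = 7L,
                             nb_mean = 2, nb_dispersion = 2,
                             gene_mean_sdlog = 0.5,
                             edge_prob = c(mirna_gene = 0.02, mirna_tf = 0.05,
                                           tf_gene = 0.05, tf_mirna = 0.05),
                             planted_avoidance = NULL,
                             genes_per_planted_family = 8L,
                             planted_ffls = NULL,
                             latent_sigma = 1,
                             mirna_expression = TRUE,
                             embedding_dim = 10L, embedding_separation = 5,
                             cluster_labels = NULL,
                             seed = 1L) {
  cfg <- as.list(environment())
  # YAML configs supply planted effects as lists of records
  as_records <- function(x) {
    if (is.null(x) || is.data.frame(x)) return(x)
    do.call(rbind, lapply(x, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  }
  planted_avoidance <- cfg$planted_avoidance <- as_records(planted_avoidance)
  planted_ffls <- cfg$planted_ffls <- as_records(planted_ffls)
  if (is.list(edge_prob)) edge_prob <- cfg$edge_prob <- unlist(edge_prob)
  counts <- c(n_clusters, cells_per_cluster, n_genes, n_tfs, n_mirna_families)
  if (any(counts < 1)) stop("all size parameters must be >= 1")
  if (frac_multi_apa < 0 || frac_multi_apa > 1)
    stop("frac_multi_apa must lie in [0, 1]")
  req_kinds <- c("mirna_gene", "mirna_tf", "tf_gene", "tf_mirna")
  if (!all(req_kinds %in% names(edge_prob)))
    stop("edge_prob needs entries: ", paste(req_kinds, collapse = ", "))
  if (any(edge_prob < 0 | edge_prob > 1)) stop("edge_prob must lie in [0, 1]")
  if (!is.null(planted_avoidance)) {
    stopifnot(all(c("cluster", "family", "delta") %in% names(planted_avoidance)))
    if (any(planted_avoidance$delta <= 0 | planted_avoidance$delta > 1))
      stop("planted avoidance delta must lie in (0, 1]")
  }
  if (!is.null(planted_ffls)) {
    stopifnot(all(c("cluster", "mirna", "tf", "gene", "rho", "de_effect")
                  %in% names(planted_ffls)))
    if (any(planted_ffls$rho <= 0 | planted_ffls$rho > 1))
      stop("planted FFL rho must lie in (0, 1]")
    if (is.null(planted_ffls$class)) planted_ffls$class <- "mirna_centric"
    cfg$planted_ffls <- planted_ffls
  }
  if (is.null(cluster_labels))
    cfg$cluster_labels <- paste0("cluster", seq_len(n_clusters))
  else if (length(cluster_labels) != n_clusters)
    stop("cluster_labels length must equal n_clusters")
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "SyntheticConfig")
}

synthetic_ids <- function(config) {
  list(genes = sprintf("G%04d", seq_len(config$n_genes)),
       tfs = sprintf("TF%03d", seq_len(config$n_tfs)),
       mirnas = sprintf("MIR%03d", seq_len(config$n_mirna_families)),
       cells = sprintf("C%05d", seq_len(config$n_clusters * config$cells_per_cluster)))
}

#' Generate the random regulatory graph
#'
#' Four independent Bernoulli edge blocks (miRNA->gene, miRNA->TF,
#' TF->gene, TF->miRNA); the edges required by any planted FFL triple
#' are force-inserted afterwards.
#'
#' @param config A [synthetic_config()].
#' @param seed RNG seed (defaults to the `"graph"` substream).
#' @return List with `interactions` (an [interaction_table()]) and
#'   `planted` (the planted-triple data frame or `NULL`).
#' @export
generate_regulatory_graph <- function(config,
                                      seed = derive_seed(config$seed, "graph")) {
  ids <- synthetic_ids(config)
  bernoulli_edges <- function(src, tgt, p, st, tt) {
    hits <- which(stats::runif(length(src) * length(tgt)) < p)
    if (length(hits) == 0)
      return(data.frame(source_id = character(0), source_type = character(0),
                        target_id = character(0), target_type = character(0)))
    i <- ((hits - 1) %% length(src)) + 1
    j <- ((hits - 1) %/% length(src)) + 1
    data.frame(source_id = src[i], source_type = st,
               target_id = tgt[j], target_type = tt)
  }
  p <- config$edge_prob
  edges <- withr::with_seed(seed, rbind(
    bernoulli_edges(ids$mirnas, ids$genes, p[["mirna_gene"]], "miRNA", "gene"),
    bernoulli_edges(ids$mirnas, ids$tfs, p[["mirna_tf"]], "miRNA", "TF"),
    bernoulli_edges(ids$tfs, ids$genes, p[["tf_gene"]], "TF", "gene"),
    bernoulli_edges(ids$tfs, ids$mirnas, p[["tf_mirna"]], "TF", "miRNA")))
  pf <- config$planted_ffls
  if (!is.null(pf) && nrow(pf)) {
    forced <- do.call(rbind, lapply(seq_len(nrow(pf)), function(i) {
      rows <- data.frame(
        source_id = c(pf$mirna[i], pf$tf[i]), source_type = c("miRNA", "TF"),
        target_id = c(pf$gene[i], pf$gene[i]), target_type = c("gene", "gene"))
      if (pf$class[i] %in% c("mirna_centric", "feedback"))
        rows <- rbind(rows, data.frame(source_id = pf$mirna[i], source_type = "miRNA",
                                       target_id = pf$tf[i], target_type = "TF"))
      if (pf$class[i] %in% c("tf_centric", "feedback"))
        rows <- rbind(rows, data.frame(source_id = pf$tf[i], source_type = "TF",
                                       target_id = pf$mirna[i], target_type = "miRNA"))
      rows
    }))
    edges <- rbind(edges, forced)
  }
  list(interactions = interaction_table(edges), planted = pf)
}

#' Generate polyA-site annotation and binding sites
#'
#' `round(frac_multi_apa * n_genes)` genes receive 2-4 increasing
#' cleavage positions (minimum spacing 50 nt) within their UTR; the
#' rest get a single cleavage at the UTR end.  Binding sites are placed
#' uniformly per family with Poisson counts; planted avoidance families
#' additionally get one APA-sensitive site (between the proximal and
#' the most distal cleavage) in each of `genes_per_planted_family`
#' multi-APA genes.  No site extends past the UTR end.
#'
#' @param config A [synthetic_config()].
#' @param seed RNG seed (defaults to the `"apa"` substream).
#' @return List with `site_meta` (gene_id, site_id, cleavage_pos),
#'   `utr_len` (named vector), `sites` (a [binding_site_table()]) and
#'   `planted_site_genes` (family -> affected genes).
#' @export
generate_apa_annotation <- function(config,
                                    seed = derive_seed(config$seed, "apa")) {
  ids <- synthetic_ids(config)
  width <- config$site_width
  withr::with_seed(seed, {
    utr_len <- stats::setNames(
      sample(seq(config$utr_length_range[1], config$utr_length_range[2]),
             config$n_genes, replace = TRUE), ids$genes)
    n_multi <- round(config$frac_multi_apa * config$n_genes)
    multi <- sort(sample(ids$genes, n_multi))
    k_range <- config$sites_per_multi_gene
    meta <- lapply(ids$genes, function(g) {
      if (g %in% multi) {
        k <- if (k_range[1] == k_range[2]) k_range[1] else
          sample(seq(k_range[1], k_range[2]), 1)
        grid <- seq(100L, utr_len[[g]], by = 10L)
        if (length(grid) < k)
          stop("utr_length too short to place ", k, " polyA sites for ", g)
        for (try in 1:100) {
          pos <- sort(sample(grid, k))
          if (min(diff(pos)) >= 50) break
          if (try == 100) stop("utr_length too short to space polyA sites for ", g)
        }
      } else pos <- utr_len[[g]]
      data.frame(gene_id = g, site_id = paste0("s", seq_along(pos)),
                 cleavage_pos = as.integer(pos))
    })
    site_meta <- do.call(rbind, meta)
    n_sites <- stats::rpois(config$n_mirna_families,
                            config$mean_binding_sites_per_family)
    site_rows <- lapply(seq_len(config$n_mirna_families), function(f) {
      n <- n_sites[f]
      if (n == 0) return(NULL)
      genes <- sample(ids$genes, n, replace = TRUE)
      if (any(utr_len[genes] < width))
        stop("utr_length too short to place binding sites")
      start <- vapply(genes, function(g)
        sample.int(utr_len[[g]] - width + 1, 1) - 1L, integer(1))
      data.frame(family_id = ids$mirnas[f], gene_id = genes,
                 start = start, end = start + width)
    })
    planted_site_genes <- list()
    pa <- config$planted_avoidance
    if (!is.null(pa) && nrow(pa)) {
      # Plant each family into multi-APA genes free of any other
      # family's APA-sensitive sites, chosen disjointly across planted
      # families, so a planted usage shift moves only its own family's
      # lost/retained balance (non-sensitive sites of other families
      # are unaffected by isoform usage by construction).
      rnd <- do.call(rbind, site_rows)
      cl_rng <- do.call(rbind, lapply(multi, function(g) {
        cl <- site_meta$cleavage_pos[site_meta$gene_id == g]
        data.frame(gene_id = g, c_min = min(cl), c_max = max(cl))
      }))
      occupied <- character(0)
      if (!is.null(rnd) && nrow(rnd)) {
        m <- merge(rnd, cl_rng, by = "gene_id")
        occupied <- unique(m$gene_id[m$end > m$c_min & m$end <= m$c_max])
      }
      free_pool <- setdiff(multi, occupied)
      for (fam in unique(pa$family)) {
        if (length(free_pool) < config$genes_per_planted_family)
          stop("not enough collateral-free multi-APA genes to plant family ", fam)
        gsel <- sort(sample(free_pool, config$genes_per_planted_family))
        free_pool <- setdiff(free_pool, gsel)
        planted_site_genes[[fam]] <- gsel
        rows <- lapply(gsel, function(g) {
          cl <- sort(site_meta$cleavage_pos[site_meta$gene_id == g])
          start <- cl[1] + 3L  # lost on the proximal isoform, retained distally
          data.frame(family_id = fam, gene_id = g,
                     start = start, end = start + width)
        })
        site_rows <- c(site_rows, rows)
      }
    }
    sites_df <- do.call(rbind, c(site_rows, list(
      data.frame(family_id = character(0), gene_id = character(0),
                 start = integer(0), end = integer(0)))))
    list(site_meta = site_meta, utr_len = utr_len,
         sites = binding_site_table(sites_df),
         planted_site_genes = planted_site_genes)
  })
}

# Dirichlet draw via normalized gammas.
rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  x / sum(x)
}

#' Generate expression, APA usage, clusters and ground truth
#'
#' Per-gene totals are negative binomial with log-normally varying
#' gene means (shared across clusters; cluster structure enters only
#' through planted effects, keeping the unplanted configuration
#' exchangeable).  Multi-site genes split each cell's total across
#' isoforms by a gene-level Dirichlet usage vector via binomial
#' thinning; planted avoidance moves usage mass `delta` to the most
#' proximal site in the named cluster.  Planted FFL triples get
#' Poisson-log-normal counts sharing a latent factor (target pairwise
#' correlation `rho`) and a `de_effect` log-fold mean shift in their
#' cluster.  Gene expression is defined as the isoform sum, so
#' conservation holds exactly.
#'
#' @param config A [synthetic_config()].
#' @param graph Output of [generate_regulatory_graph()].
#' @param apa_annotation Output of [generate_apa_annotation()].
#' @param seed RNG seed (defaults to the `"cells"` substream).
#' @return List with `expr`, `apa`, `clusters`, `embedding` (or `NULL`)
#'   and `truth` (planted effects + per-gene usage vectors).
#' @export
generate_cells <- function(config, graph, apa_annotation,
                           seed = derive_seed(config$seed, "cells")) {
  ids <- synthetic_ids(config)
  labels <- config$cluster_labels
  cell_cluster <- rep(labels, each = config$cells_per_cluster)
  n_cells <- length(ids$cells)
  rows <- c(ids$genes, ids$tfs, if (config$mirna_expression) ids$mirnas)
  withr::with_seed(seed, {
    base_mean <- stats::setNames(
      stats::rlnorm(length(rows),
                    meanlog = log(config$nb_mean) - config$gene_mean_sdlog^2 / 2,
                    sdlog = config$gene_mean_sdlog), rows)
    mu <- matrix(base_mean, nrow = length(rows), ncol = n_cells,
                 dimnames = list(rows, ids$cells))
    pf <- graph$planted
    if (!is.null(pf) && nrow(pf)) {
      for (i in seq_len(nrow(pf)))
        for (node in c(pf$mirna[i], pf$tf[i], pf$gene[i]))
          if (node %in% rows)
            mu[node, cell_cluster == pf$cluster[i]] <-
              mu[node, cell_cluster == pf$cluster[i]] * exp(pf$de_effect[i])
    }
    counts <- matrix(stats::rnbinom(length(mu), size = config$nb_dispersion,
                                    mu = mu),
                     nrow = nrow(mu), dimnames = dimnames(mu))
    if (!is.null(pf) && nrow(pf)) {
      s <- config$latent_sigma
      for (i in seq_len(nrow(pf))) {
        cells_i <- which(cell_cluster == pf$cluster[i])
        u <- stats::rnorm(length(cells_i))
        for (node in c(pf$mirna[i], pf$tf[i], pf$gene[i])) {
          if (!node %in% rows) next
          eps <- stats::rnorm(length(cells_i))
          fac <- exp(s * (sqrt(pf$rho[i]) * u + sqrt(1 - pf$rho[i]) * eps) -
                       s^2 / 2)
          counts[node, cells_i] <- stats::rpois(length(cells_i),
                                                mu[node, cells_i] * fac)
        }
      }
    }

    # isoform usage
    meta <- apa_annotation$site_meta
    meta <- meta[order(meta$gene_id, meta$cleavage_pos), ]
    pa <- config$planted_avoidance
    affected <- apa_annotation$planted_site_genes
    usage_base <- list()
    usage_by_cluster <- stats::setNames(
      replicate(length(labels), list(), simplify = FALSE), labels)
    apa_values <- matrix(0, nrow = nrow(meta), ncol = n_cells,
                         dimnames = list(paste(meta$gene_id, meta$site_id, sep = ":"),
                                         ids$cells))
    for (g in unique(meta$gene_id)) {
      ridx <- which(meta$gene_id == g)
      k <- length(ridx)
      if (k == 1) {
        apa_values[ridx, ] <- counts[g, ]
        usage_base[[g]] <- 1
        next
      }
      pi_base <- rdirichlet1(rep(2, k))
      usage_base[[g]] <- pi_base
      for (lab in labels) {
        pi_lab <- pi_base
        if (!is.null(pa) && nrow(pa)) {
          for (j in seq_len(nrow(pa))) {
            if (pa$cluster[j] == lab && g %in% (affected[[pa$family[j]]] %||% character(0))) {
              shift <- numeric(k); shift[1] <- 1
              pi_lab <- (1 - pa$delta[j]) * pi_lab + pa$delta[j] * shift
            }
          }
        }
        usage_by_cluster[[lab]][[g]] <- pi_lab
        cells_l <- which(cell_cluster == lab)
        rem <- counts[g, cells_l]
        p_rem <- 1
        for (s_i in seq_len(k - 1)) {
          prob <- if (p_rem > 1e-12) min(1, pi_lab[s_i] / p_rem) else 0
          x <- stats::rbinom(length(cells_l), rem, prob)
          apa_values[ridx[s_i], cells_l] <- x
          rem <- rem - x
          p_rem <- p_rem - pi_lab[s_i]
        }
        apa_values[ridx[k], cells_l] <- rem
      }
    }

    embedding <- NULL
    if (config$embedding_dim > 0) {
      centers <- matrix(stats::rnorm(length(labels) * config$embedding_dim,
                                     sd = config$embedding_separation),
                        nrow = length(labels))
      embedding <- centers[match(cell_cluster, labels), , drop = FALSE] +
        matrix(stats::rnorm(n_cells * config$embedding_dim), nrow = n_cells)
      rownames(embedding) <- ids$cells
      colnames(embedding) <- paste0("dim", seq_len(config$embedding_dim))
    }

    expr <- expression_matrix(counts, rows, ids$cells, normalized = FALSE)
    apa <- apa_matrix(apa_values, meta, ids$cells)
    clusters <- cluster_assignment(data.frame(cell_id = ids$cells,
                                              cluster = cell_cluster))
    truth <- list(
      planted_avoidance = if (is.null(pa)) NULL else
        cbind(pa, genes = I(lapply(pa$family, function(f) affected[[f]]))),
      planted_ffls = graph$planted,
      usage_base = usage_base, usage_by_cluster = usage_by_cluster)
    list(expr = expr, apa = apa, clusters = clusters, embedding = embedding,
         truth = truth)
  })
}

#' Generate a complete synthetic input bundle
#'
#' Runs [generate_regulatory_graph()], [generate_apa_annotation()] and
#' [generate_cells()] on independent substreams of `config$seed` and
#' verifies the ground-truth invariants (planted FFL edges exist;
#' planted families carry APA-sensitive sites; isoform sums equal gene
#' expression).
#'
#' @param config A [synthetic_config()].
#' @return A `SyntheticDataset` list: `expr`, `apa`, `clusters`,
#'   `sites`, `interactions`, `embedding`, `truth`, `config`.
#' @export
simulate_dataset <- function(config = synthetic_config()) {
  graph <- generate_regulatory_graph(config)
  ann <- generate_apa_annotation(config)
  cells <- generate_cells(config, graph, ann)
  ds <- structure(c(cells[c("expr", "apa", "clusters", "embedding", "truth")],
                    list(sites = ann$sites, interactions = graph$interactions,
                         config = config)),
                  class = "SyntheticDataset")
  # ground-truth invariants
  sums <- rowsum(as.matrix(ds$apa$values), ds$apa$site_meta$gene_id)
  genes <- rownames(sums)
  stopifnot(max(abs(sums - as.matrix(ds$expr$values)[genes, ])) == 0)
  pf <- config$planted_ffls
  if (!is.null(pf) && nrow(pf)) {
    keys <- paste(ds$interactions$source_id, ds$interactions$target_id)
    stopifnot(all(paste(pf$mirna, pf$gene) %in% keys),
              all(paste(pf$tf, pf$gene) %in% keys))
  }
  pa <- config$planted_avoidance
  if (!is.null(pa) && nrow(pa)) {
    pairs <- site_isoform_pairs(ds$apa, ds$sites, multi_apa_genes(ds$apa))
    sens_fam <- unique(pairs$family_id[pairs$sensitive])
    stopifnot(all(pa$family %in% sens_fam))
  }
  ds
}

#' @export
print.SyntheticDataset <- function(x, ...) {
  cat(sprintf("SyntheticDataset: %d rows x %d cells, %d polyA sites, %d binding sites, %d edges\n",
              length(x$expr$gene_ids), length(x$expr$cell_ids),
              nrow(x$apa$site_meta), nrow(x$sites), nrow(x$interactions)))
  invisible(x)
}

#' Write a synthetic bundle to disk in the standard formats
#'
#' @param dataset A [simulate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return Named list of paths suitable for [load_dataset()], invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  expr_x <- dataset$expr
  expr_x$values <- Matrix::Matrix(as.matrix(expr_x$values), sparse = TRUE)
  apa_x <- dataset$apa
  apa_x$values <- Matrix::Matrix(as.matrix(apa_x$values), sparse = TRUE)
  paths <- list(
    expression = write_expression(expr_x, file.path(dir, "expression")),
    apa = write_apa(apa_x, file.path(dir, "apa")),
    clusters = write_clusters(dataset$clusters, file.path(dir, "clusters.tsv")),
    binding_sites = write_binding_sites(dataset$sites,
                                        file.path(dir, "binding_sites.tsv")),
    interactions = write_interactions(dataset$interactions,
                                      file.path(dir, "interactions.tsv")))
  if (!is.null(dataset$embedding))
    paths$embedding <- write_embedding(dataset$embedding,
                                       file.path(dir, "embedding.tsv"))
  truth <- dataset$truth
  truth$planted_avoidance <- if (is.null(truth$planted_avoidance)) NULL else
    as.data.frame(lapply(truth$planted_avoidance, function(col)
      if (is.list(col)) vapply(col, paste, character(1), collapse = ",") else col))
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
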