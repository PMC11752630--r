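# Background regulatory graph assembly, exhaustive SFFL enumeration and
# classification, per-cluster expression filtering, and MFFL merging.

#' Assemble the background regulatory graph
#'
#' Unions one or more interaction tables, deduplicates, and infers node
#' types from the edge kinds.  A node appearing with conflicting types
#' (e.g. TF in one table, gene in another) is an error.
#'
#' @param tables An [interaction_table()] or list of them.
#' @return A `RegulatoryGraph` list with `edges` (interaction table),
#'   `mirnas`, `tfs`, `genes` (character vectors of node IDs).
#' @export
build_background_graph <- function(tables) {
  if (is.data.frame(tables)) tables <- list(tables)
  edges <- interaction_table(do.call(rbind, lapply(tables, as.data.frame)))
  types <- rbind(data.frame(id = edges$source_id, type = edges$source_type),
                 data.frame(id = edges$target_id, type = edges$target_type))
  types <- unique(types)
  conflict <- unique(types$id[duplicated(types$id)])
  if (length(conflict))
    stop("node(s) with conflicting types: ", paste(sort(conflict), collapse = ", "))
  structure(list(edges = edges,
                 mirnas = sort(types$id[types$type == "miRNA"]),
                 tfs = sort(types$id[types$type == "TF"]),
                 genes = sort(types$id[types$type == "gene"])),
            class = "RegulatoryGraph")
}

#' @export
print.RegulatoryGraph <- function(x, ...) {
  cat(sprintf("RegulatoryGraph: %d miRNAs, %d TFs, %d genes, %d edges\n",
              length(x$mirnas), length(x$tfs), length(x$genes), nrow(x$edges)))
  invisible(x)
}

edge_keys <- function(edges, st, tt) {
  keep <- edges$source_type == st & edges$target_type == tt
  paste(edges$source_id[keep], edges$target_id[keep], sep = "\r")
}

#' Enumerate and classify all simple feed-forward loops
#'
#' An SFFL is a triple (miRNA m, TF t, gene g) with edges m->g and t->g
#' plus at least one cross-regulation edge: only m->t gives a
#' miRNA-centric loop, only t->m a TF-centric loop, both a feedback
#' loop.  Each qualifying triple is emitted exactly once, sorted by
#' (mirna, tf, gene).
#'
#' @param graph A [build_background_graph()].
#' @return Data frame with columns `mirna`, `tf`, `gene`, `class`,
#'   `has_mt`, `has_tm`.
#' @export
enumerate_sffls <- function(graph) {
  e <- graph$edges
  mg <- e[e$source_type == "miRNA" & e$target_type == "gene",
          c("source_id", "target_id")]
  tg <- e[e$source_type == "TF" & e$target_type == "gene",
          c("source_id", "target_id")]
  empty <- data.frame(mirna = character(0), tf = character(0),
                      gene = character(0), class = character(0),
                      has_mt = logical(0), has_tm = logical(0))
  if (nrow(mg) == 0 || nrow(tg) == 0) return(empty)
  names(mg) <- c("mirna", "gene"); names(tg) <- c("tf", "gene")
  cand <- merge(mg, tg, by = "gene")
  if (nrow(cand) == 0) return(empty)
  mt_set <- edge_keys(e, "miRNA", "TF")
  tm_keys <- e[e$source_type == "TF" & e$target_type == "miRNA", ]
  tm_set <- paste(tm_keys$target_id, tm_keys$source_id, sep = "\r")  # keyed m\r t
  key <- paste(cand$mirna, cand$tf, sep = "\r")
  cand$has_mt <- key %in% mt_set
  cand$has_tm <- key %in% tm_set
  cand <- cand[cand$has_mt | cand$has_tm, , drop = FALSE]
  cand$class <- ifelse(cand$has_mt & cand$has_tm, "feedback",
                       ifelse(cand$has_mt, "mirna_centric", "tf_centric"))
  cand <- cand[order(cand$mirna, cand$tf, cand$gene),
               c("mirna", "tf", "gene", "class", "has_mt", "has_tm")]
  rownames(cand) <- NULL
  cand
}

#' Filter SFFLs by per-cluster expression prevalence
#'
#' The TF and target gene must be expressed in at least the configured
#' fraction of the cluster's cells (see [expressed_genes()]).  A miRNA
#' with an expression row must pass too; miRNAs absent from the
#' expression matrix entirely are exempt, mirroring the downstream
#' scoring rule that drops absent-miRNA terms rather than the loop.
#'
#' @param sffls Output of [enumerate_sffls()].
#' @param expressed Character vector of IDs passing the cluster's filter.
#' @param mirna_present miRNA IDs that have expression rows at all
#'   (default: none, i.e. all miRNAs exempt).
#' @param cluster Cluster label to tag the surviving rows with.
#' @return The filtered data frame with a `cluster` column.
#' @export
apply_expression_filter <- function(sffls, expressed, mirna_present = character(0),
                                    cluster = NA_character_) {
  keep <- sffls$tf %in% expressed & sffls$gene %in% expressed &
    (!(sffls$mirna %in% mirna_present) | sffls$mirna %in% expressed)
  out <- sffls[keep, , drop = FALSE]
  out$cluster <- cluster
  rownames(out) <- NULL
  out
}

#' Merge significant SFFLs into module feed-forward loops
#'
#' miRNA-centric loops are grouped by their miRNA, TF-centric loops by
#' their TF; feedback loops have two centers and join both groupings.
#' Singleton groups still form an MFFL.  Each module's node set is the
#' union of its members' nodes.
#'
#' @param sffls Data frame of significant SFFLs for one cluster
#'   (columns `mirna`, `tf`, `gene`, `class`).
#' @param cluster Cluster label.
#' @return List of MFFLs: each a list with `cluster`, `center`,
#'   `center_type` (`"miRNA"` or `"TF"`), `members` (list of member
#'   rows as lists), `nodes` (sorted character vector).
#' @export
merge_mffls <- function(sffls, cluster = unique(sffls$cluster)) {
  if (nrow(sffls) == 0) return(list())
  if (length(cluster) != 1) cluster <- NA_character_
  centers <- rbind(
    data.frame(center = sffls$mirna, center_type = "miRNA",
               idx = seq_len(nrow(sffls)))[sffls$class %in% c("mirna_centric", "feedback"), ],
    data.frame(center = sffls$tf, center_type = "TF",
               idx = seq_len(nrow(sffls)))[sffls$class %in% c("tf_centric", "feedback"), ])
  grp <- split(centers$idx, paste(centers$center_type, centers$center, sep = "\r"))
  mffls <- lapply(names(grp), function(k) {
    parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
    idx <- sort(grp[[k]])
    members <- lapply(idx, function(i)
      list(mirna = sffls$mirna[i], tf = sffls$tf[i], gene = sffls$gene[i],
           class = sffls$class[i]))
    nodes <- sort(unique(c(sffls$mirna[idx], sffls$tf[idx], sffls$gene[idx])))
    list(cluster = cluster, center = parts[2], center_type = parts[1],
         members = members, nodes = nodes)
  })
  ord <- order(vapply(mffls, function(m) paste(m$center_type, m$center), character(1)))
  mffls[ord]
}
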