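# End-to-end orchestration: simulate or load inputs, per-cluster
# expression filter and DE, avoidance permutation tests, FFL build /
# score / merge, APA-loss annotation, result files and a run manifest.

#' Read and validate a pipeline configuration from YAML
#'
#' Applies the defaults of [pipeline_config()] and [synthetic_config()]
#' (under the `simulate:` key); unknown keys and out-of-range values
#' are all reported at once.
#'
#' @param path YAML file path.
#' @return A `PipelineConfig` list.
#' @export
validate_config <- function(path) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  allowed <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(raw$simulate)) {
    sim_allowed <- names(formals(synthetic_config))
    sim_unknown <- setdiff(names(raw$simulate), sim_allowed)
    if (length(sim_unknown))
      stop("unknown simulate key(s): ", paste(sim_unknown, collapse = ", "))
  }
  do.call(pipeline_config, raw)
}

log_stage <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full analysis pipeline
#'
#' Stages, in dependency order: input (simulate or load), per-cluster
#' expression filter and Wilcoxon DE, avoidance permutation tests with
#' gene-overlap summary, background-graph assembly and SFFL
#' enumeration, per-cluster SFFL filtering / scoring / MFFL merging,
#' APA-loss annotation, and optionally centroid distances.  All result
#' files plus a `manifest.json` (configuration snapshot, seed,
#' versions, per-stage wall time, per-file MD5 hashes) are written to
#' `out_dir`.  Identical configuration and seed reproduce bit-identical
#' result files.
#'
#' @param config A [pipeline_config()] with either `simulate` overrides
#'   or input `paths`, and an `out_dir`.
#' @return Invisibly, a list with the in-memory results (`dataset`,
#'   `de`, `avoidance`, `overlap`, `sffls`, `mffls`, `centroids`,
#'   `manifest`).
#' @export
run_pipeline <- function(config) {
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  timings <- list()
  clock <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  ds <- clock("input", {
    if (!is.null(config$simulate)) {
      sim_cfg <- do.call(synthetic_config,
                         utils::modifyList(list(seed = config$seed),
                                           as.list(config$simulate)))
      d <- simulate_dataset(sim_cfg)
      write_dataset(d, file.path(out_dir, "inputs"))
      d
    } else if (!is.null(config$paths)) {
      load_dataset(config$paths, config)
    } else stop("config needs either 'simulate' or 'paths'")
  })
  labs <- sort(unique(ds$clusters$cluster))
  log_stage("input", "%d cells in %d clusters; %d expression rows; %d polyA sites",
            length(ds$expr$cell_ids), length(labs), length(ds$expr$gene_ids),
            nrow(ds$apa$site_meta))

  de <- clock("de", {
    res <- lapply(labs, function(lab) wilcoxon_de(ds$expr, ds$clusters, lab))
    names(res) <- labs
    write_tsv(do.call(rbind, res), file.path(out_dir, "de_results.tsv"))
    res
  })
  log_stage("de", "tested %d genes per cluster", length(ds$expr$gene_ids))

  avoidance <- clock("avoidance", {
    res <- avoidance_test_all(ds$apa, ds$sites, ds$clusters, config)
    write_avoidance_results(res, out_dir)
    overlap <- gene_loss_overlap(avoidance_gene_sets(res))
    write_tsv(overlap, file.path(out_dir, "gene_loss_overlap.tsv"))
    list(results = res, overlap = overlap)
  })
  log_stage("avoidance", "%d testable family x cluster pairs, %d significant",
            sum(avoidance$results$testable), sum(avoidance$results$significant))

  network <- clock("ffl", {
    graph <- build_background_graph(ds$interactions)
    all_sffls <- enumerate_sffls(graph)
    log_stage("ffl", "%d candidate SFFLs in the background graph", nrow(all_sffls))
    mirna_present <- intersect(graph$mirnas, ds$expr$gene_ids)
    per_cluster <- lapply(labs, function(lab) {
      expressed <- expressed_genes(ds$expr, ds$clusters, lab, config$min_expr_frac)
      cand <- apply_expression_filter(all_sffls, expressed, mirna_present, lab)
      pools <- list(
        mirnas = sort(unique(c(intersect(graph$mirnas, expressed),
                               setdiff(graph$mirnas, ds$expr$gene_ids)))),
        tfs = intersect(graph$tfs, expressed),
        genes = intersect(graph$genes, expressed))
      scored <- sffl_permutation_test(cand, ds$expr, ds$clusters, lab,
                                      de[[lab]], pools, config)
      sig <- scored[scored$significant, , drop = FALSE]
      mffls <- merge_mffls(sig, lab)
      log_stage("ffl", "cluster %s: %d candidates, %d significant, %d MFFLs",
                lab, nrow(cand), nrow(sig), length(mffls))
      list(scored = scored, mffls = mffls)
    })
    sffls <- do.call(rbind, lapply(per_cluster, `[[`, "scored"))
    mffls <- do.call(c, lapply(per_cluster, `[[`, "mffls"))
    sffls <- annotate_apa_loss(sffls, avoidance$results, config$alpha)
    mffls <- annotate_mffl_apa_loss(mffls, avoidance$results, config$alpha)
    sig_sffls <- sffls[sffls$significant, , drop = FALSE]
    write_network_results(sig_sffls, mffls, out_dir)
    list(sffls = sffls, mffls = mffls)
  })

  centroids <- NULL
  if (!is.null(ds$embedding) && !is.null(config$centroid_ref)) {
    centroids <- clock("centroid", {
      cd <- centroid_distances(ds$embedding, ds$clusters, config$centroid_ref)
      write_tsv(cd, file.path(out_dir, "centroid_distances.tsv"))
      cd
    })
  }

  result_files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                               "manifest.json"))
  manifest <- list(
    config = config[setdiff(names(config), c("paths", "out_dir"))],
    seed = config$seed,
    versions = list(R = as.character(getRversion()),
                    apamirnet = as.character(utils::packageVersion("apamirnet"))),
    stage_seconds = timings,
    file_md5 = as.list(tools::md5sum(file.path(out_dir, result_files))))
  names(manifest$file_md5) <- result_files
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_stage("done", "results in %s", out_dir)
  invisible(list(dataset = ds, de = de, avoidance = avoidance$results,
                 overlap = avoidance$overlap, sffls = network$sffls,
                 mffls = network$mffls, centroids = centroids,
                 manifest = manifest))
}
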