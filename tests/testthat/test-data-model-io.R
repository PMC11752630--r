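test_that("containers validate their invariants", {
  m <- matrix(1:6, 3, 2, dimnames = list(c("g1", "g2", "g3"), c("c1", "c2")))
  x <- expression_matrix(m)
  expect_identical(x$gene_ids, c("g1", "g2", "g3"))
  expect_error(expression_matrix(m, gene_ids = c("g1", "g1", "g3")), "duplicate")
  expect_error(expression_matrix(-m), "non-negative")

  meta <- data.frame(gene_id = c("g1", "g1"), site_id = c("s1", "s2"),
                     cleavage_pos = c(100L, 100L))
  expect_error(apa_matrix(matrix(0, 2, 2), meta, c("c1", "c2")),
               "duplicate cleavage_pos")
  meta$site_id <- c("s1", "s1")
  expect_error(apa_matrix(matrix(0, 2, 2), meta, c("c1", "c2")),
               "duplicate \\(gene_id, site_id\\)")

  expect_error(binding_site_table(
    data.frame(family_id = "f", gene_id = "g", start = 5L, end = 5L)),
    "start < end")
  expect_error(cluster_assignment(
    data.frame(cell_id = c("c1", "c1"), cluster = c("A", "B"))),
    "more than once")
})

test_that("interaction tables accept exactly the four edge kinds", {
  ok <- data.frame(source_id = c("m1", "m1", "t1", "t1"),
                   source_type = c("miRNA", "miRNA", "TF", "TF"),
                   target_id = c("t1", "g1", "g1", "m1"),
                   target_type = c("TF", "gene", "gene", "miRNA"))
  expect_equal(nrow(interaction_table(ok)), 4)
  expect_equal(nrow(interaction_table(rbind(ok, ok))), 4)  # dedup
  bad <- data.frame(source_id = "g1", source_type = "gene",
                    target_id = "t1", target_type = "TF")
  expect_error(interaction_table(bad), "disallowed")
  self <- data.frame(source_id = "m1", source_type = "miRNA",
                     target_id = "m1", target_type = "TF")
  expect_error(interaction_table(self), "self-edges")
})

test_that("matrix formats round-trip bit-for-bit, including zero rows", {
  dir <- withr::local_tempdir()
  vals <- Matrix::sparseMatrix(i = c(1, 3), j = c(1, 2), x = c(1 / 3, 7.25),
                               dims = c(3, 2))
  x <- expression_matrix(vals, c("g1", "gzero", "g3"), c("c1", "c2"))
  p <- write_expression(x, file.path(dir, "expr"))
  y <- read_expression(p)
  expect_identical(as.matrix(x$values), as.matrix(y$values))
  expect_identical(x$gene_ids, y$gene_ids)
  expect_identical(x$cell_ids, y$cell_ids)

  dense <- expression_matrix(matrix(c(0, 1.5, 2, 0, 0, 1 / 7), 3, 2,
                                    dimnames = list(paste0("g", 1:3),
                                                    paste0("c", 1:2))))
  pd <- write_expression(dense, file.path(dir, "dense.tsv"), sparse = FALSE)
  yd <- read_expression(pd)
  expect_equal(as.matrix(dense$values), as.matrix(yd$values))

  bundle <- toy_apa_bundle()
  pa <- write_apa(bundle$apa, file.path(dir, "apa"), sparse = TRUE)
  ya <- read_apa(pa)
  expect_identical(as.matrix(bundle$apa$values), as.matrix(ya$values))
  expect_equal(bundle$apa$site_meta, ya$site_meta)
})

test_that("tables and embeddings round-trip through TSV", {
  dir <- withr::local_tempdir()
  bundle <- toy_apa_bundle()
  write_clusters(bundle$clusters, file.path(dir, "cl.tsv"))
  expect_equal(as.data.frame(read_clusters(file.path(dir, "cl.tsv"))),
               as.data.frame(bundle$clusters))
  write_binding_sites(bundle$sites, file.path(dir, "bs.tsv"))
  expect_equal(as.data.frame(read_binding_sites(file.path(dir, "bs.tsv"))),
               as.data.frame(bundle$sites))
  emb <- matrix(rnorm(8), 4, 2, dimnames = list(paste0("c", 1:4), c("d1", "d2")))
  write_embedding(emb, file.path(dir, "emb.tsv"))
  expect_equal(read_embedding(file.path(dir, "emb.tsv")), emb)
})

test_that("load_dataset validates cross-references and names offenders", {
  dir <- withr::local_tempdir()
  ds <- simulate_dataset(synthetic_config(n_genes = 20, n_tfs = 3,
                                          n_mirna_families = 5,
                                          cells_per_cluster = 5, seed = 3))
  paths <- write_dataset(ds, dir)
  bundle <- load_dataset(paths)
  expect_identical(as.matrix(bundle$expr$values), as.matrix(ds$expr$values))
  expect_equal(nrow(bundle$clusters), 10)

  cl <- rbind(as.data.frame(ds$clusters),
              data.frame(cell_id = "X", cluster = "cluster1"))
  utils::write.table(cl, paths$clusters, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(load_dataset(paths), "X")
})

test_that("avoidance results serialize with deterministic order and round-trip", {
  dir <- withr::local_tempdir()
  res <- data.frame(cluster = c("B", "A"), family = c("f2", "f1"),
                    lost = c(3, 1.5), retained = c(1, 4.5),
                    statistic = c(0.75, 0.25), p = c(0.01, 0.2),
                    p_adj = c(0.02, 0.2))
  p <- write_avoidance_results(res, dir)
  lines <- readLines(p)
  expect_length(lines, 3)  # header + 2 rows
  back <- read_avoidance_results(p)
  expect_equal(back$cluster, c("A", "B"))  # sorted
  expect_equal(back$lost, c(1.5, 3))

  p0 <- write_avoidance_results(res[0, ], dir)
  expect_length(readLines(p0), 1)  # header only
})

test_that("network results serialize; MFFL node set equals member union", {
  dir <- withr::local_tempdir()
  sffls <- data.frame(cluster = "OPC", mirna = "MIR214", tf = "JUN",
                      gene = "PTX3", class = "mirna_centric",
                      has_mt = TRUE, has_tm = FALSE,
                      score = 2.5, p = 0.001, p_adj = 0.004,
                      significant = TRUE, mirna_sites_lost_flag = TRUE)
  mffls <- merge_mffls(sffls, "OPC")
  paths <- write_network_results(sffls, mffls, dir)
  tab <- utils::read.delim(paths[["sffl"]])
  expect_equal(tab$cluster, "OPC")
  expect_equal(tab$family, "MIR214")
  expect_equal(tab$tf, "JUN")
  expect_equal(tab$gene, "PTX3")
  back <- read_mffl_results(paths[["mffl"]])
  expect_length(back, 1)
  members <- back[[1]]$members
  union_nodes <- sort(unique(unlist(lapply(members, function(m)
    c(m$mirna, m$tf, m$gene)))))
  expect_identical(back[[1]]$nodes, union_nodes)
})
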