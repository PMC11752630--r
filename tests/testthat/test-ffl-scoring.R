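test_that("node scores transform adjusted p-values through the normal quantile", {
  expect_equal(node_score(0.5), 0)
  expect_equal(node_score(0.05), 1.6449, tolerance = 1e-4)
  expect_equal(node_score(1), qnorm(1e-12), tolerance = 1e-6)  # clip floor
  p <- seq(0.001, 0.999, length.out = 50)
  expect_true(all(diff(node_score(p)) < 0))  # strictly decreasing
  expect_error(node_score(1.2), "\\[0, 1\\]")
})

test_that("edge scores follow |atanh(r)| sqrt(n-3) with clipping", {
  x <- c(1, -1, 1, -1, 0, 0)
  y <- c(1, 1, -1, -1, 2, -2)  # orthogonal, centered
  expect_equal(edge_score(x, y), 0)

  # r = 0.5, n = 28
  set.seed(2)
  a <- rnorm(28)
  b <- 0.5 * scale(a)[, 1] + sqrt(0.75) * scale(resid(lm(rnorm(28) ~ a)))[, 1]
  r <- cor(a, b)
  expect_equal(edge_score(a, b), abs(atanh(r)) * 5)
  expect_equal(abs(atanh(0.5)) * sqrt(25), 2.7465, tolerance = 1e-4)

  z <- rnorm(10)
  s1 <- edge_score(z, z)          # r = 1 hits the clip bound
  expect_true(is.finite(s1))
  expect_equal(edge_score(3 * z + 2, z), s1)  # affine invariance
  expect_warning(e0 <- edge_score(rep(1, 10), rnorm(10)), "zero-variance")
  expect_equal(e0, 0)
  expect_error(edge_score(1:3, 1:3), "n >= 4")
  expect_error(edge_score(1:5, 1:4), "equal length")
})

scoring_fixture <- function(seed = 50, n_per = 30, mirna_expression = TRUE) {
  cfg <- synthetic_config(n_genes = 40, n_tfs = 6, n_mirna_families = 6,
                          cells_per_cluster = n_per,
                          edge_prob = c(mirna_gene = 0.3, mirna_tf = 0.3,
                                        tf_gene = 0.3, tf_mirna = 0.2),
                          mirna_expression = mirna_expression, seed = seed)
  ds <- simulate_dataset(cfg)
  de <- wilcoxon_de(ds$expr, ds$clusters, "cluster1")
  list(ds = ds, de = de)
}

test_that("overall score is the mean of available entries; drop rule is consistent", {
  fx <- scoring_fixture()
  sffl <- list(mirna = "MIR001", tf = "TF001", gene = "G0001",
               has_mt = TRUE, has_tm = FALSE)
  sc <- sffl_score(sffl, fx$ds$expr, fx$ds$clusters, "cluster1", fx$de)
  entries <- c(sc$node_scores, sc$edge_scores)
  expect_equal(sc$score, mean(entries))
  expect_equal(sc$n_terms, 6)  # 3 nodes + 3 edges for miRNA-centric

  # feedback: miRNA-TF correlation counted once per directed edge
  fb <- modifyList(sffl, list(has_tm = TRUE))
  scfb <- sffl_score(fb, fx$ds$expr, fx$ds$clusters, "cluster1", fx$de)
  expect_equal(scfb$n_terms, 7)
  expect_equal(scfb$edge_scores[["mirna_tf"]], scfb$edge_scores[["tf_mirna"]])

  # blanked miRNA expression equals scoring the TF-gene substructure
  fx0 <- scoring_fixture(mirna_expression = FALSE)
  sc0 <- sffl_score(sffl, fx0$ds$expr, fx0$ds$clusters, "cluster1", fx0$de)
  expect_equal(sc0$n_terms, 3)
  expect_named(sc0$node_scores, c("tf", "gene"))
  expect_named(sc0$edge_scores, "tf_gene")
  expect_equal(sc0$score,
               mean(c(sc0$node_scores, sc0$edge_scores[["tf_gene"]])))
})

test_that("a planted coherent triple scores above the median random triple", {
  pf <- data.frame(cluster = "cluster1", mirna = "MIR001", tf = "TF001",
                   gene = "G0001", rho = 0.9, de_effect = 1.5)
  cfg <- synthetic_config(n_genes = 60, n_tfs = 8, n_mirna_families = 8,
                          cells_per_cluster = 100, planted_ffls = pf, seed = 60)
  ds <- simulate_dataset(cfg)
  de <- wilcoxon_de(ds$expr, ds$clusters, "cluster1")
  planted_s <- sffl_score(list(mirna = "MIR001", tf = "TF001", gene = "G0001",
                               has_mt = TRUE, has_tm = FALSE),
                          ds$expr, ds$clusters, "cluster1", de)$score
  rand <- withr::with_seed(61, {
    replicate(200, sffl_score(
      list(mirna = sample(sprintf("MIR%03d", 2:8), 1),
           tf = sample(sprintf("TF%03d", 2:8), 1),
           gene = sample(sprintf("G%04d", 2:60), 1),
           has_mt = TRUE, has_tm = FALSE),
      ds$expr, ds$clusters, "cluster1", de)$score)
  })
  expect_gt(planted_s, median(rand))
})

test_that("uniform context forces permutation p = 1 for every loop", {
  n <- 20
  vals <- matrix(5, 6, 2 * n,
                 dimnames = list(c("m1", "m2", "t1", "t2", "g1", "g2"),
                                 paste0("c", 1:(2 * n))))
  expr <- expression_matrix(vals, rownames(vals), colnames(vals))
  cl <- cluster_assignment(data.frame(cell_id = colnames(vals),
                                      cluster = rep(c("A", "B"), each = n)))
  de <- data.frame(cluster = "A", gene_id = rownames(vals), p = 1, p_adj = 1)
  sffls <- data.frame(mirna = "m1", tf = "t1", gene = "g1",
                      class = "mirna_centric", has_mt = TRUE, has_tm = FALSE,
                      cluster = "A")
  pools <- list(mirnas = c("m1", "m2"), tfs = c("t1", "t2"),
                genes = c("g1", "g2"))
  cfg <- pipeline_config(n_permutations = 100, seed = 4)
  suppressWarnings(
    scored <- sffl_permutation_test(sffls, expr, cl, "A", de, pools, cfg))
  expect_equal(scored$p, 1)
})

test_that("Monte-Carlo SFFL p agrees with exhaustive triple enumeration", {
  fx <- scoring_fixture(seed = 70, n_per = 25)
  pools <- list(mirnas = c("MIR001", "MIR002"), tfs = c("TF001", "TF002"),
                genes = c("G0001", "G0002"))
  sffls <- data.frame(mirna = "MIR001", tf = "TF001", gene = "G0001",
                      class = "mirna_centric", has_mt = TRUE, has_tm = FALSE,
                      cluster = "cluster1")
  cfg <- pipeline_config(n_permutations = 10000, seed = 5)
  scored <- sffl_permutation_test(sffls, fx$ds$expr, fx$ds$clusters, "cluster1",
                                  fx$de, pools, cfg)
  combos <- expand.grid(m = pools$mirnas, t = pools$tfs, g = pools$genes,
                        stringsAsFactors = FALSE)
  all8 <- vapply(seq_len(8), function(i)
    sffl_score(list(mirna = combos$m[i], tf = combos$t[i], gene = combos$g[i],
                    has_mt = TRUE, has_tm = FALSE),
               fx$ds$expr, fx$ds$clusters, "cluster1", fx$de)$score,
    numeric(1))
  exact_p <- mean(all8 >= scored$score)
  tol <- 3 * sqrt(exact_p * (1 - exact_p) / cfg$n_permutations) +
    2 / cfg$n_permutations
  expect_lt(abs(scored$p - exact_p), tol)
})

test_that("SFFL p-values are deterministic and order-independent", {
  fx <- scoring_fixture(seed = 80)
  graph <- build_background_graph(fx$ds$interactions)
  sffls <- enumerate_sffls(graph)
  expect_gte(nrow(sffls), 2)
  expressed <- expressed_genes(fx$ds$expr, fx$ds$clusters, "cluster1", 0)
  cand <- apply_expression_filter(sffls, expressed,
                                  intersect(graph$mirnas, fx$ds$expr$gene_ids),
                                  "cluster1")
  pools <- list(mirnas = graph$mirnas, tfs = graph$tfs, genes = graph$genes)
  cfg <- pipeline_config(n_permutations = 200, seed = 6)
  s1 <- sffl_permutation_test(cand, fx$ds$expr, fx$ds$clusters, "cluster1",
                              fx$de, pools, cfg)
  shuffled <- cand[rev(seq_len(nrow(cand))), ]
  s2 <- sffl_permutation_test(shuffled, fx$ds$expr, fx$ds$clusters, "cluster1",
                              fx$de, pools, cfg)
  expect_identical(s1$p, s2$p)  # both return sorted (mirna, tf, gene)
  expect_identical(s1$mirna, s2$mirna)
})

test_that("APA-loss annotation joins on (cluster, family) with warnings", {
  avoidance <- data.frame(cluster = c("OPC", "OPC"),
                          family = c("MIR214", "MIR9"),
                          p_adj = c(0.01, 0.8))
  sffls <- data.frame(cluster = c("OPC", "OPC", "Neo"),
                      mirna = c("MIR214", "MIR9", "MIR214"),
                      tf = "JUN", gene = "PTX3")
  expect_warning(out <- annotate_apa_loss(sffls, avoidance, 0.05), "Neo")
  expect_equal(out$mirna_sites_lost_flag, c(TRUE, FALSE, FALSE))

  mffls <- list(list(cluster = "OPC", center = "MIR214", center_type = "miRNA",
                     members = list(list(mirna = "MIR214", tf = "JUN",
                                         gene = "PTX3", class = "mirna_centric")),
                     nodes = c("JUN", "MIR214", "PTX3")))
  ann <- annotate_mffl_apa_loss(mffls, avoidance, 0.05)
  expect_true(ann[[1]]$apa_loss_center)
  expect_true(ann[[1]]$apa_loss_any)
})
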