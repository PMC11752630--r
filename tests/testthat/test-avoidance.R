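test_that("site fate is retained only when wholly upstream of cleavage", {
  expect_equal(site_fate(150, 157, 100), "lost")
  expect_equal(site_fate(150, 157, 157), "retained")  # boundary
  expect_equal(site_fate(150, 157, 156), "lost")      # one base truncated
  expect_error(site_fate(150, 150, 100))              # start < end required
})

test_that("lost/retained masses follow the worked two-isoform example", {
  bundle <- toy_apa_bundle(values = rbind(c(20, 10, 0, 0),
                                          c(4, 6, 0, 0),
                                          c(1, 1, 1, 1)))
  # cluster A cells c1,c2: proximal sum 30, distal sum 10
  lr <- family_lost_retained(bundle$apa, bundle$sites, c("c1", "c2"), "GA")
  fa <- lr[lr$family_id == "FAMA", ]
  expect_equal(c(fa$lost, fa$retained), c(30, 10))
  expect_equal(avoidance_statistic(fa$lost, fa$retained), 0.75)
  # FAMB upstream of both cleavages: never lost
  fb <- lr[lr$family_id == "FAMB", ]
  expect_equal(fb$lost, 0)
  expect_equal(fb$retained, 40)
})

test_that("lost/retained masses equal a brute-force quadruple loop", {
  set.seed(99)
  meta <- data.frame(gene_id = rep(c("g1", "g2", "g3"), times = c(2, 3, 2)),
                     site_id = c("s1", "s2", "s1", "s2", "s3", "s1", "s2"),
                     cleavage_pos = c(100L, 200L, 50L, 150L, 400L, 80L, 300L))
  vals <- matrix(rpois(7 * 6, 4), 7, 6,
                 dimnames = list(NULL, paste0("c", 1:6)))
  apa <- apa_matrix(vals, meta, paste0("c", 1:6))
  starts <- sample(0:380, 8)
  sites <- binding_site_table(data.frame(
    family_id = sample(c("fA", "fB"), 8, replace = TRUE),
    gene_id = sample(c("g1", "g2", "g3"), 8, replace = TRUE),
    start = starts, end = starts + 7L))
  cells <- c("c1", "c3", "c4")
  eligible <- c("g1", "g2", "g3")
  got <- family_lost_retained(apa, sites, cells, eligible)
  # oracle: exhaustive loop over (gene, isoform, site, cell)
  for (fam in unique(sites$family_id)) {
    L <- 0; R <- 0
    for (i in seq_len(nrow(meta))) {
      g <- meta$gene_id[i]
      if (!g %in% eligible) next
      fs <- sites[sites$gene_id == g & sites$family_id == fam, , drop = FALSE]
      for (b in seq_len(nrow(fs))) for (cc in cells) {
        if (site_fate(fs$start[b], fs$end[b], meta$cleavage_pos[i]) == "lost")
          L <- L + unname(vals[i, cc]) else R <- R + unname(vals[i, cc])
      }
    }
    row <- got[got$family_id == fam, ]
    if (nrow(row)) expect_equal(c(row$lost, row$retained), c(L, R))
    else expect_equal(L + R, 0)
  }
})

test_that("lost fraction orders families exactly like the lost/retained ratio", {
  set.seed(5)
  L <- runif(1000, 0, 10); R <- runif(1000, 0.01, 10)
  frac <- avoidance_statistic(L, R)
  expect_equal(order(frac), order(L / R))
  expect_equal(avoidance_statistic(0, 3), 0)
  expect_true(is.na(avoidance_statistic(0, 0)))
})

test_that("weighted masses are invariant to cell order and additive", {
  bundle <- toy_apa_bundle()
  a <- family_lost_retained(bundle$apa, bundle$sites, c("c1", "c2", "c3"), "GA")
  b <- family_lost_retained(bundle$apa, bundle$sites, c("c3", "c1", "c2"), "GA")
  expect_equal(a, b)
  p1 <- family_lost_retained(bundle$apa, bundle$sites, c("c1", "c2"), "GA")
  p2 <- family_lost_retained(bundle$apa, bundle$sites, "c3", "GA")
  expect_equal(a$lost, p1$lost + p2$lost)
  expect_equal(a$retained, p1$retained + p2$retained)
})

test_that("identical cells give permutation p = 1 for every family", {
  vals <- rbind(rep(5, 4), rep(2, 4), rep(1, 4))
  bundle <- toy_apa_bundle(values = vals)
  cfg <- pipeline_config(n_permutations = 200, min_expr_frac = 0, seed = 1)
  res <- avoidance_permutation_test(bundle$apa, bundle$sites, bundle$clusters,
                                    "A", cfg)
  expect_true(all(res$p[res$testable] == 1))
})

test_that("Monte-Carlo permutation p agrees with exhaustive labeling enumeration", {
  bundle <- toy_apa_bundle()  # 4 cells, clusters 2 + 2
  cfg <- pipeline_config(n_permutations = 10000, min_expr_frac = 0, seed = 3)
  res <- avoidance_permutation_test(bundle$apa, bundle$sites, bundle$clusters,
                                    "A", cfg)
  fa <- res[res$family == "FAMA", ]
  stats <- exact_avoidance_stats(bundle$apa, bundle$sites, "FAMA", "GA", 2)
  exact_p <- mean(stats >= fa$statistic)
  tol <- 3 * sqrt(exact_p * (1 - exact_p) / cfg$n_permutations) + 2 / cfg$n_permutations
  expect_lt(abs(fa$p - exact_p), tol)
})

test_that("avoidance results are deterministic and relabeling-invariant", {
  ds <- simulate_dataset(synthetic_config(n_genes = 80, n_tfs = 5,
                                          n_mirna_families = 20,
                                          cells_per_cluster = 25, seed = 8))
  cfg <- pipeline_config(n_permutations = 300, seed = 8)
  r1 <- avoidance_permutation_test(ds$apa, ds$sites, ds$clusters, "cluster1", cfg)
  r2 <- avoidance_permutation_test(ds$apa, ds$sites, ds$clusters, "cluster1", cfg)
  expect_identical(r1$p, r2$p)

  renamed <- ds$clusters
  renamed$cluster <- c(cluster1 = "zeta", cluster2 = "alpha")[renamed$cluster]
  r3 <- avoidance_permutation_test(ds$apa, ds$sites,
                                   cluster_assignment(renamed), "zeta", cfg)
  expect_equal(r1$p, r3$p)
  expect_equal(r1$statistic, r3$statistic)
})

test_that("binary mode counts used isoforms at the prevalence threshold", {
  vals <- rbind(c(10, 20, 1, 2), c(0, 0, 9, 7), c(5, 5, 5, 5))
  bundle <- toy_apa_bundle(values = vals)
  # cluster A (c1, c2): distal isoform undetected -> not used
  lr <- family_lost_retained(bundle$apa, bundle$sites, c("c1", "c2"), "GA",
                             mode = "binary")
  fa <- lr[lr$family_id == "FAMA", ]
  expect_equal(c(fa$lost, fa$retained), c(1, 0))
  lr2 <- family_lost_retained(bundle$apa, bundle$sites, c("c3", "c4"), "GA",
                              mode = "binary")
  fa2 <- lr2[lr2$family_id == "FAMA", ]
  expect_equal(c(fa2$lost, fa2$retained), c(1, 1))
})

test_that("gene overlap counts match inclusion-exclusion on Venn regions", {
  ov <- gene_loss_overlap(list(A = c("g1", "g2"), B = c("g2", "g3")))
  expect_equal(ov$count[ov$clusters == "A"], 1)
  expect_equal(ov$count[ov$clusters == "B"], 1)
  expect_equal(ov$count[ov$clusters == "A&B"], 1)

  identical_sets <- gene_loss_overlap(list(X = c("a", "b"), Y = c("a", "b")))
  expect_equal(nrow(identical_sets), 1)
  expect_equal(identical_sets$clusters, "X&Y")

  set.seed(21)
  sets <- lapply(1:3, function(i) sample(paste0("g", 1:20), sample(3:15, 1)))
  names(sets) <- c("P", "Q", "R")
  ov3 <- gene_loss_overlap(sets)
  # oracle: brute-force membership tabulation
  genes <- sort(unique(unlist(sets)))
  expected <- table(vapply(genes, function(g)
    paste(names(sets)[vapply(sets, function(s) g %in% s, logical(1))],
          collapse = "&"), character(1)))
  for (k in names(expected))
    expect_equal(ov3$count[ov3$clusters == k], as.integer(expected[[k]]))
  expect_equal(sum(ov3$count), length(genes))
})
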