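# Transcriptome processing, co-expression clustering, cluster maps,
# gene-trait networks.

test_that("single-donor single-sample mapping is plain z-scoring", {
  set.seed(1)
  regions <- paste0("r", 1:6)
  samples <- data.frame(donor = "d1", region = regions)
  expr <- matrix(rnorm(6 * 5), 6, dimnames = list(NULL, paste0("g", 1:5)))
  em <- map_samples_to_regions(samples, expr,
                               regions = data.frame(region = regions,
                                                    hemisphere = rep(c("L", "R"), 3)))
  expect_equal(unname(em$values), unname(rowz(t(expr))), tolerance = 1e-12)
})

test_that("duplicate samples and donor medians behave as stated", {
  regions <- paste0("r", 1:3)
  expr1 <- matrix(1:9, 3, dimnames = list(NULL, paste0("g", 1:3)))
  # duplicating a sample leaves the region mean unchanged
  s1 <- data.frame(donor = "d1", region = regions)
  s2 <- data.frame(donor = "d1", region = c(regions, "r1"))
  e2 <- rbind(expr1, expr1[1, ])
  m1 <- map_samples_to_regions(s1, expr1)
  m2 <- map_samples_to_regions(s2, e2)
  expect_equal(m1$values, m2$values)
  # median over donors {x, x, y} is x
  s3 <- data.frame(donor = rep(c("d1", "d2", "d3"), each = 3),
                   region = rep(regions, 3))
  e3 <- rbind(expr1, expr1, expr1 + 10)
  m3 <- map_samples_to_regions(s3, e3)
  expect_equal(m3$values, m1$values)
})

test_that("coordinate mapping respects the atlas and the distance bound", {
  labs <- array(0L, c(6, 4, 4))
  labs[1:3, , ] <- 1L; labs[4:6, , ] <- 2L
  atlas <- region_atlas(labs, c(`1` = "left", `2` = "right"),
                        hemisphere = c("L", "R"), voxdim = c(2, 2, 2))
  samples <- data.frame(donor = "d1",
                        x = c(1, 9, 50), y = c(1, 1, 1), z = c(1, 1, 1))
  expr <- matrix(rnorm(9), 3, dimnames = list(NULL, paste0("g", 1:3)))
  # both regions get a sample; the far sample is silently out of range
  expect_no_warning(em <- map_samples_to_regions(samples, expr, atlas = atlas))
  expect_identical(colnames(em$values), c("left", "right"))
})

test_that("co-expression has the exact self, negation and block properties", {
  em <- generate_expression(expression_truth(n_genes = 40, k_clusters = 4,
                                             within_cluster_corr = 0.8, seed = 2))
  vals <- em$values
  vals[2, ] <- vals[1, ]
  vals[3, ] <- -vals[1, ]
  C <- coexpression(vals)
  expect_equal(C[1, 2], 1, tolerance = 1e-12)
  expect_equal(C[1, 3], -1, tolerance = 1e-12)
  C0 <- coexpression(em)
  same <- outer(em$clusters, em$clusters, "==") & upper.tri(C0)
  diff <- (!outer(em$clusters, em$clusters, "==")) & upper.tri(C0)
  expect_gt(mean(C0[same]), mean(C0[diff]))
})

test_that("anti-correlated blocks are split at k = 2 with high silhouette", {
  set.seed(3)
  u <- rnorm(30)
  vals <- rbind(matrix(rep(u, 10), 10, byrow = TRUE),
                matrix(rep(-u, 10), 10, byrow = TRUE)) +
    matrix(rnorm(600, 0, 0.05), 20)
  rownames(vals) <- paste0("g", 1:20)
  cl <- cluster_genes(coexpression(vals), k_range = 2:6)
  expect_identical(cl$k, 2L)
  expect_gt(max(cl$silhouette), 0.9)
  expect_identical(length(unique(cl$labels[1:10])), 1L)
})

test_that("clustering is invariant to gene order and validates k_range", {
  em <- generate_expression(expression_truth(n_genes = 60, k_clusters = 3,
                                             within_cluster_corr = 0.8, seed = 4))
  C <- coexpression(em)
  cl1 <- cluster_genes(C, k_range = 2:6)
  perm <- sample(60)
  cl2 <- cluster_genes(C[perm, perm], k_range = 2:6)
  expect_identical(cl2$k, cl1$k)
  expect_equal(adjusted_rand_index(cl2$labels, cl1$labels[perm]), 1)
  expect_error(cluster_genes(C, k_range = 1:5), "k_range")
  expect_error(cluster_genes(C, k_range = 2:60), "k_range")
})

test_that("adjusted Rand agrees with the mclust implementation", {
  set.seed(5)
  for (i in 1:5) {
    a <- sample(1:4, 50, replace = TRUE)
    b <- sample(1:3, 50, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(1:10, rev(1:10)), 1)
})

test_that("cluster maps are z-scored per hemisphere and keep single genes", {
  em <- generate_expression(expression_truth(n_genes = 30, n_regions = 20,
                                             k_clusters = 3,
                                             within_cluster_corr = 0.8, seed = 6))
  labels <- em$clusters
  labels[1] <- 99L  # isolate one gene in its own cluster
  maps <- cluster_maps(em, labels)
  hemi <- em$regions$hemisphere
  for (h in c("L", "R")) {
    expect_equal(unname(rowMeans(maps[, hemi == h])), rep(0, nrow(maps)),
                 tolerance = 1e-12)
    expect_equal(unname(apply(maps[, hemi == h], 1, sd)), rep(1, nrow(maps)),
                 tolerance = 1e-12)
  }
  single_raw <- em$values[1, ]
  manual <- single_raw
  for (h in c("L", "R")) manual[hemi == h] <- scale(single_raw[hemi == h])[, 1]
  expect_equal(unname(maps["cluster_99", ]), unname(manual), tolerance = 1e-12)
})

test_that("a planted right-hemisphere bias shows up in the raw cluster means", {
  em <- generate_expression(expression_truth(n_genes = 60, k_clusters = 2,
                                             within_cluster_corr = 0.8,
                                             right_bias = c(1.5, 0), seed = 7))
  raw <- cluster_maps(em, em$clusters, rescale = FALSE)
  hemi <- em$regions$hemisphere
  expect_gt(mean(raw["cluster_1", hemi == "R"]),
            mean(raw["cluster_1", hemi == "L"]))
})

test_that("gene-trait networks take the best p and reject weak associations", {
  dmap <- data.frame(trait = c("t_tangle", "t_plaque", "t_memory"),
                     domain = c("tau", "amyloid", "cognition"))
  tab <- data.frame(gene = c("G1", "G1", "G1", "G2", "G3"),
                    trait = c("t_tangle", "t_tangle", "t_plaque", "t_memory",
                              "ignored_trait"),
                    p = c(1e-8, 1e-6, 1e-7, 1e-9, 1e-12))
  net <- gene_trait_network(tab, dmap)
  expect_equal(net$edges$weight[net$edges$gene == "G1" &
                                  net$edges$trait == "t_tangle"], 1e-8)
  expect_equal(net$domain_edges$weight[net$domain_edges$gene == "G1" &
                                         net$domain_edges$domain == "tau"], 1e-8)
  expect_false("G3" %in% net$edges$gene)  # trait outside the domain map
  expect_warning(gene_trait_network(rbind(tab, data.frame(gene = "G4",
                                                          trait = "t_tangle",
                                                          p = 1e-4)), dmap),
                 "rejected")
  empty <- gene_trait_network(tab[0, ], dmap)
  expect_identical(nrow(empty$edges), 0L)
})

test_that("planted four-cluster expression is recovered by silhouette", {
  em <- generate_expression(expression_truth(n_genes = 200, k_clusters = 4,
                                             within_cluster_corr = 0.8, seed = 8))
  cl <- cluster_genes(coexpression(em), k_range = 2:8)
  expect_identical(cl$k, 4L)
  expect_gte(adjusted_rand_index(cl$labels, em$clusters), 0.9)
})

test_that("re-z-scoring an expression matrix is idempotent", {
  em <- generate_expression(expression_truth(n_genes = 25, seed = 9))
  expect_equal(unname(rowz(em$values)), unname(em$values), tolerance = 1e-12)
})
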