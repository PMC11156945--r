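# Directional spreading graph, node degrees, PC skeleton, orientation.

test_that("connectivity r equals the residualize-then-correlate oracle", {
  set.seed(1)
  n <- 45
  B <- matrix(rnorm(n * 4), n, dimnames = list(NULL, c("A", "B", "C", "D")))
  f <- B + matrix(rnorm(n * 4, 0, 0.3), n)
  colnames(f) <- colnames(B)
  covs <- data.frame(age = rnorm(n), sex = rbinom(n, 1, 0.5))
  g <- tau_connectivity(tau_panel(B, f, 2.5), covariates = covs)
  for (i in colnames(B)) for (j in colnames(B)) {
    if (i == j) next
    Z <- cbind(B[, j], as.matrix(covs))
    expect_equal(g$r[i, j], pcor_resid(B[, i], f[, j], Z), tolerance = 1e-10)
  }
})

test_that("no-progression data is reported as degenerate, not significant", {
  set.seed(2)
  B <- matrix(rnorm(120), 40, dimnames = list(NULL, c("A", "B", "C")))
  g <- tau_connectivity(tau_panel(B, B, 2))
  expect_true(all(g$degenerate))
  expect_true(all(is.na(g$r)))
  expect_false(any(g$adjacency))
})

test_that("connectivity is invariant to affine rescaling of a region", {
  set.seed(3)
  n <- 60
  B <- matrix(rnorm(n * 3), n, dimnames = list(NULL, c("A", "B", "C")))
  f <- B + matrix(rnorm(n * 3, 0, 0.4), n); colnames(f) <- colnames(B)
  g1 <- tau_connectivity(tau_panel(B, f, 2))
  B2 <- B; B2[, "A"] <- 100 + 7 * B2[, "A"]
  f2 <- f; f2[, "A"] <- 100 + 7 * f2[, "A"]
  g2 <- tau_connectivity(tau_panel(B2, f2, 2))
  expect_equal(abs(g1$r), abs(g2$r), tolerance = 1e-10)
})

test_that("extra baseline-side nodes act as sources only", {
  set.seed(4)
  n <- 50
  B <- matrix(rnorm(n * 3), n, dimnames = list(NULL, c("A", "B", "C")))
  f <- B + matrix(rnorm(n * 3, 0, 0.4), n); colnames(f) <- colnames(B)
  drn <- matrix(rnorm(n), n, dimnames = list(NULL, "DRN_MD"))
  g <- tau_connectivity(tau_panel(B, f, 2, extra = drn))
  expect_true("DRN_MD" %in% rownames(g$r))
  expect_false("DRN_MD" %in% colnames(g$r))
  deg <- node_degrees(g)
  expect_identical(deg$in_degree[deg$region == "DRN_MD"], 0)
})

test_that("weighted degrees follow the edge weights", {
  set.seed(5)
  B <- matrix(rnorm(200), 50, dimnames = list(NULL, c("A", "B", "C", "D")))
  f <- B + matrix(rnorm(200, 0, 0.5), 50); colnames(f) <- colnames(B)
  g <- tau_connectivity(tau_panel(B, f, 2))
  g$adjacency[] <- FALSE
  deg0 <- node_degrees(g)
  expect_true(all(deg0$out_degree == 0) && all(deg0$in_degree == 0))
  g$adjacency["A", "B"] <- TRUE
  deg1 <- node_degrees(g)
  expect_equal(deg1$out_degree[deg1$region == "A"], abs(g$r["A", "B"]))
  expect_equal(deg1$in_degree[deg1$region == "B"], abs(g$r["A", "B"]))
})

test_that("panel construction enforces matching shapes and intervals", {
  B <- matrix(rnorm(30), 10, dimnames = list(NULL, c("A", "B", "C")))
  expect_error(tau_panel(B, B[, 1:2], 2), "share")
  expect_error(tau_panel(B, B, 0), "interval")
  expect_error(tau_connectivity(tau_panel(B, B + rnorm(30), 2)), "too few")
})

test_that("the PC skeleton matches brute-force testing on small graphs", {
  gen <- list(
    chain3 = function(n) {
      A <- rnorm(n); B <- 0.8 * A + 0.6 * rnorm(n); C <- 0.8 * B + 0.6 * rnorm(n)
      cbind(A = A, B = B, C = C)
    },
    collider = function(n) {
      A <- rnorm(n); B <- rnorm(n); C <- 0.7 * A + 0.7 * B + 0.5 * rnorm(n)
      cbind(A = A, B = B, C = C)
    },
    independent4 = function(n) {
      matrix(rnorm(4 * n), n, dimnames = list(NULL, LETTERS[1:4]))
    },
    diamond = function(n) {
      A <- rnorm(n); B <- 0.8 * A + 0.6 * rnorm(n); C <- 0.8 * A + 0.6 * rnorm(n)
      D <- 0.6 * B + 0.6 * C + 0.5 * rnorm(n)
      cbind(A = A, B = B, C = C, D = D)
    })
  for (nm in names(gen)) {
    set.seed(match(nm, names(gen)) * 13)
    data <- gen[[nm]](1000)
    sk <- pc_skeleton(data, alpha = 0.05)
    expect_equal(unname(sk$edges), unname(brute_skeleton(data, alpha = 0.05)),
                 label = paste("skeleton for", nm))
  }
})

test_that("a linear chain is pruned to its backbone with the right sepset", {
  set.seed(6)
  n <- 500
  A <- rnorm(n); B <- 0.8 * A + 0.6 * rnorm(n); C <- 0.8 * B + 0.6 * rnorm(n)
  sk <- pc_skeleton(cbind(A = A, B = B, C = C))
  expect_false(sk$edges["A", "C"])
  expect_true(sk$edges["A", "B"] && sk$edges["B", "C"])
  expect_identical(sk$sepsets[["A|C"]], "B")
})

test_that("the skeleton is a subgraph of the marginal correlation graph", {
  set.seed(7)
  data <- matrix(rnorm(200 * 6), 200)
  data[, 2] <- data[, 1] + 0.5 * rnorm(200)
  data[, 3] <- data[, 2] + 0.5 * rnorm(200)
  colnames(data) <- LETTERS[1:6]
  sk <- pc_skeleton(data, alpha = 0.05)
  n <- nrow(data)
  for (i in 1:5) for (j in (i + 1):6) {
    if (sk$edges[i, j]) {
      expect_lt(fisher_p(cor(data[, i], data[, j]), n, 0), 0.05)
    }
  }
})

test_that("tiny samples are refused for the Fisher-z test", {
  data <- matrix(rnorm(4 * 3), 4, dimnames = list(NULL, c("A", "B", "C")))
  expect_error(pc_skeleton(data), "sample too small")
})

test_that("backbone orientation mirrors the bipartite graph", {
  set.seed(8)
  B <- matrix(rnorm(150), 50, dimnames = list(NULL, c("A", "B", "C")))
  f <- B + matrix(rnorm(150, 0, 0.5), 50); colnames(f) <- colnames(B)
  g <- tau_connectivity(tau_panel(B, f, 2))
  sk <- pc_skeleton(B, alpha = 0.9)  # keep some edges to orient
  g$adjacency[] <- FALSE
  und <- orient_backbone(sk, g)
  expect_true(all(und$oriented == "undirected"))
  g$adjacency["A", "B"] <- TRUE
  one <- orient_backbone(sk, g)
  ab <- one$oriented_edges$direction[one$oriented_edges$from == "A" &
                                       one$oriented_edges$to == "B"]
  if (length(ab)) expect_identical(ab, "forward")
  g$adjacency["B", "A"] <- TRUE
  both <- orient_backbone(sk, g)
  ab2 <- both$oriented_edges$direction[both$oriented_edges$from == "A" &
                                         both$oriented_edges$to == "B"]
  if (length(ab2)) expect_identical(ab2, "both")
})

test_that("planted spreading structure is recovered end to end", {
  tr <- spread_truth()
  co <- quick_cohort(89, seed = 9)
  pan <- generate_regional_tau(co, tr, seed = 10)
  g <- tau_connectivity(pan, covariates = co[c(default_covariates, "interval")])
  planted <- paste(tr$edges$from, tr$edges$to)
  for (e in seq_len(nrow(tr$edges))) {
    expect_true(g$adjacency[tr$edges$from[e], tr$edges$to[e]])
    expect_false(g$adjacency[tr$edges$to[e], tr$edges$from[e]])
  }
  deg <- node_degrees(g)
  # sources of planted edges dominate out-degree
  top <- deg$region[which.max(deg$out_degree)]
  expect_true(top %in% tr$edges$from)
})
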