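# Voxel-wise GLM engine, smoothness estimation, Monte-Carlo nulls.

test_that("the voxel GLM matches lm() at a single voxel", {
  set.seed(1)
  n <- 45
  tab <- data.frame(age = rnorm(n, 70, 8), sex = rbinom(n, 1, 0.5),
                    smoking = rbinom(n, 1, 0.3))
  x <- rnorm(n)
  y <- 0.4 * x + 0.05 * tab$age + rnorm(n)
  design <- build_design(tab, x, c("age", "sex", "smoking"),
                         predictor_name = "x")
  map <- fit_voxel_glm(volume_set(matrix(y, ncol = 1)), design)
  ref <- summary(lm(y ~ x + age + sex + smoking, data = tab))$coefficients
  expect_equal(map$t, unname(ref["x", "t value"]), tolerance = 1e-10)
  expect_equal(map$p, unname(ref["x", "Pr(>|t|)"]), tolerance = 1e-10)
  expect_equal(map$df, n - 5L)
})

test_that("Z is the sign-preserving normal transform of the t p-value", {
  set.seed(2)
  vol <- noise_volume(30, d = c(8, 8, 4))
  tab <- data.frame(age = rnorm(30, 70, 8))
  design <- build_design(tab, rnorm(30), "age", predictor_name = "x")
  map <- fit_voxel_glm(vol, design)
  expect_equal(2 * pnorm(-abs(map$z)), map$p, tolerance = 1e-12)
  expect_identical(sign(map$z), sign(map$t))
  expect_identical(order(map$z), order(map$t))
})

test_that("an exact fit is reported as a capped Z with a flag", {
  x <- rnorm(20)
  tab <- data.frame(dummy = rnorm(20))
  design <- build_design(tab, x, predictor_name = "x")
  vol <- volume_set(cbind(x, rnorm(20)))
  map <- fit_voxel_glm(vol, design)
  expect_true(map$capped[1])
  expect_false(map$capped[2])
  expect_true(is.finite(map$z[1]))
})

test_that("a permuted predictor produces a calibrated voxel null", {
  set.seed(3)
  n <- 50
  vol <- volume_set(matrix(rnorm(n * 2000), n))
  tab <- data.frame(age = rnorm(n, 70, 8))
  design <- build_design(tab, sample(rnorm(n)), "age", predictor_name = "x")
  map <- fit_voxel_glm(vol, design)
  expect_gt(mean(map$p < 0.05), 0.03)
  expect_lt(mean(map$p < 0.05), 0.075)
})

test_that("rank-deficient designs fail before any voxel is fit", {
  x <- rnorm(20)
  X <- cbind(`(Intercept)` = 1, x = x, x2 = x)
  attr(X, "predictor") <- "x"
  expect_error(fit_voxel_glm(noise_volume(20), X), "rank deficient")
})

test_that("smoothness estimation recovers white and smoothed fields", {
  set.seed(4)
  d <- c(20, 20, 20)
  white <- noise_volume(25, d = d)
  fw <- estimate_smoothness(white)
  expect_lt(abs(fw - 2) / 2, 0.2)  # ~ voxel size
  arrs <- t(sapply(1:25, function(i) {
    as.vector(gaussian_smooth_3d(array(rnorm(prod(d)), d), 6, c(2, 2, 2)))
  }))
  fw6 <- estimate_smoothness(volume_set(arrs, dim = d))
  expect_lt(abs(fw6 - sqrt(36 + 4)) / sqrt(36 + 4), 0.15)
})

test_that("smoothness estimation refuses degenerate input", {
  expect_error(estimate_smoothness(
    volume_set(matrix(1, 3, 1000), dim = c(10, 10, 10))), "constant")
  expect_error(estimate_smoothness(noise_volume(3, d = c(4, 4, 4))),
               "mask too small")
})

test_that("the odorant-count null behaves at its limits and repeats under a seed", {
  mask <- array(TRUE, c(6, 6, 6))
  tiny <- odorant_count_null(mask, 2, n_iter = 200, alpha = 1e-12, seed = 5)
  expect_identical(tiny$threshold_count, 1L)
  a <- odorant_count_null(mask, 2, n_iter = 150, seed = 6)
  b <- odorant_count_null(mask, 2, n_iter = 150, seed = 6)
  expect_identical(a$max_counts, b$max_counts)
  expect_error(odorant_count_null(mask, 2, n_iter = 50), "unstable")
})

test_that("unsmoothed count nulls match the binomial law", {
  nul <- odorant_count_null(array(TRUE, c(10, 10, 10)), 2, n_iter = 600,
                            seed = 7)
  emp <- nul$count_freq / sum(nul$count_freq)
  tv <- 0.5 * sum(abs(emp - dbinom(0:40, 40, 0.05)))
  expect_lt(tv, 0.02)
})

test_that("count maps aggregate identical and missing maps correctly", {
  set.seed(8)
  vol <- noise_volume(30, d = c(5, 5, 4))
  tab <- data.frame(age = rnorm(30))
  design <- build_design(tab, rnorm(30), "age", predictor_name = "x")
  map <- fit_voxel_glm(vol, design)
  maps <- rep(list(map), 40)
  cm <- count_map(maps, alpha = 0.05, threshold_count = 10)
  expect_true(all(cm$counts %in% c(0L, 40L)))
  maps[3] <- list(NULL)
  cm2 <- count_map(maps, alpha = 0.05)
  expect_identical(cm2$n_missing, 1L)
  expect_identical(cm2$n_maps, 39L)
  expect_false(any(cm2$flagged))  # no threshold supplied
})

test_that("cluster correction handles empty and saturated cases", {
  set.seed(9)
  vol <- noise_volume(40, d = c(8, 8, 8))
  tab <- data.frame(age = rnorm(40))
  x <- rnorm(40)
  design <- build_design(tab, x, "age", predictor_name = "x")
  map <- fit_voxel_glm(vol, design)
  empty <- cluster_correct(map, 2, voxel_p = 1e-9, n_iter = 150, seed = 10)
  expect_identical(nrow(empty$clusters), 0L)
  # plant a huge effect in a block of voxels
  arr <- vol$data
  arr[, 1:120] <- arr[, 1:120] + outer(x, rep(3, 120))
  mapP <- fit_voxel_glm(volume_set(arr, dim = c(8, 8, 8)), design)
  cl <- cluster_correct(mapP, 2, n_iter = 400, seed = 11)
  expect_gte(nrow(cl$clusters), 1L)
  expect_equal(cl$clusters$cluster_p[1], 1 / 401, tolerance = 1e-12)
})

test_that("Monte-Carlo and permutation cluster nulls agree on white noise", {
  set.seed(12)
  n <- 40
  d <- c(8, 8, 8)
  vol <- noise_volume(n, d = d)
  tab <- data.frame(age = rnorm(n))
  design <- build_design(tab, rnorm(n), "age", predictor_name = "x")
  map <- fit_voxel_glm(vol, design, return_residuals = TRUE)
  fw <- estimate_smoothness(map$residuals)
  cl <- cluster_correct(map, fw, n_iter = 500, seed = 13)
  perm <- permutation_cluster_null(vol, design, n_iter = 500, seed = 14)
  expect_gt(nrow(cl$clusters), 0)  # 5% of 512 voxels are suprathreshold
  s <- cl$clusters$size[1]
  p_perm <- (1 + sum(perm >= s)) / (1 + length(perm))
  expect_lt(abs(cl$clusters$cluster_p[1] - p_perm), 0.15)
})

test_that("per-odorant maps skip constant odorants with a warning", {
  co <- quick_cohort(25, seed = 15)
  co$odorant_01 <- 1L
  vol <- noise_volume(25, d = c(5, 5, 2))
  expect_warning(maps <- odorant_maps(vol, co), "odorant_01")
  expect_null(maps[["odorant_01"]])
  expect_s3_class(maps[["odorant_02"]], "stat_map")
})
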