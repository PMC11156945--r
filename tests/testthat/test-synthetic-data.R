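# Generators: validation, determinism, noise-free limits, and recoverability
# of the planted structure by simple direct estimators.

test_that("cohort and truth specifications validate their invariants", {
  expect_error(cohort_spec(n_subjects = 0), "n_subjects")
  expect_error(cohort_spec(outlier_fraction = 1), "outlier_fraction")
  expect_error(cohort_spec(odorant_difficulties = rep(0.2, 39)), "40 odorant")
  expect_error(cohort_spec(odorant_difficulties = c(rep(0.2, 39), 1.2)),
               "in \\(0, 1\\)")
  expect_error(spread_truth(edges = data.frame(from = "AON", to = "AON",
                                               beta = 0.1)), "self-edges")
  expect_error(spread_truth(edges = data.frame(from = "AON", to = "XX",
                                               beta = 0.1)), "not in regions")
  expect_error(spread_truth(noise_sd = 0), "noise_sd")
  expect_error(expression_truth(within_cluster_corr = 1), "within_cluster_corr")
  expect_error(expression_truth(n_regions = 7), "even")
  expect_error(expression_truth(k_clusters = 10, n_genes = 5), "k_clusters")
  expect_error(tract_phantom_spec(n_segments = 1), "n_segments")
  expect_error(tract_phantom_spec(curve_control_points =
                                    rbind(c(0, 0, 0), c(0, 0, 0), c(1, 1, 1))),
               "degenerate curve")
})

test_that("generators are pure functions of their seed", {
  sp <- cohort_spec(n_subjects = 50, seed = 7)
  expect_identical(generate_cohort(sp), generate_cohort(sp))
  tr <- spread_truth()
  co <- quick_cohort(30, seed = 2)
  expect_identical(generate_regional_tau(co, tr, seed = 5),
                   generate_regional_tau(co, tr, seed = 5))
  et <- expression_truth(n_genes = 40, seed = 3)
  expect_identical(generate_expression(et), generate_expression(et))
  # seeded calls do not disturb the global RNG stream
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(generate_cohort(sp)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("composites are response sums within 0..40 in both response models", {
  for (model in c("quota", "independent")) {
    co <- quick_cohort(80, seed = 4, response_model = model)
    resp <- as.matrix(co[sprintf("odorant_%02d", 1:40)])
    expect_true(all(resp %in% c(0L, 1L)))
    expect_identical(co$upsit, as.integer(rowSums(resp)))
    expect_true(all(co$upsit >= 0 & co$upsit <= 40))
  }
})

test_that("noise-free quota cohort reproduces the rounded quadratic trend", {
  sp <- cohort_spec(n_subjects = 100, outlier_fraction = 0, score_noise_sd = 0,
                    odorant_noise_sd = 0,
                    odorant_difficulties = rep(0.25, 40),
                    covariate_effects = c(), seed = 9)
  co <- generate_cohort(sp)
  trend <- attr(co, "trend")
  expect_identical(co$upsit, as.integer(pmin(pmax(round(trend), 0), 40)))
})

test_that("a flat age trend leaves no recoverable age slope", {
  ts <- vapply(1:80, function(s) {
    co <- generate_cohort(cohort_spec(n_subjects = 120,
                                      quadratic_coeffs = c(30, 0, 0),
                                      outlier_fraction = 0,
                                      covariate_effects = c(), seed = 700 + s))
    summary(lm(upsit ~ age, data = co))$coefficients["age", "t value"]
  }, numeric(1))
  expect_lt(abs(mean(ts)), 0.35)
  expect_lt(mean(abs(ts) > 1.96), 0.13)  # nominal 5% plus binomial slack
})

test_that("planted outliers sit far below the trend", {
  co <- quick_cohort(200, seed = 5, covariate_effects = c())
  out <- attr(co, "outliers")
  expect_equal(sum(out), 10)  # floor(0.05 * 200)
  dev <- co$upsit - attr(co, "trend")
  expect_true(all(dev[out] < -6))
})

test_that("regional tau carries the planted transfer structure", {
  co <- quick_cohort(400, seed = 11)
  # no edges: follow-up drifts around baseline
  none <- spread_truth(edges = data.frame(from = character(0),
                                          to = character(0), beta = numeric(0)))
  pan0 <- generate_regional_tau(co, none, seed = 12)
  expect_lt(max(abs(colMeans(pan0$followup - pan0$baseline))), 0.01)
  # single planted edge: conditioned partial correlation is positive
  # (interval joins the conditioning set, as in the spreading analysis)
  one <- spread_truth(edges = data.frame(from = "Amyg", to = "PirF", beta = 0.15))
  pan1 <- generate_regional_tau(co, one, seed = 13)
  r_fwd <- pcor_resid(pan1$baseline[, "Amyg"], pan1$followup[, "PirF"],
                      cbind(pan1$baseline[, "PirF"], pan1$interval))
  r_rev <- pcor_resid(pan1$baseline[, "PirF"], pan1$followup[, "Amyg"],
                      cbind(pan1$baseline[, "Amyg"], pan1$interval))
  expect_gt(r_fwd, 0.5)
  expect_lt(abs(r_rev), 0.15)
})

test_that("painted volumes return regional values through ROI extraction", {
  tr <- spread_truth()
  co <- quick_cohort(20, seed = 21)
  pan <- generate_regional_tau(co, tr, seed = 22)
  atlas <- synthetic_region_atlas(tr$regions)
  exact <- paint_volumes(pan, atlas, "baseline")
  expect_equal(unname(regional_means(exact, atlas)), unname(pan$baseline),
               tolerance = 1e-12)
  smoothed <- paint_volumes(pan, atlas, "baseline", smoothing_fwhm = 4,
                            noise_sd = 0.02, seed = 23)
  rm_s <- regional_means(smoothed, atlas)
  cors <- vapply(seq_along(tr$regions),
                 function(k) cor(rm_s[, k], pan$baseline[, k]), numeric(1))
  expect_true(all(cors > 0.9))
  # atlas must cover the panel regions
  small <- synthetic_region_atlas(tr$regions[1:4])
  expect_error(paint_volumes(pan, small, "baseline"), "does not cover")
})

test_that("atlas construction rejects labels absent from the volume", {
  labs <- array(0L, c(4, 4, 4)); labs[1:2, , ] <- 1L
  expect_error(region_atlas(labs, c(`1` = "A", `2` = "B")), "missing from")
})

test_that("tract phantom voxels lie inside the tube radius", {
  co <- quick_cohort(10, seed = 31)
  spec <- tract_phantom_spec(seed = 32)
  ph <- generate_tract_md(co, spec)
  expect_gt(sum(ph$mask), 0)
  co_idx <- which(ph$mask)
  vox <- arrayInd(co_idx, dim(ph$mask))
  centers <- sweep(sweep(vox - 0.5, 2, ph$voxdim, "*"), 2, ph$origin, "+")
  mind <- vapply(seq_len(nrow(centers)), function(i) {
    min(sqrt(colSums((t(ph$curve) - centers[i, ])^2)))
  }, numeric(1))
  expect_true(all(mind <= spec$radius + 1e-9))
  expect_true(all(ph$segment >= 1 & ph$segment <= spec$n_segments))
})

test_that("expression generator plants the requested correlation structure", {
  tight <- generate_expression(expression_truth(n_genes = 60, k_clusters = 3,
                                                within_cluster_corr = 0.999,
                                                seed = 41))
  C <- coexpression(tight)
  within <- C[outer(tight$clusters, tight$clusters, "==") & upper.tri(C)]
  expect_gt(mean(within), 0.99)
  # a single cluster has no block structure: arbitrary pseudo-blocks show
  # the same within- as between-block correlation
  flat <- generate_expression(expression_truth(n_genes = 100, k_clusters = 1,
                                               within_cluster_corr = 0.5,
                                               seed = 42))
  Cf <- coexpression(flat)
  pseudo <- rep(1:4, length.out = 100)
  same <- outer(pseudo, pseudo, "==") & upper.tri(Cf)
  diff <- (!outer(pseudo, pseudo, "==")) & upper.tri(Cf)
  expect_lt(abs(mean(Cf[same]) - mean(Cf[diff])), 0.05)
})

test_that("rank-one study exposes a normalized planted weight vector", {
  st <- generate_rank_one_study(n_subjects = 40, n_voxels = 30, seed = 51)
  expect_equal(sum(st$weights^2), 1, tolerance = 1e-12)
  expect_identical(st$table$upsit,
                   as.integer(rowSums(st$table[sprintf("odorant_%02d", 1:40)])))
  expect_equal(nrow(st$tau$data), 40L)
})
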