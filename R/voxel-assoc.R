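# Voxel-wise GLMs and their Monte-Carlo nulls: per-odorant association maps,
# the smoothness-matched odorant-count null, and cluster-extent correction.

#' Voxel-wise general linear model
#'
#' Ordinary least squares at every in-mask voxel; the t statistic of the
#' design's predictor of interest is converted to a sign-preserving Z via the
#' two-sided t p-value. Voxels with an exact fit (zero residual variance) are
#' reported at the Z cap and flagged.
#'
#' @param vol A [volume_set()] of outcomes.
#' @param design Design matrix from [build_design()] (attribute
#'   `"predictor"` names the column of interest).
#' @param return_residuals Keep the residual volumes (needed for
#'   [estimate_smoothness()])?
#' @return Object of class `stat_map`: `t`, `z`, `p` per voxel, `df`,
#'   `predictor`, `capped` flags, grid geometry, and optionally `residuals`
#'   as a [volume_set()].
#' @export
fit_voxel_glm <- function(vol, design, return_residuals = FALSE) {
  stopifnot(inherits(vol, "volume_set"))
  pred <- attr(design, "predictor")
  if (is.null(pred)) stop("design lacks a predictor attribute; use build_design()",
                          call. = FALSE)
  jcol <- match(pred, colnames(design))
  fit <- ols_tstats(vol$data, design, jcol, return_residuals = return_residuals)
  res <- NULL
  if (return_residuals) {
    res <- volume_set(fit$residuals, dim = vol$dim, voxdim = vol$voxdim,
                      mask = vol$mask)
  }
  structure(list(t = fit$t, z = fit$z, p = fit$p, df = fit$df,
                 predictor = pred, capped = fit$capped,
                 dim = vol$dim, voxdim = vol$voxdim, mask = vol$mask,
                 residuals = res),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat("<stat_map> predictor '", x$predictor, "', ", length(x$z),
      " voxels, df = ", x$df, "\n", sep = "")
  invisible(x)
}

#' Estimate the Gaussian-equivalent smoothness (FWHM) of residual maps
#'
#' Lag-one spatial autocorrelation of the standardized residuals along each
#' grid axis, pooled over subjects, is inverted through the Gaussian
#' autocorrelation function; the voxel size is added in quadrature so pure
#' white noise reads approximately one voxel. Used to match the smoothness of
#' simulated null maps to the data.
#'
#' @param residuals A [volume_set()] of residual maps (e.g. from
#'   [fit_voxel_glm()] with `return_residuals = TRUE`).
#' @param min_voxels Minimum mask size.
#' @return Estimated FWHM in mm (scalar; per-axis values in attribute
#'   `"per_axis"`).
#' @export
estimate_smoothness <- function(residuals, min_voxels = 100L) {
  stopifnot(inherits(residuals, "volume_set"))
  if (sum(residuals$mask) < min_voxels) {
    stop("mask too small to estimate smoothness (<", min_voxels, " voxels)",
         call. = FALSE)
  }
  sds <- apply(residuals$data, 1L, stats::sd)
  if (any(!is.finite(sds)) || any(sds == 0)) {
    stop("constant residual map: zero variance, smoothness undefined", call. = FALSE)
  }
  d <- residuals$dim
  mask <- residuals$mask
  num <- den <- c(0, 0, 0)
  for (i in seq_len(nrow(residuals$data))) {
    arr <- array(NA_real_, d)
    arr[mask] <- (residuals$data[i, ] - mean(residuals$data[i, ])) / sds[i]
    for (a in 1:3) {
      idx_lo <- slice_index(d, a, 1L, d[a] - 1L)
      idx_hi <- slice_index(d, a, 2L, d[a])
      x <- arr[idx_lo]; y <- arr[idx_hi]
      ok <- !is.na(x) & !is.na(y)
      num[a] <- num[a] + sum(x[ok] * y[ok])
      den[a] <- den[a] + sum(ok)
    }
  }
  rho <- pmin(pmax(num / pmax(den, 1), 0), 0.999)
  facf <- ifelse(rho > 1e-6,
                 residuals$voxdim * sqrt(2 * log(2) / (-log(rho))), 0)
  per_axis <- sqrt(facf^2 + residuals$voxdim^2)
  structure(mean(per_axis), per_axis = per_axis)
}

# logical index array selecting positions `from:to` along axis `a`
slice_index <- function(d, a, from, to) {
  idx <- rep(list(quote(expr = )), 3)
  out <- array(FALSE, d)
  sel <- lapply(seq_len(3), function(k) if (k == a) from:to else seq_len(d[k]))
  out[sel[[1]], sel[[2]], sel[[3]]] <- TRUE
  out
}

#' Monte-Carlo null for the odorant-count map
#'
#' Per iteration, `n_maps` independent Gaussian maps with the estimated data
#' smoothness are thresholded at the two-sided level `alpha`; the per-voxel
#' count of significant maps is recorded. The count threshold is the smallest
#' count whose family-wise probability (via the distribution of the maximum
#' count over the mask) is below `fwe_alpha`.
#'
#' @param mask Logical 3D array (analysis mask) or a [volume_set()]/
#'   `stat_map` whose mask is used.
#' @param fwhm_est Estimated map smoothness, mm (from
#'   [estimate_smoothness()]); values at or below the voxel size give
#'   unsmoothed white-noise nulls.
#' @param n_iter Number of iterations (default 5000; fewer than 100 refused).
#' @param n_maps Maps per iteration (default 40 odorants).
#' @param alpha Per-map two-sided voxel significance level.
#' @param fwe_alpha Family-wise level for the count threshold.
#' @param voxdim Voxel sizes, mm (taken from `mask` when it is a volume
#'   object).
#' @param seed Integer seed.
#' @return List: `threshold_count`, `max_counts` (per-iteration maximum count
#'   over the mask), `count_freq` (pooled voxel-count frequencies, counts `0
#'   .. n_maps`), `alpha`, `n_iter`, `n_maps`, `fwhm_est`.
#' @export
odorant_count_null <- function(mask, fwhm_est, n_iter = 5000L, n_maps = 40L,
                               alpha = 0.05, fwe_alpha = 0.05,
                               voxdim = c(2, 2, 2), seed = NULL) {
  if (n_iter < 100L) stop("n_iter < 100 gives an unstable null; refused", call. = FALSE)
  g <- resolve_geometry(mask, voxdim)
  zthr <- stats::qnorm(1 - alpha / 2)
  sampler <- make_null_sampler(g$dim, g$voxdim, fwhm_est)
  mvec <- as.vector(g$mask)
  white <- isTRUE(attr(sampler, "white"))
  nvox <- sum(mvec)
  with_seed(seed, {
    max_counts <- integer(n_iter)
    count_freq <- integer(n_maps + 1L)
    for (it in seq_len(n_iter)) {
      if (white) {
        # unsmoothed fields: threshold in-mask normal draws directly
        m <- matrix(abs(stats::rnorm(nvox * n_maps)) > zthr, nrow = nvox)
      } else {
        maps <- sampler(n_maps)
        m <- matrix(abs(maps) > zthr, nrow = prod(g$dim))[mvec, , drop = FALSE]
      }
      counts <- rowSums(m)
      max_counts[it] <- max(counts)
      tab <- tabulate(counts + 1L, nbins = n_maps + 1L)
      count_freq <- count_freq + tab
    }
    exceed <- vapply(seq_len(n_maps + 1L) - 1L,
                     function(cc) mean(max_counts >= cc), numeric(1))
    thr <- which(exceed < fwe_alpha)
    threshold_count <- if (length(thr)) min(thr) - 1L else NA_integer_
    list(threshold_count = threshold_count, max_counts = max_counts,
         count_freq = stats::setNames(count_freq, 0:n_maps),
         alpha = alpha, fwe_alpha = fwe_alpha, n_iter = n_iter,
         n_maps = n_maps, fwhm_est = fwhm_est)
  })
}

resolve_geometry <- function(mask, voxdim) {
  if (inherits(mask, "volume_set") || inherits(mask, "stat_map")) {
    list(dim = mask$dim, voxdim = mask$voxdim, mask = mask$mask)
  } else {
    stopifnot(is.logical(mask), length(dim(mask)) == 3L)
    list(dim = dim(mask), voxdim = voxdim, mask = mask)
  }
}

#' Per-voxel count of significant odorant maps
#'
#' @param maps List of 40 `stat_map`s (entries may be `NULL` for odorants
#'   with undefined maps, e.g. identified by everyone; these are excluded and
#'   counted in `n_missing`).
#' @param alpha Voxel significance level (two-sided).
#' @param threshold_count Minimal non-chance count, from
#'   [odorant_count_null()] (optional).
#' @return Object of class `count_map`: `counts` per voxel, `flagged`
#'   (counts at or above the threshold; all `FALSE` when no threshold),
#'   `n_maps`, `n_missing`, `alpha`, `threshold_count`, and grid geometry.
#' @export
count_map <- function(maps, alpha = 0.05, threshold_count = NULL) {
  ok <- !vapply(maps, is.null, logical(1))
  if (!any(ok)) stop("all odorant maps missing", call. = FALSE)
  first <- maps[[which(ok)[1]]]
  counts <- rep(0L, length(first$z))
  for (m in maps[ok]) counts <- counts + (m$p < alpha)
  flagged <- if (is.null(threshold_count)) rep(FALSE, length(counts)) else
    counts >= threshold_count
  structure(list(counts = counts, flagged = flagged, n_maps = sum(ok),
                 n_missing = sum(!ok), alpha = alpha,
                 threshold_count = threshold_count,
                 dim = first$dim, voxdim = first$voxdim, mask = first$mask),
            class = "count_map")
}

#' Cluster-extent Monte-Carlo correction
#'
#' Suprathreshold clusters (two-sided voxel threshold `voxel_p`) are compared
#' to the distribution of the maximum cluster size in smoothness-matched
#' Gaussian null maps. The corrected p of a cluster is the fraction of null
#' maxima at least as large, floored at `1 / (n_iter + 1)`.
#'
#' @param map A `stat_map`.
#' @param fwhm_est Estimated map smoothness, mm.
#' @param voxel_p Voxel-level two-sided threshold (default 0.05).
#' @param n_iter Null iterations (default 10000).
#' @param connectivity 26 (default) or 6.
#' @param null_max_sizes Optional precomputed null maximum cluster sizes for
#'   this mask/smoothness/threshold (e.g. from [cluster_null_distribution()]),
#'   reused instead of simulating.
#' @param seed Integer seed.
#' @return Object of class `cluster_result`: data frame `clusters` (id, size,
#'   corrected `cluster_p`, peak |z|), `membership` (cluster id per voxel, 0
#'   outside clusters), `null_max_sizes`, and the parameters. Empty when no
#'   voxel is suprathreshold.
#' @export
cluster_correct <- function(map, fwhm_est, voxel_p = 0.05, n_iter = 10000L,
                            connectivity = 26, null_max_sizes = NULL,
                            seed = NULL) {
  stopifnot(inherits(map, "stat_map"))
  supra <- array(FALSE, map$dim)
  supra[map$mask] <- is.finite(map$p) & map$p < voxel_p
  comp <- label_components(supra, connectivity)
  if (is.null(null_max_sizes)) {
    null_max_sizes <- cluster_null_distribution(
      map, fwhm_est, voxel_p = voxel_p, n_iter = n_iter,
      connectivity = connectivity, seed = seed)
  }
  n_iter <- length(null_max_sizes)
  membership <- rep(0L, sum(map$mask))
  clusters <- data.frame(cluster = integer(0), size = integer(0),
                         cluster_p = numeric(0), peak_z = numeric(0))
  if (length(comp$sizes)) {
    mask_lin <- which(map$mask)
    pos <- match(comp$index, mask_lin)
    membership[pos] <- comp$membership
    sizes <- comp$sizes
    pvals <- vapply(sizes, function(s) {
      (1 + sum(null_max_sizes >= s)) / (1 + n_iter)
    }, numeric(1))
    peak <- vapply(seq_along(sizes), function(k) {
      max(abs(map$z[pos[comp$membership == k]]))
    }, numeric(1))
    o <- order(sizes, decreasing = TRUE)
    clusters <- data.frame(cluster = seq_along(sizes)[o], size = sizes[o],
                           cluster_p = pvals[o], peak_z = peak[o])
  }
  structure(list(clusters = clusters, membership = membership,
                 null_max_sizes = null_max_sizes, voxel_p = voxel_p,
                 n_iter = n_iter, fwhm_est = fwhm_est,
                 connectivity = connectivity,
                 dim = map$dim, voxdim = map$voxdim, mask = map$mask),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result> ", nrow(x$clusters), " clusters (voxel p < ",
      x$voxel_p, ", ", x$n_iter, " null iterations)\n", sep = "")
  if (nrow(x$clusters)) print(utils::head(x$clusters, 10))
  invisible(x)
}

#' Null distribution of the maximum cluster size
#'
#' Smoothness-matched Gaussian maps are thresholded like the data; the
#' largest suprathreshold cluster size is recorded per iteration. Computing
#' this once and passing it to [cluster_correct()] lets many same-geometry
#' maps share one null.
#'
#' @inheritParams cluster_correct
#' @param mask Logical 3D array, `volume_set` or `stat_map` giving geometry.
#' @param voxdim Voxel sizes when `mask` is a plain array.
#' @return Integer vector of length `n_iter`.
#' @export
cluster_null_distribution <- function(mask, fwhm_est, voxel_p = 0.05,
                                      n_iter = 10000L, connectivity = 26,
                                      voxdim = c(2, 2, 2), seed = NULL) {
  g <- resolve_geometry(mask, voxdim)
  zthr <- stats::qnorm(1 - voxel_p / 2)
  sampler <- make_null_sampler(g$dim, g$voxdim, fwhm_est)
  with_seed(seed, {
    vapply(seq_len(n_iter), function(it) {
      arr <- sampler(1L)[, , , 1L]
      supra <- abs(arr) > zthr & g$mask
      comp <- label_components(supra, connectivity)
      if (length(comp$sizes)) max(comp$sizes) else 0L
    }, integer(1))
  })
}

#' Permutation null distribution of the maximum cluster size
#'
#' Cross-method check for the Monte-Carlo cluster null: the predictor of
#' interest is permuted across subjects, the voxel-wise GLM refit, and the
#' maximum suprathreshold cluster size recorded.
#'
#' @param vol Outcome [volume_set()].
#' @param design Design matrix from [build_design()].
#' @param voxel_p Two-sided voxel threshold.
#' @param n_iter Number of permutations.
#' @param connectivity 26 or 6.
#' @param seed Integer seed.
#' @return Integer vector of length `n_iter`.
#' @export
permutation_cluster_null <- function(vol, design, voxel_p = 0.05,
                                     n_iter = 1000L, connectivity = 26,
                                     seed = NULL) {
  pred <- attr(design, "predictor")
  jcol <- match(pred, colnames(design))
  n <- nrow(design)
  with_seed(seed, {
    vapply(seq_len(n_iter), function(it) {
      Xp <- design
      Xp[, jcol] <- design[sample.int(n), jcol]
      fit <- ols_tstats(vol$data, Xp, jcol)
      supra <- array(FALSE, vol$dim)
      supra[vol$mask] <- is.finite(fit$p) & fit$p < voxel_p
      comp <- label_components(supra, connectivity)
      if (length(comp$sizes)) max(comp$sizes) else 0L
    }, integer(1))
  })
}

#' Per-odorant association maps
#'
#' One voxel-wise GLM per odorant with the binary identified/not response as
#' predictor (a covariate-adjusted two-group comparison). Odorants identified
#' by everyone or no one in the sample have no defined map and yield `NULL`
#' with a warning.
#'
#' @param vol Outcome [volume_set()] (tau, amyloid, GM density ...).
#' @param table Subject table with `odorant_*` columns.
#' @param covariates Covariate column names.
#' @return List of 40 `stat_map`s (or `NULL` for constant odorants), named by
#'   odorant column.
#' @export
odorant_maps <- function(vol, table, covariates = c("age", "sex", "apoe4", "smoking")) {
  cols <- odorant_cols()
  maps <- vector("list", 40L)
  names(maps) <- cols
  for (k in seq_along(cols)) {
    resp <- table[[cols[k]]]
    if (is.null(resp)) stop("missing odorant column: ", cols[k], call. = FALSE)
    if (stats::var(resp) == 0) {
      warning("odorant ", cols[k], " constant in sample; map undefined",
              call. = FALSE)
      next
    }
    design <- build_design(table, cols[k], covariates)
    maps[[k]] <- fit_voxel_glm(vol, design)
  }
  maps
}
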