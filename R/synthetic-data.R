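# Synthetic study generators. Every downstream stage (aging norms, voxel-wise
# association, odorant biomarkers, along-tract statistics, spreading graph,
# gene co-expression) has a generator here that plants a known effect, so the
# whole pipeline is testable without access-restricted cohort data.

#' Cohort generator specification
#'
#' Describes a synthetic aging cohort: a quadratic normative trend of the
#' 40-item smell-identification composite against age, per-odorant
#' difficulties, gross low-scoring outliers and covariate effects.
#'
#' Two response models are available. The default `"quota"` model is a
#' noisy-threshold (Thurstonian) one: each subject's composite target is the
#' (clamped, rounded) quadratic age trend plus covariate effects and Gaussian
#' noise; the identified items are the `target` easiest odorants under a
#' logistic perturbation of the item difficulties, so the composite equals
#' its target exactly. It induces inter-odorant correlation through the
#' shared target, as real items correlate through a subject's overall
#' ability. The `"independent"` model draws each item as an independent
#' Bernoulli with probability `plogis(logit(trend/40) - centered item
#' difficulty)` — responses are conditionally independent given age and
#' covariates, the regime in which per-odorant association maps are mutually
#' independent under the null (used for calibration studies of the
#' odorant-count correction). In both models the composite is the row sum of
#' the binary responses.
#'
#' @param n_subjects Number of subjects.
#' @param age_range Two values, years.
#' @param quadratic_coeffs `c(a0, a1, a2)` of mean composite
#'   `a0 + a1*age + a2*age^2`. The default peaks near age 55 at ~36/40 and
#'   loses ~10 points by age 90.
#' @param odorant_difficulties 40 values in (0,1); higher is harder. The
#'   default spans identification rates from ~95% down to ~55%.
#' @param outlier_fraction Fraction of subjects whose composite is shifted by
#'   `outlier_shift`.
#' @param outlier_shift Points added to outlier composites (default -15).
#' @param score_noise_sd SD of the composite around its trend, points.
#' @param odorant_noise_sd Scale of the logistic perturbation of item
#'   difficulties (logit units); 0 makes the item ordering deterministic.
#' @param covariate_effects Named numeric: additive composite effects of
#'   `sex`, `apoe4`, `smoking`, `education` (per unit of the covariate).
#' @param response_model `"quota"` (default) or `"independent"`; see
#'   Details.
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 418,
                        age_range = c(50, 90),
                        quadratic_coeffs = c(5.75, 1.1, -0.01),
                        odorant_difficulties = default_difficulties(),
                        outlier_fraction = 0.05,
                        outlier_shift = -15,
                        score_noise_sd = 2,
                        odorant_noise_sd = 1,
                        covariate_effects = c(apoe4 = -1, smoking = -1),
                        response_model = c("quota", "independent"),
                        seed = NULL) {
  response_model <- match.arg(response_model)
  if (n_subjects < 1) stop("n_subjects must be >= 1", call. = FALSE)
  if (outlier_fraction < 0 || outlier_fraction >= 1) {
    stop("outlier_fraction must be in [0, 1)", call. = FALSE)
  }
  if (length(odorant_difficulties) != 40L) {
    stop("exactly 40 odorant difficulties required", call. = FALSE)
  }
  if (any(odorant_difficulties <= 0 | odorant_difficulties >= 1)) {
    stop("odorant difficulties must lie in (0, 1)", call. = FALSE)
  }
  if (length(quadratic_coeffs) != 3L) stop("quadratic_coeffs must have length 3",
                                           call. = FALSE)
  if (score_noise_sd < 0 || odorant_noise_sd < 0) {
    stop("noise SDs must be non-negative", call. = FALSE)
  }
  structure(as.list(environment()), class = "cohort_spec")
}

#' @rdname cohort_spec
#' @export
default_difficulties <- function() {
  # identification rates in the field run from >90% (onion, peanut, smoke)
  # down to <60% (lime, lemon); spread difficulties accordingly
  seq(0.05, 0.45, length.out = 40)
}

odorant_cols <- function() sprintf("odorant_%02d", 1:40)

#' Generate a synthetic aging cohort
#'
#' @param spec A [cohort_spec()].
#' @return A data frame (one row per subject) with demographics, covariates,
#'   40 binary odorant responses (`odorant_01` ... `odorant_40`), the
#'   composite `upsit` (row sum of the responses, in 0..40), and PACC
#'   cognitive composites at two visits. Attributes: `"trend"` (the noiseless
#'   covariate-adjusted trend per subject) and `"outliers"` (logical,
#'   planted gross outliers).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n_subjects
    age <- pmin(pmax(stats::rnorm(n, 72, 8.3), spec$age_range[1]), spec$age_range[2])
    sex <- stats::rbinom(n, 1, 0.56)
    apoe4 <- stats::rbinom(n, 1, 0.29)
    smoking <- stats::rbinom(n, 1, 0.27)
    education <- pmin(pmax(round(stats::rnorm(n, 16, 3)), 8), 20)
    interval <- pmax(stats::rnorm(n, 2.38, 0.45), 1)
    a <- spec$quadratic_coeffs
    trend <- a[1] + a[2] * age + a[3] * age^2
    eff <- spec$covariate_effects
    for (cv in names(eff)) trend <- trend + eff[[cv]] * get(cv)
    target <- trend + stats::rnorm(n, 0, spec$score_noise_sd)
    outliers <- rep(FALSE, n)
    n_out <- floor(spec$outlier_fraction * n)
    if (n_out > 0) {
      outliers[sample.int(n, n_out)] <- TRUE
      target[outliers] <- target[outliers] + spec$outlier_shift
    }
    base_difficulty <- stats::qlogis(spec$odorant_difficulties)
    resp <- matrix(0L, n, 40L, dimnames = list(NULL, odorant_cols()))
    if (spec$response_model == "quota") {
      target <- pmin(pmax(round(target), 0), 40)
      for (i in seq_len(n)) {
        d <- base_difficulty + spec$odorant_noise_sd * stats::rlogis(40)
        if (target[i] > 0) resp[i, order(d)[seq_len(target[i])]] <- 1L
      }
    } else {
      ability <- stats::qlogis(pmin(pmax(target / 40, 0.02), 0.98))
      item <- base_difficulty - mean(base_difficulty)
      prob <- stats::plogis(outer(ability, item, "-"))
      resp[] <- stats::rbinom(n * 40L, 1L, prob)
    }
    upsit <- as.integer(rowSums(resp))
    dev <- upsit - trend
    pacc_baseline <- 0.04 * dev + stats::rnorm(n, 0, 0.5)
    pacc_followup <- 0.8 * pacc_baseline + 0.05 * dev + stats::rnorm(n, 0, 0.3)
    out <- data.frame(subject_id = sprintf("sub-%04d", seq_len(n)),
                      age = age, sex = sex, apoe4 = apoe4, smoking = smoking,
                      education = education, interval = interval,
                      stringsAsFactors = FALSE)
    out <- cbind(out, as.data.frame(resp))
    out$upsit <- upsit
    out$pacc_baseline <- pacc_baseline
    out$pacc_followup <- pacc_followup
    attr(out, "trend") <- trend
    attr(out, "outliers") <- outliers
    out
  })
}

#' Ground truth for a directed tau-spreading simulation
#'
#' Planted transfer model: follow-up tau in a target region equals its
#' baseline plus the sum over incoming edges of `beta * baseline(source) *
#' interval`, plus Gaussian noise. Defaults plant three medial-temporal to
#' olfactory edges over the eight-region panel used throughout.
#'
#' @param regions Ordered region names.
#' @param edges Data frame with columns `from`, `to`, `beta` (SUVr per SUVr
#'   per year). No self-edges.
#' @param baseline_mean,baseline_sd Baseline SUVr distribution (scalar or per
#'   region).
#' @param noise_sd Follow-up noise SD, SUVr.
#' @param interval_mean,interval_sd Inter-scan interval distribution, years
#'   (used only if the cohort carries no `interval` column).
#' @return An object of class `spread_truth`.
#' @export
spread_truth <- function(regions = c("AON", "TUR", "PirF", "PirT",
                                     "Ent", "Amyg", "Hipp", "Parahipp"),
                         edges = data.frame(
                           from = c("Amyg", "Ent", "Parahipp"),
                           to = c("PirF", "AON", "TUR"),
                           beta = 0.15),
                         baseline_mean = 1.2, baseline_sd = 0.15,
                         noise_sd = 0.05,
                         interval_mean = 2.38, interval_sd = 0.45) {
  stopifnot(all(c("from", "to", "beta") %in% names(edges)) || nrow(edges) == 0)
  if (nrow(edges)) {
    if (any(edges$from == edges$to)) stop("self-edges are not allowed", call. = FALSE)
    bad <- setdiff(c(edges$from, edges$to), regions)
    if (length(bad)) stop("edge endpoints not in regions: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    if (any(!is.finite(edges$beta))) stop("edge coefficients must be finite",
                                          call. = FALSE)
  }
  if (noise_sd <= 0) stop("noise_sd must be > 0", call. = FALSE)
  structure(list(regions = regions, edges = edges,
                 baseline_mean = rep_len(baseline_mean, length(regions)),
                 baseline_sd = rep_len(baseline_sd, length(regions)),
                 noise_sd = noise_sd, interval_mean = interval_mean,
                 interval_sd = interval_sd),
            class = "spread_truth")
}

#' Generate regional tau at two visits with a planted spreading structure
#'
#' @param cohort Subject table from [generate_cohort()] (its `interval`
#'   column is used as the inter-scan interval), or an integer number of
#'   subjects.
#' @param truth A [spread_truth()].
#' @param seed Integer seed.
#' @return Object of class `regional_tau_panel`: list with `baseline` and
#'   `followup` (subjects x regions SUVr matrices), `interval` (years) and
#'   `regions`.
#' @export
generate_regional_tau <- function(cohort, truth, seed = NULL) {
  stopifnot(inherits(truth, "spread_truth"))
  with_seed(seed, {
    if (is.numeric(cohort) && length(cohort) == 1L) {
      n <- as.integer(cohort)
      interval <- pmax(stats::rnorm(n, truth$interval_mean, truth$interval_sd), 0.5)
    } else {
      n <- nrow(cohort)
      interval <- cohort$interval
      if (is.null(interval)) {
        interval <- pmax(stats::rnorm(n, truth$interval_mean, truth$interval_sd), 0.5)
      }
    }
    R <- length(truth$regions)
    baseline <- sapply(seq_len(R), function(r) {
      stats::rnorm(n, truth$baseline_mean[r], truth$baseline_sd[r])
    })
    colnames(baseline) <- truth$regions
    transfer <- matrix(0, R, R, dimnames = list(truth$regions, truth$regions))
    if (nrow(truth$edges)) {
      for (e in seq_len(nrow(truth$edges))) {
        transfer[truth$edges$from[e], truth$edges$to[e]] <- truth$edges$beta[e]
      }
    }
    followup <- baseline + (baseline %*% transfer) * interval +
      matrix(stats::rnorm(n * R, 0, truth$noise_sd), n, R)
    colnames(followup) <- truth$regions
    structure(list(baseline = baseline, followup = followup,
                   interval = interval, regions = truth$regions, truth = truth),
              class = "regional_tau_panel")
  })
}

#' Build a block-layout synthetic atlas
#'
#' Regions are contiguous rectangular blocks tiling the grid, so regional
#' means of painted volumes are well defined and smoothing leakage between
#' regions is limited.
#'
#' @param regions Character vector of region names.
#' @param block Voxels per block along each axis.
#' @param voxdim Voxel sizes, mm.
#' @return A [region_atlas()].
#' @export
synthetic_region_atlas <- function(regions, block = 6L, voxdim = c(2, 2, 2)) {
  R <- length(regions)
  nb <- ceiling(R^(1 / 3))
  nblocks <- c(nb, nb, ceiling(R / nb^2))
  d <- nblocks * block
  labels <- array(0L, d)
  k <- 0L
  for (bz in seq_len(nblocks[3])) for (by in seq_len(nblocks[2])) {
    for (bx in seq_len(nblocks[1])) {
      k <- k + 1L
      if (k > R) break
      labels[(bx - 1L) * block + seq_len(block),
             (by - 1L) * block + seq_len(block),
             (bz - 1L) * block + seq_len(block)] <- k
    }
  }
  region_atlas(labels, stats::setNames(regions, seq_len(R)), voxdim = voxdim)
}

#' Paint regional values into per-subject volumes
#'
#' Each atlas region is filled with the subject's regional value, voxel noise
#' is added, and the volume is Gaussian-smoothed. With zero noise and zero
#' smoothing, regional mean extraction recovers the input exactly.
#'
#' @param panel A `regional_tau_panel` or a subjects x regions matrix with
#'   region column names.
#' @param atlas A [region_atlas()] whose names cover the panel regions.
#' @param visit `"baseline"` or `"followup"` (ignored for a matrix panel).
#' @param smoothing_fwhm Gaussian FWHM, mm.
#' @param noise_sd Voxel noise SD added before smoothing.
#' @param seed Integer seed.
#' @return A [volume_set()] masked to labelled voxels.
#' @export
paint_volumes <- function(panel, atlas, visit = c("baseline", "followup"),
                          smoothing_fwhm = 0, noise_sd = 0, seed = NULL) {
  values <- if (inherits(panel, "regional_tau_panel")) {
    panel[[match.arg(visit)]]
  } else {
    as.matrix(panel)
  }
  regions <- colnames(values)
  if (is.null(regions)) stop("panel must carry region column names", call. = FALSE)
  missing <- setdiff(regions, atlas$names)
  if (length(missing)) stop("atlas does not cover regions: ",
                            paste(missing, collapse = ", "), call. = FALSE)
  d <- dim(atlas$labels)
  mask <- atlas$labels > 0L
  label_of <- as.integer(names(atlas$names))[match(regions, atlas$names)]
  for (lab in label_of) {
    if (!any(atlas$labels == lab)) stop("empty region in atlas (label ", lab, ")",
                                        call. = FALSE)
  }
  with_seed(seed, {
    n <- nrow(values)
    fill <- array(0, d)
    data <- matrix(NA_real_, n, sum(mask))
    for (i in seq_len(n)) {
      arr <- fill
      for (k in seq_along(regions)) {
        arr[atlas$labels == label_of[k]] <- values[i, k]
      }
      if (noise_sd > 0) arr <- arr + array(stats::rnorm(prod(d), 0, noise_sd), d)
      if (smoothing_fwhm > 0) arr <- gaussian_smooth_3d(arr, smoothing_fwhm, atlas$voxdim)
      data[i, ] <- arr[mask]
    }
    rownames(data) <- rownames(values)
    volume_set(data, dim = d, voxdim = atlas$voxdim, mask = mask)
  })
}

#' Tract phantom specification
#'
#' A tube of given radius around a smooth 3D curve, with a mean-diffusivity
#' effect of the smell-identification composite planted on a contiguous run
#' of the tract's equal-length segments.
#'
#' @param n_segments Number of equal-arc-length segments (default 100).
#' @param curve_control_points Matrix of 3D control points, mm; the centerline
#'   interpolates them with a natural spline.
#' @param radius Tube radius, mm.
#' @param effect_segments Integer segment indices carrying the effect.
#' @param effect_size MD change per composite point (mm^2/s), applied to the
#'   subject's composite deviation from the sample mean.
#' @param md_baseline Baseline MD, mm^2/s.
#' @param md_noise_sd Voxel-level MD noise SD, mm^2/s.
#' @param voxdim Voxel sizes, mm.
#' @param seed Integer seed.
#' @return Object of class `tract_phantom_spec`.
#' @export
tract_phantom_spec <- function(n_segments = 100L,
                               curve_control_points = default_tract_curve(),
                               radius = 3,
                               effect_segments = integer(),
                               effect_size = 2e-6,
                               md_baseline = 7e-4,
                               md_noise_sd = 4e-5,
                               voxdim = c(2, 2, 2),
                               seed = NULL) {
  if (n_segments < 2) stop("n_segments must be >= 2", call. = FALSE)
  if (radius <= 0) stop("radius must be > 0", call. = FALSE)
  curve_control_points <- as.matrix(curve_control_points)
  if (ncol(curve_control_points) != 3L || nrow(curve_control_points) < 2L) {
    stop("curve_control_points must be an m x 3 matrix with m >= 2", call. = FALSE)
  }
  if (any(rowSums((diff(curve_control_points))^2) == 0)) {
    stop("degenerate curve: repeated consecutive control points", call. = FALSE)
  }
  structure(as.list(environment()), class = "tract_phantom_spec")
}

#' @rdname tract_phantom_spec
#' @export
default_tract_curve <- function() {
  # gentle arc ~100 mm long
  t <- seq(0, 1, length.out = 7)
  cbind(x = 10 + 80 * t, y = 20 + 16 * sin(pi * t), z = 14 + 10 * t)
}

# Natural-spline interpolation of the control polygon, resampled densely and
# then to near-equal arc-length steps.
interpolate_curve <- function(points, n_out = 400L) {
  s <- c(0, cumsum(sqrt(rowSums(diff(points)^2))))
  fine <- sapply(1:3, function(a) {
    stats::spline(s, points[, a], n = n_out * 4L, method = "natural")$y
  })
  arc <- c(0, cumsum(sqrt(rowSums(diff(fine)^2))))
  target <- seq(0, arc[length(arc)], length.out = n_out)
  out <- sapply(1:3, function(a) stats::approx(arc, fine[, a], xout = target)$y)
  list(points = out, arc = target)
}

#' Generate a tract phantom and per-subject MD volumes
#'
#' @param cohort Subject table from [generate_cohort()] (needs `upsit`).
#' @param spec A [tract_phantom_spec()].
#' @return List with `md` (a [volume_set()] over the tube mask), `mask`
#'   (logical array), `voxdim`, `curve` (fine centerline points), the true
#'   `segment` index of every mask voxel (by arc position, in mask order),
#'   and `endpoints` (world mm coordinates of the curve ends).
#' @export
generate_tract_md <- function(cohort, spec) {
  stopifnot(inherits(spec, "tract_phantom_spec"))
  cur <- interpolate_curve(spec$curve_control_points)
  margin <- spec$radius + 2 * max(spec$voxdim)
  lo <- apply(cur$points, 2, min) - margin
  hi <- apply(cur$points, 2, max) + margin
  d <- pmax(ceiling((hi - lo) / spec$voxdim) + 1L, 4L)
  # voxel center world coordinate: lo + (index - 0.5) * voxdim
  centers <- lapply(1:3, function(a) lo[a] + (seq_len(d[a]) - 0.5) * spec$voxdim[a])
  grid <- as.matrix(expand.grid(centers[[1]], centers[[2]], centers[[3]]))
  # nearest centerline sample for each voxel
  nn <- nearest_point_index(grid, cur$points)
  dist <- sqrt(rowSums((grid - cur$points[nn, , drop = FALSE])^2))
  inside <- dist <= spec$radius
  mask <- array(inside, d)
  arc_pos <- cur$arc[nn[inside]]
  total <- cur$arc[length(cur$arc)]
  seg <- pmin(pmax(ceiling(arc_pos / total * spec$n_segments), 1L), spec$n_segments)
  with_seed(spec$seed, {
    n <- nrow(cohort)
    dev <- cohort$upsit - mean(cohort$upsit)
    v <- sum(inside)
    eff_vox <- seg %in% spec$effect_segments
    md <- matrix(spec$md_baseline, n, v) +
      outer(dev * spec$effect_size, as.numeric(eff_vox)) +
      matrix(stats::rnorm(n * v, 0, spec$md_noise_sd), n, v)
    rownames(md) <- cohort$subject_id
    list(md = volume_set(md, dim = d, voxdim = spec$voxdim, mask = mask),
         mask = mask, voxdim = spec$voxdim, curve = cur$points,
         segment = seg, origin = lo,
         endpoints = rbind(cur$points[1, ], cur$points[nrow(cur$points), ]))
  })
}

# index of the nearest row of `ref` for each row of `x` (chunked to bound
# memory)
nearest_point_index <- function(x, ref, chunk = 2048L) {
  out <- integer(nrow(x))
  r2 <- rowSums(ref^2)
  for (start in seq(1L, nrow(x), by = chunk)) {
    i <- start:min(start + chunk - 1L, nrow(x))
    d2 <- outer(rowSums(x[i, , drop = FALSE]^2), r2, "+") -
      2 * x[i, , drop = FALSE] %*% t(ref)
    out[i] <- max.col(-d2, ties.method = "first")
  }
  out
}

#' Ground truth for a clustered expression simulation
#'
#' @param n_genes Number of genes.
#' @param n_regions Number of regions (even; split into left/right halves).
#' @param k_clusters Number of planted co-expression clusters.
#' @param within_cluster_corr Expected pairwise correlation within a cluster,
#'   in (0,1).
#' @param right_bias Per-cluster additive expression bias in right-hemisphere
#'   regions (scalar or length `k_clusters`).
#' @param seed Integer seed.
#' @return Object of class `expression_truth`.
#' @export
expression_truth <- function(n_genes = 390L, n_regions = 68L, k_clusters = 4L,
                             within_cluster_corr = 0.8, right_bias = 0,
                             seed = NULL) {
  if (k_clusters > n_genes) stop("k_clusters must be <= n_genes", call. = FALSE)
  if (n_regions %% 2L != 0L) stop("n_regions must be even (hemisphere split)",
                                  call. = FALSE)
  if (within_cluster_corr <= 0 || within_cluster_corr >= 1) {
    stop("within_cluster_corr must lie in (0, 1)", call. = FALSE)
  }
  structure(as.list(environment()), class = "expression_truth")
}

#' Generate a genes-by-regions expression matrix with planted clusters
#'
#' Each cluster has a latent region profile; genes are that profile mixed
#' with independent noise so that within-cluster pairwise correlation equals
#' `within_cluster_corr`. Rows are z-scored across regions.
#'
#' @param truth An [expression_truth()].
#' @return Object of class `expression_matrix`: list with `values`
#'   (genes x regions, row-z-scored), `regions` (data frame: region,
#'   hemisphere), and `clusters` (true gene labels).
#' @export
generate_expression <- function(truth) {
  stopifnot(inherits(truth, "expression_truth"))
  with_seed(truth$seed, {
    g <- truth$n_genes; r <- truth$n_regions; k <- truth$k_clusters
    rho <- truth$within_cluster_corr
    bias <- rep_len(truth$right_bias, k)
    labels <- sort(rep_len(seq_len(k), g))
    hemi <- rep(c("L", "R"), each = r / 2)
    latent <- matrix(stats::rnorm(k * r), k, r)
    vals <- sqrt(rho) * latent[labels, , drop = FALSE] +
      sqrt(1 - rho) * matrix(stats::rnorm(g * r), g, r)
    vals <- vals + outer(bias[labels], as.numeric(hemi == "R"))
    vals <- row_zscore(vals)
    region <- paste0(rep(c("lh", "rh"), each = r / 2), "_region_",
                     sprintf("%02d", c(seq_len(r / 2), seq_len(r / 2))))
    dimnames(vals) <- list(paste0("gene_", sprintf("%03d", seq_len(g))), region)
    structure(list(values = vals,
                   regions = data.frame(region = region, hemisphere = hemi,
                                        stringsAsFactors = FALSE),
                   clusters = stats::setNames(labels, rownames(vals)),
                   truth = truth),
              class = "expression_matrix")
  })
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("<expression_matrix> ", nrow(x$values), " genes x ", ncol(x$values),
      " regions\n", sep = "")
  invisible(x)
}

#' Simulate a rank-one odorant-severity study
#'
#' Plants a single latent severity axis: subject severity drives tau in a
#' fixed voxel pattern and lowers the identification probability of each
#' odorant in proportion to a ground-truth weight vector. Used to validate
#' the PCA biomarker stage end to end.
#'
#' @param n_subjects,n_voxels Problem size.
#' @param weights Ground-truth odorant weights (length 40, normalized
#'   internally). The default is a signed gradient from +1 to -1 across the
#'   items: like empirical component loadings it is signed and near zero
#'   mean, so the odorant-centered PCA sees the full planted direction.
#' @param effect Logit-scale effect of `severity * weight` on the odds of
#'   missing an item (kept in the logistic's near-linear range by default).
#' @param tau_noise_sd Voxel noise SD relative to a unit-SD severity signal.
#' @param seed Integer seed.
#' @return List with `table` (subject table with odorant responses and
#'   covariates), `tau` (a flat-grid [volume_set()]), `severity`, and the
#'   normalized `weights`.
#' @export
generate_rank_one_study <- function(n_subjects = 150L, n_voxels = 500L,
                                    weights = NULL, effect = 4,
                                    tau_noise_sd = 1, seed = NULL) {
  if (is.null(weights)) {
    weights <- seq(1, -1, length.out = 40)
  }
  weights <- weights / sqrt(sum(weights^2))
  with_seed(seed, {
    n <- n_subjects
    severity <- stats::rnorm(n)
    # higher severity -> more misses on high-weight odorants
    pmiss <- stats::plogis(outer(severity * effect, weights) - 0.5)
    resp <- matrix(stats::rbinom(n * 40L, 1L, 1 - pmiss), n, 40L,
                   dimnames = list(NULL, odorant_cols()))
    pattern <- stats::runif(n_voxels, 0.5, 1.5)
    tau <- outer(severity, pattern) +
      matrix(stats::rnorm(n * n_voxels, 0, tau_noise_sd), n, n_voxels)
    table <- data.frame(subject_id = sprintf("sub-%04d", seq_len(n)),
                        age = stats::rnorm(n, 72, 8),
                        sex = stats::rbinom(n, 1, 0.5),
                        apoe4 = stats::rbinom(n, 1, 0.3),
                        smoking = stats::rbinom(n, 1, 0.25),
                        stringsAsFactors = FALSE)
    table <- cbind(table, as.data.frame(resp))
    table$upsit <- as.integer(rowSums(resp))
    list(table = table, tau = volume_set(tau), severity = severity,
         weights = weights)
  })
}

#' Write a subject table or regional panel to CSV
#'
#' @param x Subject table (data frame) or `regional_tau_panel`.
#' @param path Output file (panel writes one row per subject with
#'   `baseline_`/`followup_` column prefixes plus `interval`).
#' @return Invisibly, `path`.
#' @export
write_table_csv <- function(x, path) {
  if (inherits(x, "regional_tau_panel")) {
    df <- data.frame(subject = seq_len(nrow(x$baseline)))
    b <- as.data.frame(x$baseline); names(b) <- paste0("baseline_", names(b))
    f <- as.data.frame(x$followup); names(f) <- paste0("followup_", names(f))
    df <- cbind(df, b, f, interval = x$interval)
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    utils::write.csv(x, path, row.names = FALSE)
  }
  invisible(path)
}
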