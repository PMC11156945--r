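# Shared internals: seeded evaluation, separable Gaussian smoothing on 3D
# grids, connected-component labeling, and the vectorized OLS t/z engine used
# by every GLM-based stage.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded generators are pure
#' functions of their arguments and never perturb the global stream.
#'
#' @param seed Integer seed, or `NULL` to use the current stream.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number or NULL", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive deterministic per-stage sub-seeds from one master seed (kept < 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# z-score each row (mean 0, sd 1 across columns), without scale() attributes
row_zscore <- function(m) {
  mu <- rowMeans(m)
  s <- sqrt(rowSums((m - mu)^2) / (ncol(m) - 1L))
  out <- (m - mu) / s
  dimnames(out) <- dimnames(m)
  out
}

# --- separable Gaussian smoothing ------------------------------------------

# One-axis Gaussian convolution matrix (n x n) at kernel sd `sigma` (mm) for
# voxel spacing `delta` (mm); rows renormalized so constants are preserved at
# the edges.
gaussian_kernel_matrix <- function(n, sigma, delta) {
  if (sigma <= 0) return(diag(n))
  d <- outer(seq_len(n), seq_len(n), "-") * delta
  K <- exp(-d^2 / (2 * sigma^2))
  K / rowSums(K)
}

# Apply matrix K along axis `axis` of a 3D (or 3D + trailing map) array.
apply_along_axis <- function(arr, K, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(seq_along(d), axis))
  a <- aperm(arr, perm)
  da <- dim(a)
  m <- K %*% matrix(a, nrow = da[1L])
  dim(m) <- da
  aperm(m, order(perm))
}

#' Smooth a 3D array with an isotropic Gaussian kernel
#'
#' Separable convolution with edge renormalization (constants are preserved).
#'
#' @param arr 3D numeric array.
#' @param fwhm Kernel full width at half maximum, mm. `0` returns `arr`.
#' @param voxdim Voxel dimensions, mm (length 3).
#' @return Smoothed array, same dimensions.
#' @export
gaussian_smooth_3d <- function(arr, fwhm, voxdim = c(1, 1, 1)) {
  stopifnot(length(dim(arr)) == 3L, length(voxdim) == 3L, fwhm >= 0)
  if (fwhm == 0) return(arr)
  sigma <- fwhm / sqrt(8 * log(2))
  for (a in 1:3) {
    K <- gaussian_kernel_matrix(dim(arr)[a], sigma, voxdim[a])
    arr <- apply_along_axis(arr, K, a)
  }
  arr
}

# Sampler of smoothness-matched standardized Gaussian null fields. The
# requested smoothness `fwhm` is interpreted as an *estimated* map smoothness
# (which includes the voxel grain, see estimate_smoothness()); the generating
# kernel width is deconvolved accordingly, so fwhm at the voxel size yields
# unsmoothed white noise. Fields are rescaled to exact unit variance at every
# voxel using the kernel's squared-weight map.
make_null_sampler <- function(dim3, voxdim, fwhm) {
  stopifnot(length(dim3) == 3L)
  kernel_fwhm <- sqrt(max(fwhm^2 - mean(voxdim)^2, 0))
  sigma0 <- kernel_fwhm / sqrt(8 * log(2))
  # a kernel whose nearest-neighbor weight is < 1e-3 of the center is a
  # delta at this voxel size: plain white noise
  if (sigma0 < min(voxdim) / sqrt(2 * log(1000))) {
    f <- function(n_maps = 1L) {
      array(stats::rnorm(prod(dim3) * n_maps), c(dim3, n_maps))
    }
    attr(f, "white") <- TRUE
    return(f)
  }
  sigma <- kernel_fwhm / sqrt(8 * log(2))
  Ks <- lapply(1:3, function(a) gaussian_kernel_matrix(dim3[a], sigma, voxdim[a]))
  # per-voxel variance of the smoothed field: outer product of row sums of K^2
  v1 <- rowSums(Ks[[1]]^2); v2 <- rowSums(Ks[[2]]^2); v3 <- rowSums(Ks[[3]]^2)
  sdmap <- sqrt(outer(outer(v1, v2), v3))
  function(n_maps = 1L) {
    arr <- array(stats::rnorm(prod(dim3) * n_maps), c(dim3, n_maps))
    for (a in 1:3) arr <- apply_along_axis(arr, Ks[[a]], a)
    arr / as.vector(sdmap)
  }
}

# --- connected components ---------------------------------------------------

neighbor_offsets <- function(connectivity = 26) {
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6) {
    offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  } else if (connectivity != 26) {
    stop("connectivity must be 6 or 26", call. = FALSE)
  }
  # keep one representative per +/- pair (edges are undirected)
  keep <- offs[, 3] > 0 | (offs[, 3] == 0 & (offs[, 2] > 0 | (offs[, 2] == 0 & offs[, 1] > 0)))
  offs[keep, , drop = FALSE]
}

# Label connected components of a logical 3D array. Returns integer membership
# per TRUE voxel (in `which(x)` order) and component sizes; empty input gives
# zero components.
label_components <- function(x, connectivity = 26) {
  stopifnot(is.logical(x), length(dim(x)) == 3L)
  idx <- which(x)
  nv <- length(idx)
  if (nv == 0L) return(list(membership = integer(0), sizes = integer(0), index = idx))
  d <- dim(x)
  id <- array(0L, d)
  id[idx] <- seq_len(nv)
  co <- arrayInd(idx, d)
  offs <- neighbor_offsets(connectivity)
  from <- integer(0); to <- integer(0)
  for (k in seq_len(nrow(offs))) {
    nb <- sweep(co, 2L, offs[k, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    nb_lin <- nb[ok, 1] + (nb[ok, 2] - 1L) * d[1] + (nb[ok, 3] - 1L) * d[1] * d[2]
    nb_id <- id[nb_lin]
    hit <- nb_id > 0L
    from <- c(from, which(ok)[hit])
    to <- c(to, nb_id[hit])
  }
  g <- igraph::make_empty_graph(n = nv, directed = FALSE)
  if (length(from)) g <- igraph::add_edges(g, rbind(from, to))
  comp <- igraph::components(g)
  list(membership = comp$membership, sizes = as.integer(comp$csize), index = idx)
}

# --- vectorized OLS ---------------------------------------------------------

# Z-statistic bound: sign-preserving normal quantile of the two-sided t
# p-value; p-values that underflow are capped here and flagged.
.Z_CAP <- 38

# Mass-univariate OLS of each column of Y on design X; t, z, p for column
# `jcol` of X. Returns residuals for smoothness estimation when asked.
ols_tstats <- function(Y, X, jcol, return_residuals = FALSE) {
  Y <- as.matrix(Y)
  n <- nrow(X); p <- ncol(X)
  if (nrow(Y) != n) stop("outcome and design have different numbers of rows", call. = FALSE)
  if (n <= p) stop("more design columns than subjects", call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[seq(qrX$rank + 1L, p)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  coefs <- qr.coef(qrX, Y)
  res <- qr.resid(qrX, Y)
  df <- n - p
  rss <- colSums(res^2)
  XtXinv <- chol2inv(qr.R(qrX))
  # qr.R is in pivoted order; map jcol through the pivot
  jpiv <- match(jcol, qrX$pivot)
  cjj <- XtXinv[jpiv, jpiv]
  se <- sqrt(pmax(rss, 0) / df * cjj)
  tval <- as.vector(coefs[jcol, ]) / unname(se)
  # an (numerically) exact fit has no meaningful t statistic
  degenerate <- !is.finite(tval) | rss < 1e-24 * colSums(Y^2) + 1e-300
  pval <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  z <- sign(tval) * stats::qnorm(pval / 2, lower.tail = FALSE)
  capped <- degenerate | !is.finite(z) | abs(z) >= .Z_CAP
  z[capped] <- sign(tval[capped]) * .Z_CAP
  z[is.nan(tval)] <- NA_real_
  list(t = unname(tval), z = unname(z), p = unname(pval), df = df,
       capped = unname(capped), degenerate = unname(degenerate),
       residuals = if (return_residuals) res else NULL)
}
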