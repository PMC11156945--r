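# PCA odorant biomarkers: the bipartite odorant-by-voxel association matrix,
# its principal components over the odorant dimension, subject dysfunction
# scores, and back-projection to voxel maps.

#' Build the odorant-by-voxel association matrix
#'
#' Row k is the voxel-wise Z map of the GLM with odorant k's identification
#' as predictor, concatenated over the supplied volume blocks (tau voxels
#' then amyloid voxels for the cross-sectional variant; follow-up minus
#' baseline tau voxels alone for the longitudinal variant). Constant
#' odorants yield missing rows, which are flagged.
#'
#' @param table Subject table with `odorant_*` columns.
#' @param volumes Named list of [volume_set()]s, one per block (e.g.
#'   `list(tau = ..., amyloid = ...)`), aligned to `table` rows.
#' @param covariates Covariate column names for every odorant GLM.
#' @return Object of class `odorant_assoc`: `z` (40 x total voxels matrix),
#'   `block` (column block labels), `missing` (logical per odorant).
#' @export
build_assoc_matrix <- function(table, volumes,
                               covariates = c("age", "sex", "apoe4", "smoking")) {
  stopifnot(is.list(volumes), length(volumes) >= 1L)
  if (is.null(names(volumes))) names(volumes) <- paste0("block", seq_along(volumes))
  for (v in volumes) {
    stopifnot(inherits(v, "volume_set"))
    if (nrow(v$data) != nrow(table)) {
      stop("volume block and table have different subject counts", call. = FALSE)
    }
  }
  nv <- vapply(volumes, function(v) ncol(v$data), integer(1))
  block <- rep(names(volumes), nv)
  Z <- matrix(NA_real_, 40L, sum(nv),
              dimnames = list(odorant_cols(), NULL))
  missing <- rep(FALSE, 40L)
  for (k in seq_len(40L)) {
    col <- odorant_cols()[k]
    resp <- table[[col]]
    if (is.null(resp)) stop("missing odorant column: ", col, call. = FALSE)
    if (stats::var(resp) == 0) { missing[k] <- TRUE; next }
    design <- build_design(table, col, covariates)
    zrow <- unlist(lapply(volumes, function(v) fit_voxel_glm(v, design)$z))
    Z[k, ] <- zrow
  }
  structure(list(z = Z, block = block, missing = missing,
                 covariates = covariates),
            class = "odorant_assoc")
}

#' @export
print.odorant_assoc <- function(x, ...) {
  cat("<odorant_assoc> 40 odorants x ", ncol(x$z), " voxels (",
      paste(unique(x$block), collapse = " + "), "); ",
      sum(x$missing), " missing rows\n", sep = "")
  invisible(x)
}

#' Principal components of the odorant association matrix
#'
#' SVD of the matrix centered across odorants (odorants are the
#' observations, voxels the features; Z values enter unscaled). Missing
#' odorant rows are mean-imputed — zero after centering — and flagged. Each
#' component is sign-flipped so its largest-magnitude odorant weight is
#' positive.
#'
#' @param assoc An `odorant_assoc` (or a plain odorants x voxels matrix).
#' @param n_components Number of components to retain, or `NULL` to keep the
#'   smallest set whose cumulative variance explained reaches
#'   `var_threshold`.
#' @param var_threshold Cumulative variance-explained target used when
#'   `n_components` is `NULL`.
#' @return Object of class `odorant_components`: `weights` (40 x k loadings,
#'   unit norm columns), `variance_explained` (per component),
#'   `missing` flags, `n_components`.
#' @export
pca_components <- function(assoc, n_components = NULL, var_threshold = 0.2) {
  if (inherits(assoc, "odorant_assoc")) {
    Z <- assoc$z; missing <- assoc$missing
  } else {
    Z <- as.matrix(assoc); missing <- rowSums(!is.finite(Z)) > 0
  }
  if (sum(!missing) < 2L) stop("need at least two non-missing odorant rows",
                               call. = FALSE)
  Zc <- Z
  cm <- colMeans(Z[!missing, , drop = FALSE])
  Zc <- sweep(Z, 2L, cm)
  Zc[missing, ] <- 0
  sv <- svd(Zc)
  ve <- sv$d^2 / sum(sv$d^2)
  k <- if (!is.null(n_components)) {
    min(n_components, length(sv$d))
  } else {
    max(1L, which(cumsum(ve) >= var_threshold)[1])
  }
  W <- sv$u[, seq_len(k), drop = FALSE]
  rownames(W) <- rownames(Z)
  flipped <- logical(k)
  for (j in seq_len(k)) {
    lead <- which.max(abs(W[, j]))
    if (W[lead, j] < 0) { W[, j] <- -W[, j]; flipped[j] <- TRUE }
  }
  colnames(W) <- paste0("PC", seq_len(k))
  structure(list(weights = W, variance_explained = ve[seq_len(k)],
                 all_variance = ve, missing = missing, flipped = flipped,
                 n_components = k),
            class = "odorant_components")
}

#' @export
print.odorant_components <- function(x, ...) {
  cat("<odorant_components> ", x$n_components, " components; variance explained: ",
      paste(sprintf("%.1f%%", 100 * x$variance_explained), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Olfactory dysfunction scores from component weights
#'
#' Per-subject linear combination of the binary odorant responses with the
#' component's odorant weights.
#'
#' @param components An `odorant_components` (its columns are used) or a
#'   numeric weight vector of length 40.
#' @param table Subject table with `odorant_*` columns.
#' @param component Which component column to use (default 1).
#' @param center Center the responses by their sample means first?
#' @return Numeric vector of subject scores.
#' @export
score_subjects <- function(components, table, component = 1L, center = FALSE) {
  w <- if (inherits(components, "odorant_components")) {
    components$weights[, component]
  } else {
    as.numeric(components)
  }
  if (length(w) != 40L) stop("need 40 odorant weights", call. = FALSE)
  R <- as.matrix(table[odorant_cols()])
  if (center) R <- sweep(R, 2L, colMeans(R))
  as.vector(R %*% w)
}

#' Back-project a dysfunction score to a corrected voxel map
#'
#' Voxel-wise GLM with the score as predictor of interest, optionally
#' followed by cluster-extent correction; an extra numeric adjustment (e.g.
#' the other PET modality's global value) can be appended to the covariates.
#'
#' @param score Per-subject dysfunction score.
#' @param vol Outcome [volume_set()].
#' @param table Subject table.
#' @param covariates Covariate column names.
#' @param adjust Optional named list of extra numeric covariate vectors.
#' @param correct Apply [cluster_correct()]?
#' @param ... Passed to [cluster_correct()] (e.g. `fwhm_est`, `n_iter`,
#'   `seed`).
#' @return The `stat_map`, with element `clusters` (a `cluster_result`) when
#'   `correct = TRUE`.
#' @export
backproject <- function(score, vol, table,
                        covariates = c("age", "sex", "apoe4", "smoking"),
                        adjust = NULL, correct = FALSE, ...) {
  tab <- table
  if (!is.null(adjust)) {
    for (nm in names(adjust)) tab[[nm]] <- adjust[[nm]]
    covariates <- c(covariates, names(adjust))
  }
  design <- build_design(tab, score, covariates, predictor_name = "dysfunction_score")
  map <- fit_voxel_glm(vol, design, return_residuals = correct)
  if (correct) {
    args <- list(...)
    if (is.null(args$fwhm_est)) args$fwhm_est <- estimate_smoothness(map$residuals)
    map$clusters <- do.call(cluster_correct, c(list(map = map), args))
  }
  map
}
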