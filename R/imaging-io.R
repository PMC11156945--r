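# Volume, atlas and table plumbing: NIfTI IO, analysis masks, regional means
# and GLM design construction.

#' Construct a volume set
#'
#' A volume set holds aligned per-subject 3D scalar volumes (tau SUVr, amyloid
#' DVR, grey-matter density or mean diffusivity) as a subjects-by-voxels
#' matrix restricted to an analysis mask, together with the grid geometry.
#'
#' @param data Numeric matrix, subjects x in-mask voxels, or subjects x V for
#'   a flat geometry when `dim` is `NULL` (a synthetic "grid" of V x 1 x 1).
#' @param dim Grid dimensions (length 3), or `NULL` for a flat grid.
#' @param voxdim Voxel sizes in mm (length 3).
#' @param mask Logical array of grid dimensions selecting the analysis
#'   voxels; defaults to all voxels. `ncol(data)` must equal `sum(mask)`.
#' @param affine Optional 4x4 voxel-to-world affine; defaults to a scaled
#'   identity from `voxdim`.
#' @param subjects Optional subject identifiers (rownames).
#' @return An object of class `volume_set`.
#' @export
volume_set <- function(data, dim = NULL, voxdim = c(2, 2, 2), mask = NULL,
                       affine = NULL, subjects = NULL) {
  data <- as.matrix(data)
  if (is.null(dim)) dim <- c(ncol(data), 1L, 1L)
  stopifnot(length(dim) == 3L, length(voxdim) == 3L)
  if (is.null(mask)) mask <- array(TRUE, dim)
  stopifnot(is.logical(mask), all(base::dim(mask) == dim))
  if (ncol(data) != sum(mask)) {
    stop("ncol(data) must equal the number of in-mask voxels", call. = FALSE)
  }
  if (is.null(affine)) affine <- diag(c(voxdim, 1))
  if (!is.null(subjects)) rownames(data) <- subjects
  structure(list(data = data, dim = as.integer(dim), voxdim = as.numeric(voxdim),
                 mask = mask, affine = affine),
            class = "volume_set")
}

#' @export
print.volume_set <- function(x, ...) {
  cat("<volume_set> ", nrow(x$data), " subjects, grid ",
      paste(x$dim, collapse = "x"), ", ", sum(x$mask), " in-mask voxels\n", sep = "")
  invisible(x)
}

#' Number of subjects / voxels in a volume set
#' @param vol A `volume_set`.
#' @return Integer count.
#' @export
n_subjects <- function(vol) nrow(vol$data)

#' Reconstruct one subject's full 3D array from a volume set
#'
#' Out-of-mask voxels are `NA`.
#'
#' @param vol A `volume_set`.
#' @param subject Row index.
#' @return 3D array with the grid dimensions of `vol`.
#' @export
volume_array <- function(vol, subject = 1L) {
  arr <- array(NA_real_, vol$dim)
  arr[vol$mask] <- vol$data[subject, ]
  arr
}

#' Read aligned NIfTI volumes into a volume set
#'
#' All files must share grid dimensions and voxel sizes. The default analysis
#' mask keeps voxels that are finite in every subject and have nonzero
#' variance across subjects; `mask_policy = "finite"` keeps all all-finite
#' voxels, and an explicit logical array can be supplied instead.
#'
#' @param paths Character vector of NIfTI file paths (one per subject).
#' @param mask_policy `"finite_nonconstant"` (default), `"finite"`, `"all"`,
#'   or a logical array of grid dimensions.
#' @return A `volume_set`.
#' @export
read_volumes <- function(paths, mask_policy = "finite_nonconstant") {
  stopifnot(length(paths) >= 1L)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) stop("missing volume files: ", paste(missing, collapse = ", "),
                            call. = FALSE)
  imgs <- lapply(paths, RNifti::readNifti)
  dims <- lapply(imgs, dim)
  if (length(unique(lapply(dims, paste, collapse = "x"))) != 1L) {
    stop("volume grids differ between files (alignment error)", call. = FALSE)
  }
  d <- dims[[1L]]
  if (length(d) != 3L) stop("expected 3D volumes", call. = FALSE)
  voxdim <- RNifti::pixdim(imgs[[1L]])[1:3]
  affine <- structure(RNifti::xform(imgs[[1L]]), code = NULL)
  flat <- do.call(rbind, lapply(imgs, as.vector))
  mask <- resolve_mask(flat, d, mask_policy)
  volume_set(flat[, as.vector(mask), drop = FALSE], dim = d, voxdim = voxdim,
             mask = mask, affine = affine,
             subjects = sub("\\.nii(\\.gz)?$", "", basename(paths)))
}

resolve_mask <- function(flat, d, mask_policy) {
  if (is.array(mask_policy)) {
    stopifnot(is.logical(mask_policy), all(dim(mask_policy) == d))
    return(mask_policy)
  }
  finite <- colSums(!is.finite(flat)) == 0L
  keep <- switch(mask_policy,
    all = rep(TRUE, ncol(flat)),
    finite = finite,
    finite_nonconstant = {
      v <- rep(FALSE, ncol(flat))
      v[finite] <- matrixStats_colVars(flat[, finite, drop = FALSE]) > 0
      if (nrow(flat) == 1L) v <- finite  # variance undefined for one subject
      v
    },
    stop("unknown mask_policy: ", mask_policy, call. = FALSE))
  array(keep, d)
}

# colVars without extra dependencies
matrixStats_colVars <- function(m) {
  if (nrow(m) < 2L) return(rep(NA_real_, ncol(m)))
  cm <- colMeans(m)
  colSums(sweep(m, 2L, cm)^2) / (nrow(m) - 1L)
}

#' Write a volume set to NIfTI files
#'
#' @param vol A `volume_set`.
#' @param dir Output directory (created if needed).
#' @param prefix Filename prefix; files are `<prefix>_<subject>.nii.gz`.
#' @param fill Value for out-of-mask voxels.
#' @return Invisibly, the written paths.
#' @export
write_volumes <- function(vol, dir, prefix = "vol", fill = 0) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- rownames(vol$data)
  if (is.null(ids)) ids <- sprintf("%03d", seq_len(nrow(vol$data)))
  paths <- file.path(dir, paste0(prefix, "_", ids, ".nii.gz"))
  for (i in seq_len(nrow(vol$data))) {
    arr <- array(fill, vol$dim)
    arr[vol$mask] <- vol$data[i, ]
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- vol$voxdim
    RNifti::writeNifti(img, paths[i])
  }
  invisible(paths)
}

#' Construct a region atlas
#'
#' @param labels Integer 3D array; 0 is background, named regions >= 1.
#' @param names Character vector of region names, indexed by label value
#'   (either named by label or in label order `1..max`).
#' @param hemisphere Optional character vector (`"L"`/`"R"`) parallel to
#'   `names`.
#' @param voxdim Voxel sizes in mm.
#' @return An object of class `region_atlas`.
#' @export
region_atlas <- function(labels, names, hemisphere = NULL, voxdim = c(2, 2, 2)) {
  stopifnot(length(dim(labels)) == 3L)
  labels <- array(as.integer(labels), dim(labels))
  lab_values <- sort(unique(labels[labels > 0L]))
  if (is.null(base::names(names))) {
    base::names(names) <- as.character(seq_along(names))
  }
  present <- as.integer(base::names(names)) %in% lab_values
  if (!all(present)) {
    stop("atlas labels missing from the label volume: ",
         paste(base::names(names)[!present], collapse = ", "), call. = FALSE)
  }
  if (!is.null(hemisphere)) {
    stopifnot(length(hemisphere) == length(names), all(hemisphere %in% c("L", "R")))
  }
  structure(list(labels = labels, names = names, hemisphere = hemisphere,
                 voxdim = as.numeric(voxdim)),
            class = "region_atlas")
}

#' @export
print.region_atlas <- function(x, ...) {
  cat("<region_atlas> ", length(x$names), " regions on grid ",
      paste(dim(x$labels), collapse = "x"), "\n", sep = "")
  invisible(x)
}

#' Regional mean extraction
#'
#' Mean value of each atlas region over the in-mask voxels of a volume set.
#' Regions with no in-mask voxel yield `NA` with a warning.
#'
#' @param vol A `volume_set`.
#' @param atlas A `region_atlas` on the same grid.
#' @return Subjects x regions numeric matrix (columns named by region).
#' @export
regional_means <- function(vol, atlas) {
  if (!all(dim(atlas$labels) == vol$dim)) {
    stop("atlas and volume grids differ", call. = FALSE)
  }
  lab_in_mask <- atlas$labels[vol$mask]
  out <- matrix(NA_real_, nrow(vol$data), length(atlas$names),
                dimnames = list(rownames(vol$data), unname(atlas$names)))
  for (k in seq_along(atlas$names)) {
    lab <- as.integer(names(atlas$names)[k])
    sel <- lab_in_mask == lab
    if (!any(sel)) {
      warning("region '", atlas$names[k], "' has no in-mask voxels", call. = FALSE)
      next
    }
    out[, k] <- rowMeans(vol$data[, sel, drop = FALSE])
  }
  out
}

#' Build a GLM design matrix from a subject table
#'
#' Intercept + predictor of interest + covariates, in that column order.
#' Covariates enter unstandardized (binary 0/1, age in years). Longitudinal
#' designs include the inter-scan interval by listing `"interval"` among the
#' covariates.
#'
#' @param table Subject table (data frame).
#' @param predictor Column name of the predictor of interest, or a numeric
#'   vector of length `nrow(table)` (then named via `predictor_name`).
#' @param covariates Character vector of covariate column names (may be
#'   empty).
#' @param predictor_name Name used for a numeric `predictor`.
#' @return Numeric matrix with attribute `"predictor"` naming the column of
#'   interest; full column rank is enforced.
#' @export
build_design <- function(table, predictor, covariates = character(),
                         predictor_name = "predictor") {
  if (anyDuplicated(covariates)) {
    stop("duplicate covariate requested: ",
         paste(unique(covariates[duplicated(covariates)]), collapse = ", "),
         call. = FALSE)
  }
  if (is.character(predictor)) {
    if (!predictor %in% names(table)) stop("predictor column not found: ", predictor,
                                           call. = FALSE)
    if (predictor %in% covariates) {
      stop("predictor also requested as covariate: ", predictor, call. = FALSE)
    }
    pvec <- table[[predictor]]
    pname <- predictor
  } else {
    pvec <- as.numeric(predictor)
    if (length(pvec) != nrow(table)) stop("numeric predictor has wrong length",
                                          call. = FALSE)
    pname <- predictor_name
  }
  missing_cov <- setdiff(covariates, names(table))
  if (length(missing_cov)) stop("covariate columns not found: ",
                                paste(missing_cov, collapse = ", "), call. = FALSE)
  X <- cbind(`(Intercept)` = 1, stats::setNames(list(pvec), pname)[[1]])
  colnames(X)[2] <- pname
  for (cv in covariates) X <- cbind(X, stats::setNames(list(as.numeric(table[[cv]])), cv)[[1]])
  colnames(X) <- c("(Intercept)", pname, covariates)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[seq(qrX$rank + 1L, ncol(X))]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  attr(X, "predictor") <- pname
  X
}
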