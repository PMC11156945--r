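# Along-tract statistics: skeletonize a tract mask into a centerline, divide
# it into equal-arc-length segments, assign voxels to segments, and fit a GLM
# of segment mean diffusivity against odor identification.

#' Skeletonize a tract mask into equal-length segments
#'
#' The centerline is the distance-weighted shortest path through the
#' 26-connected voxel graph of the mask between the endpoints, smoothed with
#' a spline and resampled to equal arc-length steps; the arc is cut into
#' `n_segments` equal-length segments and every mask voxel is assigned to the
#' segment of its nearest centerline sample (ties toward the lower segment
#' index).
#'
#' @param mask Logical 3D array.
#' @param source_point,target_point Endpoints in world mm.
#' @param n_segments Number of segments (default 100).
#' @param voxdim Voxel sizes, mm.
#' @param origin World coordinate of the corner of voxel (1,1,1); voxel
#'   centers sit at `origin + (index - 0.5) * voxdim`.
#' @param smooth Spline-smooth the raw voxel path before resampling?
#' @return Object of class `tract_skeleton`: `centerline` (dense equal-arc
#'   points, mm), `arc` (cumulative arc length), `segment_boundaries`
#'   (`n_segments + 1` arc cut points), `voxel_assignment` (segment index per
#'   mask voxel, in `which(mask)` order), `n_segments`, plus the geometry.
#' @export
skeletonize <- function(mask, source_point, target_point, n_segments = 100L,
                        voxdim = c(2, 2, 2), origin = c(0, 0, 0),
                        smooth = TRUE) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L, n_segments >= 2L)
  d <- dim(mask)
  idx <- which(mask)
  if (!length(idx)) stop("empty tract mask", call. = FALSE)
  co <- arrayInd(idx, d)
  world <- sweep(sweep(co - 0.5, 2L, voxdim, "*"), 2L, origin, "+")
  g <- mask_voxel_graph(mask, voxdim)
  src <- nearest_point_index(rbind(as.numeric(source_point)), world)
  tgt <- nearest_point_index(rbind(as.numeric(target_point)), world)
  comp <- igraph::components(g)
  if (comp$membership[src] != comp$membership[tgt]) {
    stop("tract mask is disconnected between the endpoints (",
         comp$no, " components; source in component ", comp$membership[src],
         ", target in component ", comp$membership[tgt], ")", call. = FALSE)
  }
  # compute the path between the endpoints in a canonical order, so the
  # centerline geometry cannot depend on which endpoint is called the source
  # (shortest-path tie-breaks would otherwise pick different equal-length
  # paths); orient the result to the requested direction afterwards
  flip <- src > tgt
  ends <- if (flip) c(tgt, src) else c(src, tgt)
  path <- igraph::shortest_paths(g, from = ends[1], to = ends[2],
                                 output = "vpath")$vpath[[1]]
  pts <- world[as.integer(path), , drop = FALSE]
  if (smooth && nrow(pts) >= 8L) {
    s <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
    df <- max(4, min(12, nrow(pts) / 6))
    pts <- sapply(1:3, function(a) {
      stats::predict(stats::smooth.spline(s, pts[, a], df = df), s)$y
    })
  }
  n_out <- 10L * n_segments + 1L
  cur <- interpolate_curve(pts, n_out = n_out)
  total <- cur$arc[length(cur$arc)]
  point_segment <- pmin(floor(cur$arc / total * n_segments) + 1L, n_segments)
  nn <- nearest_point_index(world, cur$points)
  assignment <- point_segment[nn]
  centerline <- cur$points
  arc <- cur$arc
  if (flip) {  # mirror the canonical result back to the requested direction
    centerline <- centerline[nrow(centerline):1, , drop = FALSE]
    arc <- total - rev(arc)
    assignment <- n_segments + 1L - assignment
  }
  structure(list(centerline = centerline, arc = arc,
                 segment_boundaries = seq(0, total, length.out = n_segments + 1L),
                 voxel_assignment = assignment, n_segments = as.integer(n_segments),
                 mask = mask, voxdim = voxdim, origin = origin),
            class = "tract_skeleton")
}

# weighted 26-connectivity graph over mask voxels (edge weight = physical
# distance)
mask_voxel_graph <- function(mask, voxdim) {
  d <- dim(mask)
  idx <- which(mask)
  nv <- length(idx)
  id <- array(0L, d)
  id[idx] <- seq_len(nv)
  co <- arrayInd(idx, d)
  offs <- neighbor_offsets(26)
  from <- integer(0); to <- integer(0); w <- numeric(0)
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
    w <- c(w, rep(sqrt(sum((offs[k, ] * voxdim)^2)), sum(hit)))
  }
  g <- igraph::make_empty_graph(n = nv, directed = FALSE)
  if (length(from)) {
    g <- igraph::add_edges(g, rbind(from, to))
    igraph::E(g)$weight <- w
  }
  g
}

#' @export
print.tract_skeleton <- function(x, ...) {
  cat("<tract_skeleton> ", x$n_segments, " segments over ",
      round(max(x$arc), 1), " mm; ", length(x$voxel_assignment),
      " assigned voxels\n", sep = "")
  invisible(x)
}

#' Per-segment mean diffusivity profiles
#'
#' @param skel A [skeletonize()] result.
#' @param md A [volume_set()] of MD volumes on the same mask.
#' @return Subjects x segments matrix of segment mean MD; empty segments are
#'   `NA`.
#' @export
segment_profiles <- function(skel, md) {
  stopifnot(inherits(skel, "tract_skeleton"), inherits(md, "volume_set"))
  if (ncol(md$data) != length(skel$voxel_assignment)) {
    stop("MD volume mask does not match the skeleton's tract mask", call. = FALSE)
  }
  out <- matrix(NA_real_, nrow(md$data), skel$n_segments,
                dimnames = list(rownames(md$data),
                                paste0("seg_", sprintf("%03d", seq_len(skel$n_segments)))))
  for (s in seq_len(skel$n_segments)) {
    sel <- skel$voxel_assignment == s
    if (any(sel)) out[, s] <- rowMeans(md$data[, sel, drop = FALSE])
  }
  out
}

#' Along-tract GLM of segment MD against odor identification
#'
#' One GLM per segment with the smell-identification composite (or another
#' predictor) as the variable of interest. Output rows are ordered from the
#' source endpoint to the target.
#'
#' @param profiles Subjects x segments matrix from [segment_profiles()].
#' @param table Subject table.
#' @param predictor Predictor column name (default `"upsit"`).
#' @param covariates Covariate column names.
#' @param fdr Add Benjamini-Hochberg adjusted p-values over segments?
#' @return Data frame with one row per segment: `segment`, `t`, `z`, `p`
#'   (and `p_fdr` when requested); `NA` for empty segments. Attribute
#'   `"df"` carries the residual degrees of freedom.
#' @export
along_tract_glm <- function(profiles, table, predictor = "upsit",
                            covariates = c("age", "sex", "smoking"),
                            fdr = FALSE) {
  stopifnot(nrow(profiles) == nrow(table))
  n_seg <- ncol(profiles)
  empty <- colSums(is.na(profiles)) > 0
  if (mean(empty) > 0.5) {
    stop("more than half of the tract segments are empty; refusing", call. = FALSE)
  }
  design <- build_design(table, predictor, covariates)
  jcol <- match(attr(design, "predictor"), colnames(design))
  fit <- ols_tstats(profiles[, !empty, drop = FALSE], design, jcol)
  out <- data.frame(segment = seq_len(n_seg), t = NA_real_, z = NA_real_,
                    p = NA_real_)
  out$t[!empty] <- fit$t
  out$z[!empty] <- fit$z
  out$p[!empty] <- fit$p
  if (fdr) out$p_fdr <- stats::p.adjust(out$p, method = "BH")
  attr(out, "df") <- fit$df
  attr(out, "predictor") <- attr(design, "predictor")
  out
}
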