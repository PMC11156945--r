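# Directional tau-spreading graph: conditioned baseline-to-longitudinal
# partial correlations (the bipartite graph), weighted node degrees, the
# PC-algorithm skeleton over baseline values, and backbone orientation.

#' Assemble a regional tau panel
#'
#' @param baseline,followup Subjects x regions SUVr matrices with identical
#'   region column names.
#' @param interval Inter-scan interval per subject, years (> 0).
#' @param covariates Optional data frame of per-subject covariates.
#' @param extra Optional subjects x k matrix of additional baseline-side
#'   node values (e.g. dorsal raphe nucleus mean diffusivity); these act as
#'   sources only.
#' @return Object of class `regional_tau_panel`.
#' @export
tau_panel <- function(baseline, followup, interval, covariates = NULL,
                      extra = NULL) {
  baseline <- as.matrix(baseline); followup <- as.matrix(followup)
  if (!identical(dim(baseline), dim(followup)) ||
      !identical(colnames(baseline), colnames(followup))) {
    stop("baseline and follow-up must share subjects and region names",
         call. = FALSE)
  }
  if (length(interval) == 1L) interval <- rep(interval, nrow(baseline))
  if (any(interval <= 0)) stop("interval must be > 0", call. = FALSE)
  if (!is.null(extra)) {
    extra <- as.matrix(extra)
    stopifnot(nrow(extra) == nrow(baseline), !is.null(colnames(extra)))
  }
  structure(list(baseline = baseline, followup = followup, interval = interval,
                 regions = colnames(baseline), covariates = covariates,
                 extra = extra),
            class = "regional_tau_panel")
}

#' Directional bipartite tau-connectivity graph
#'
#' For every ordered region pair (i -> j, i != j) the partial correlation of
#' baseline tau at the source i with follow-up tau at the target j is
#' computed conditioning on baseline tau at the target itself (so the
#' association reflects longitudinal accumulation, not cross-sectional
#' covariance) plus any covariates. Edges with p below `alpha` form the
#' directed graph; the full r and p matrices are kept.
#'
#' @param panel A `regional_tau_panel` (from [tau_panel()] or
#'   [generate_regional_tau()]).
#' @param covariates Data frame or matrix of per-subject covariates appended
#'   to every conditioning set (e.g. age, sex, APOE4, smoking, interval), or
#'   `NULL`.
#' @param alpha Edge significance level (default 0.05, uncorrected; set
#'   `fdr = TRUE` for a Benjamini-Hochberg variant).
#' @param fdr Apply BH correction over all ordered pairs before thresholding?
#' @return Object of class `spread_graph`: `r` and `p` (sources x targets
#'   matrices, rows = source region, `NA` on the diagonal), `adjacency`
#'   (logical), `alpha`, `df`, `degenerate` flags (targets whose conditioned
#'   follow-up is numerically constant).
#' @export
tau_connectivity <- function(panel, covariates = NULL, alpha = 0.05, fdr = FALSE) {
  stopifnot(inherits(panel, "regional_tau_panel"))
  B <- panel$baseline; f <- panel$followup
  n <- nrow(B)
  if (is.null(covariates) && !is.null(panel$covariates)) covariates <- panel$covariates
  C <- if (is.null(covariates)) NULL else as.matrix(as.data.frame(covariates))
  q <- 1L + if (is.null(C)) 0L else ncol(C)  # conditioning variables per test
  if (n < q + 12L) stop("too few subjects for the conditioning set", call. = FALSE)
  sources <- cbind(B, panel$extra)
  src_names <- colnames(sources)
  tgt_names <- colnames(B)
  r <- p <- matrix(NA_real_, length(src_names), length(tgt_names),
                   dimnames = list(src_names, tgt_names))
  degenerate <- stats::setNames(rep(FALSE, length(tgt_names)), tgt_names)
  df <- n - 2L - q
  for (j in seq_along(tgt_names)) {
    cond <- cbind(1, B[, j], C)
    qrC <- qr(cond)
    ry <- qr.resid(qrC, f[, j])
    if (stats::sd(ry) < 1e-12 * max(stats::sd(f[, j]), 1e-300)) {
      degenerate[j] <- TRUE
      next
    }
    RX <- qr.resid(qrC, sources)
    for (i in seq_along(src_names)) {
      if (src_names[i] == tgt_names[j]) next
      sx <- stats::sd(RX[, i])
      if (sx < 1e-300) next  # constant source region
      rij <- stats::cor(RX[, i], ry)
      r[i, j] <- rij
      tstat <- rij * sqrt(df / max(1 - rij^2, 1e-300))
      p[i, j] <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
    }
  }
  pthr <- p
  if (fdr) pthr[] <- stats::p.adjust(p, method = "BH")
  adjacency <- !is.na(pthr) & pthr < alpha
  structure(list(r = r, p = p, adjacency = adjacency, alpha = alpha,
                 fdr = fdr, df = df, degenerate = degenerate,
                 sources = src_names, targets = tgt_names),
            class = "spread_graph")
}

#' @export
print.spread_graph <- function(x, ...) {
  cat("<spread_graph> ", sum(x$adjacency), " directed edges among ",
      length(x$sources), " sources / ", length(x$targets),
      " targets (alpha = ", x$alpha, ")\n", sep = "")
  invisible(x)
}

#' Weighted in/out degrees of a spreading graph
#'
#' Out-degree of a region is the sum of |r| over its significant outgoing
#' edges; in-degree the analogue over incoming edges.
#'
#' @param g A `spread_graph`.
#' @return Data frame: `region`, `out_degree`, `in_degree`.
#' @export
node_degrees <- function(g) {
  stopifnot(inherits(g, "spread_graph"))
  w <- abs(g$r) * g$adjacency
  regions <- union(g$sources, g$targets)
  out <- stats::setNames(rep(0, length(regions)), regions)
  inn <- out
  rs <- rowSums(w, na.rm = TRUE)
  cs <- colSums(w, na.rm = TRUE)
  out[g$sources] <- rs
  inn[g$targets] <- cs
  data.frame(region = regions, out_degree = unname(out), in_degree = unname(inn))
}

# Partial correlation of x, y given columns S of data, via the inverse of the
# correlation submatrix.
pcor_from_cor <- function(C, i, j, S) {
  sub <- C[c(i, j, S), c(i, j, S), drop = FALSE]
  P <- tryCatch(solve(sub), error = function(e) MASS_ginv(sub))
  -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
}

# minimal pseudo-inverse fallback for near-singular conditioning sets
MASS_ginv <- function(m, tol = 1e-10) {
  sv <- svd(m)
  pos <- sv$d > tol * sv$d[1]
  sv$v[, pos, drop = FALSE] %*% (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
}

# size-m subsets of a node vector, lexicographic; robust to length-1 input
# (utils::combn would expand a scalar into seq_len)
enumerate_subsets <- function(x, m) {
  if (m == 0L) return(list(integer(0)))
  if (length(x) < m) return(list())
  if (length(x) == 1L) return(list(x))
  utils::combn(x, m, simplify = FALSE)
}

# Fisher-z test of (partial) correlation
fisher_z_p <- function(r, n, q) {
  r <- min(max(r, -0.999999), 0.999999)
  stat <- sqrt(n - q - 3) * abs(atanh(r))
  2 * stats::pnorm(stat, lower.tail = FALSE)
}

#' PC-algorithm skeleton via partial-correlation independence tests
#'
#' Classic skeleton phase: starting from the complete undirected graph, for
#' conditioning-set sizes l = 0, 1, ... each remaining edge X-Y is tested
#' against every size-l subset of X's current neighbors (lexicographic
#' enumeration over sorted neighbor lists, so the result is deterministic);
#' the edge is removed, and the separating set recorded, at the first
#' independence found (Fisher-z test at level `alpha`).
#'
#' @param data Subjects x nodes numeric matrix (e.g. baseline tau plus DRN
#'   mean diffusivity).
#' @param alpha Independence test level.
#' @param max_cond Largest conditioning-set size to try.
#' @return Object of class `backbone_graph`: `edges` (logical adjacency),
#'   `sepsets` (named list of separating sets per removed edge), `alpha`,
#'   `nodes`, `oriented` (set by [orient_backbone()], `NULL` here).
#' @export
pc_skeleton <- function(data, alpha = 0.05, max_cond = Inf) {
  data <- as.matrix(data)
  n <- nrow(data); pn <- ncol(data)
  if (pn < 2L) stop("need at least two nodes", call. = FALSE)
  nodes <- colnames(data)
  if (is.null(nodes)) nodes <- paste0("V", seq_len(pn))
  C <- stats::cor(data)
  adj <- matrix(TRUE, pn, pn, dimnames = list(nodes, nodes))
  diag(adj) <- FALSE
  sepsets <- list()
  l <- 0L
  while (l <= max_cond) {
    # Fisher-z needs n - |S| - 3 - 2 ... require positive variance term
    if (n - l - 2L - 3L < 1L) {
      if (l == 0L) stop("sample too small for any Fisher-z test", call. = FALSE)
      warning("sample size limits conditioning sets to size ", l - 1L,
              call. = FALSE)
      break
    }
    any_big_enough <- FALSE
    for (i in seq_len(pn)) {
      for (j in seq_len(pn)) {
        if (i >= j || !adj[i, j]) next
        done <- FALSE
        for (anchor in c(i, j)) {
          nbrs <- sort(setdiff(which(adj[anchor, ]), c(i, j)))
          if (length(nbrs) < l) next
          any_big_enough <- TRUE
          subsets <- enumerate_subsets(nbrs, l)
          for (S in subsets) {
            r <- pcor_from_cor(C, i, j, S)
            if (!is.finite(r)) next
            if (fisher_z_p(r, n, length(S)) > alpha) {
              adj[i, j] <- adj[j, i] <- FALSE
              sepsets[[paste(nodes[i], nodes[j], sep = "|")]] <- nodes[S]
              done <- TRUE
              break
            }
          }
          if (done) break
        }
      }
    }
    if (!any_big_enough && l > 0L) break
    l <- l + 1L
  }
  structure(list(edges = adj, sepsets = sepsets, alpha = alpha, nodes = nodes,
                 n = n, oriented = NULL),
            class = "backbone_graph")
}

#' @export
print.backbone_graph <- function(x, ...) {
  cat("<backbone_graph> ", sum(x$edges) / 2, " undirected edges among ",
      length(x$nodes), " nodes; ", length(x$sepsets),
      " separating sets recorded\n", sep = "")
  if (!is.null(x$oriented)) {
    cat("  orientation: ", sum(x$oriented == "forward"), " forward, ",
        sum(x$oriented == "backward"), " backward, ",
        sum(x$oriented == "both"), " bidirectional, ",
        sum(x$oriented == "undirected"), " undirected\n", sep = "")
  }
  invisible(x)
}

#' Orient backbone edges from the bipartite spreading graph
#'
#' Each skeleton edge {i, j} gets an arrow i -> j when the spreading graph
#' has a significant i -> j edge but not j -> i, a bidirectional mark when
#' both directions are significant, and stays undirected when neither is.
#'
#' @param skeleton A `backbone_graph` from [pc_skeleton()].
#' @param g A `spread_graph` from [tau_connectivity()] over (at least) the
#'   same nodes.
#' @return The skeleton with `oriented`: a data frame (`from`, `to`,
#'   `direction` in `forward`/`backward`/`both`/`undirected`, where
#'   `forward` means `from -> to` in the node-order listing).
#' @export
orient_backbone <- function(skeleton, g) {
  stopifnot(inherits(skeleton, "backbone_graph"), inherits(g, "spread_graph"))
  sig <- function(a, b) {
    if (!(a %in% g$sources) || !(b %in% g$targets)) return(FALSE)
    isTRUE(g$adjacency[a, b])
  }
  out <- data.frame(from = character(0), to = character(0),
                    direction = character(0), stringsAsFactors = FALSE)
  nodes <- skeleton$nodes
  for (i in seq_along(nodes)) for (j in seq_along(nodes)) {
    if (i >= j || !skeleton$edges[i, j]) next
    fwd <- sig(nodes[i], nodes[j])
    bwd <- sig(nodes[j], nodes[i])
    dir <- if (fwd && bwd) "both" else if (fwd) "forward" else
      if (bwd) "backward" else "undirected"
    out <- rbind(out, data.frame(from = nodes[i], to = nodes[j],
                                 direction = dir, stringsAsFactors = FALSE))
  }
  skeleton$oriented <- out$direction
  skeleton$oriented_edges <- out
  skeleton
}
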