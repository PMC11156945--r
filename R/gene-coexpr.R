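# Regional transcriptome processing and co-expression clustering: sample to
# region mapping with donor medians, Pearson co-expression, agglomerative
# clustering with silhouette-selected k, per-cluster hemisphere-z-scored
# maps, and gene-trait bipartite networks.

#' Map donor samples to atlas regions and build an expression matrix
#'
#' Samples are averaged within region per donor, the median across donors is
#' taken, and each gene is z-scored across regions. Samples may carry an
#' explicit `region` assignment or `x`,`y`,`z` world coordinates, in which
#' case the nearest labelled atlas voxel within `max_distance` is used.
#'
#' @param samples Data frame with `donor` plus either `region` or
#'   `x`,`y`,`z` columns, one row per sample.
#' @param expr Samples x genes numeric matrix aligned to `samples` rows.
#' @param atlas Optional [region_atlas()] (required for coordinate mapping);
#'   its names/hemispheres populate the region metadata.
#' @param regions Optional data frame (`region`, `hemisphere`) when mapping
#'   by explicit assignment without an atlas.
#' @param max_distance Coordinate-mapping bound, mm.
#' @return An `expression_matrix` (see [generate_expression()]); regions
#'   with no sample in any donor are dropped with a warning.
#' @export
map_samples_to_regions <- function(samples, expr, atlas = NULL, regions = NULL,
                                   max_distance = 4) {
  expr <- as.matrix(expr)
  stopifnot(nrow(samples) == nrow(expr), "donor" %in% names(samples))
  if (!"region" %in% names(samples)) {
    if (is.null(atlas)) stop("coordinate mapping needs an atlas", call. = FALSE)
    stopifnot(all(c("x", "y", "z") %in% names(samples)))
    lab_idx <- which(atlas$labels > 0L)
    co <- arrayInd(lab_idx, dim(atlas$labels))
    world <- sweep(co - 0.5, 2L, atlas$voxdim, "*")
    pts <- as.matrix(samples[, c("x", "y", "z")])
    nn <- nearest_point_index(pts, world)
    dist <- sqrt(rowSums((pts - world[nn, , drop = FALSE])^2))
    lab <- atlas$labels[lab_idx[nn]]
    samples$region <- unname(atlas$names[as.character(lab)])
    samples$region[dist > max_distance] <- NA
  }
  meta <- region_metadata(atlas, regions, samples$region)
  donors <- unique(samples$donor)
  region_names <- meta$region
  per_donor <- array(NA_real_, c(length(donors), length(region_names), ncol(expr)))
  for (di in seq_along(donors)) {
    for (ri in seq_along(region_names)) {
      sel <- samples$donor == donors[di] & samples$region %in% region_names[ri]
      if (any(sel)) per_donor[di, ri, ] <- colMeans(expr[sel, , drop = FALSE])
    }
  }
  med <- apply(per_donor, c(2, 3), stats::median, na.rm = TRUE)  # regions x genes
  vals <- t(med)  # genes x regions
  empty <- colSums(is.finite(vals)) == 0
  if (any(empty)) {
    warning("regions with no samples in any donor dropped: ",
            paste(region_names[empty], collapse = ", "), call. = FALSE)
    vals <- vals[, !empty, drop = FALSE]
    meta <- meta[!empty, , drop = FALSE]
  }
  vals <- row_zscore(vals)
  dimnames(vals) <- list(colnames(expr), meta$region)
  structure(list(values = vals, regions = meta, clusters = NULL),
            class = "expression_matrix")
}

region_metadata <- function(atlas, regions, seen) {
  if (!is.null(atlas)) {
    data.frame(region = unname(atlas$names),
               hemisphere = if (is.null(atlas$hemisphere)) NA_character_ else
                 atlas$hemisphere,
               stringsAsFactors = FALSE)
  } else if (!is.null(regions)) {
    stopifnot("region" %in% names(regions))
    regions
  } else {
    data.frame(region = sort(unique(stats::na.omit(seen))),
               hemisphere = NA_character_, stringsAsFactors = FALSE)
  }
}

#' Gene-gene co-expression matrix
#'
#' Pairwise Pearson correlation of gene expression profiles across regions
#' (pairwise-complete over missing regions).
#'
#' @param expr An `expression_matrix` or a genes x regions matrix.
#' @return Symmetric genes x genes correlation matrix with unit diagonal.
#' @export
coexpression <- function(expr) {
  vals <- if (inherits(expr, "expression_matrix")) expr$values else as.matrix(expr)
  C <- stats::cor(t(vals), use = "pairwise.complete.obs")
  diag(C) <- 1
  C
}

#' Cluster genes by co-expression with silhouette-selected k
#'
#' Agglomerative hierarchical clustering on distance `1 - r`; the number of
#' clusters maximizing the mean silhouette width over `k_range` is selected.
#'
#' @param coexpr Gene-gene correlation matrix from [coexpression()].
#' @param k_range Candidate cluster counts (within `2 .. n_genes - 1`).
#' @param linkage `"average"` (default), `"complete"` or `"ward.D2"`.
#' @return Object of class `coexpr_clusters`: `labels` (gene -> cluster),
#'   `k`, `silhouette` (mean width per candidate k), `hclust`, `coexpr`.
#' @export
cluster_genes <- function(coexpr, k_range = 2:8, linkage = "average") {
  ng <- nrow(coexpr)
  if (any(k_range < 2L) || any(k_range > ng - 1L)) {
    stop("k_range must lie within [2, n_genes - 1]", call. = FALSE)
  }
  d <- stats::as.dist(1 - coexpr)
  hc <- stats::hclust(d, method = linkage)
  sil <- vapply(k_range, function(k) {
    lab <- stats::cutree(hc, k = k)
    mean(cluster::silhouette(lab, d)[, "sil_width"])
  }, numeric(1))
  k <- k_range[which.max(sil)]
  labels <- stats::cutree(hc, k = k)
  structure(list(labels = labels, k = k,
                 silhouette = stats::setNames(sil, k_range),
                 hclust = hc, coexpr = coexpr, linkage = linkage),
            class = "coexpr_clusters")
}

#' @export
print.coexpr_clusters <- function(x, ...) {
  cat("<coexpr_clusters> k = ", x$k, " (mean silhouette ",
      round(max(x$silhouette), 3), "); sizes: ",
      paste(table(x$labels), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Per-cluster mean-expression region maps
#'
#' Mean expression over each cluster's genes per region, then z-scored
#' separately within each hemisphere (the display convention for cluster
#' maps).
#'
#' @param expr An `expression_matrix` with hemisphere metadata.
#' @param clusters A `coexpr_clusters` (or an integer label vector).
#' @param rescale Z-score within hemisphere (default `TRUE`); `FALSE`
#'   returns raw cluster means.
#' @return Clusters x regions matrix.
#' @export
cluster_maps <- function(expr, clusters, rescale = TRUE) {
  stopifnot(inherits(expr, "expression_matrix"))
  labels <- if (inherits(clusters, "coexpr_clusters")) clusters$labels else clusters
  stopifnot(length(labels) == nrow(expr$values))
  ks <- sort(unique(labels))
  maps <- t(sapply(ks, function(k) {
    colMeans(expr$values[labels == k, , drop = FALSE])
  }))
  rownames(maps) <- paste0("cluster_", ks)
  if (rescale) {
    hemi <- expr$regions$hemisphere
    for (h in unique(hemi)) {
      sel <- hemi == h
      if (sum(sel) > 1L) {
        maps[, sel] <- t(scale(t(maps[, sel, drop = FALSE])))
      }
    }
  }
  maps
}

#' Gene-trait bipartite network with domain reduction
#'
#' Gene-trait edges are weighted by the best (minimum) GWAS p-value over the
#' supporting associations; traits are grouped into domains (tau, amyloid,
#' Alzheimer's disease, aging, cognition, brain) and the reduced gene-domain
#' network takes the best p over member traits. Associations at or above the
#' catalog inclusion bound (1e-5) are rejected.
#'
#' @param gene_trait_table Data frame with columns `gene`, `trait`, `p`.
#' @param domain_map Data frame with columns `trait`, `domain`; traits
#'   outside the map are dropped.
#' @param p_bound Catalog inclusion bound (default `1e-5`).
#' @return Object of class `gene_trait_network`: `edges` (gene, trait,
#'   weight), `domain_edges` (gene, domain, weight), `domains`.
#' @export
gene_trait_network <- function(gene_trait_table, domain_map, p_bound = 1e-5) {
  stopifnot(all(c("gene", "trait", "p") %in% names(gene_trait_table)),
            all(c("trait", "domain") %in% names(domain_map)))
  tab <- gene_trait_table
  bad <- tab$p >= p_bound
  if (any(bad)) {
    warning(sum(bad), " association(s) at p >= ", p_bound, " rejected",
            call. = FALSE)
    tab <- tab[!bad, , drop = FALSE]
  }
  tab <- tab[tab$trait %in% domain_map$trait, , drop = FALSE]
  if (!nrow(tab)) {
    return(structure(list(edges = data.frame(gene = character(0),
                                             trait = character(0),
                                             weight = numeric(0)),
                          domain_edges = data.frame(gene = character(0),
                                                    domain = character(0),
                                                    weight = numeric(0)),
                          domains = unique(domain_map$domain)),
                     class = "gene_trait_network"))
  }
  tab$domain <- domain_map$domain[match(tab$trait, domain_map$trait)]
  best <- function(df, by) {
    agg <- stats::aggregate(df$p, by = df[by], FUN = min)
    names(agg)[ncol(agg)] <- "weight"
    agg[do.call(order, agg[by]), , drop = FALSE]
  }
  edges <- best(tab, c("gene", "trait"))
  domain_edges <- best(tab, c("gene", "domain"))
  structure(list(edges = edges, domain_edges = domain_edges,
                 domains = unique(domain_map$domain)),
            class = "gene_trait_network")
}

#' @export
print.gene_trait_network <- function(x, ...) {
  cat("<gene_trait_network> ", nrow(x$edges), " gene-trait edges, ",
      nrow(x$domain_edges), " gene-domain edges\n", sep = "")
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement of two labelings; 1 is identity (up to label
#' renaming), 0 is chance level.
#'
#' @param a,b Integer or factor label vectors of equal length.
#' @return Numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- ch2(length(a))
  expected <- sum_a * sum_b / n
  denom <- (sum_a + sum_b) / 2 - expected
  if (denom == 0) return(1)
  (sum_ij - expected) / denom
}
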