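# End-to-end orchestration: one config drives simulate -> norms -> voxelwise
# -> biomarker -> tracts -> graph -> genes, with a JSON manifest recording
# parameters, seeds and output hashes. Stages communicate through files in
# the run directory, so a run can be resumed, inspected or failed mid-way.

#' Build a run configuration
#'
#' Defaults use the full-study parameter set (RANSAC 5000 iterations /
#' sample size 20 / threshold 6; odorant-count null 5000 x 40 maps;
#' cluster-extent null 10000 iterations). `demo = TRUE` shrinks cohort,
#' grids and iteration counts to a laptop-scale smoke run.
#'
#' @param out_dir Run directory.
#' @param seed Master seed; per-stage sub-seeds are derived from it.
#' @param demo Use small demo sizes?
#' @param ... Named overrides of individual fields (applied last).
#' @return A nested list of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, demo = FALSE, ...) {
  cfg <- list(
    out_dir = out_dir,
    seed = as.integer(seed),
    n_subjects = if (demo) 300L else 418L,
    n_imaging = if (demo) 60L else 155L,
    covariates = c("age", "sex", "apoe4", "smoking"),
    cognition_covariates = c("age", "sex", "apoe4", "smoking", "education"),
    tract_covariates = c("age", "sex", "smoking"),
    atlas_block = 6L,
    paint = list(smoothing_fwhm = 4, noise_sd = 0.05),
    ransac = list(n_iter = if (demo) 500L else 5000L, sample_size = 20L,
                  threshold = 6),
    count_null = list(n_iter = if (demo) 300L else 5000L, alpha = 0.05),
    cluster = list(n_iter = if (demo) 300L else 10000L, voxel_p = 0.05,
                   connectivity = 26),
    biomarker = list(n_components = 3L),
    tract = list(n_segments = 100L, effect_segments = 40:60),
    graph = list(alpha = 0.05, max_cond = if (demo) 2L else 3L),
    genes = list(n_genes = if (demo) 80L else 390L, k_clusters = 4L,
                 within_cluster_corr = 0.8, k_range = 2:6)
  )
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with (a subset of) [run_config()] fields; `out_dir`
#'   and `seed` must be present.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$out_dir)) stop("config must set out_dir", call. = FALSE)
  base <- run_config(out_dir = y$out_dir, seed = y$seed %||% 1L,
                     demo = isTRUE(y$demo))
  for (nm in setdiff(names(y), c("out_dir", "seed", "demo"))) {
    if (is.list(base[[nm]]) && is.list(y[[nm]])) {
      for (sub in names(y[[nm]])) base[[nm]][[sub]] <- y[[nm]][[sub]]
    } else {
      base[[nm]] <- y[[nm]]
    }
  }
  base
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pipeline_stages <- function() {
  c("simulate", "norms", "voxelwise", "biomarker", "tracts", "graph", "genes")
}

#' Run the full synthetic study
#'
#' Executes the requested stages in dependency order inside
#' `config$out_dir`, each reading its inputs from files the earlier stages
#' wrote. On a stage failure the error is recorded in the manifest, later
#' stages are skipped, and prior outputs are retained.
#'
#' @param config A [run_config()] (or a YAML path for [read_run_config()]).
#' @param stages Stage subset to run, in pipeline order.
#' @return Invisibly, the manifest list (also written to
#'   `out_dir/manifest.json`).
#' @export
run_all <- function(config, stages = pipeline_stages()) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, pipeline_stages(), several.ok = TRUE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(unclass(config), file.path(config$out_dir, "config.yaml"))
  seeds <- stats::setNames(derive_seeds(config$seed, length(pipeline_stages())),
                           pipeline_stages())
  manifest <- list(package = "olfatau",
                   version = as.character(utils::packageVersion("olfatau")),
                   seed = config$seed,
                   stage_seeds = as.list(seeds),
                   stages = list())
  failed <- FALSE
  for (st in pipeline_stages()) {
    if (!st %in% stages) next
    if (failed) {
      manifest$stages[[st]] <- list(status = "skipped")
      next
    }
    res <- tryCatch({
      outputs <- do.call(paste0("stage_", st),
                         list(config = config, seed = seeds[[st]]))
      list(status = "ok", outputs = outputs,
           md5 = manifest_hashes(config$out_dir, outputs))
    }, error = function(e) {
      list(status = "failed", error = conditionMessage(e))
    })
    manifest$stages[[st]] <- res
    if (res$status == "failed") failed <- TRUE
  }
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

# md5 of text outputs only (volume files are listed but not hashed)
manifest_hashes <- function(out_dir, outputs) {
  rel <- outputs[grepl("\\.(csv|json|yaml)$", outputs)]
  paths <- file.path(out_dir, rel)
  h <- tools::md5sum(paths)
  stats::setNames(as.list(unname(h)), rel)
}

stage_dir <- function(config, st) {
  d <- file.path(config$out_dir, st)
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  d
}

require_input <- function(config, rel, stage) {
  path <- file.path(config$out_dir, rel)
  if (!file.exists(path)) {
    stop("stage '", stage, "' missing required input: ", rel, call. = FALSE)
  }
  path
}

stage_simulate <- function(config, seed) {
  d <- stage_dir(config, "simulate")
  sub_seeds <- derive_seeds(seed, 6)
  spec <- cohort_spec(n_subjects = config$n_subjects, seed = sub_seeds[1])
  cohort <- generate_cohort(spec)
  write_table_csv(cohort, file.path(d, "cohort.csv"))
  imaging <- cohort[seq_len(min(config$n_imaging, nrow(cohort))), ]
  utils::write.csv(imaging, file.path(d, "cohort_imaging.csv"), row.names = FALSE)

  truth <- spread_truth()
  panel <- generate_regional_tau(imaging, truth, seed = sub_seeds[2])
  write_table_csv(panel, file.path(d, "panel.csv"))
  atlas <- synthetic_region_atlas(truth$regions, block = config$atlas_block)
  saveRDS_free_atlas(atlas, d)
  vol_b <- paint_volumes(panel, atlas, "baseline",
                         smoothing_fwhm = config$paint$smoothing_fwhm,
                         noise_sd = config$paint$noise_sd, seed = sub_seeds[3])
  write_volumes(vol_b, file.path(d, "tau_baseline"), prefix = "tau")
  utils::write.csv(data.frame(subject_id = imaging$subject_id),
                   file.path(d, "imaging_subjects.csv"), row.names = FALSE)

  tr_spec <- tract_phantom_spec(n_segments = config$tract$n_segments,
                                effect_segments = config$tract$effect_segments,
                                seed = sub_seeds[4])
  tract <- generate_tract_md(imaging, tr_spec)
  write_volumes(tract$md, file.path(d, "tract_md"), prefix = "md")
  utils::write.csv(data.frame(origin = tract$origin,
                              endpoint_source = tract$endpoints[1, ],
                              endpoint_target = tract$endpoints[2, ]),
                   file.path(d, "tract_geometry.csv"), row.names = FALSE)
  mask_img <- RNifti::asNifti(array(as.integer(tract$mask), dim(tract$mask)))
  RNifti::pixdim(mask_img) <- tract$voxdim
  RNifti::writeNifti(mask_img, file.path(d, "tract_mask.nii.gz"))

  etruth <- expression_truth(n_genes = config$genes$n_genes,
                             k_clusters = config$genes$k_clusters,
                             within_cluster_corr = config$genes$within_cluster_corr,
                             seed = sub_seeds[5])
  emat <- generate_expression(etruth)
  utils::write.csv(cbind(gene = rownames(emat$values), as.data.frame(emat$values)),
                   file.path(d, "expression.csv"), row.names = FALSE)
  utils::write.csv(emat$regions, file.path(d, "expression_regions.csv"),
                   row.names = FALSE)
  gt <- synthetic_gene_traits(rownames(emat$values), seed = sub_seeds[6])
  utils::write.csv(gt$table, file.path(d, "gene_traits.csv"), row.names = FALSE)
  utils::write.csv(gt$domains, file.path(d, "trait_domains.csv"), row.names = FALSE)
  file.path("simulate", c("cohort.csv", "cohort_imaging.csv", "panel.csv",
                          "atlas_regions.csv", "tract_geometry.csv",
                          "expression.csv", "expression_regions.csv",
                          "gene_traits.csv", "trait_domains.csv"))
}

# atlas serialized as NIfTI labels + region CSV (text manifest hashes the CSV)
saveRDS_free_atlas <- function(atlas, d) {
  img <- RNifti::asNifti(array(as.integer(atlas$labels), dim(atlas$labels)))
  RNifti::pixdim(img) <- atlas$voxdim
  RNifti::writeNifti(img, file.path(d, "atlas.nii.gz"))
  utils::write.csv(data.frame(label = as.integer(names(atlas$names)),
                              region = unname(atlas$names)),
                   file.path(d, "atlas_regions.csv"), row.names = FALSE)
}

read_atlas_files <- function(d) {
  img <- RNifti::readNifti(file.path(d, "atlas.nii.gz"))
  meta <- utils::read.csv(file.path(d, "atlas_regions.csv"))
  region_atlas(array(as.integer(img), dim(img)),
               stats::setNames(meta$region, meta$label),
               voxdim = RNifti::pixdim(img)[1:3])
}

# small synthetic gene-trait catalog extract keyed to the six domains
synthetic_gene_traits <- function(genes, seed = NULL, fraction = 0.15) {
  domains <- c("tau", "amyloid", "alzheimers", "aging", "cognition", "brain")
  traits <- paste0(rep(domains, each = 2), "_trait_", rep(1:2, length(domains)))
  dmap <- data.frame(trait = traits, domain = rep(domains, each = 2),
                     stringsAsFactors = FALSE)
  with_seed(seed, {
    hit <- sample(genes, max(1L, round(fraction * length(genes))))
    rows <- do.call(rbind, lapply(hit, function(g) {
      k <- sample(1:3, 1)
      data.frame(gene = g, trait = sample(traits, k),
                 p = 10^stats::runif(k, -12, -5.05), stringsAsFactors = FALSE)
    }))
    list(table = rows, domains = dmap)
  })
}

stage_norms <- function(config, seed) {
  d <- stage_dir(config, "norms")
  cohort <- utils::read.csv(require_input(config, "simulate/cohort.csv", "norms"))
  fit <- fit_ransac_quadratic(cohort$age, cohort$upsit,
                              n_iter = config$ransac$n_iter,
                              sample_size = config$ransac$sample_size,
                              threshold = config$ransac$threshold, seed = seed)
  dev <- deviation_scores(fit, cohort$age, cohort$upsit)
  jsonlite::write_json(list(coeffs = as.list(fit$coeffs),
                            n_inliers = fit$n_inliers,
                            threshold = fit$threshold,
                            n_iter = fit$n_iter, sample_size = fit$sample_size),
                       file.path(d, "ransac.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(data.frame(subject_id = cohort$subject_id, age = cohort$age,
                              upsit = cohort$upsit, deviation = dev,
                              inlier = fit$inlier_mask),
                   file.path(d, "deviations.csv"), row.names = FALSE)
  rates <- odorant_rates(cohort)
  utils::write.csv(data.frame(odorant = names(rates), rate = as.numeric(rates)),
                   file.path(d, "odorant_rates.csv"), row.names = FALSE)
  file.path("norms", c("ransac.json", "deviations.csv", "odorant_rates.csv"))
}

read_tau_volumes <- function(config, stage) {
  d <- file.path(config$out_dir, "simulate")
  require_input(config, "simulate/cohort_imaging.csv", stage)
  paths <- sort(list.files(file.path(d, "tau_baseline"), full.names = TRUE,
                           pattern = "\\.nii"))
  if (!length(paths)) stop("stage '", stage, "' missing required input: ",
                           "simulate/tau_baseline volumes", call. = FALSE)
  atlas <- read_atlas_files(d)
  vol <- read_volumes(paths, mask_policy = atlas$labels > 0L)
  list(vol = vol, atlas = atlas,
       table = utils::read.csv(file.path(d, "cohort_imaging.csv")))
}

stage_voxelwise <- function(config, seed) {
  d <- stage_dir(config, "voxelwise")
  sub_seeds <- derive_seeds(seed, 3)
  inp <- read_tau_volumes(config, "voxelwise")
  design <- build_design(inp$table, "upsit", config$covariates)
  map <- fit_voxel_glm(inp$vol, design, return_residuals = TRUE)
  fwhm <- estimate_smoothness(map$residuals)
  maps <- odorant_maps(inp$vol, inp$table, config$covariates)
  null <- odorant_count_null(inp$vol, fwhm, n_iter = config$count_null$n_iter,
                             alpha = config$count_null$alpha, seed = sub_seeds[1])
  cm <- count_map(maps, alpha = config$count_null$alpha,
                  threshold_count = null$threshold_count)
  cl <- cluster_correct(map, fwhm, voxel_p = config$cluster$voxel_p,
                        n_iter = config$cluster$n_iter,
                        connectivity = config$cluster$connectivity,
                        seed = sub_seeds[2])
  utils::write.csv(data.frame(voxel = seq_along(map$z), t = map$t, z = map$z,
                              p = map$p, count = cm$counts,
                              flagged = cm$flagged),
                   file.path(d, "voxel_stats.csv"), row.names = FALSE)
  utils::write.csv(cl$clusters, file.path(d, "clusters.csv"), row.names = FALSE)
  jsonlite::write_json(list(fwhm_est = as.numeric(fwhm),
                            threshold_count = null$threshold_count,
                            n_missing_odorants = cm$n_missing,
                            count_null_iter = null$n_iter,
                            cluster_null_iter = cl$n_iter),
                       file.path(d, "summary.json"), auto_unbox = TRUE, digits = NA)
  file.path("voxelwise", c("voxel_stats.csv", "clusters.csv", "summary.json"))
}

stage_biomarker <- function(config, seed) {
  d <- stage_dir(config, "biomarker")
  inp <- read_tau_volumes(config, "biomarker")
  assoc <- build_assoc_matrix(inp$table, list(tau = inp$vol), config$covariates)
  comp <- pca_components(assoc, n_components = config$biomarker$n_components)
  scores <- score_subjects(comp, inp$table)
  bp <- backproject(scores, inp$vol, inp$table, config$covariates,
                    correct = TRUE, voxel_p = config$cluster$voxel_p,
                    n_iter = config$cluster$n_iter, seed = seed)
  utils::write.csv(cbind(data.frame(odorant = rownames(comp$weights)),
                         as.data.frame(comp$weights)),
                   file.path(d, "loadings.csv"), row.names = FALSE)
  utils::write.csv(data.frame(subject_id = inp$table$subject_id, score = scores),
                   file.path(d, "scores.csv"), row.names = FALSE)
  utils::write.csv(bp$clusters$clusters, file.path(d, "backprojection_clusters.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(variance_explained = comp$variance_explained,
                            n_components = comp$n_components),
                       file.path(d, "summary.json"), auto_unbox = TRUE, digits = NA)
  file.path("biomarker", c("loadings.csv", "scores.csv",
                           "backprojection_clusters.csv", "summary.json"))
}

stage_tracts <- function(config, seed) {
  d <- stage_dir(config, "tracts")
  sim <- file.path(config$out_dir, "simulate")
  geom <- utils::read.csv(require_input(config, "simulate/tract_geometry.csv",
                                        "tracts"))
  mask_img <- RNifti::readNifti(require_input(config, "simulate/tract_mask.nii.gz",
                                              "tracts"))
  mask <- array(as.integer(mask_img) > 0L, dim(mask_img))
  voxdim <- RNifti::pixdim(mask_img)[1:3]
  paths <- sort(list.files(file.path(sim, "tract_md"), full.names = TRUE,
                           pattern = "\\.nii"))
  md <- read_volumes(paths, mask_policy = mask)
  table <- utils::read.csv(file.path(sim, "cohort_imaging.csv"))
  skel <- skeletonize(mask, geom$endpoint_source, geom$endpoint_target,
                      n_segments = config$tract$n_segments,
                      voxdim = voxdim, origin = geom$origin)
  prof <- segment_profiles(skel, md)
  res <- along_tract_glm(prof, table, covariates = config$tract_covariates)
  utils::write.csv(res, file.path(d, "along_tract.csv"), row.names = FALSE)
  utils::write.csv(cbind(subject_id = table$subject_id, as.data.frame(prof)),
                   file.path(d, "profiles.csv"), row.names = FALSE)
  file.path("tracts", c("along_tract.csv", "profiles.csv"))
}

stage_graph <- function(config, seed) {
  d <- stage_dir(config, "graph")
  panel_df <- utils::read.csv(require_input(config, "simulate/panel.csv", "graph"))
  b_cols <- grep("^baseline_", names(panel_df), value = TRUE)
  f_cols <- grep("^followup_", names(panel_df), value = TRUE)
  baseline <- as.matrix(panel_df[b_cols]); colnames(baseline) <- sub("^baseline_", "", b_cols)
  followup <- as.matrix(panel_df[f_cols]); colnames(followup) <- sub("^followup_", "", f_cols)
  table <- utils::read.csv(file.path(config$out_dir, "simulate/cohort_imaging.csv"))
  panel <- tau_panel(baseline, followup, panel_df$interval,
                     covariates = table[c("age", "sex", "apoe4", "smoking",
                                          "interval")])
  g <- tau_connectivity(panel, alpha = config$graph$alpha)
  deg <- node_degrees(g)
  skel <- pc_skeleton(baseline, alpha = config$graph$alpha,
                      max_cond = config$graph$max_cond)
  skel <- orient_backbone(skel, g)
  utils::write.csv(as.data.frame(g$r), file.path(d, "adjacency_r.csv"))
  utils::write.csv(as.data.frame(g$p), file.path(d, "adjacency_p.csv"))
  utils::write.csv(deg, file.path(d, "degrees.csv"), row.names = FALSE)
  utils::write.csv(skel$oriented_edges, file.path(d, "backbone_edges.csv"),
                   row.names = FALSE)
  file.path("graph", c("adjacency_r.csv", "adjacency_p.csv", "degrees.csv",
                       "backbone_edges.csv"))
}

stage_genes <- function(config, seed) {
  d <- stage_dir(config, "genes")
  ex <- utils::read.csv(require_input(config, "simulate/expression.csv", "genes"),
                        check.names = FALSE)
  vals <- as.matrix(ex[, -1]); rownames(vals) <- ex$gene
  regions <- utils::read.csv(file.path(config$out_dir,
                                       "simulate/expression_regions.csv"))
  emat <- structure(list(values = vals, regions = regions, clusters = NULL),
                    class = "expression_matrix")
  co <- coexpression(emat)
  cl <- cluster_genes(co, k_range = config$genes$k_range)
  maps <- cluster_maps(emat, cl)
  gt <- utils::read.csv(file.path(config$out_dir, "simulate/gene_traits.csv"))
  dmap <- utils::read.csv(file.path(config$out_dir, "simulate/trait_domains.csv"))
  net <- gene_trait_network(gt, dmap)
  utils::write.csv(data.frame(gene = names(cl$labels), cluster = cl$labels),
                   file.path(d, "cluster_labels.csv"), row.names = FALSE)
  utils::write.csv(cbind(cluster = rownames(maps), as.data.frame(maps)),
                   file.path(d, "cluster_maps.csv"), row.names = FALSE)
  utils::write.csv(net$edges, file.path(d, "trait_edges.csv"), row.names = FALSE)
  utils::write.csv(net$domain_edges, file.path(d, "domain_edges.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(k = cl$k,
                            silhouette = as.list(cl$silhouette)),
                       file.path(d, "summary.json"), auto_unbox = TRUE, digits = NA)
  file.path("genes", c("cluster_labels.csv", "cluster_maps.csv",
                       "trait_edges.csv", "domain_edges.csv", "summary.json"))
}
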