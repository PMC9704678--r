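#' Pipeline run configuration
#'
#' Bundles everything one end-to-end run needs.  Inputs may be file paths
#' (foci text/CSV, expression CSV, atlas NIfTI) or `"synthetic"`, in which
#' case the generators produce them from `truth`.
#'
#' @param foci path to a foci file, a [foci_dataset()], or `"synthetic"`.
#' @param foci_dialect `"csv"` or `"sleuth"` when `foci` is a path.
#' @param expression path to an expression CSV, a named-by-gene list of
#'   donor lists, or `"synthetic"`.
#' @param atlas path to a label NIfTI, a [network_atlas()], or
#'   `"synthetic"`.
#' @param genes character vector of gene symbols (non-empty).
#' @param grid analysis [voxel_grid()].
#' @param mask analysis mask `brain_volume` (default: ellipsoid brain box).
#' @param ale an [ale_config()].
#' @param perm a [permutation_config()].
#' @param truth a [synthetic_truth()] driving any synthetic inputs.
#' @param n_experiments,subjects_range synthetic foci scenario.
#' @param k_networks synthetic atlas size.
#' @param out_dir output directory (`NULL`: nothing written).
#' @param seed master seed; sub-seeds are derived per stage.
#' @return an object of class `run_config`.
#' @export
run_config <- function(foci = "synthetic", foci_dialect = "csv",
                       expression = "synthetic", atlas = "synthetic",
                       genes = c("MECP2", "SHANK1", "SHANK2", "SHANK3",
                                 "NLGN3", "NLGN4X", "NRXN1", "CNTNAP2"),
                       grid = default_grid(4),
                       mask = NULL,
                       ale = ale_config(),
                       perm = permutation_config(),
                       truth = NULL,
                       n_experiments = 40L,
                       subjects_range = c(10L, 30L),
                       k_networks = 9L,
                       out_dir = NULL,
                       seed = 1L) {
  stopifnot(length(genes) >= 1L)
  if (is.null(mask)) mask <- ellipsoid_mask(grid)
  seed <- as.integer(seed)
  ale$seed <- sub_seed(seed, "ale")
  perm$seed <- sub_seed(seed, "perm")
  if (is.null(truth)) truth <- synthetic_truth(seed = sub_seed(seed, "truth"))
  else truth$seed <- sub_seed(seed, "truth")
  for (nm in c("foci", "expression", "atlas")) {
    v <- get(nm)
    if (is.character(v) && length(v) == 1L && v != "synthetic" &&
        !file.exists(v))
      stop("run_config: ", nm, " path does not exist: ", v)
  }
  structure(list(foci = foci, foci_dialect = foci_dialect,
                 expression = expression, atlas = atlas, genes = genes,
                 grid = grid, mask = mask, ale = ale, perm = perm,
                 truth = truth, n_experiments = as.integer(n_experiments),
                 subjects_range = as.integer(subjects_range),
                 k_networks = as.integer(k_networks),
                 out_dir = out_dir, seed = seed),
            class = "run_config")
}

pipeline_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full pipeline
#'
#' Stages: (1) ALE meta-analysis per direction (decrease / increase);
#' (2) voxel-wise gene expression maps; (3) cluster-wise ALE-expression
#' correlations (genes x directions volumes); (4) network projection and
#' cluster-permutation significance.  All volumes, tables and a JSON
#' manifest (config, seeds, versions, file checksums) are written to
#' `cfg$out_dir` when set.  Re-running with the same config reproduces
#' identical tables.
#'
#' @param cfg a [run_config()].
#' @return an object of class `pipeline_result`: list with `ale`
#'   (per-direction `ale_result`s), `gene_maps`, `correlations`
#'   (`correlation_volume_set`), `network_stats`, `exclusions`, and
#'   `manifest`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  t0 <- Sys.time()

  # ---- inputs -------------------------------------------------------
  dataset <- resolve_foci(cfg)
  exclusions <- attr(dataset, "exclusions") %||%
    data.frame(experiment_id = character(), rule = character(),
               detail = character())
  atlas <- resolve_atlas(cfg)

  # ---- stage 1: ALE per direction ----------------------------------
  ale_res <- list()
  for (dir in c("decrease", "increase")) {
    exps <- Filter(function(e) e$direction == dir, dataset$experiments)
    if (!length(exps))
      stop("pipeline stage ALE failed: no '", dir, "' experiments")
    sub <- foci_dataset(exps, label = paste0(dataset$label, ":", dir))
    cfg_dir <- cfg$ale
    cfg_dir$seed <- sub_seed(cfg$ale$seed, dir)
    pipeline_log("ale", "%s: %d experiments, %d foci", dir, length(exps),
                 sum(vapply(exps, function(e) nrow(e$foci), 0L)))
    ale_res[[dir]] <- run_ale(sub, cfg$grid, cfg$mask, cfg_dir)
    pipeline_log("ale", "%s: %d clusters retained", dir,
                 nrow(ale_res[[dir]]$cluster_table))
  }

  # ---- stage 2: gene expression maps -------------------------------
  donor_sets <- resolve_expression(cfg, ale_res)
  gene_maps <- lapply(cfg$genes, function(g) {
    if (is.null(donor_sets[[g]]))
      stop("pipeline stage genemap failed: no expression samples for ", g)
    build_gene_map(donor_sets[[g]], g, cfg$grid, cfg$mask)
  })
  pipeline_log("genemap", "%d gene maps built", length(gene_maps))

  # ---- stage 3: cluster-wise correlations --------------------------
  zmaps <- lapply(ale_res, `[[`, "z")
  labels <- lapply(ale_res, `[[`, "clusters")
  corrset <- correlate_all(zmaps, gene_maps, labels)
  pipeline_log("correlate", "%d correlation volumes, %d cluster rows",
               length(corrset$volumes), nrow(corrset$table))

  # ---- stage 4: network permutation --------------------------------
  stats <- network_analysis(corrset, labels, atlas, cfg$perm)
  pipeline_log("networks", "%d (gene, direction, network) rows",
               nrow(stats))

  res <- structure(list(ale = ale_res, gene_maps = gene_maps,
                        correlations = corrset, network_stats = stats,
                        atlas = atlas, exclusions = exclusions,
                        config = cfg, manifest = NULL),
                   class = "pipeline_result")
  if (!is.null(cfg$out_dir))
    res$manifest <- write_pipeline_outputs(res, cfg$out_dir, t0)
  res
}

resolve_foci <- function(cfg) {
  if (inherits(cfg$foci, "foci_dataset")) return(cfg$foci)
  if (identical(cfg$foci, "synthetic"))
    return(generate_foci(cfg$truth, cfg$n_experiments,
                         cfg$subjects_range, cfg$mask))
  read_foci(cfg$foci, dialect = cfg$foci_dialect)
}

resolve_atlas <- function(cfg) {
  if (inherits(cfg$atlas, "network_atlas")) {
    a <- cfg$atlas
    if (!same_grid(a$labels$grid, cfg$grid)) {
      lab <- regrid_atlas(a$labels, cfg$grid)
      a <- network_atlas(lab, a$names)
    }
    return(a)
  }
  if (identical(cfg$atlas, "synthetic"))
    return(generate_atlas(cfg$grid, cfg$k_networks,
                          seed = sub_seed(cfg$seed, "atlas"),
                          mask = cfg$mask))
  lab <- regrid_atlas(read_volume(cfg$atlas), cfg$grid)
  present <- setdiff(sort(unique(round(as.vector(lab$values)))), 0)
  network_atlas(lab, stats::setNames(paste0("Net", present),
                                     as.character(present)))
}

resolve_expression <- function(cfg, ale_res) {
  if (is.list(cfg$expression)) return(cfg$expression)
  if (identical(cfg$expression, "synthetic")) {
    # reference pattern for planted effects: the decrease Z map
    ref <- ale_res$decrease$z
    tgt <- NULL
    if (!is.null(cfg$truth$gene_effects)) {
      # target region: voxels inside decrease clusters
      tgt <- ale_res$decrease$clusters$values > 0
    }
    out <- lapply(cfg$genes, function(g)
      generate_expression(cfg$truth, g, cfg$mask,
                          reference_pattern = ref, target_mask = tgt))
    names(out) <- cfg$genes
    return(out)
  }
  read_expression_samples(cfg$expression)
}

write_pipeline_outputs <- function(res, out_dir, t0) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  wv <- function(vol, name) {
    path <- file.path(out_dir, paste0(name, ".nii.gz"))
    write_volume(vol, path)
    files <<- c(files, path)
  }
  wt <- function(df, name) {
    path <- file.path(out_dir, paste0(name, ".csv"))
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }
  for (dir in names(res$ale)) {
    r <- res$ale[[dir]]
    wv(r$ale, paste0("ale_", dir))
    wv(r$p, paste0("p_", dir))
    wv(r$z, paste0("z_", dir))
    wv(r$clusters, paste0("clusters_", dir))
    wt(r$cluster_table, paste0("cluster_table_", dir))
  }
  for (gm in res$gene_maps) wv(gm$volume, paste0("gene_", gm$gene))
  for (key in names(res$correlations$volumes)) {
    safe <- gsub("|", "_", key, fixed = TRUE)
    wv(res$correlations$volumes[[key]], paste0("corr_", safe))
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    srows <- res$network_stats[res$network_stats$gene == parts[1] &
                                 res$network_stats$direction == parts[2], ]
    wv(significance_mask_volume(res$correlations$volumes[[key]],
                                res$atlas, srows),
       paste0("corr_sig_", safe))
  }
  wt(res$correlations$table, "cluster_correlations")
  wt(res$network_stats, "network_stats")
  for (dir in names(res$ale))
    wt(network_stats_wide(res$network_stats, dir),
       paste0("network_stats_wide_", dir))
  wt(res$exclusions, "exclusions")
  wv(res$atlas$labels, "atlas")

  manifest <- list(
    created = format(t0, tz = "UTC", usetz = TRUE),
    seed = res$config$seed,
    genes = res$config$genes,
    grid = list(shape = res$config$grid$shape,
                affine = as.vector(res$config$grid$affine)),
    ale_config = unclass(res$config$ale),
    permutation_config = unclass(res$config$perm),
    fwhm_used = lapply(res$ale, `[[`, "fwhm_used"),
    versions = list(R = as.character(getRversion()),
                    alexpr = as.character(
                      utils::packageVersion("alexpr"))),
    checksums = as.list(tools::md5sum(sort(files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}
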