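# Self-calibration harness: replicated synthetic runs of the
# correlation + network-permutation stages against a fixed cluster
# geometry, used to measure the empirical type-I error of the
# cluster-permutation test (rho = 0) and its power to recover a planted
# within-network gene-alteration association (rho > 0).

# greedy placement of `n_blocks` axis-aligned blocks (dim `bd` voxels)
# fully inside parcel `parcel`, pairwise separated by at least `gap`
# voxels (Chebyshev, so blocks never touch even diagonally)
block_positions <- function(parcel_lab, parcel, n_blocks, bd = c(3L, 4L, 3L),
                            gap = 1L) {
  shape <- dim(parcel_lab)
  chosen <- list()
  ok_corner <- function(c0) {
    sub <- parcel_lab[c0[1]:(c0[1] + bd[1] - 1L),
                      c0[2]:(c0[2] + bd[2] - 1L),
                      c0[3]:(c0[3] + bd[3] - 1L)]
    all(sub == parcel)
  }
  separated <- function(c0) {
    for (p in chosen) {
      if (all(c0 < p + bd + gap) && all(p < c0 + bd + gap)) return(FALSE)
    }
    TRUE
  }
  for (k in seq_len(shape[3] - bd[3] + 1L)) {
    for (j in seq_len(shape[2] - bd[2] + 1L)) {
      for (i in seq_len(shape[1] - bd[1] + 1L)) {
        if (length(chosen) >= n_blocks) break
        c0 <- c(i, j, k)
        if (ok_corner(c0) && separated(c0))
          chosen[[length(chosen) + 1L]] <- c0
      }
    }
  }
  chosen
}

# fixed study geometry for the calibration harness: grid, mask, atlas,
# cluster-label volume (blocks of `block_dim` voxels; `n_target` blocks
# in the target parcel, `n_other` in each remaining parcel), the target
# network label, and a smooth deterministic reference pattern standing in
# for the ALE Z map
calibration_geometry <- function(seed = 1L, voxel_mm = 4,
                                 half_mm = 36, k = 9L,
                                 n_target = 6L, n_other = 2L,
                                 block_dim = c(3L, 4L, 3L), gap = 1L) {
  grid <- default_grid(voxel_mm, c(-half_mm, half_mm),
                       c(-half_mm, half_mm), c(-half_mm, half_mm))
  mask <- brain_volume(grid, 1, mask = array(TRUE, grid$shape))
  atlas <- generate_atlas(grid, k, seed = seed, mask = mask,
                          symmetric = TRUE)
  plab <- round(atlas$labels$values)
  # target parcel: the one admitting the most separated blocks
  capacity <- vapply(seq_len(k), function(p)
    length(block_positions(plab, p, n_target, block_dim, gap)), 0L)
  target <- which.max(capacity)
  if (capacity[target] < n_target)
    stop("calibration geometry: no parcel can host ", n_target, " blocks")
  lab <- array(0, grid$shape)
  cl <- 0L
  paint <- function(c0, bd) {
    cl <<- cl + 1L
    lab[c0[1]:(c0[1] + bd[1] - 1L), c0[2]:(c0[2] + bd[2] - 1L),
        c0[3]:(c0[3] + bd[3] - 1L)] <<- cl
  }
  target_ids <- integer(0)
  for (c0 in block_positions(plab, target, n_target, block_dim, gap)) {
    paint(c0, block_dim)
    target_ids <- c(target_ids, cl)
  }
  for (p in setdiff(seq_len(k), target)) {
    pos <- block_positions(plab, p, n_other, block_dim, gap)
    for (c0 in pos) paint(c0, block_dim)
  }
  labels <- brain_volume(grid, lab, array(TRUE, grid$shape))
  # smooth reference pattern standing in for the ALE Z map: correlation
  # length well above the typical nearest-sample distance (so Voronoi
  # propagation preserves planted sample-level correlation), and even in
  # x so the left-right symmetry assumed when mirroring left-only donors
  # holds exactly
  xyz <- grid_coords(grid)
  zref <- brain_volume(grid, array(
    cos(xyz[, 1] / 15) + sin(xyz[, 2] / 18) + sin(xyz[, 3] / 14) +
      0.5 * cos(xyz[, 1] / 9) * sin((xyz[, 2] + xyz[, 3]) / 22),
    grid$shape),
    array(TRUE, grid$shape))
  list(grid = grid, mask = mask, atlas = atlas, labels = labels,
       target_network = unname(atlas$names[as.character(target)]),
       target_ids = target_ids, n_clusters = cl, zref = zref)
}

#' Empirical calibration of the cluster-permutation network test
#'
#' Runs replicated synthetic experiments against one fixed cluster
#' geometry (block clusters on a 4 mm grid, several per bilateral
#' network parcel, with a deterministic smooth reference pattern
#' standing in for the ALE Z map).  Each replicate draws a fresh donor
#' panel, builds the gene expression map, correlates it with the
#' reference within every cluster, and applies the cluster-permutation
#' network test.
#'
#' With `rho = 0` the gene fields are independent of the reference
#' pattern, so the fraction of significant (network, replicate) cells
#' estimates the test's type-I error at level `1 - ci`.  With `rho > 0`
#' the planted correlation is confined to the clusters of one target
#' network, and the fraction of replicates in which that network comes
#' out significant estimates power.
#'
#' @param n_replicates number of replicate datasets.
#' @param rho planted sample-level correlation inside the target
#'   network's clusters (0 = null simulation).
#' @param cfg a [permutation_config()] (n_perm, ci, seed).
#' @param geometry_seed seed fixing the atlas/cluster geometry.
#' @param n_samples_per_donor expression samples per donor.
#' @param smoothness_mm expression field length scale.
#' @param half_mm half-width of the cubic analysis domain.
#' @param block_dim cluster block dimensions in voxels.
#' @param n_target,n_other clusters planted in the target parcel and (at
#'   most) in each remaining parcel.
#' @param n_left_only left-hemisphere-only donors out of the six.  The
#'   null (type-I) calibration defaults to bilateral donors: hemispheric
#'   mirroring copies a donor's left-hemisphere field onto the right, so
#'   a cluster and its mirror partner -- same bilateral network -- carry
#'   correlated r values, and the cluster-permutation null (which
#'   assumes exchangeable clusters) becomes anticonservative.  That
#'   dependence is a property of the mirroring assumption, not of the
#'   permutation machinery this calibration probes; set
#'   `n_left_only = 4` to measure the combined behaviour.
#' @return list with `per_network` (data.frame: replicate, network,
#'   mean_r, significant), `target_network`, `rejection_rate` (over all
#'   defined cells), and `target_rate` (over the target network only).
#' @export
simulate_network_calibration <- function(n_replicates = 100L, rho = 0,
                                         cfg = permutation_config(
                                           n_perm = 1000L, seed = 1L),
                                         geometry_seed = 1L,
                                         n_samples_per_donor = 500L,
                                         smoothness_mm = 8,
                                         half_mm = 44,
                                         block_dim = c(4L, 4L, 4L),
                                         n_target = 6L, n_other = 3L,
                                         gap = 1L,
                                         n_left_only = if (rho == 0) 0L
                                                       else 4L) {
  geo <- calibration_geometry(seed = geometry_seed, half_mm = half_mm,
                              block_dim = block_dim,
                              n_target = n_target, n_other = n_other,
                              gap = gap)
  counts <- cluster_network_counts(geo$labels, geo$atlas)
  # plant over the whole target parcel: the samples whose Voronoi cells
  # cover the target clusters live throughout the parcel, not only
  # inside the cluster voxels themselves.  The atlas parcels are
  # bilateral (x-symmetric), so left-only donors carry the planted
  # signal that mirroring then places into the right-hemisphere half of
  # the target network -- the same left-right symmetry the mirroring
  # step assumes.
  target_label <- names(geo$atlas$names)[
    unname(geo$atlas$names) == geo$target_network]
  target_mask <- round(geo$atlas$labels$values) == as.integer(target_label)
  cluster_mask <- brain_volume(geo$grid,
                               array(as.numeric(geo$labels$values > 0),
                                     geo$grid$shape),
                               mask = geo$labels$values > 0)
  rows <- vector("list", n_replicates)
  for (rep_i in seq_len(n_replicates)) {
    truth <- synthetic_truth(
      gene_effects = if (rho != 0)
        data.frame(gene = "SIM", target = "target", rho = rho) else NULL,
      expression_field_smoothness = smoothness_mm,
      n_samples_per_donor = n_samples_per_donor,
      n_left_only = n_left_only,
      seed = sub_seed(cfg$seed, paste0("calib", rep_i)))
    donors <- generate_expression(truth, "SIM", geo$mask,
                                  reference_pattern = geo$zref,
                                  target_mask = target_mask)
    # evaluate the tessellation on the cluster voxels only: nearest-
    # sample assignment does not depend on the evaluation mask, so the
    # values at cluster voxels are identical to a whole-mask build
    gm <- build_gene_map(donors, "SIM", geo$grid, cluster_mask)
    res <- lapply(seq_len(geo$n_clusters), function(k)
      correlate_cluster(geo$zref, gm, geo$labels, k, gene = "SIM",
                        direction = "decrease"))
    r <- vapply(res, function(x) if (isTRUE(x$ok)) x$r else NA_real_, 0.0)
    obs <- network_means_from_r(r, counts)
    null <- permutation_null(r, geo$labels, geo$atlas, cfg,
                             stream = paste0("calibperm", rep_i))
    st <- assess_significance(
      data.frame(network = names(obs), label = seq_along(obs),
                 mean_r = unname(obs),
                 n_voxels_used = as.integer(colSums(counts))),
      null, cfg)
    rows[[rep_i]] <- data.frame(replicate = rep_i, network = st$network,
                                mean_r = st$mean_r,
                                significant = st$significant)
  }
  per_network <- do.call(rbind, rows)
  defined <- is.finite(per_network$mean_r)
  tgt <- per_network$network == geo$target_network
  list(per_network = per_network,
       target_network = geo$target_network,
       rejection_rate = mean(per_network$significant[defined]),
       target_rate = mean(per_network$significant[tgt & defined]))
}
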