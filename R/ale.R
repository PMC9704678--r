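#' ALE configuration
#'
#' Parameters of the anatomical likelihood estimation meta-analysis.
#'
#' The Gaussian kernel width is either a fixed FWHM in mm (default 10 mm)
#' or the tag `"sample_size_rule"`, under which an experiment on n subjects
#' gets `FWHM = fwhm_ref * sqrt(n_ref / n)` (wider kernels for smaller
#' samples, shrinking with the square root of the sample size).
#'
#' @param fwhm_mm positive number, or `"sample_size_rule"`.
#' @param fwhm_ref,n_ref reference FWHM (mm) and sample size for the
#'   sample-size rule.
#' @param alpha voxel-level significance threshold (default 0.05,
#'   uncorrected).
#' @param min_cluster_mm3 minimum cluster extent in mm^3 (default 150).
#' @param n_null number of random-foci null iterations (default 10000).
#' @param voxels_per_iter in-mask evaluation points sampled per null
#'   iteration (default 1).
#' @param connectivity cluster connectivity: 6, 18 or 26 (default 26).
#' @param within_experiment_combine `"max"` (default) or `"prob_union"`;
#'   how multiple focus kernels of one experiment combine into its
#'   modelled-activation map.
#' @param seed master seed for the null simulation.
#' @return an object of class `ale_config`.
#' @export
ale_config <- function(fwhm_mm = 10, fwhm_ref = 10, n_ref = 10,
                       alpha = 0.05, min_cluster_mm3 = 150,
                       n_null = 10000L, voxels_per_iter = 1L,
                       connectivity = 26L,
                       within_experiment_combine = c("max", "prob_union"),
                       seed = 1L) {
  within_experiment_combine <- match.arg(within_experiment_combine)
  if (is.character(fwhm_mm)) {
    stopifnot(fwhm_mm == "sample_size_rule")
  } else {
    stopifnot(is.numeric(fwhm_mm), fwhm_mm > 0)
  }
  stopifnot(alpha > 0, alpha < 1, min_cluster_mm3 > 0, n_null >= 1,
            connectivity %in% c(6L, 18L, 26L))
  structure(list(fwhm_mm = fwhm_mm, fwhm_ref = fwhm_ref, n_ref = n_ref,
                 alpha = alpha, min_cluster_mm3 = min_cluster_mm3,
                 n_null = as.integer(n_null),
                 voxels_per_iter = as.integer(voxels_per_iter),
                 connectivity = as.integer(connectivity),
                 within_experiment_combine = within_experiment_combine,
                 seed = as.integer(seed)),
            class = "ale_config")
}

# FWHM actually used for an experiment under the configured rule
experiment_fwhm <- function(cfg, n_subjects) {
  if (is.character(cfg$fwhm_mm))
    cfg$fwhm_ref * sqrt(cfg$n_ref / n_subjects)
  else cfg$fwhm_mm
}

#' Gaussian kernel width: FWHM to standard deviation
#'
#' `sigma = FWHM / sqrt(8 ln 2)`.
#'
#' @param fwhm_mm full width at half maximum, mm, > 0.
#' @return sigma in mm.
#' @export
kernel_sigma <- function(fwhm_mm) {
  if (any(!is.finite(fwhm_mm)) || any(fwhm_mm <= 0))
    stop("kernel_sigma: fwhm_mm must be positive")
  fwhm_mm / sqrt(8 * log(2))
}

# Gaussian probability mass per voxel at squared distances d2 (mm^2):
# density (sigma^3 (2 pi)^{3/2})^{-1} exp(-d2 / (2 sigma^2)) times the
# voxel volume.
gauss_mass <- function(d2, sigma, voxel_volume) {
  voxel_volume / (sigma^3 * (2 * pi)^1.5) * exp(-d2 / (2 * sigma^2))
}

#' Per-focus Gaussian kernel volume
#'
#' Three-dimensional Gaussian probability distribution centred on the
#' focus, evaluated at every voxel centre and scaled by the voxel volume so
#' that values are probability mass per voxel (summing to ~1 on a grid
#' extending several sigma beyond the focus).
#'
#' @param f a [focus()] in TAL space, or a length-3 numeric mm coordinate.
#' @param grid a [voxel_grid()].
#' @param sigma Gaussian standard deviation in mm, > 0.
#' @return a [brain_volume()] of kernel mass (full grid mask).
#' @export
focus_kernel <- function(f, grid, sigma) {
  stopifnot(sigma > 0)
  if (inherits(f, "focus")) {
    if (f$space != "TAL") stop("focus_kernel: focus must be in TAL space")
    f <- c(f$x, f$y, f$z)
  }
  f <- as.numeric(f)
  xyz <- grid_coords(grid)
  lo <- apply(xyz, 2, min); hi <- apply(xyz, 2, max)
  if (any(f < lo) || any(f > hi))
    warning("focus lies outside the grid bounding box; kernel truncated")
  d2 <- (xyz[, 1] - f[1])^2 + (xyz[, 2] - f[2])^2 + (xyz[, 3] - f[3])^2
  vals <- gauss_mass(d2, sigma, grid$voxel_volume)
  brain_volume(grid, array(vals, grid$shape),
               mask = array(TRUE, grid$shape))
}

#' Modelled-activation map of one experiment
#'
#' Combines the experiment's focus kernels into one volume.  Under
#' `"max"` each voxel takes the strongest single-focus mass (robust to
#' within-experiment focus multiplicity); under `"prob_union"` kernels
#' combine as independent probabilities, `1 - prod(1 - k_i)`.
#'
#' @param e an [experiment()] in TAL space.
#' @param grid a [voxel_grid()].
#' @param cfg an [ale_config()].
#' @return a [brain_volume()] with values in `[0, 1)`.
#' @export
experiment_ma_map <- function(e, grid, cfg = ale_config()) {
  if (e$space != "TAL")
    stop("experiment_ma_map: experiment must be in TAL space (convert first)")
  sigma <- kernel_sigma(experiment_fwhm(cfg, e$n_subjects))
  xyz <- grid_coords(grid)
  acc <- NULL
  for (i in seq_len(nrow(e$foci))) {
    d2 <- (xyz[, 1] - e$foci[i, 1])^2 + (xyz[, 2] - e$foci[i, 2])^2 +
      (xyz[, 3] - e$foci[i, 3])^2
    k <- gauss_mass(d2, sigma, grid$voxel_volume)
    acc <- if (is.null(acc)) {
      if (cfg$within_experiment_combine == "max") k else 1 - (1 - k)
    } else if (cfg$within_experiment_combine == "max") {
      pmax(acc, k)
    } else {
      1 - (1 - acc) * (1 - k)
    }
  }
  acc <- pmin(acc, 1 - .Machine$double.eps)
  brain_volume(grid, array(acc, grid$shape),
               mask = array(TRUE, grid$shape))
}

#' Union of modelled-activation maps into the ALE map
#'
#' The voxel-wise probabilistic union over experiments,
#' `ALE(v) = 1 - prod_e (1 - MA_e(v))`.
#'
#' @param ma_maps list of [brain_volume()]s sharing one grid, values in
#'   `[0, 1)`.
#' @return a [brain_volume()] of ALE values.
#' @export
ale_union <- function(ma_maps) {
  stopifnot(length(ma_maps) >= 1L)
  g <- ma_maps[[1]]$grid
  acc <- array(1, g$shape)
  for (m in ma_maps) {
    check_same_grid(ma_maps[[1]], m, "MA maps")
    if (any(m$values < 0) || any(m$values >= 1))
      stop("MA map values must lie in [0, 1)")
    acc <- acc * (1 - m$values)
  }
  brain_volume(g, 1 - acc, mask = array(TRUE, g$shape))
}

# ALE values for a block of null iterations.  `mass` is an n_foci x
# n_iter matrix of kernel masses of each random focus at its iteration's
# evaluation point; rows are partitioned into pseudo-experiments by
# `exp_of_focus`.  Per-experiment combine, then probabilistic union.
null_ale_values <- function(mass, exp_of_focus, combine) {
  surv <- rep(1, ncol(mass))  # prod over experiments of (1 - MA_e)
  for (e in unique(exp_of_focus)) {
    rows <- which(exp_of_focus == e)
    ma_e <- if (combine == "max") {
      Reduce(pmax, lapply(rows, function(r) mass[r, ]))
    } else {
      1 - Reduce(`*`, lapply(rows, function(r) 1 - mass[r, ]))
    }
    surv <- surv * (1 - pmin(ma_e, 1 - 1e-15))
  }
  1 - surv
}

#' Empirical random-foci null distribution of the ALE statistic
#'
#' For each iteration, `n` random foci (n = the observed total focus
#' count) are drawn uniformly within the analysis mask, partitioned into
#' pseudo-experiments matching the observed foci-per-experiment structure,
#' and the resulting ALE value is evaluated at randomly sampled in-mask
#' voxel centres.  The pooled values form the empirical null used to
#' convert ALE to p.
#'
#' @param foci_per_experiment integer vector: observed focus count of each
#'   experiment (its sum is the number of random foci per iteration).
#' @param mask a [brain_volume()] whose mask defines the sampling domain.
#' @param cfg an [ale_config()]; `n_null`, `voxels_per_iter`, the kernel
#'   rule and `seed` are used.
#' @param n_subjects integer vector aligned with `foci_per_experiment`
#'   (needed when the sample-size kernel rule is active); defaults to
#'   `n_ref` for all.
#' @return an object of class `ale_null`: list with sorted numeric
#'   `values` and `n` (sample count).
#' @export
ale_null <- function(foci_per_experiment, mask, cfg = ale_config(),
                     n_subjects = NULL) {
  stopifnot(all(foci_per_experiment >= 1))
  if (cfg$n_null < 100L)
    warning("n_null < 100: null tail estimates will be unstable")
  if (is.null(n_subjects))
    n_subjects <- rep(cfg$n_ref, length(foci_per_experiment))
  in_idx <- which(mask$mask)
  if (!length(in_idx)) stop("ale_null: empty mask")
  xyz_all <- grid_coords(mask$grid)

  n_exp <- length(foci_per_experiment)
  n_foci <- sum(foci_per_experiment)
  n_iter <- cfg$n_null
  vpi <- cfg$voxels_per_iter
  sigma_e <- kernel_sigma(vapply(n_subjects, function(n)
    experiment_fwhm(cfg, n), 0.0))
  exp_of_focus1 <- rep.int(seq_len(n_exp), foci_per_experiment)

  with_seed(sub_seed(cfg$seed, "ale_null"), {
    # uniform within the mask volume: random in-mask voxel plus uniform
    # jitter inside that voxel
    draw_points <- function(n, jitter = TRUE) {
      pick <- in_idx[sample.int(length(in_idx), n, replace = TRUE)]
      pts <- xyz_all[pick, , drop = FALSE]
      if (jitter) {
        u <- matrix(stats::runif(3 * n, -0.5, 0.5), ncol = 3)
        pts <- pts + u %*% t(mask$grid$affine[1:3, 1:3])
      }
      pts
    }
    vals <- numeric(0)
    block <- 2000L  # iterations per vectorized block
    done <- 0L
    sigma_of_focus <- sigma_e[exp_of_focus1]
    while (done < n_iter) {
      nb <- min(block, n_iter - done)
      foci_xyz <- draw_points(nb * n_foci)  # iteration-major blocks of n_foci
      block_vals <- numeric(0)
      for (v in seq_len(vpi)) {
        eval_xyz <- draw_points(nb, jitter = FALSE)
        d2 <- (foci_xyz[, 1] - rep(eval_xyz[, 1], each = n_foci))^2 +
          (foci_xyz[, 2] - rep(eval_xyz[, 2], each = n_foci))^2 +
          (foci_xyz[, 3] - rep(eval_xyz[, 3], each = n_foci))^2
        mass <- matrix(gauss_mass(d2, sigma_of_focus,
                                  mask$grid$voxel_volume),
                       nrow = n_foci)
        block_vals <- c(block_vals, null_ale_values(
          mass, exp_of_focus1, cfg$within_experiment_combine))
      }
      vals <- c(vals, block_vals)
      done <- done + nb
    }
  })
  structure(list(values = sort(vals), n = length(vals)),
            class = "ale_null")
}

#' Convert an ALE map to p and Z maps against an empirical null
#'
#' `p(v) = (1 + #\{null >= ALE(v)\}) / (1 + N)` (add-one rank rule, so p is
#' never 0 and Z is finite); `z(v)` is the one-sided standard-normal
#' quantile of `1 - p(v)`.
#'
#' @param ale a [brain_volume()] of ALE values.
#' @param null an `ale_null` object (or a numeric vector of null samples).
#' @return list with `p` and `z` brain volumes (defined on the ALE mask).
#' @export
ale_to_p_z <- function(ale, null) {
  nv <- if (inherits(null, "ale_null")) null$values else sort(as.numeric(null))
  if (!length(nv)) stop("ale_to_p_z: empty null distribution")
  if (length(unique(nv)) == 1L && length(nv) > 1L)
    warning("degenerate null distribution (all values identical)")
  N <- length(nv)
  a <- ale$values[ale$mask]
  n_lt <- findInterval(a, nv, left.open = TRUE)  # #{null < a}
  # add-one rank rule, clamped to [1/(N+1), N/(N+1)] so z is finite at
  # both rank extremes
  p <- pmin((1 + (N - n_lt)) / (1 + N), N / (1 + N))
  z <- stats::qnorm(p, lower.tail = FALSE)
  pv <- array(NA_real_, ale$grid$shape); pv[ale$mask] <- p
  zv <- array(NA_real_, ale$grid$shape); zv[ale$mask] <- z
  list(p = brain_volume(ale$grid, pv, ale$mask),
       z = brain_volume(ale$grid, zv, ale$mask))
}

# neighbour offsets for 6/18/26-connectivity
connectivity_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  ord <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6" = ord == 1, "18" = ord >= 1 & ord <= 2, "26" = ord >= 1,
                 stop("connectivity must be 6, 18 or 26"))
  g[keep, , drop = FALSE]
}

#' Extract suprathreshold clusters from a p map
#'
#' Connected components of `{p < alpha}` under the configured
#' connectivity; components smaller than `min_cluster_mm3` are removed;
#' survivors are relabelled 1..C in decreasing size order (ties broken by
#' lexicographic peak coordinate).
#'
#' @param p a [brain_volume()] of p-values in (0, 1].
#' @param cfg an [ale_config()] (alpha, min_cluster_mm3, connectivity).
#' @param ale optional ALE (or Z) volume used to locate cluster peaks; when
#'   absent, the peak is the minimum-p voxel.
#' @return list with `labels` (integer-label `brain_volume`, 0 = none) and
#'   `cluster_table` (data.frame: cluster_id, n_voxels, volume_mm3,
#'   peak_x, peak_y, peak_z, peak_ale).
#' @export
extract_clusters <- function(p, cfg = ale_config(), ale = NULL) {
  shape <- p$grid$shape
  supra <- p$mask & is.finite(p$values) & (p$values < cfg$alpha)
  lab <- array(0L, shape)
  empty_table <- data.frame(cluster_id = integer(), n_voxels = integer(),
                            volume_mm3 = numeric(), peak_x = numeric(),
                            peak_y = numeric(), peak_z = numeric(),
                            peak_ale = numeric())
  idx <- which(supra)
  if (!length(idx)) {
    message("extract_clusters: no suprathreshold voxels")
    return(list(labels = brain_volume(p$grid, array(0, shape),
                                      array(TRUE, shape)),
                cluster_table = empty_table))
  }
  offs <- connectivity_offsets(cfg$connectivity)
  comp <- flood_label(supra, offs)
  # size filter in mm^3, strict >= retention
  vox_vol <- p$grid$voxel_volume
  sizes <- tabulate(comp[idx])
  keep_ids <- which(sizes * vox_vol >= cfg$min_cluster_mm3)
  if (!length(keep_ids)) {
    message("extract_clusters: all clusters below minimum extent")
    return(list(labels = brain_volume(p$grid, array(0, shape),
                                      array(TRUE, shape)),
                cluster_table = empty_table))
  }
  peak_src <- if (!is.null(ale)) ale$values else -p$values
  xyz <- NULL
  info <- lapply(keep_ids, function(id) {
    vox <- idx[comp[idx] == id]
    pk <- vox[which.max(peak_src[vox])]
    ijk <- arrayInd(pk, shape) - 1L
    pxyz <- drop(p$grid$affine %*% c(ijk, 1))[1:3]
    list(vox = vox, n = length(vox), peak = pxyz,
         peak_ale = if (!is.null(ale)) ale$values[pk] else NA_real_)
  })
  n_vox <- vapply(info, `[[`, 0L, "n")
  pk <- t(vapply(info, `[[`, numeric(3), "peak"))
  ord <- order(-n_vox, pk[, 1], pk[, 2], pk[, 3])
  out <- array(0L, shape)
  rows <- vector("list", length(ord))
  for (r in seq_along(ord)) {
    inf <- info[[ord[r]]]
    out[inf$vox] <- r
    rows[[r]] <- data.frame(cluster_id = r, n_voxels = inf$n,
                            volume_mm3 = inf$n * vox_vol,
                            peak_x = inf$peak[1], peak_y = inf$peak[2],
                            peak_z = inf$peak[3], peak_ale = inf$peak_ale)
  }
  list(labels = brain_volume(p$grid, array(as.numeric(out), shape),
                             array(TRUE, shape)),
       cluster_table = do.call(rbind, rows))
}

# connected-component labelling of a logical 3D array by breadth-first
# search over the TRUE voxels only
flood_label <- function(supra, offs) {
  shape <- dim(supra)
  comp <- array(0L, shape)
  idx <- which(supra)
  ijk <- arrayInd(idx, shape)
  pos <- array(0L, shape); pos[idx] <- seq_along(idx)
  cur <- 0L
  for (s in seq_along(idx)) {
    if (comp[idx[s]] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[idx[s]] <- cur
    while (length(queue)) {
      q <- queue[length(queue)]
      queue <- queue[-length(queue)]
      base <- ijk[q, ]
      nb <- sweep(offs, 2, base, "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= shape[1] &
        nb[, 2] >= 1 & nb[, 2] <= shape[2] &
        nb[, 3] >= 1 & nb[, 3] <= shape[3]
      if (!any(ok)) next
      nb <- nb[ok, , drop = FALSE]
      lin <- (nb[, 3] - 1L) * (shape[1] * shape[2]) +
        (nb[, 2] - 1L) * shape[1] + nb[, 1]
      for (l in lin) {
        if (supra[l] && comp[l] == 0L) {
          comp[l] <- cur
          queue <- c(queue, pos[l])
        }
      }
    }
  }
  comp
}

#' Run a complete ALE meta-analysis for one direction
#'
#' Converts the dataset to Talairach space, screens experiments, builds
#' per-experiment modelled-activation maps, forms their probabilistic
#' union, simulates the random-foci null, converts ALE to p and Z, and
#' extracts suprathreshold clusters.
#'
#' @param dataset a [foci_dataset()] (any mix of TAL/MNI experiments).
#' @param grid analysis [voxel_grid()].
#' @param mask a [brain_volume()] mask (defaults to the full grid).
#' @param cfg an [ale_config()].
#' @return an object of class `ale_result`: list with `ale`, `p`, `z`,
#'   `clusters` (label volume), `cluster_table`, `null`, `config`, and
#'   `fwhm_used` (per experiment).
#' @export
run_ale <- function(dataset, grid, mask = NULL, cfg = ale_config()) {
  if (is.null(mask))
    mask <- brain_volume(grid, 1, mask = array(TRUE, grid$shape))
  check_grid <- same_grid(mask$grid, grid)
  if (!check_grid) stop("mask grid does not match the analysis grid")
  dataset <- dataset_to_tal(dataset)
  exps <- dataset$experiments
  ma <- lapply(exps, experiment_ma_map, grid = grid, cfg = cfg)
  ale <- ale_union(ma)
  ale$values[!mask$mask] <- NA_real_
  ale <- brain_volume(grid, ale$values, mask$mask)
  null <- ale_null(vapply(exps, function(e) nrow(e$foci), 0L), mask, cfg,
                   n_subjects = vapply(exps, `[[`, 0L, "n_subjects"))
  pz <- ale_to_p_z(ale, null)
  cl <- extract_clusters(pz$p, cfg, ale = ale)
  structure(list(ale = ale, p = pz$p, z = pz$z,
                 clusters = cl$labels, cluster_table = cl$cluster_table,
                 null = null, config = cfg,
                 fwhm_used = vapply(exps, function(e)
                   experiment_fwhm(cfg, e$n_subjects), 0.0)),
            class = "ale_result")
}

#' @export
print.ale_result <- function(x, ...) {
  cat(sprintf("<ale_result: %d clusters, max ALE %.4g>\n",
              nrow(x$cluster_table),
              max(x$ale$values[x$ale$mask])))
  invisible(x)
}
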