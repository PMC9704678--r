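#' Ground truth for synthetic datasets
#'
#' Defines the statistical structure the generators emulate: clustered VBM
#' foci around planted alteration centres with uniform background noise,
#' spatially smooth donor expression fields with optional planted
#' correlation to a reference alteration pattern, and the donor panel
#' composition (six donors, four left-hemisphere-only, as in the AHBA).
#'
#' @param alteration_centres data.frame with columns `x, y, z` (mm),
#'   `direction` (`"decrease"`/`"increase"`), `sd_mm` (spatial jitter SD)
#'   and `hit_prob` (per-experiment probability of reporting the centre).
#' @param background_foci_rate expected uniform background foci per
#'   experiment (Poisson rate).
#' @param gene_effects data.frame with columns `gene`, `target` (name of a
#'   target-region mask supplied at generation time) and `rho` (planted
#'   sample-level correlation with the reference pattern, in (-1, 1));
#'   genes absent from the table are pure noise.
#' @param expression_field_smoothness Gaussian length scale (mm) of the
#'   smooth donor expression fields.
#' @param n_donors,n_left_only donor panel size and how many donors cover
#'   the left hemisphere only.
#' @param n_samples_per_donor expression samples drawn per donor.
#' @param seed master seed.
#' @return an object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(alteration_centres = default_centres(),
                            background_foci_rate = 2,
                            gene_effects = NULL,
                            expression_field_smoothness = 15,
                            n_donors = 6L, n_left_only = 4L,
                            n_samples_per_donor = 200L,
                            seed = 1L) {
  stopifnot(n_left_only <= n_donors, background_foci_rate >= 0,
            expression_field_smoothness > 0)
  stopifnot(all(alteration_centres$hit_prob >= 0),
            all(alteration_centres$hit_prob <= 1))
  if (!is.null(gene_effects))
    stopifnot(all(abs(gene_effects$rho) < 1))
  structure(list(alteration_centres = alteration_centres,
                 background_foci_rate = background_foci_rate,
                 gene_effects = gene_effects,
                 expression_field_smoothness = expression_field_smoothness,
                 n_donors = as.integer(n_donors),
                 n_left_only = as.integer(n_left_only),
                 n_samples_per_donor = as.integer(n_samples_per_donor),
                 seed = as.integer(seed)),
            class = "synthetic_truth")
}

#' Default planted alteration centres
#'
#' Four decrease and four increase centres at plausible Talairach
#' locations (insula, pericentral, cingulate, cerebellar and prefrontal
#' territory), 6 mm spatial jitter, reported by 80% of experiments.
#' @export
default_centres <- function() {
  data.frame(
    x = c(-38, 40, -4, -20, 30, -30, 6, 16),
    y = c(-18, -20, -40, -60, 40, 38, 20, -80),
    z = c(8, 42, 40, -24, 20, 16, -12, -28),
    direction = rep(c("decrease", "increase"), each = 4),
    sd_mm = 6,
    hit_prob = 0.8)
}

# uniform random points inside a mask (voxel centre + in-voxel jitter)
sample_in_mask <- function(n, mask, left_only = FALSE) {
  idx <- which(mask$mask)
  if (!length(idx)) stop("sample_in_mask: empty mask")
  xyz_all <- grid_coords(mask$grid)
  if (left_only) {
    idx <- idx[xyz_all[idx, 1] <= 0]
    if (!length(idx)) stop("sample_in_mask: mask has no left-hemisphere voxels")
  }
  pick <- idx[sample.int(length(idx), n, replace = TRUE)]
  pts <- xyz_all[pick, , drop = FALSE]
  u <- matrix(stats::runif(3 * n, -0.5, 0.5), ncol = 3)
  pts + u %*% t(mask$grid$affine[1:3, 1:3])
}

#' Generate a synthetic foci dataset
#'
#' Each experiment is assigned a direction (alternating so both are
#' covered); for each alteration centre of that direction it reports, with
#' the centre's hit probability, one focus jittered by an isotropic
#' Gaussian of the centre's spatial SD, plus `Poisson(background rate)`
#' foci uniform in the mask.  Experiments that would end up with zero foci
#' get one background focus so every experiment is non-empty.
#'
#' @param truth a [synthetic_truth()].
#' @param n_experiments total experiments to generate.
#' @param subjects_range integer pair; subject counts drawn uniformly.
#' @param mask sampling mask ([brain_volume()]).
#' @param stream seed stream label.
#' @return a [foci_dataset()] in TAL space.
#' @export
generate_foci <- function(truth, n_experiments, subjects_range = c(10L, 30L),
                          mask, stream = "foci") {
  stopifnot(n_experiments >= 1L)
  centres <- truth$alteration_centres
  exps <- vector("list", n_experiments)
  with_seed(sub_seed(truth$seed, stream), {
    for (i in seq_len(n_experiments)) {
      dir <- if (i %% 2L == 1L) "decrease" else "increase"
      cc <- centres[centres$direction == dir, , drop = FALSE]
      foci <- matrix(numeric(), ncol = 3)
      for (j in seq_len(nrow(cc))) {
        if (stats::runif(1) <= cc$hit_prob[j]) {
          f <- c(cc$x[j], cc$y[j], cc$z[j]) +
            stats::rnorm(3, 0, cc$sd_mm[j])
          foci <- rbind(foci, f)
        }
      }
      n_bg <- stats::rpois(1, truth$background_foci_rate)
      if (nrow(foci) == 0L && n_bg == 0L) n_bg <- 1L
      if (n_bg > 0L)
        foci <- rbind(foci, sample_in_mask(n_bg, mask))
      exps[[i]] <- experiment(
        sprintf("synth_%03d", i), dir,
        sample(seq(subjects_range[1], subjects_range[2]), 1L),
        foci, "TAL")
    }
  })
  foci_dataset(exps, label = "synthetic")
}

# smooth standardized field values at points `pts`, built by Gaussian
# kernel mixing of white noise placed on `n_knots` random in-mask knots;
# length scale = kernel SD in mm
smooth_field_at <- function(pts, mask, length_scale, n_knots = 150L) {
  knots <- sample_in_mask(n_knots, mask)
  noise <- stats::rnorm(n_knots)
  d2 <- outer(rowSums(pts^2), rep(1, n_knots)) +
    outer(rep(1, nrow(pts)), rowSums(knots^2)) -
    2 * pts %*% t(knots)
  w <- exp(-pmax(d2, 0) / (2 * length_scale^2))
  v <- as.numeric((w %*% noise) / pmax(rowSums(w), 1e-12))
  s <- sqrt(mean((v - mean(v))^2))
  if (s < 1e-12) return(v - mean(v))
  (v - mean(v)) / s
}

#' Generate synthetic donor expression samples for one gene
#'
#' Per donor, sample locations are drawn uniformly in the mask (left
#' hemisphere only for the left-only donors) and values are a smooth
#' Gaussian-mixed noise field.  If the gene has a planted effect, samples
#' falling inside the target region get
#' `sqrt(1 - rho^2) * field + rho * reference` (the reference pattern
#' standardized over the mask and interpolated at the sample), so the
#' sample-level correlation with the reference inside the target is `rho`.
#'
#' @param truth a [synthetic_truth()].
#' @param gene gene symbol.
#' @param mask sampling mask.
#' @param reference_pattern optional `brain_volume` (e.g. an ALE Z map)
#'   required when the gene has a planted `rho`.
#' @param target_mask optional logical array (grid shape): where the
#'   planted correlation applies.  Defaults to everywhere.
#' @param stream seed stream label (distinct per gene).
#' @return list of [donor_samples()].
#' @export
generate_expression <- function(truth, gene, mask,
                                reference_pattern = NULL,
                                target_mask = NULL,
                                stream = paste0("expr|", gene)) {
  eff <- NULL
  if (!is.null(truth$gene_effects)) {
    hit <- truth$gene_effects$gene == gene
    if (any(hit)) eff <- truth$gene_effects[which(hit)[1], ]
  }
  if (!is.null(eff) && eff$rho != 0 && is.null(reference_pattern))
    stop("generate_expression: gene '", gene,
         "' has a planted rho but no reference pattern was supplied")
  ref_at <- NULL
  if (!is.null(reference_pattern)) {
    rv <- reference_pattern$values[reference_pattern$mask]
    mu <- mean(rv); s <- sqrt(mean((rv - mu)^2))
    ref_at <- function(pts) {
      ijk <- round(world_to_voxel(reference_pattern$grid, pts))
      sh <- reference_pattern$grid$shape
      ijk[, 1] <- pmin(pmax(ijk[, 1], 1), sh[1])
      ijk[, 2] <- pmin(pmax(ijk[, 2], 1), sh[2])
      ijk[, 3] <- pmin(pmax(ijk[, 3], 1), sh[3])
      lin <- (ijk[, 3] - 1) * prod(sh[1:2]) + (ijk[, 2] - 1) * sh[1] +
        ijk[, 1]
      v <- (reference_pattern$values[lin] - mu) / max(s, 1e-12)
      v[!is.finite(v)] <- 0
      v
    }
  }
  in_target <- function(pts) {
    if (is.null(target_mask)) return(rep(TRUE, nrow(pts)))
    ijk <- round(world_to_voxel(mask$grid, pts))
    sh <- mask$grid$shape
    ok <- ijk[, 1] >= 1 & ijk[, 1] <= sh[1] & ijk[, 2] >= 1 &
      ijk[, 2] <= sh[2] & ijk[, 3] >= 1 & ijk[, 3] <= sh[3]
    out <- rep(FALSE, nrow(pts))
    lin <- (ijk[ok, 3] - 1) * prod(sh[1:2]) + (ijk[ok, 2] - 1) * sh[1] +
      ijk[ok, 1]
    out[ok] <- target_mask[lin]
    out
  }
  donors <- vector("list", truth$n_donors)
  with_seed(sub_seed(truth$seed, stream), {
    for (d in seq_len(truth$n_donors)) {
      left <- d > (truth$n_donors - truth$n_left_only)
      pts <- sample_in_mask(truth$n_samples_per_donor, mask,
                            left_only = left)
      if (left) pts[, 1] <- pmin(pts[, 1], 0)
      v <- smooth_field_at(pts, mask, truth$expression_field_smoothness)
      if (!is.null(eff) && eff$rho != 0) {
        tgt <- in_target(pts)
        v[tgt] <- sqrt(1 - eff$rho^2) * v[tgt] + eff$rho * ref_at(pts)[tgt]
      }
      donors[[d]] <- donor_samples(
        sprintf("donor%d", d),
        if (left) "left_only" else "bilateral", pts, v)
    }
  })
  donors
}

#' Generate a contiguous K-network parcellation
#'
#' Voronoi parcels of `k` random in-mask seed points: every in-mask voxel
#' takes the label of its nearest seed, giving contiguous parcels tiling
#' the mask.
#'
#' @param grid a [voxel_grid()].
#' @param k number of networks (>= 2).
#' @param seed integer seed.
#' @param mask optional mask volume (defaults to the full grid).
#' @param names parcel names; defaults to [default_network_names()].
#' @param symmetric if `TRUE`, seed points come in x-mirrored pairs (plus
#'   one midline seed when k is odd), so parcels are bilateral like real
#'   resting-state networks; requires an x-symmetric grid and mask for
#'   exact parcel symmetry.
#' @return a [network_atlas()].
#' @export
generate_atlas <- function(grid, k, seed = 1L, mask = NULL, names = NULL,
                           symmetric = FALSE) {
  stopifnot(k >= 2L)
  if (is.null(mask))
    mask <- brain_volume(grid, 1, mask = array(TRUE, grid$shape))
  idx <- which(mask$mask)
  if (k > length(idx)) stop("k exceeds the number of in-mask voxels")
  seed_net <- seq_len(k)   # network of each seed point
  with_seed(sub_seed(seed, "atlas"), {
    if (symmetric) {
      # one x-mirrored seed pair per network, so every parcel is
      # bilateral (like real resting-state networks) and exactly
      # x-symmetric on a symmetric grid/mask
      xyz <- grid_coords(grid)
      left <- idx[xyz[idx, 1] < 0]
      ls <- xyz[left[sample.int(length(left), k)], , drop = FALSE]
      seeds <- rbind(ls, ls %*% diag(c(-1, 1, 1)))
      seed_net <- rep(seq_len(k), 2L)
    } else {
      seeds <- grid_coords(grid)[idx[sample.int(length(idx), k)], ,
                                 drop = FALSE]
    }
  })
  pts <- grid_coords(grid)[idx, , drop = FALSE]
  lab_vals <- array(0, grid$shape)
  lab_vals[idx] <- seed_net[nearest_sample(pts, seeds)]
  labels <- brain_volume(grid, lab_vals, array(TRUE, grid$shape))
  atlas <- network_atlas(labels, names %||% default_network_names(k))
  attr(atlas, "seeds_mm") <- seeds  # ground truth for validation
  atlas
}
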