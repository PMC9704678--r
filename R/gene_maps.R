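#' Donor expression samples for one gene
#'
#' Point samples of one donor's expression of one gene: Talairach mm
#' coordinates plus an expression value per sample.  Donors covering only
#' the left hemisphere (`coverage = "left_only"`) are mirrored across the
#' midsagittal plane before tessellation.
#'
#' @param donor_id donor identifier.
#' @param coverage `"bilateral"` or `"left_only"`.
#' @param coords n x 3 matrix of mm coordinates, n >= 2.
#' @param values numeric expression values, length n.
#' @param midline_tol mm tolerance for the left-only constraint (default 1).
#' @return an object of class `donor_samples`.
#' @export
donor_samples <- function(donor_id, coverage = c("bilateral", "left_only"),
                          coords, values, midline_tol = 1) {
  coverage <- match.arg(coverage)
  coords <- matrix(as.numeric(coords), ncol = 3)
  values <- as.numeric(values)
  stopifnot(nrow(coords) >= 2L, nrow(coords) == length(values),
            all(is.finite(coords)), all(is.finite(values)))
  if (coverage == "left_only" && any(coords[, 1] > midline_tol))
    stop("left_only donor '", donor_id, "' has samples with x > ",
         midline_tol, " mm")
  structure(list(donor_id = as.character(donor_id), coverage = coverage,
                 coords = coords, values = values),
            class = "donor_samples")
}

#' Standardize a donor's sample values to z-scores
#'
#' Mean 0, SD 1 across the donor's own samples (population SD, divisor n);
#' removes donor-level scale and offset before maps are averaged across
#' donors.  The convention is irrelevant to the downstream Pearson
#' correlations, which are scale-invariant.
#'
#' @param d a [donor_samples()].
#' @return the donor with standardized values.
#' @export
zscore_samples <- function(d) {
  v <- d$values
  mu <- mean(v)
  sd_pop <- sqrt(mean((v - mu)^2))
  if (sd_pop == 0)
    stop("zscore_samples: donor '", d$donor_id,
         "' has zero expression variance")
  d$values <- (v - mu) / sd_pop
  d
}

#' Mirror a left-hemisphere-only donor across the midline
#'
#' Assumes left/right symmetry of expression: every sample with
#' `x < -midline_tol` is duplicated at `(-x, y, z)` with the same value;
#' samples within the midline tolerance stay single.  Output coverage is
#' bilateral.
#'
#' @param d a [donor_samples()] with `coverage = "left_only"`.
#' @param midline_tol mm half-width of the midline band (default 1).
#' @return a bilateral `donor_samples`.
#' @export
mirror_left_only <- function(d, midline_tol = 1) {
  if (d$coverage != "left_only")
    stop("mirror_left_only: donor '", d$donor_id, "' is already bilateral")
  dup <- d$coords[, 1] < -midline_tol
  mirrored <- d$coords[dup, , drop = FALSE]
  mirrored[, 1] <- -mirrored[, 1]
  donor_samples(d$donor_id, "bilateral",
                rbind(d$coords, mirrored),
                c(d$values, d$values[dup]),
                midline_tol = midline_tol)
}

# nearest-sample index for each row of `pts` (m x 3) among `samples`
# (n x 3), Euclidean distance in world mm.  Running argmin over samples,
# vectorized over points; the strict `<` update gives equidistant points
# to the lowest sample index.
nearest_sample <- function(pts, samples) {
  n <- nrow(pts)
  best <- rep.int(1L, n)
  bestd <- (pts[, 1] - samples[1, 1])^2 + (pts[, 2] - samples[1, 2])^2 +
    (pts[, 3] - samples[1, 3])^2
  for (j in seq_len(nrow(samples))[-1]) {
    dj <- (pts[, 1] - samples[j, 1])^2 + (pts[, 2] - samples[j, 2])^2 +
      (pts[, 3] - samples[j, 3])^2
    upd <- dj < bestd
    if (any(upd)) {
      best[upd] <- j
      bestd[upd] <- dj[upd]
    }
  }
  best
}

#' Voronoi expression volume of one donor
#'
#' Fills every in-mask voxel with the expression value of its nearest
#' sample (Euclidean distance in mm): each sample's Voronoi cell carries
#' the sample's value, with the sample point as cell barycentre.
#' Equidistant voxels take the lowest sample index.
#'
#' @param d a [donor_samples()] (bilateralized and z-scored upstream).
#' @param grid a [voxel_grid()].
#' @param mask a [brain_volume()] whose mask defines the in-brain voxels.
#' @return a `brain_volume` defined on the mask.
#' @export
voronoi_map <- function(d, grid, mask) {
  check_same_grid(mask, list(grid = grid), "mask and target grid")
  idx <- which(mask$mask)
  if (!length(idx)) stop("voronoi_map: empty mask")
  pts <- grid_coords(grid)[idx, , drop = FALSE]
  nn <- nearest_sample(pts, d$coords)
  vals <- array(NA_real_, grid$shape)
  vals[idx] <- d$values[nn]
  brain_volume(grid, vals, mask$mask)
}

#' Average donor volumes into a gene expression map
#'
#' @param maps list of `brain_volume`s on one grid (one per donor).
#' @param gene gene symbol.
#' @param donors_used donor ids, recorded in the result.
#' @return an object of class `gene_expression_map`: list with `gene`,
#'   `volume`, `donors_used`.
#' @export
average_donors <- function(maps, gene, donors_used = NULL) {
  stopifnot(length(maps) >= 1L)
  for (m in maps) check_same_grid(maps[[1]], m, "donor maps")
  g <- maps[[1]]$grid
  mask <- Reduce(`&`, lapply(maps, `[[`, "mask"))
  acc <- array(0, g$shape)
  for (m in maps) acc <- acc + m$values
  acc <- acc / length(maps)
  acc[!mask] <- NA_real_
  structure(list(gene = as.character(gene),
                 volume = brain_volume(g, acc, mask),
                 donors_used = donors_used %||% paste0("donor", seq_along(maps))),
            class = "gene_expression_map")
}

#' Build one gene's expression volume from donor samples
#'
#' Per donor: z-score sample values, mirror left-only donors across the
#' midline, tessellate (Voronoi) onto the analysis grid; then average the
#' donor volumes voxel-wise.
#'
#' @param donors list of [donor_samples()] for one gene.
#' @param gene gene symbol.
#' @param grid analysis [voxel_grid()].
#' @param mask analysis mask volume.
#' @param zscore_stage `"per_donor"` (default: standardize samples before
#'   tessellation) or `"post_average"` (standardize the averaged volume
#'   over in-mask voxels instead).
#' @param midline_tol mirroring tolerance in mm.
#' @return a `gene_expression_map`.
#' @export
build_gene_map <- function(donors, gene, grid, mask,
                           zscore_stage = c("per_donor", "post_average"),
                           midline_tol = 1) {
  zscore_stage <- match.arg(zscore_stage)
  stopifnot(length(donors) >= 1L)
  maps <- lapply(donors, function(d) {
    if (zscore_stage == "per_donor") d <- zscore_samples(d)
    if (d$coverage == "left_only") d <- mirror_left_only(d, midline_tol)
    voronoi_map(d, grid, mask)
  })
  gm <- average_donors(maps, gene,
                       donors_used = vapply(donors, `[[`, "", "donor_id"))
  if (zscore_stage == "post_average") {
    v <- gm$volume$values[gm$volume$mask]
    sd_pop <- sqrt(mean((v - mean(v))^2))
    if (sd_pop == 0) stop("post-average z-scoring: zero variance")
    vals <- (gm$volume$values - mean(v)) / sd_pop
    gm$volume <- brain_volume(grid, vals, gm$volume$mask)
  }
  gm
}

#' @export
print.gene_expression_map <- function(x, ...) {
  cat(sprintf("<gene_expression_map %s: %d donors>\n",
              x$gene, length(x$donors_used)))
  invisible(x)
}
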