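# shared fixtures: tiny grids, toy datasets and label volumes, all built
# in code

tiny_grid <- function(n = 7L, voxel = 2) {
  half <- (n - 1) / 2 * voxel
  default_grid(voxel, c(-half, half), c(-half, half), c(-half, half))
}

full_mask <- function(grid) {
  brain_volume(grid, 1, mask = array(TRUE, grid$shape))
}

# a small two-experiment CSV foci table
example_foci_csv <- function() c(
  "experiment_id,direction,n_subjects,space,x,y,z",
  "exp1,decrease,12,TAL,-10,0,4",
  "exp1,decrease,12,TAL,6,2,0",
  "exp1,decrease,12,TAL,0,-8,2",
  "exp2,decrease,15,TAL,2,4,-6",
  "exp2,decrease,15,TAL,-4,6,0",
  "exp2,decrease,15,TAL,8,-2,2")

# deterministic piecewise label volume: two cubic clusters in one corner
# each, labelled 1 and 2
two_cluster_labels <- function(grid) {
  lab <- array(0, grid$shape)
  lab[1:3, 1:3, 1:3] <- 1
  n <- grid$shape
  lab[(n[1] - 2):n[1], (n[2] - 2):n[2], (n[3] - 2):n[3]] <- 2
  brain_volume(grid, lab, array(TRUE, grid$shape))
}

# smooth deterministic scalar volume for use as a Z-map stand-in
wave_volume <- function(grid, phase = 0) {
  xyz <- grid_coords(grid)
  v <- sin(xyz[, 1] / 11 + phase) + cos(xyz[, 2] / 7 - phase) +
    sin(xyz[, 3] / 5) + 0.05 * xyz[, 1] / 10
  brain_volume(grid, array(v, grid$shape), array(TRUE, grid$shape))
}

# cluster geometry for permutation tests: n_cl spherical clusters of
# radius r_vox voxels planted at given in-mask centres
sphere_labels <- function(grid, centres_mm, r_mm) {
  xyz <- grid_coords(grid)
  lab <- array(0, grid$shape)
  for (i in seq_len(nrow(centres_mm))) {
    d2 <- (xyz[, 1] - centres_mm[i, 1])^2 +
      (xyz[, 2] - centres_mm[i, 2])^2 + (xyz[, 3] - centres_mm[i, 3])^2
    lab[d2 <= r_mm^2 & lab == 0] <- i
  }
  brain_volume(grid, lab, array(TRUE, grid$shape))
}
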