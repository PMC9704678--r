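# toy geometry: 4 clusters on an 8^3 grid, a 3-network atlas
toy_geometry <- function() {
  g <- tiny_grid(8, 4)
  centres <- rbind(c(-8, -8, -8), c(8, 8, 8), c(-8, 8, 0), c(8, -8, 0))
  labels <- sphere_labels(g, centres, 7)
  nl <- array(0, g$shape)
  nl[1:4, , ] <- 1
  nl[5:8, 1:4, ] <- 2
  nl[5:8, 5:8, ] <- 3
  atlas <- network_atlas(
    brain_volume(g, nl, array(TRUE, g$shape)),
    stats::setNames(c("A", "B", "C"), 1:3))
  list(grid = g, labels = labels, atlas = atlas)
}

mk_res <- function(id, r) structure(
  list(gene = "G", direction = "decrease", cluster_id = id, r = r,
       n_voxels = 10L, fisher_z = atanh(r), t_stat = 0, ok = TRUE),
  class = "cluster_correlation")

test_that("network means average non-zero voxels within each network", {
  g <- tiny_grid(8, 4)
  nl <- array(0, g$shape); nl[1:4, , ] <- 1; nl[5:8, , ] <- 2
  atlas <- network_atlas(brain_volume(g, nl, array(TRUE, g$shape)),
                         stats::setNames(c("A", "B"), 1:2))
  # one cluster wholly inside A: mean_r(A) = its r, B missing
  lab <- array(0, g$shape); lab[2:3, 2:3, 2:3] <- 1
  labels <- brain_volume(g, lab, array(TRUE, g$shape))
  vol <- build_correlation_volume(list(mk_res(1L, 0.2)), labels)
  nm <- network_mean(vol, atlas)
  expect_equal(nm$mean_r[nm$network == "A"], 0.2)
  expect_true(is.na(nm$mean_r[nm$network == "B"]))
  expect_equal(nm$n_voxels_used[nm$network == "B"], 0L)
  # two equal-sized clusters r = 0.2 and 0.1 in A: mean 0.15
  lab[2:3, 5:6, 2:3] <- 2
  labels <- brain_volume(g, lab, array(TRUE, g$shape))
  vol <- build_correlation_volume(list(mk_res(1L, 0.2), mk_res(2L, 0.1)),
                                  labels)
  expect_equal(network_mean(vol, atlas)$mean_r[1], 0.15)
  # a straddling cluster contributes its r to both networks, weighted by
  # its voxel count on each side (per-voxel accumulation oracle)
  lab <- array(0, g$shape)
  lab[3:5, 2, 2] <- 3           # 2 voxels in A, 1 in B
  lab[2, 5:6, 5] <- 4           # 2 voxels in A
  labels <- brain_volume(g, lab, array(TRUE, g$shape))
  vol <- build_correlation_volume(list(mk_res(3L, 0.3), mk_res(4L, 0.6)),
                                  labels)
  nm <- network_mean(vol, atlas)
  expect_equal(nm$mean_r[nm$network == "A"], (2 * 0.3 + 2 * 0.6) / 4)
  expect_equal(nm$mean_r[nm$network == "B"], 0.3)
})

test_that("observed means depend on geometry, not cluster ids", {
  geo <- toy_geometry()
  rs <- c(0.4, -0.2, 0.1, 0.3)
  vol1 <- build_correlation_volume(
    lapply(1:4, function(k) mk_res(k, rs[k])), geo$labels)
  # relabel clusters 1..4 -> 4..1 and permute r accordingly
  relab <- geo$labels
  relab$values[] <- ifelse(relab$values > 0, 5 - relab$values, 0)
  vol2 <- build_correlation_volume(
    lapply(1:4, function(k) mk_res(k, rev(rs)[k])), relab)
  expect_equal(network_mean(vol1, geo$atlas)$mean_r,
               network_mean(vol2, geo$atlas)$mean_r)
})

test_that("exhaustive cluster permutation matches the enumeration oracle", {
  geo <- toy_geometry()
  rs <- c(0.4, -0.2, 0.1, 0.3)
  null <- permutation_null(rs, geo$labels, geo$atlas, exhaustive = TRUE)
  expect_equal(nrow(null), 24L)
  # oracle: enumerate the permutation group independently and recompute
  # each network mean by voxel-wise accumulation
  counts <- alexpr:::cluster_network_counts(geo$labels, geo$atlas)
  perms <- expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4)
  perms <- as.matrix(perms[apply(perms, 1, function(p)
    length(unique(p)) == 4), ])
  expect_equal(nrow(perms), 24L)
  oracle <- t(apply(perms, 1, function(p) {
    r <- rs[p]
    as.numeric(crossprod(counts, r) / colSums(counts))
  }))
  sort_rows <- function(m) m[do.call(order, as.data.frame(m)), ]
  expect_equal(sort_rows(unname(null)), sort_rows(unname(oracle)),
               tolerance = 1e-12)
  # conservation: the permutation-group average of each network mean is
  # the grand cluster mean under that network's voxel weighting
  expect_equal(unname(colMeans(null)),
               unname(colMeans(oracle)), tolerance = 1e-12)
})

test_that("identity permutation reproduces observed means; shared r is degenerate", {
  geo <- toy_geometry()
  counts <- alexpr:::cluster_network_counts(geo$labels, geo$atlas)
  rs <- c(0.4, -0.2, 0.1, 0.3)
  obs <- alexpr:::network_means_from_r(rs, counts)
  vol <- build_correlation_volume(
    lapply(1:4, function(k) mk_res(k, rs[k])), geo$labels)
  expect_equal(unname(obs), network_mean(vol, geo$atlas)$mean_r)
  # all clusters share one r: every null mean equals the observed mean
  null <- permutation_null(rep(0.25, 4), geo$labels, geo$atlas,
                           permutation_config(n_perm = 200, seed = 3))
  expect_true(all(abs(null - 0.25) < 1e-12))
  stats <- assess_significance(
    network_mean(build_correlation_volume(
      lapply(1:4, function(k) mk_res(k, 0.25)), geo$labels), geo$atlas),
    null, permutation_config(n_perm = 200, seed = 3))
  expect_false(any(stats$significant))
  expect_true(all(stats$degenerate))
})

test_that("permutation null is reproducible and warns when degenerate", {
  geo <- toy_geometry()
  cfg <- permutation_config(n_perm = 300, seed = 5)
  rs <- c(0.4, -0.2, 0.1, 0.3)
  n1 <- permutation_null(rs, geo$labels, geo$atlas, cfg)
  n2 <- permutation_null(rs, geo$labels, geo$atlas, cfg)
  expect_identical(n1, n2)
  expect_warning(
    permutation_null(c(0.4, NA, NA, NA), geo$labels, geo$atlas, cfg),
    "degenerate")
})

test_that("significance thresholds follow the one-sided rank rules", {
  geo <- toy_geometry()
  cfg <- permutation_config(n_perm = 400, seed = 9)
  obs <- data.frame(network = c("A", "B"), label = 1:2,
                    mean_r = c(10, NA), n_voxels_used = c(5L, 0L))
  null <- cbind(A = runif(400), B = runif(400))
  st <- assess_significance(obs, null, cfg)
  # observed above every null value: p at its floor, significant
  expect_equal(st$p_perm[1], 1 / 401)
  expect_true(st$significant[1])
  expect_equal(st$null_threshold[1], sort(null[, "A"])[380])
  # empty network: emitted, never significant, p undefined
  expect_false(st$significant[2])
  expect_true(is.na(st$p_perm[2]))
  # observed at the null median: p ~ 0.5, not significant
  obs2 <- data.frame(network = "A", label = 1L,
                     mean_r = median(null[, "A"]),
                     n_voxels_used = 5L)
  st2 <- assess_significance(obs2, null, cfg)
  expect_equal(st2$p_perm, 0.5, tolerance = 0.01)
  expect_false(st2$significant)
  # toy exhaustive case: p matches the exact rank count
  rs <- c(0.4, -0.2, 0.1, 0.3)
  exh <- permutation_null(rs, geo$labels, geo$atlas, exhaustive = TRUE)
  counts <- alexpr:::cluster_network_counts(geo$labels, geo$atlas)
  obs_m <- alexpr:::network_means_from_r(rs, counts)
  obs3 <- data.frame(network = names(obs_m), label = 1:3,
                     mean_r = unname(obs_m),
                     n_voxels_used = as.integer(colSums(counts)))
  st3 <- assess_significance(obs3, exh, cfg)
  for (i in 1:3)
    expect_equal(st3$p_perm[i],
                 (1 + sum(exh[, i] >= obs_m[i])) / 25)
})

test_that("multiple-testing adjustment is off by default but available", {
  geo <- toy_geometry()
  z <- wave_volume(geo$grid)
  set.seed(41)
  genemaps <- lapply(c("G1", "G2"), function(nm) structure(
    list(gene = nm, volume = brain_volume(
      geo$grid, array(rnorm(prod(geo$grid$shape)), geo$grid$shape),
      array(TRUE, geo$grid$shape)), donors_used = "d"),
    class = "gene_expression_map"))
  corrset <- correlate_all(list(decrease = z, increase = z), genemaps,
                           list(decrease = geo$labels,
                                increase = geo$labels))
  cfg <- permutation_config(n_perm = 200, seed = 2)
  plain <- network_analysis(corrset, list(decrease = geo$labels,
                                          increase = geo$labels),
                            geo$atlas, cfg)
  expect_false("p_adj" %in% names(plain))
  adj <- network_analysis(corrset, list(decrease = geo$labels,
                                        increase = geo$labels),
                          geo$atlas, cfg, p_adjust = "BH")
  expect_true("p_adj" %in% names(adj))
  expect_true(all(adj$p_adj >= adj$p_perm - 1e-12, na.rm = TRUE))
})

test_that("significance masking keeps only significant networks' voxels", {
  geo <- toy_geometry()
  rs <- c(0.4, -0.2, 0.1, 0.3)
  vol <- build_correlation_volume(
    lapply(1:4, function(k) mk_res(k, rs[k])), geo$labels)
  stats <- data.frame(network = c("A", "B", "C"), label = 1:3,
                      significant = c(TRUE, FALSE, FALSE))
  masked <- significance_mask_volume(vol, geo$atlas, stats)
  inA <- round(geo$atlas$labels$values) == 1
  expect_equal(masked$values[inA], vol$values[inA])
  expect_true(all(masked$values[!inA] == 0))
})
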