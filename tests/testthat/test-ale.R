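test_that("kernel sigma follows the FWHM relation", {
  expect_equal(kernel_sigma(sqrt(8 * log(2))), 1)
  expect_equal(kernel_sigma(2 * sqrt(8 * log(2))), 2)
  expect_equal(kernel_sigma(10), 10 / sqrt(8 * log(2)))
  expect_error(kernel_sigma(0), "positive")
  expect_error(kernel_sigma(-3), "positive")
})

test_that("focus kernel is a Gaussian probability mass per voxel", {
  g <- tiny_grid(21, 1)      # 21 mm cube, 1 mm voxels
  sigma <- 2
  k <- focus_kernel(c(0, 0, 0), g, sigma)
  centre <- (g$shape + 1) / 2
  v0 <- k$values[centre[1], centre[2], centre[3]]
  # value at the focus voxel is the maximum
  expect_equal(as.vector(arrayInd(which.max(k$values), g$shape)),
               as.vector(centre))
  # d = sigma vs d = 0: Gaussian shape ratio exp(1/2)
  vs <- k$values[centre[1] + sigma, centre[2], centre[3]]
  expect_equal(v0 / vs, exp(0.5))
  # normalization on a >= 5 sigma grid
  expect_equal(sum(k$values), 1, tolerance = 0.01)
  expect_true(all(k$values >= 0))
})

test_that("focus kernel equals a three-nested-loop direct evaluation", {
  g <- tiny_grid(7, 2)
  sigma <- 2
  f <- c(1, -2, 0.5)
  k <- focus_kernel(f, g, sigma)
  oracle <- array(NA_real_, g$shape)
  for (i in 1:7) for (j in 1:7) for (l in 1:7) {
    xyz <- drop(g$affine %*% c(i - 1, j - 1, l - 1, 1))[1:3]
    d2 <- sum((xyz - f)^2)
    oracle[i, j, l] <- g$voxel_volume / (sigma^3 * (2 * pi)^1.5) *
      exp(-d2 / (2 * sigma^2))
  }
  expect_equal(k$values, oracle, tolerance = 1e-12)
})

test_that("out-of-grid focus warns and truncates rather than failing", {
  g <- tiny_grid(7, 2)
  expect_warning(k <- focus_kernel(c(100, 0, 0), g, 2), "outside")
  expect_true(all(is.finite(k$values)))
})

test_that("modelled-activation maps combine focus kernels correctly", {
  g <- tiny_grid(11, 2)
  cfg <- ale_config(fwhm_mm = 2 * sqrt(8 * log(2)))  # sigma = 2
  # one focus: MA equals the kernel under either rule
  e1 <- experiment("e1", "decrease", 12, rbind(c(0, 0, 0)), "TAL")
  k <- focus_kernel(c(0, 0, 0), g, 2)
  expect_equal(experiment_ma_map(e1, g, cfg)$values, k$values)
  cfg_u <- ale_config(fwhm_mm = cfg$fwhm_mm,
                      within_experiment_combine = "prob_union")
  expect_equal(experiment_ma_map(e1, g, cfg_u)$values, k$values)
  # two identical foci under max: idempotent
  e2 <- experiment("e2", "decrease", 12,
                   rbind(c(0, 0, 0), c(0, 0, 0)), "TAL")
  expect_equal(experiment_ma_map(e2, g, cfg)$values, k$values)
  # two foci 3 sigma apart under prob_union: 1 - (1-a)(1-b)
  e3 <- experiment("e3", "decrease", 12,
                   rbind(c(-3, 0, 0), c(3, 0, 0)), "TAL")
  a <- focus_kernel(c(-3, 0, 0), g, 2)$values
  b <- focus_kernel(c(3, 0, 0), g, 2)$values
  expect_equal(experiment_ma_map(e3, g, cfg_u)$values,
               1 - (1 - a) * (1 - b), tolerance = 1e-12)
  # mixed-space input must be converted first
  e_mni <- experiment("m", "decrease", 12, rbind(c(0, 0, 0)), "MNI")
  expect_error(experiment_ma_map(e_mni, g, cfg), "TAL")
})

test_that("ALE union is the probabilistic union of MA maps", {
  g <- tiny_grid(5, 2)
  one <- brain_volume(g, array(0.3, g$shape), array(TRUE, g$shape))
  expect_equal(ale_union(list(one))$values, one$values)
  half <- brain_volume(g, array(0.5, g$shape), array(TRUE, g$shape))
  expect_equal(ale_union(list(half, half))$values[1], 0.75)
  # ten random maps vs a log-space product oracle
  set.seed(1)
  maps <- lapply(1:10, function(i)
    brain_volume(g, array(runif(prod(g$shape), 0, 0.9), g$shape),
                 array(TRUE, g$shape)))
  got <- ale_union(maps)$values
  oracle <- 1 - exp(Reduce(`+`, lapply(maps, function(m)
    log1p(-m$values))))
  expect_equal(got, oracle, tolerance = 1e-12)
  # union dominates every input (monotonicity)
  for (m in maps) expect_true(all(got >= m$values - 1e-15))
  expect_true(all(got >= 0 & got < 1))
})

test_that("the random-foci null is reproducible and lives in [0, 1)", {
  g <- tiny_grid(9, 4)
  mask <- full_mask(g)
  cfg <- ale_config(n_null = 300, seed = 11)
  n1 <- ale_null(c(3, 2), mask, cfg)
  n2 <- ale_null(c(3, 2), mask, cfg)
  expect_identical(n1$values, n2$values)
  expect_equal(n1$n, 300L)
  expect_true(all(n1$values >= 0 & n1$values < 1))
  n3 <- ale_null(c(3, 2), mask, ale_config(n_null = 300, seed = 12))
  expect_false(identical(n1$values, n3$values))
  expect_warning(ale_null(c(3, 2), mask,
                          ale_config(n_null = 50, seed = 1)), "unstable")
})

test_that("single-kernel null matches an independent resampling oracle", {
  # one experiment, one focus, sigma small vs voxel size: the null value
  # at a sampled voxel is the kernel mass at the distance between two
  # uniform in-mask points; compare distribution against a direct
  # resampling oracle
  g <- tiny_grid(9, 4)
  mask <- full_mask(g)
  fwhm <- 8 * sqrt(8 * log(2))  # sigma = 8 mm
  cfg <- ale_config(fwhm_mm = fwhm, n_null = 400, seed = 5)
  null <- ale_null(1L, mask, cfg)
  set.seed(99)
  xyz <- grid_coords(g)
  sim <- replicate(400, {
    f <- xyz[sample.int(nrow(xyz), 1), ] + runif(3, -2, 2)
    v <- xyz[sample.int(nrow(xyz), 1), ]
    d2 <- sum((f - v)^2)
    g$voxel_volume / (8^3 * (2 * pi)^1.5) * exp(-d2 / (2 * 8^2))
  })
  # same distribution: compare quartiles within Monte Carlo slack
  expect_equal(unname(quantile(null$values, c(0.25, 0.5, 0.75))),
               unname(quantile(sim, c(0.25, 0.5, 0.75))),
               tolerance = 0.25)
  expect_gt(stats::ks.test(null$values, sim)$p.value, 0.001)
})

test_that("ALE to p/z conversion follows the add-one rank rule", {
  g <- tiny_grid(3, 2)
  null <- sort(runif(999, 0.2, 0.8))
  N <- length(null)
  vals <- array(c(0.1, median(null), 0.9, rep(0.5, prod(g$shape) - 3)),
                g$shape)
  ale <- brain_volume(g, vals, array(TRUE, g$shape))
  pz <- ale_to_p_z(ale, null)
  p <- pz$p$values; z <- pz$z$values
  # below every null sample: p at its ceiling, z negative
  expect_equal(p[1], N / (N + 1))
  expect_lt(z[1], 0)
  # above every null sample
  expect_equal(p[3], 1 / (N + 1))
  # at the median: p ~ 0.5, z ~ 0 within rank resolution
  expect_equal(p[2], 0.5, tolerance = 0.01)
  expect_equal(z[2], 0, tolerance = 0.05)
  # p-z consistency at every voxel
  expect_lt(max(abs(pnorm(z) + p - 1)), 1e-6)
  # monotone: higher ALE, lower p
  expect_true(all(diff(p[order(vals)]) <= 0))
  expect_error(ale_to_p_z(ale, numeric(0)), "empty")
})

test_that("cluster extraction applies the 150 mm3 minimum extent rule", {
  g <- tiny_grid(12, 2)   # 8 mm3 voxels
  cfg <- ale_config(alpha = 0.05, min_cluster_mm3 = 150)
  pv <- array(0.5, g$shape)
  pv[2:3, 2:3, 2:3] <- 0.01          # 8 voxels = 64 mm3 -> removed
  p <- brain_volume(g, pv, array(TRUE, g$shape))
  suppressMessages(cl <- extract_clusters(p, cfg))
  expect_equal(nrow(cl$cluster_table), 0L)
  expect_true(all(cl$labels$values == 0))
  pv[7:11, 8:11, 6] <- 0.01          # 20 voxels = 160 mm3 -> retained
  p <- brain_volume(g, pv, array(TRUE, g$shape))
  suppressMessages(cl <- extract_clusters(p, cfg))
  expect_equal(cl$cluster_table$n_voxels, c(20L))
  expect_equal(cl$cluster_table$volume_mm3, 160)
  # every labelled voxel is suprathreshold
  expect_true(all(pv[cl$labels$values > 0] < cfg$alpha))
})

test_that("connectivity controls whether diagonal blobs merge", {
  g <- tiny_grid(10, 4)  # 64 mm3 voxels: 3 voxels > 150 mm3
  pv <- array(0.5, g$shape)
  pv[2:4, 2, 2] <- 0.01
  pv[5:7, 3, 3] <- 0.01   # touches (4,2,2) only diagonally
  p <- brain_volume(g, pv, array(TRUE, g$shape))
  cl26 <- extract_clusters(p, ale_config(connectivity = 26L,
                                         min_cluster_mm3 = 150))
  suppressMessages(
    cl6 <- extract_clusters(p, ale_config(connectivity = 6L,
                                          min_cluster_mm3 = 150)))
  expect_equal(nrow(cl26$cluster_table), 1L)
  expect_equal(nrow(cl6$cluster_table), 2L)
  # flood-fill oracle: 26-connected components via iterative dilation
  expect_equal(sum(cl26$labels$values > 0), 6L)
})

test_that("pipeline ALE equals the brute-force per-voxel computation", {
  # compact version of the full-pipeline oracle (small n); the acceptance
  # suite runs the larger configuration
  g <- tiny_grid(8, 4)
  set.seed(3)
  exps <- lapply(1:3, function(i)
    experiment(paste0("e", i), "decrease", 10 + i,
               matrix(runif(9, -12, 12), ncol = 3), "TAL"))
  cfg <- ale_config(fwhm_mm = 10)
  sigma <- kernel_sigma(10)
  ale <- ale_union(lapply(exps, experiment_ma_map, grid = g, cfg = cfg))
  oracle <- array(NA_real_, g$shape)
  for (i in 1:8) for (j in 1:8) for (l in 1:8) {
    xyz <- drop(g$affine %*% c(i - 1, j - 1, l - 1, 1))[1:3]
    surv <- 1
    for (e in exps) {
      ks <- apply(e$foci, 1, function(f)
        g$voxel_volume / (sigma^3 * (2 * pi)^1.5) *
          exp(-sum((xyz - f)^2) / (2 * sigma^2)))
      surv <- surv * (1 - max(ks))
    }
    oracle[i, j, l] <- 1 - surv
  }
  expect_lt(max(abs(ale$values - oracle)), 1e-10)
})

test_that("adding an experiment never decreases ALE anywhere", {
  g <- tiny_grid(8, 4)
  set.seed(8)
  exps <- lapply(1:4, function(i)
    experiment(paste0("e", i), "decrease", 12,
               matrix(runif(6, -12, 12), ncol = 3), "TAL"))
  cfg <- ale_config()
  ma <- lapply(exps, experiment_ma_map, grid = g, cfg = cfg)
  a3 <- ale_union(ma[1:3])$values
  a4 <- ale_union(ma)$values
  expect_true(all(a4 >= a3 - 1e-15))
})

test_that("sample-size kernel rule widens kernels for smaller samples", {
  cfg <- ale_config(fwhm_mm = "sample_size_rule", fwhm_ref = 10, n_ref = 10)
  f10 <- alexpr:::experiment_fwhm(cfg, 10)
  f40 <- alexpr:::experiment_fwhm(cfg, 40)
  expect_equal(f10, 10)
  expect_equal(f40, 5)        # FWHM ~ 1/sqrt(n)
  expect_gt(f10, f40)
})

test_that("voxel threshold is calibrated on uniform random foci", {
  # with foci uniform in the mask, a random voxel's ALE value follows
  # the same law as the random-foci null, so the suprathreshold voxel
  # fraction at alpha = 0.05 should be ~0.05 before cluster filtering
  g <- default_grid(6, c(-36, 36), c(-36, 36), c(-36, 36))
  mask <- ellipsoid_mask(g, c(34, 34, 34))
  centres <- data.frame(x = 0, y = 0, z = 0, direction = "decrease",
                        sd_mm = 0, hit_prob = 0)
  fracs <- vapply(1:3, function(i) {
    truth <- synthetic_truth(alteration_centres = centres,
                             background_foci_rate = 5, seed = 40 + i)
    ds <- generate_foci(truth, 15L, c(10L, 25L), mask)
    cfg <- ale_config(n_null = 4000L, seed = 50 + i)
    ale <- ale_union(lapply(ds$experiments, experiment_ma_map,
                            grid = g, cfg = cfg))
    ale$values[!mask$mask] <- NA; ale$mask <- mask$mask
    null <- ale_null(vapply(ds$experiments, function(e) nrow(e$foci), 0L),
                     mask, cfg)
    pz <- ale_to_p_z(ale, null)
    mean(pz$p$values[mask$mask] < 0.05)
  }, 0.0)
  expect_gte(mean(fracs), 0.03)
  expect_lte(mean(fracs), 0.07)
})
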