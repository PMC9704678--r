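#' Resting-state network atlas
#'
#' An integer label volume (0 = unassigned) plus network names, e.g. the
#' Yeo 7 cortical networks complemented by basal ganglia/thalamus and
#' cerebellum parcels.
#'
#' @param labels a [brain_volume()] of integer labels 0..K.
#' @param names named character vector or list mapping label (as
#'   character) to network name; must cover every non-zero label present.
#' @return an object of class `network_atlas`.
#' @export
network_atlas <- function(labels, names) {
  lab <- round(labels$values)
  if (any(lab < 0)) stop("atlas labels must be non-negative")
  present <- setdiff(sort(unique(as.vector(lab[labels$mask]))), 0)
  nm <- unlist(names)
  missing <- setdiff(as.character(present), base::names(nm))
  if (length(missing))
    stop("atlas names missing for label(s): ", paste(missing, collapse = ", "))
  structure(list(labels = labels, names = nm), class = "network_atlas")
}

#' Canonical network names for a K=9 parcellation
#'
#' The Yeo-7 cortical networks plus basal ganglia/thalamus and cerebellum.
#' @param k number of networks; for k != 9, generic `Net<k>` names.
#' @export
default_network_names <- function(k = 9L) {
  nm <- if (k == 9L)
    c("Visual", "SMN", "DAN", "VAN/SN", "Limbic", "FPN", "DMN",
      "BG/Thal", "Cerebellum")
  else paste0("Net", seq_len(k))
  stats::setNames(nm, as.character(seq_len(k)))
}

#' Permutation test configuration
#'
#' @param n_perm number of cluster permutations (default 10000).
#' @param ci one-sided confidence level for the null threshold (default
#'   0.95).
#' @param seed master seed.
#' @export
permutation_config <- function(n_perm = 10000L, ci = 0.95, seed = 1L) {
  stopifnot(n_perm >= 100L, ci > 0.5, ci < 1)
  structure(list(n_perm = as.integer(n_perm), ci = ci,
                 seed = as.integer(seed)),
            class = "permutation_config")
}

# Voxel counts of each (cluster, network) cell: C x K matrix over in-mask
# voxels carrying both a cluster label and a network label.  The fixed
# geometry every permutation re-uses.
cluster_network_counts <- function(labels, atlas) {
  check_same_grid(labels, atlas$labels, "cluster labels and atlas")
  cl <- round(labels$values)
  nl <- round(atlas$labels$values)
  keep <- cl > 0 & nl > 0 & labels$mask & atlas$labels$mask
  cl_ids <- sort(unique(as.vector(cl[cl > 0 & labels$mask])))
  k_ids <- as.integer(names(atlas$names))
  counts <- matrix(0L, nrow = length(cl_ids), ncol = length(k_ids),
                   dimnames = list(cl_ids, unname(atlas$names)))
  if (any(keep)) {
    tab <- table(factor(cl[keep], levels = cl_ids),
                 factor(nl[keep], levels = k_ids))
    counts[] <- as.integer(tab)
  }
  counts
}

# network means for one r-vector over the fixed geometry; clusters with
# undefined (NA) or exactly-zero r are excluded voxel-wise, matching the
# "coefficients if different from 0" rule
network_means_from_r <- function(r, counts) {
  use <- is.finite(r) & r != 0
  k <- ncol(counts)
  if (!any(use))
    return(stats::setNames(rep(NA_real_, k), colnames(counts)))
  w <- counts[use, , drop = FALSE]
  num <- as.numeric(crossprod(w, r[use]))
  den <- as.numeric(colSums(w))
  out <- ifelse(den > 0, num / den, NA_real_)
  stats::setNames(out, colnames(counts))
}

#' Network-level mean correlation
#'
#' For each network, the mean of the correlation volume over voxels with
#' that network's label and a non-zero correlation value.  Networks with
#' no such voxels are reported missing (`mean_r = NA`, `n_voxels_used =
#' 0`).
#'
#' @param corr a piecewise-constant correlation `brain_volume`.
#' @param atlas a [network_atlas()].
#' @return data.frame: network, label, mean_r, n_voxels_used.
#' @export
network_mean <- function(corr, atlas) {
  check_same_grid(corr, atlas$labels, "correlation volume and atlas")
  nl <- round(atlas$labels$values)
  vals <- corr$values
  keep <- nl > 0 & atlas$labels$mask & corr$mask & is.finite(vals) &
    vals != 0
  k_ids <- as.integer(names(atlas$names))
  mean_r <- n_used <- numeric(length(k_ids))
  for (i in seq_along(k_ids)) {
    vox <- keep & nl == k_ids[i]
    n_used[i] <- sum(vox)
    mean_r[i] <- if (n_used[i]) mean(vals[vox]) else NA_real_
  }
  data.frame(network = unname(atlas$names), label = k_ids,
             mean_r = mean_r, n_voxels_used = as.integer(n_used))
}

#' Cluster-permutation null distribution of network means
#'
#' Holds cluster geometry fixed and permutes the vector of cluster r
#' values uniformly at random (without replacement; the identity may
#' occur), recomputing every network's non-zero-voxel mean at each
#' iteration.
#'
#' @param cluster_r numeric vector of cluster r values, ordered by
#'   cluster id 1..C (NA allowed for undefined clusters).
#' @param labels cluster-label volume.
#' @param atlas a [network_atlas()].
#' @param cfg a [permutation_config()].
#' @param exhaustive if `TRUE`, enumerate all `C!` permutations instead of
#'   sampling (feasible for small C; overrides `n_perm`).
#' @param stream seed stream label (distinct per gene/direction).
#' @return matrix `n_perm x K` of null network means (columns named by
#'   network).
#' @export
permutation_null <- function(cluster_r, labels, atlas,
                             cfg = permutation_config(),
                             exhaustive = FALSE, stream = "perm") {
  counts <- cluster_network_counts(labels, atlas)
  C <- nrow(counts)
  stopifnot(length(cluster_r) == C)
  if (sum(is.finite(cluster_r)) < 2L)
    warning("fewer than 2 defined cluster r values: degenerate null, ",
            "significance impossible")
  perms <- if (exhaustive) {
    all_permutations(C)
  } else {
    NULL
  }
  n_it <- if (exhaustive) nrow(perms) else cfg$n_perm
  out <- matrix(NA_real_, n_it, ncol(counts),
                dimnames = list(NULL, colnames(counts)))
  if (!exhaustive) {
    with_seed(sub_seed(cfg$seed, stream), {
      perms <- if (C == 1L) matrix(1L, n_it, 1L) else
        t(replicate(n_it, sample.int(C)))
    })
  }
  if (all(is.finite(cluster_r)) && all(cluster_r != 0)) {
    # fast path: every cluster contributes, so the per-network
    # denominators are permutation-invariant and the whole null is one
    # matrix product
    R <- matrix(cluster_r[perms], nrow = n_it)
    den <- colSums(counts)
    out[] <- (R %*% counts) / rep(den, each = n_it)
    out[, den == 0] <- NA_real_
  } else {
    for (i in seq_len(n_it))
      out[i, ] <- network_means_from_r(cluster_r[perms[i, ]], counts)
  }
  out
}

# all C! permutations as rows (small C only)
all_permutations <- function(C) {
  if (C == 1L) return(matrix(1L, 1, 1))
  do.call(rbind, lapply(seq_len(C), function(v) {
    sub <- all_permutations(C - 1L)
    rest <- setdiff(seq_len(C), v)
    unname(cbind(v, matrix(rest[sub], nrow(sub))))
  }))
}

#' Significance of observed network means against the permutation null
#'
#' One-sided: a network's gene-alteration association is significant when
#' its observed mean exceeds the `ci` upper quantile of its null means
#' (the order statistic of rank `ceiling(ci * n)`); `p_perm` uses the
#' add-one rank rule `(1 + #\{null >= obs\}) / (1 + n)`.
#'
#' @param observed data.frame from [network_mean()].
#' @param null matrix from [permutation_null()] (columns = networks).
#' @param cfg a [permutation_config()].
#' @param gene,direction metadata columns for the output.
#' @return data.frame: gene, direction, network, mean_r, n_voxels_used,
#'   null_threshold, p_perm, significant, degenerate.
#' @export
assess_significance <- function(observed, null, cfg = permutation_config(),
                                gene = NA_character_,
                                direction = NA_character_) {
  stopifnot(nrow(null) >= 1L)
  out <- observed
  out$gene <- gene
  out$direction <- direction
  out$null_threshold <- NA_real_
  out$p_perm <- NA_real_
  out$significant <- FALSE
  out$degenerate <- FALSE
  for (i in seq_len(nrow(out))) {
    nm <- out$network[i]
    nd <- null[, nm]
    nd <- nd[is.finite(nd)]
    if (!length(nd)) { out$degenerate[i] <- TRUE; next }
    thr <- sort(nd)[ceiling(cfg$ci * length(nd))]
    out$null_threshold[i] <- thr
    if (length(unique(nd)) == 1L) out$degenerate[i] <- TRUE
    obs <- out$mean_r[i]
    if (!is.finite(obs)) next  # empty network: not significant, p undefined
    out$p_perm[i] <- (1 + sum(nd >= obs)) / (1 + length(nd))
    out$significant[i] <- obs > thr
  }
  out[, c("gene", "direction", "network", "label", "mean_r",
          "n_voxels_used", "null_threshold", "p_perm", "significant",
          "degenerate")]
}

#' Network permutation analysis for a full correlation volume set
#'
#' Runs [network_mean()], [permutation_null()] and
#' [assess_significance()] for every (gene, direction), with an
#' independent sub-seed per pair.  Decrease and increase clusters are
#' permuted separately.
#'
#' @param corrset a `correlation_volume_set` from [correlate_all()].
#' @param labels named list `list(decrease = , increase = )` of
#'   cluster-label volumes.
#' @param atlas a [network_atlas()].
#' @param cfg a [permutation_config()].
#' @param p_adjust multiple-testing adjustment across the networks x genes
#'   grid, per direction: `"none"` (default, matching the uncorrected
#'   reporting convention), or any method of [stats::p.adjust()].
#' @return data.frame of `assess_significance()` rows for all pairs, plus
#'   a `p_adj` column when adjustment is requested.
#' @export
network_analysis <- function(corrset, labels, atlas,
                             cfg = permutation_config(),
                             p_adjust = "none") {
  rows <- list()
  for (key in names(corrset$volumes)) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    gene <- parts[1]; dir <- parts[2]
    res <- corrset$results[[key]]
    ids <- vapply(res, `[[`, 0, "cluster_id")
    r <- rep(NA_real_, max(ids))
    r[ids] <- vapply(res, function(x) if (isTRUE(x$ok)) x$r else NA_real_,
                     0.0)
    obs <- network_mean(corrset$volumes[[key]], atlas)
    null <- permutation_null(r, labels[[dir]], atlas, cfg,
                             stream = paste0("perm|", key))
    rows[[key]] <- assess_significance(obs, null, cfg, gene = gene,
                                       direction = dir)
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (!identical(p_adjust, "none")) {
    out$p_adj <- NA_real_
    for (dir in unique(out$direction)) {
      sel <- out$direction == dir & is.finite(out$p_perm)
      out$p_adj[sel] <- stats::p.adjust(out$p_perm[sel], method = p_adjust)
    }
  }
  out
}

#' Pivot a network stats table to the networks x genes layout
#'
#' @param stats long data.frame from [network_analysis()].
#' @param direction which direction to tabulate.
#' @param mark_significant append `*` to significant cells.
#' @return data.frame with one row per network, one column per gene.
#' @export
network_stats_wide <- function(stats, direction,
                               mark_significant = TRUE) {
  s <- stats[stats$direction == direction, ]
  genes <- unique(s$gene)
  nets <- unique(s$network)
  out <- data.frame(network = nets)
  for (g in genes) {
    col <- vapply(nets, function(n) {
      row <- s[s$gene == g & s$network == n, ]
      if (!nrow(row) || !is.finite(row$mean_r[1])) return(NA_character_)
      v <- sprintf("%.2f", row$mean_r[1])
      if (mark_significant && isTRUE(row$significant[1]))
        v <- paste0(v, "*")
      v
    }, "")
    out[[g]] <- col
  }
  out
}

#' Mask a correlation volume to its significant networks
#'
#' Keeps cluster-wise r values only at voxels of networks flagged
#' significant for that (gene, direction); everything else is 0.
#'
#' @param corr piecewise-constant correlation `brain_volume`.
#' @param atlas a [network_atlas()].
#' @param stats rows of a [network_analysis()] table for one
#'   (gene, direction).
#' @return a `brain_volume`.
#' @export
significance_mask_volume <- function(corr, atlas, stats) {
  sig <- stats$label[stats$significant]
  vals <- corr$values
  keep <- round(atlas$labels$values) %in% sig
  vals[!keep] <- 0
  brain_volume(corr$grid, vals, corr$mask)
}
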