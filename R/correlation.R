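#' Pearson correlation between the ALE Z map and a gene map within a cluster
#'
#' Computed over the cluster's voxels that carry finite values in both
#' maps (pairwise exclusion; `n_voxels` reports the pairs actually used).
#' The Fisher variance-stabilizing transform `atanh(r)` and the Student
#' statistic `t = r * sqrt(n - 2) / sqrt(1 - r^2)` are both recorded;
#' network-level significance downstream uses neither (it is permutation
#' based).
#'
#' @param zmap ALE Z volume ([brain_volume()]).
#' @param genemap a `gene_expression_map` (or a `brain_volume`).
#' @param labels cluster-label volume.
#' @param cluster_id cluster to correlate.
#' @param gene,direction metadata carried into the result.
#' @param min_voxels minimum usable voxel pairs (default 3).
#' @return an object of class `cluster_correlation`: gene, direction,
#'   cluster_id, r, n_voxels, fisher_z, t_stat, ok (FALSE when r is
#'   undefined: too few voxels or zero variance).
#' @export
correlate_cluster <- function(zmap, genemap, labels, cluster_id,
                              gene = NA_character_,
                              direction = NA_character_, min_voxels = 3L) {
  gvol <- if (inherits(genemap, "gene_expression_map")) genemap$volume
          else genemap
  check_same_grid(zmap, gvol, "Z map and gene map")
  check_same_grid(zmap, labels, "Z map and cluster labels")
  vox <- which(round(labels$values) == cluster_id & labels$mask)
  if (!length(vox))
    stop("cluster ", cluster_id, " not present in the label volume")
  a <- zmap$values[vox]
  b <- gvol$values[vox]
  ok_pair <- is.finite(a) & is.finite(b) & zmap$mask[vox] & gvol$mask[vox]
  a <- a[ok_pair]; b <- b[ok_pair]
  n <- length(a)
  bad <- function(reason) structure(
    list(gene = gene, direction = direction, cluster_id = cluster_id,
         r = NA_real_, n_voxels = n, fisher_z = NA_real_,
         t_stat = NA_real_, ok = FALSE, reason = reason),
    class = "cluster_correlation")
  if (n < min_voxels) return(bad("fewer than min_voxels usable pairs"))
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    return(bad("zero variance inside cluster"))
  r <- stats::cor(a, b)
  t_stat <- if (abs(r) < 1) r * sqrt(n - 2) / sqrt(1 - r^2) else
    sign(r) * Inf
  structure(list(gene = gene, direction = direction,
                 cluster_id = cluster_id, r = r, n_voxels = n,
                 fisher_z = atanh(r), t_stat = t_stat, ok = TRUE,
                 reason = NA_character_),
            class = "cluster_correlation")
}

#' Paint cluster-wise r values into a volume
#'
#' Every voxel of cluster k takes that cluster's r; voxels outside any
#' cluster, and clusters whose r is undefined, are 0.
#'
#' @param results list of `cluster_correlation` objects (unique
#'   cluster_id).
#' @param labels cluster-label volume.
#' @return a `brain_volume` of piecewise-constant correlation values.
#' @export
build_correlation_volume <- function(results, labels) {
  ids <- vapply(results, `[[`, 0, "cluster_id")
  if (anyDuplicated(ids))
    stop("duplicate cluster_id in correlation results")
  lut <- numeric(max(c(0, round(labels$values)), 1))
  for (res in results) {
    if (isTRUE(res$ok)) lut[res$cluster_id] <- res$r
    # undefined r stays 0
  }
  lab <- round(labels$values)
  vals <- array(0, labels$grid$shape)
  nz <- lab > 0
  vals[nz] <- lut[lab[nz]]
  brain_volume(labels$grid, vals, array(TRUE, labels$grid$shape))
}

#' Cluster-wise correlations for all genes and both directions
#'
#' Iterates over every (gene, direction, cluster) triple, producing one
#' piecewise-constant correlation volume per (gene, direction) -- with 8
#' genes, the 16 gene-specific maps -- plus the full correlation table.
#'
#' @param zmaps named list `list(decrease = , increase = )` of Z volumes.
#' @param genemaps list of `gene_expression_map`s.
#' @param labels named list `list(decrease = , increase = )` of
#'   cluster-label volumes.
#' @param min_voxels minimum usable voxels per cluster (default 3).
#' @return an object of class `correlation_volume_set`: list with
#'   `volumes` (named `"<gene>|<direction>"`), `table` (data.frame), and
#'   `results` (nested list of `cluster_correlation`s).
#' @export
correlate_all <- function(zmaps, genemaps, labels, min_voxels = 3L) {
  for (dir in c("decrease", "increase")) {
    if (is.null(zmaps[[dir]]) || is.null(labels[[dir]]))
      stop("correlate_all: missing direction '", dir,
           "' (both directions are required)")
  }
  stopifnot(length(genemaps) >= 1L)
  volumes <- list()
  results <- list()
  rows <- list()
  for (gm in genemaps) {
    for (dir in c("decrease", "increase")) {
      ids <- sort(setdiff(unique(round(labels[[dir]]$values)), 0))
      res <- lapply(ids, function(k)
        correlate_cluster(zmaps[[dir]], gm, labels[[dir]], k,
                          gene = gm$gene, direction = dir,
                          min_voxels = min_voxels))
      key <- paste(gm$gene, dir, sep = "|")
      volumes[[key]] <- build_correlation_volume(res, labels[[dir]])
      results[[key]] <- res
      rows[[key]] <- do.call(rbind, lapply(res, function(x)
        data.frame(gene = x$gene, direction = x$direction,
                   cluster_id = x$cluster_id, r = x$r,
                   n_voxels = x$n_voxels, fisher_z = x$fisher_z,
                   t_stat = x$t_stat, ok = x$ok)))
    }
  }
  structure(list(volumes = volumes,
                 table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
                 results = results),
            class = "correlation_volume_set")
}

#' @export
print.correlation_volume_set <- function(x, ...) {
  cat(sprintf("<correlation_volume_set: %d volumes, %d cluster rows>\n",
              length(x$volumes), nrow(x$table)))
  invisible(x)
}
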