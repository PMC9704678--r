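#' Read a pipeline configuration from YAML
#'
#' Maps a plain YAML file onto [run_config()].  Recognized top-level keys:
#' `foci`, `foci_dialect`, `expression`, `atlas`, `genes`, `seed`,
#' `out_dir`, `n_experiments`, `subjects_range`, `k_networks`,
#' `grid: {voxel_mm, xlim, ylim, zlim}`, `ale: {...}` (fields of
#' [ale_config()], plus optional `icbm2tal` 16-number row-major override
#' consumed by the CLI), and `perm: {...}` (fields of
#' [permutation_config()]).
#'
#' @param path YAML file.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  grid <- if (!is.null(y$grid)) {
    do.call(default_grid, c(
      list(voxel_mm = y$grid$voxel_mm %||% 2),
      Filter(Negate(is.null),
             list(xlim = unlist(y$grid$xlim), ylim = unlist(y$grid$ylim),
                  zlim = unlist(y$grid$zlim)))))
  } else default_grid(4)
  ale <- do.call(ale_config,
                 y$ale[intersect(names(y$ale), names(formals(ale_config)))]
                 %||% list())
  perm <- do.call(permutation_config,
                  y$perm[intersect(names(y$perm),
                                   names(formals(permutation_config)))]
                  %||% list())
  args <- list(grid = grid, ale = ale, perm = perm)
  for (nm in c("foci", "foci_dialect", "expression", "atlas", "genes",
               "seed", "out_dir", "n_experiments", "k_networks")) {
    if (!is.null(y[[nm]])) args[[nm]] <- unlist(y[[nm]])
  }
  if (!is.null(y$subjects_range))
    args$subjects_range <- as.integer(unlist(y$subjects_range))
  do.call(run_config, args)
}
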