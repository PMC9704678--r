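#' Read a foci table
#'
#' Two dialects are supported.
#'
#' * `csv`: columns `experiment_id, direction, n_subjects, space, x, y, z`,
#'   one row per focus; rows sharing an `experiment_id` form one experiment.
#' * `sleuth`: a Sleuth-like text format of blank-line-separated blocks:
#'   a global `// Reference=Talairach` (or `MNI`) header, then per block
#'   `// <Author>: <Contrast>` and `// Subjects=<n>` comment lines
#'   (optionally `// Direction=decrease|increase`, default decrease)
#'   followed by one whitespace-separated `x y z` row per focus.
#'
#' Experiments failing the screening rules (fewer than 10 participants, no
#' foci) are excluded and reported in the attached exclusion report.
#'
#' @param source path to a file, or a character vector of lines.
#' @param dialect `"csv"` or `"sleuth"`.
#' @param min_subjects screening threshold, default 10.
#' @param label dataset label.
#' @return a [foci_dataset()] with attribute `"exclusions"` (data.frame
#'   `experiment_id, rule, detail`).
#' @export
read_foci <- function(source, dialect = c("csv", "sleuth"),
                      min_subjects = 10L, label = NULL) {
  dialect <- match.arg(dialect)
  lines <- if (length(source) == 1L && file.exists(source)) {
    if (is.null(label)) label <- basename(source)
    readLines(source, warn = FALSE)
  } else {
    as.character(source)
  }
  if (is.null(label)) label <- "foci"
  if (!length(lines) || all(!nzchar(trimws(lines))))
    stop("read_foci: empty source")
  exps <- switch(dialect,
                 csv = parse_foci_csv(lines),
                 sleuth = parse_foci_sleuth(lines))
  scr <- screen_experiments(exps, min_subjects = min_subjects)
  if (!length(scr$experiments))
    stop("read_foci: no experiment passed screening")
  ds <- foci_dataset(scr$experiments, label = label)
  attr(ds, "exclusions") <- scr$exclusions
  ds
}

parse_foci_csv <- function(lines) {
  df <- utils::read.csv(text = paste(lines, collapse = "\n"),
                        stringsAsFactors = FALSE)
  need <- c("experiment_id", "direction", "n_subjects", "space",
            "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("foci CSV is missing columns: ", paste(miss, collapse = ", "))
  bad_space <- setdiff(unique(df$space), c("TAL", "MNI"))
  if (length(bad_space))
    stop("unknown space tag(s): ", paste(bad_space, collapse = ", "))
  bad_dir <- setdiff(unique(df$direction), c("decrease", "increase"))
  if (length(bad_dir))
    stop("unknown direction(s): ", paste(bad_dir, collapse = ", "))
  for (v in c("x", "y", "z")) {
    cv <- suppressWarnings(as.numeric(df[[v]]))
    if (any(!is.finite(cv))) {
      row <- which(!is.finite(cv))[1]
      stop(sprintf("malformed coordinate in column %s, data row %d", v, row))
    }
    df[[v]] <- cv
  }
  lapply(split(df, factor(df$experiment_id, levels = unique(df$experiment_id))),
         function(g) {
           if (length(unique(g$space)) > 1L)
             stop("experiment ", g$experiment_id[1], " mixes spaces")
           if (length(unique(g$direction)) > 1L)
             stop("experiment ", g$experiment_id[1], " mixes directions")
           experiment(g$experiment_id[1], g$direction[1],
                      g$n_subjects[1], as.matrix(g[, c("x", "y", "z")]),
                      g$space[1])
         })
}

parse_foci_sleuth <- function(lines) {
  space <- "TAL"
  exps <- list()
  cur <- NULL
  flush <- function() {
    if (is.null(cur)) return()
    if (is.null(cur$id)) cur$id <<- sprintf("experiment_%03d", length(exps) + 1L)
    foci <- if (length(cur$rows)) do.call(rbind, cur$rows) else
      matrix(numeric(), ncol = 3)
    exps[[length(exps) + 1L]] <<- list(
      id = cur$id, direction = cur$direction %||% "decrease",
      n_subjects = cur$n %||% NA_integer_,
      foci = foci, space = space)
    cur <<- NULL
  }
  for (ln in seq_along(lines)) {
    raw <- trimws(lines[ln])
    if (!nzchar(raw)) { flush(); next }
    if (startsWith(raw, "//")) {
      body <- trimws(sub("^//", "", raw))
      if (grepl("^Reference\\s*=", body, ignore.case = TRUE)) {
        tag <- toupper(trimws(sub("^Reference\\s*=", "", body,
                                  ignore.case = TRUE)))
        space <- switch(tag,
                        TALAIRACH = , TAL = "TAL",
                        MNI = "MNI",
                        stop(sprintf("line %d: unknown space tag '%s'",
                                     ln, tag)))
      } else if (grepl("^Subjects\\s*=", body, ignore.case = TRUE)) {
        if (is.null(cur)) cur <- list(rows = list())
        cur$n <- as.integer(sub("^Subjects\\s*=", "", body,
                                ignore.case = TRUE))
      } else if (grepl("^Direction\\s*=", body, ignore.case = TRUE)) {
        if (is.null(cur)) cur <- list(rows = list())
        cur$direction <- match.arg(
          tolower(trimws(sub("^Direction\\s*=", "", body,
                             ignore.case = TRUE))),
          c("decrease", "increase"))
      } else {
        # "// Author: Contrast" opens a new block
        if (!is.null(cur) && length(cur$rows)) flush()
        if (is.null(cur)) cur <- list(rows = list())
        cur$id <- body
      }
    } else {
      xyz <- suppressWarnings(as.numeric(strsplit(raw, "[ \t,]+")[[1]]))
      if (length(xyz) != 3L || any(!is.finite(xyz)))
        stop(sprintf("line %d: malformed coordinate line '%s'", ln, raw))
      if (is.null(cur)) cur <- list(rows = list())
      cur$rows[[length(cur$rows) + 1L]] <- xyz
    }
  }
  flush()
  lapply(exps, function(e) {
    if (is.na(e$n_subjects))
      stop("experiment '", e$id, "' has no // Subjects= line")
    if (nrow(e$foci) == 0L) return(e)  # screened later with a report
    experiment(e$id, e$direction, e$n_subjects, e$foci, e$space)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a foci dataset to CSV lines
#' @param dataset a [foci_dataset()].
#' @param path optional output file; if `NULL`, lines are returned.
#' @export
write_foci <- function(dataset, path = NULL) {
  rows <- do.call(rbind, lapply(dataset$experiments, function(e) {
    data.frame(experiment_id = e$id, direction = e$direction,
               n_subjects = e$n_subjects, space = e$space,
               x = e$foci[, 1], y = e$foci[, 2], z = e$foci[, 3])
  }))
  if (is.null(path)) {
    con <- textConnection("out", "w", local = TRUE)
    utils::write.csv(rows, con, row.names = FALSE, quote = FALSE)
    close(con)
    return(out)
  }
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' The mask is reconstructed as the finite-value support of the data
#' (NaN/Inf voxels are outside the mask).
#'
#' @param path a `.nii` / `.nii.gz` file.
#' @return a [brain_volume()].
#' @export
read_volume <- function(path) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("not a readable NIfTI file: ",
                                           path, " (", conditionMessage(e), ")"))
  vals <- array(as.numeric(img), dim = dim(img)[1:3])
  aff <- unname(structure(RNifti::xform(img), imagedim = NULL, code = NULL))
  attributes(aff) <- list(dim = c(4L, 4L))
  grid <- voxel_grid(dim(vals), aff)
  mask <- is.finite(vals)
  vals[!mask] <- NA_real_
  brain_volume(grid, vals, mask)
}

#' Write a volume as NIfTI-1
#'
#' Out-of-mask voxels are written as NaN so the mask round-trips as the
#' finite-value support.
#'
#' @param v a [brain_volume()].
#' @param path output `.nii` / `.nii.gz` path.
#' @param na_outside write NaN outside the mask (default TRUE).
#' @export
write_volume <- function(v, path, na_outside = TRUE) {
  vals <- v$values
  if (na_outside) vals[!v$mask] <- NA_real_
  img <- RNifti::asNifti(vals)
  img <- RNifti::`sform<-`(img, structure(v$grid$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Resample an integer label volume onto a target grid
#'
#' Nearest-neighbour resampling: each target voxel centre is mapped through
#' the atlas affine and takes the label of the nearest atlas voxel; centres
#' falling outside the atlas array get label 0 (unassigned).  No new labels
#' are ever introduced.
#'
#' @param atlas a [brain_volume()] of non-negative integer labels.
#' @param target a [voxel_grid()].
#' @return a `brain_volume` of labels on `target`.
#' @export
regrid_atlas <- function(atlas, target) {
  av <- atlas$values
  av[!atlas$mask] <- 0
  if (any(abs(av - round(av)) > 1e-6) || any(av < 0))
    stop("atlas labels must be non-negative integers")
  if (same_grid(atlas$grid, target)) {
    return(brain_volume(target, round(av), mask = array(TRUE, target$shape)))
  }
  xyz <- grid_coords(target)
  ijk <- round(world_to_voxel(atlas$grid, xyz))
  inb <- ijk[, 1] >= 1 & ijk[, 1] <= atlas$grid$shape[1] &
    ijk[, 2] >= 1 & ijk[, 2] <= atlas$grid$shape[2] &
    ijk[, 3] >= 1 & ijk[, 3] <= atlas$grid$shape[3]
  out <- numeric(nrow(ijk))
  lin <- (ijk[inb, 3] - 1) * prod(atlas$grid$shape[1:2]) +
    (ijk[inb, 2] - 1) * atlas$grid$shape[1] + ijk[inb, 1]
  out[inb] <- round(av[lin])
  brain_volume(target, array(out, target$shape),
               mask = array(TRUE, target$shape))
}

#' Read donor expression samples from CSV
#'
#' Long format: columns `donor_id, coverage, gene, x, y, z, value`;
#' coordinates in Talairach mm.  One file may carry several genes.
#'
#' @param path CSV file path (or character lines).
#' @return named list (by gene) of lists of [donor_samples()].
#' @export
read_expression_samples <- function(path) {
  df <- if (length(path) == 1L && file.exists(path)) {
    utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    utils::read.csv(text = paste(path, collapse = "\n"),
                    stringsAsFactors = FALSE)
  }
  need <- c("donor_id", "coverage", "gene", "x", "y", "z", "value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("expression CSV is missing columns: ", paste(miss, collapse = ", "))
  lapply(split(df, df$gene), function(g) {
    lapply(split(g, g$donor_id), function(d) {
      donor_samples(d$donor_id[1], d$coverage[1],
                    as.matrix(d[, c("x", "y", "z")]), d$value)
    })
  })
}
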