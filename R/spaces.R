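#' @name icbm2tal
#' @title MNI (ICBM) to Talairach affine conversion
#'
#' @description Stereotaxic conversion between MNI/ICBM-152 space and
#' Talairach space using the pooled-fit icbm2tal affine of Lancaster et
#' al. (2007, Human Brain Mapping 28:1194-1205).  Foci reported in MNI
#' space are converted before entering the ALE analysis, which operates
#' entirely in Talairach space.
NULL

# Lancaster et al. (2007) pooled icbm2tal fit (average of the SPM and FSL
# fits); row-major.  Overridable via the `matrix` argument of mni_to_tal().
.icbm2tal_pooled <- matrix(c(
  0.9357,  0.0029, -0.0072, -1.0423,
 -0.0065,  0.9396, -0.0726, -1.3940,
  0.0103,  0.0752,  0.8967,  3.6475,
  0,       0,       0,       1
), nrow = 4, byrow = TRUE)

#' The icbm2tal affine matrix
#' @return the 4x4 pooled-fit Lancaster matrix.
#' @export
icbm2tal_matrix <- function() .icbm2tal_pooled

#' Construct a focus (peak coordinate)
#'
#' @param x,y,z coordinates in mm.
#' @param space `"TAL"` or `"MNI"`.
#' @return an object of class `focus`.
#' @export
focus <- function(x, y, z, space = c("TAL", "MNI")) {
  space <- match.arg(space)
  stopifnot(is.finite(x), is.finite(y), is.finite(z))
  structure(list(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
                 space = space), class = "focus")
}

#' Convert an MNI-space focus to Talairach space
#'
#' Applies the icbm2tal affine.  Calling this on a focus already in
#' Talairach space is a contract violation, not a no-op: silently accepting
#' TAL input would mask double conversion.
#'
#' @param p a [focus()] with `space = "MNI"`, or an n x 3 matrix of MNI mm
#'   coordinates.
#' @param matrix 4x4 conversion affine; defaults to the pooled Lancaster fit.
#' @return a focus in TAL space (or an n x 3 matrix of TAL coordinates).
#' @export
mni_to_tal <- function(p, matrix = icbm2tal_matrix()) {
  if (inherits(p, "focus")) {
    if (p$space != "MNI")
      stop("mni_to_tal: input focus is not in MNI space")
    out <- drop(matrix %*% c(p$x, p$y, p$z, 1))
    return(focus(out[1], out[2], out[3], space = "TAL"))
  }
  p <- base::matrix(as.numeric(p), ncol = 3)
  out <- cbind(p, 1) %*% t(matrix)
  out[, 1:3, drop = FALSE]
}

#' Inverse conversion (Talairach back to MNI)
#' @inheritParams mni_to_tal
#' @export
tal_to_mni <- function(p, matrix = icbm2tal_matrix()) {
  inv <- solve(matrix)
  if (inherits(p, "focus")) {
    if (p$space != "TAL") stop("tal_to_mni: input focus is not in TAL space")
    out <- drop(inv %*% c(p$x, p$y, p$z, 1))
    return(focus(out[1], out[2], out[3], space = "MNI"))
  }
  p <- base::matrix(as.numeric(p), ncol = 3)
  out <- cbind(p, 1) %*% t(inv)
  out[, 1:3, drop = FALSE]
}

#' Construct an experiment (one VBM contrast)
#'
#' @param id unique experiment identifier.
#' @param direction `"decrease"` (patients < controls) or `"increase"`.
#' @param n_subjects sample size of the contrast.
#' @param foci n x 3 matrix of peak coordinates (mm).
#' @param space stereotaxic space of the foci, `"TAL"` or `"MNI"`.
#' @return an object of class `experiment`.
#' @export
experiment <- function(id, direction = c("decrease", "increase"),
                       n_subjects, foci, space = c("TAL", "MNI")) {
  direction <- match.arg(direction)
  space <- match.arg(space)
  foci <- matrix(as.numeric(foci), ncol = 3)
  stopifnot(nrow(foci) >= 1L, all(is.finite(foci)))
  n_subjects <- as.integer(n_subjects)
  stopifnot(length(n_subjects) == 1L, n_subjects >= 1L)
  structure(list(id = as.character(id), direction = direction,
                 n_subjects = n_subjects, foci = foci, space = space),
            class = "experiment")
}

#' Construct a foci dataset
#'
#' @param experiments list of [experiment()] objects, unique ids.
#' @param label free-text dataset label.
#' @export
foci_dataset <- function(experiments, label = "") {
  stopifnot(length(experiments) >= 1L)
  ids <- vapply(experiments, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate experiment ids in dataset")
  structure(list(experiments = experiments, label = as.character(label)),
            class = "foci_dataset")
}

#' @export
print.foci_dataset <- function(x, ...) {
  nf <- sum(vapply(x$experiments, function(e) nrow(e$foci), 0L))
  cat(sprintf("<foci_dataset '%s': %d experiments, %d foci>\n",
              x$label, length(x$experiments), nf))
  invisible(x)
}

#' Convert every experiment of a dataset to Talairach space
#'
#' MNI experiments go through [mni_to_tal()]; TAL experiments pass through.
#'
#' @param dataset a [foci_dataset()].
#' @param matrix conversion affine.
#' @return a dataset with all experiments in TAL space.
#' @export
dataset_to_tal <- function(dataset, matrix = icbm2tal_matrix()) {
  dataset$experiments <- lapply(dataset$experiments, function(e) {
    if (e$space == "MNI") {
      e$foci <- mni_to_tal(e$foci, matrix)
      e$space <- "TAL"
    }
    e
  })
  dataset
}

# Screening rules applied to parsed experiments.  The minimum sample size
# mirrors the VBM inclusion criterion (contrasts on fewer than 10
# participants are excluded); ROI-based contrasts are an editorial
# exclusion upstream of this package.
MIN_SUBJECTS <- 10L

#' Validate experiments against the inclusion rules
#'
#' Experiments violating a rule are removed and reported, not silently
#' dropped; the analysis continues with the valid subset.
#'
#' @param experiments list of [experiment()] objects (or raw parsed lists).
#' @param min_subjects minimum participants per experiment (default 10).
#' @return list with `experiments` (the retained list) and `exclusions`
#'   (data.frame with columns experiment_id, rule, detail).
#' @export
screen_experiments <- function(experiments, min_subjects = MIN_SUBJECTS) {
  excl <- list()
  keep <- logical(length(experiments))
  for (i in seq_along(experiments)) {
    e <- experiments[[i]]
    if (is.null(e$foci) || nrow(e$foci) == 0L) {
      excl[[length(excl) + 1L]] <- data.frame(
        experiment_id = e$id, rule = "no foci",
        detail = "experiment reports zero coordinates")
    } else if (e$n_subjects < min_subjects) {
      excl[[length(excl) + 1L]] <- data.frame(
        experiment_id = e$id, rule = "min subjects",
        detail = sprintf("n_subjects=%d < %d", e$n_subjects, min_subjects))
    } else {
      keep[i] <- TRUE
    }
  }
  exclusions <- if (length(excl)) do.call(rbind, excl) else
    data.frame(experiment_id = character(), rule = character(),
               detail = character())
  list(experiments = experiments[keep], exclusions = exclusions)
}
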