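#' Volume grid geometry
#'
#' A `volume_grid` records the 3-D voxel lattice shared by all volumes in an
#' analysis: the array shape, the 4x4 voxel-to-world affine (mm) and the voxel
#' size. Every mask, activation map and statistic map in a study must live on
#' one common grid; no implicit resampling is ever performed.
#'
#' Voxel order is frozen as ascending linear index in R's native column-major
#' array layout (first axis fastest). Voxel indices are 1-based; world
#' coordinates are obtained through the affine.
#'
#' @param shape integer vector of length 3, voxels per axis (all >= 1).
#' @param voxel_size numeric vector of length 3, mm per axis. Ignored if
#'   `affine` is given.
#' @param affine optional 4x4 voxel-to-world matrix; defaults to a diagonal
#'   scaling by `voxel_size` centred on the volume.
#' @return an object of class `volume_grid`.
#' @export
volume_grid <- function(shape, voxel_size = c(2, 2, 2), affine = NULL) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L))
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
    affine[1:3, 4] <- -voxel_size * (shape - 1) / 2
  }
  affine <- as.matrix(affine)
  stopifnot(identical(dim(affine), c(4L, 4L)))
  if (abs(det(affine)) < .Machine$double.eps)
    stop("grid affine must be invertible")
  structure(
    list(shape = shape, affine = affine,
         voxel_size = sqrt(colSums(affine[1:3, 1:3]^2))),
    class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat("volume_grid:", paste(x$shape, collapse = " x "),
      "voxels,", paste(signif(x$voxel_size, 4), collapse = " x "), "mm\n")
  invisible(x)
}

grids_match <- function(a, b, tol = 1e-4) {
  identical(a$shape, b$shape) && max(abs(a$affine - b$affine)) <= tol
}

#' Read a NIfTI volume
#'
#' Thin wrapper around [RNifti::readNifti()] that validates dimensionality and
#' returns the data together with its grid geometry.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return list with elements `data` (3-D or 4-D array), `grid`
#'   ([volume_grid]) and `n_frames` (1 for 3-D volumes).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("malformed NIfTI file '", path,
                                           "': ", conditionMessage(e)))
  d <- dim(img)
  if (!length(d) %in% c(3L, 4L))
    stop("expected a 3-D or 4-D volume, got ", length(d), " dimensions")
  aff <- matrix(as.numeric(RNifti::xform(img)), 4, 4)
  grid <- volume_grid(d[1:3], affine = aff)
  list(data = array(as.numeric(img), dim = d), grid = grid,
       n_frames = if (length(d) == 4L) d[4] else 1L)
}

#' Write a NIfTI volume
#'
#' @param data 3-D or 4-D numeric array whose first three dimensions match
#'   `grid$shape`.
#' @param grid a [volume_grid].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(data, grid, path) {
  stopifnot(inherits(grid, "volume_grid"))
  d <- dim(data)
  if (!length(d) %in% c(3L, 4L) || !identical(as.integer(d[1:3]), grid$shape))
    stop("data dimensions do not match the grid")
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- grid$voxel_size
  img <- RNifti::`qform<-`(img, structure(grid$affine, code = 2L))
  img <- RNifti::`sform<-`(img, structure(grid$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Brain mask on a common grid
#'
#' Converts a binary volume into the canonical mask object used to vectorize
#' activation maps. The in-mask voxels are stored as strictly increasing
#' 1-based linear indices into the column-major array, which freezes the
#' feature order of every vectorized map: `vectorize()` is a bijection between
#' in-mask volumes and length-`n_voxels` vectors.
#'
#' @param mask_volume 3-D array (or logical array) of zeros/non-zeros, or a
#'   path to a NIfTI mask.
#' @param grid the [volume_grid] of the mask; derived from the file when
#'   `mask_volume` is a path.
#' @return an object of class `brain_mask` with fields `grid`, `indices`,
#'   `n_voxels`.
#' @export
brain_mask <- function(mask_volume, grid = NULL) {
  if (is.character(mask_volume)) {
    v <- read_volume(mask_volume)
    if (length(dim(v$data)) != 3L) stop("mask must be 3-D")
    grid <- v$grid
    mask_volume <- v$data
  }
  stopifnot(inherits(grid, "volume_grid"),
            identical(as.integer(dim(mask_volume)), grid$shape))
  idx <- which(mask_volume != 0)
  if (length(idx) == 0L) stop("mask is empty")
  structure(list(grid = grid, indices = idx, n_voxels = length(idx)),
            class = "brain_mask")
}

#' @export
print.brain_mask <- function(x, ...) {
  cat("brain_mask:", x$n_voxels, "voxels on a",
      paste(x$grid$shape, collapse = " x "), "grid\n")
  invisible(x)
}

#' Restrict a mask to a subset of its voxels
#'
#' Utility for ROI analyses: builds a new `brain_mask` from a logical or
#' integer subset of an existing mask's voxels (in mask order).
#'
#' @param mask a [brain_mask].
#' @param keep logical vector of length `n_voxels`, or integer positions into
#'   the mask's voxel order.
#' @export
mask_subset <- function(mask, keep) {
  stopifnot(inherits(mask, "brain_mask"))
  if (is.logical(keep)) {
    stopifnot(length(keep) == mask$n_voxels)
    keep <- which(keep)
  }
  structure(list(grid = mask$grid, indices = mask$indices[sort(keep)],
                 n_voxels = length(keep)),
            class = "brain_mask")
}

#' Vectorize a volume over a mask
#'
#' Extracts the in-mask voxels of a volume in the mask's frozen voxel order.
#' The grid of the volume must match the mask grid exactly (affine agreement
#' to 1e-4 mm); mismatches raise an error rather than silently resampling.
#'
#' @param volume 3-D array, or the list returned by [read_volume()].
#' @param mask a [brain_mask].
#' @param grid [volume_grid] of `volume` when it is a bare array; defaults to
#'   the mask grid (shapes are still checked).
#' @return numeric vector of length `mask$n_voxels`.
#' @export
vectorize <- function(volume, mask, grid = NULL) {
  stopifnot(inherits(mask, "brain_mask"))
  if (is.list(volume) && !is.null(volume$grid)) {
    grid <- volume$grid
    volume <- volume$data
  }
  if (!is.null(grid) && !grids_match(grid, mask$grid))
    stop("volume grid does not match mask grid; resample upstream ",
         "(no implicit resampling)")
  if (!identical(as.integer(dim(volume)), mask$grid$shape))
    stop("volume shape does not match mask grid")
  v <- as.numeric(volume[mask$indices])
  if (any(!is.finite(v)))
    stop("non-finite values inside the mask")
  v
}

#' Restore a vector to a 3-D volume
#'
#' Inverse of [vectorize()]: in-mask voxels take the vector's values, all
#' other voxels the fill value (0 by default, matching the zero background of
#' displayed statistic maps).
#'
#' @param values numeric vector of length `mask$n_voxels`.
#' @param mask a [brain_mask].
#' @param fill value for out-of-mask voxels.
#' @export
unvectorize <- function(values, mask, fill = 0) {
  stopifnot(inherits(mask, "brain_mask"), length(values) == mask$n_voxels)
  out <- array(fill, dim = mask$grid$shape)
  out[mask$indices] <- values
  out
}

#' Masked activation map
#'
#' A vectorized beta (activation) map with provenance metadata: one
#' participant x unit (rating level, single trial, condition or contrast).
#'
#' @param values numeric vector of length `mask$n_voxels`; must be finite.
#' @param mask a [brain_mask].
#' @param participant participant identifier.
#' @param unit one of `"rating-level"`, `"trial"`, `"condition"`,
#'   `"contrast"`.
#' @param rating rating label 1-5 or `NA`.
#' @param condition condition label or `NA`.
#' @param study study identifier.
#' @export
activation_map <- function(values, mask, participant = NA, unit = "trial",
                           rating = NA, condition = NA, study = NA) {
  stopifnot(inherits(mask, "brain_mask"))
  values <- as.numeric(values)
  if (length(values) != mask$n_voxels)
    stop("values length (", length(values), ") != mask n_voxels (",
         mask$n_voxels, ")")
  if (any(!is.finite(values))) stop("activation map contains non-finite values")
  unit <- match.arg(unit, c("rating-level", "trial", "condition", "contrast"))
  if (!is.na(rating) && !(rating %in% 1:5)) stop("rating must be in 1..5")
  structure(list(values = values, mask = mask,
                 meta = list(participant = participant, unit = unit,
                             rating = rating, condition = condition,
                             study = study)),
            class = "activation_map")
}

#' @export
print.activation_map <- function(x, ...) {
  cat("activation_map:", x$mask$n_voxels, "voxels; participant",
      as.character(x$meta$participant), "| unit", x$meta$unit,
      if (!is.na(x$meta$rating)) paste("| rating", x$meta$rating) else "",
      "\n")
  invisible(x)
}

# Stack a list of activation_map (or bare vectors) into a maps x voxels matrix
maps_matrix <- function(maps, mask = NULL) {
  if (is.matrix(maps)) return(maps)
  rows <- lapply(maps, function(m) {
    if (inherits(m, "activation_map")) {
      if (!is.null(mask) && !grids_match(m$mask$grid, mask$grid))
        stop("activation maps on different grids")
      m$values
    } else as.numeric(m)
  })
  n <- unique(vapply(rows, length, 1L))
  if (length(n) != 1L) stop("maps have different lengths")
  do.call(rbind, rows)
}

#' Read a trial/events table
#'
#' Reads a tab-separated events file describing the anticipation trials of a
#' threat-anticipation run: onset and duration in seconds (0-based from run
#' start), condition, 1-5 subjective rating, whether the trial was followed by
#' a shock, and the run index. An optional `trial_type` column distinguishes
#' anticipation epochs from no-interest epochs (outcome, rating, dummy or
#' missed trials); absent, every row is an anticipation trial.
#'
#' @param path TSV file with columns `onset`, `duration`, `condition`,
#'   `rating`, `shock_followed`, `run`.
#' @param conditions permitted condition vocabulary.
#' @return a `data.frame` of typed trials, ordered as in the file.
#' @export
read_events <- function(path,
                        conditions = c("safety", "low", "medium", "high")) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  required <- c("onset", "duration", "condition", "rating",
                "shock_followed", "run")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("events file lacks required column(s): ",
         paste(missing, collapse = ", "))
  tab$onset <- as.numeric(tab$onset)
  tab$duration <- as.numeric(tab$duration)
  tab$rating <- suppressWarnings(as.integer(tab$rating))
  tab$shock_followed <- as.logical(tab$shock_followed)
  tab$run <- as.integer(tab$run)
  if (is.null(tab$trial_type)) tab$trial_type <- "anticipation"
  if (any(tab$onset < 0, na.rm = TRUE)) stop("negative onsets")
  for (r in unique(tab$run)) {
    o <- tab$onset[tab$run == r]
    if (is.unsorted(o)) stop("onsets not nondecreasing within run ", r)
  }
  bad <- !is.na(tab$rating) & !(tab$rating %in% 1:5)
  if (any(bad))
    stop("rating outside 1..5 in row(s) ",
         paste(which(bad), collapse = ", "))
  unknown <- setdiff(unique(tab$condition), c(conditions, NA))
  if (length(unknown))
    stop("unknown condition label(s): ", paste(unknown, collapse = ", "))
  tab
}

#' Write a trial/events table
#'
#' @param events data.frame as returned by [read_events()].
#' @param path output TSV path.
#' @export
write_events <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
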