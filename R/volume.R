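#' 3D scalar volume with world geometry
#'
#' The basic image container: a 3D array of voxel values plus the geometry
#' (voxel spacing in mm, world origin in mm, and a 3x3 orthonormal direction
#' matrix) that places voxel indices in continuous world coordinates. Voxel
#' indices are 0-based throughout the package; the world coordinate of voxel
#' index \eqn{i} is \eqn{origin + orientation \cdot (spacing \circ i)}.
#'
#' @param values numeric 3D array of voxel values.
#' @param spacing numeric length-3, voxel size in mm per axis (all > 0).
#' @param origin numeric length-3, world position (mm) of voxel (0,0,0).
#' @param orientation 3x3 orthonormal direction matrix (columns are the world
#'   directions of the voxel axes). Default identity (axis-aligned).
#' @param modality one of `"CT_HU"`, `"PET_SUV"`, `"MASK"`, `"LABEL"`,
#'   `"FEATURE"`. `MASK` volumes must contain only 0/1; `LABEL` volumes only
#'   non-negative integers.
#' @return an object of class `scalar_volume`.
#' @export
scalar_volume <- function(values, spacing, origin = c(0, 0, 0),
                          orientation = diag(3),
                          modality = c("FEATURE", "CT_HU", "PET_SUV", "MASK", "LABEL")) {
  modality <- match.arg(modality)
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive voxel sizes in mm", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be a finite length-3 vector", call. = FALSE)
  orientation <- as.matrix(orientation)
  if (!all(dim(orientation) == c(3L, 3L)) ||
      max(abs(crossprod(orientation) - diag(3))) > 1e-6)
    stop("`orientation` must be a 3x3 orthonormal matrix", call. = FALSE)
  if (modality == "MASK" && !all(values %in% c(0, 1)))
    stop("MASK volumes may contain only {0, 1}", call. = FALSE)
  if (modality == "LABEL" &&
      (any(values < 0) || max(abs(values - round(values))) > 0))
    stop("LABEL volumes may contain only non-negative integers", call. = FALSE)
  structure(
    list(values = values, spacing = spacing, origin = origin,
         orientation = orientation, modality = modality),
    class = "scalar_volume"
  )
}

#' @export
print.scalar_volume <- function(x, ...) {
  cat(sprintf("<scalar_volume %s> %s voxels @ %s mm, origin (%s)\n",
              x$modality, paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ", ")))
  cat(sprintf("  value range [%g, %g]\n",
              suppressWarnings(min(x$values, na.rm = TRUE)),
              suppressWarnings(max(x$values, na.rm = TRUE))))
  invisible(x)
}

#' @export
dim.scalar_volume <- function(x) dim(x$values)

#' Voxel volume in mm^3
#' @param vol a `scalar_volume`.
#' @return scalar, product of the three spacings (mm^3).
#' @export
voxel_volume_mm3 <- function(vol) prod(vol$spacing)

#' World coordinates of voxel indices
#'
#' Maps 0-based voxel indices to world mm via
#' `origin + orientation %*% (spacing * index)`.
#'
#' @param vol a `scalar_volume`.
#' @param index integer triple, or an n x 3 matrix of 0-based indices.
#' @param check if `TRUE` (default for single triples), indices must lie
#'   inside the volume bounds.
#' @return numeric length-3 (single index) or n x 3 matrix of mm coordinates.
#' @export
world_coordinates <- function(vol, index, check = !is.matrix(index)) {
  single <- !is.matrix(index)
  idx <- if (single) matrix(as.numeric(index), nrow = 1) else index
  if (ncol(idx) != 3L) stop("`index` must have 3 columns", call. = FALSE)
  if (check) {
    d <- dim(vol$values)
    bad <- idx[, 1] < 0 | idx[, 2] < 0 | idx[, 3] < 0 |
      idx[, 1] > d[1] - 1 | idx[, 2] > d[2] - 1 | idx[, 3] > d[3] - 1
    if (any(bad)) stop("voxel index out of bounds", call. = FALSE)
  }
  w <- sweep(idx, 2, vol$spacing, `*`) %*% t(vol$orientation)
  w <- sweep(w, 2, vol$origin, `+`)
  if (single) as.numeric(w) else w
}

#' Continuous voxel indices of world points
#'
#' Inverse of [world_coordinates()]: maps world mm points to continuous
#' 0-based voxel indices of `vol` (not rounded, not bounds-checked).
#'
#' @param vol a `scalar_volume`.
#' @param world n x 3 matrix (or length-3 vector) of world mm points.
#' @return n x 3 matrix of continuous indices.
#' @export
index_coordinates <- function(vol, world) {
  if (!is.matrix(world)) world <- matrix(as.numeric(world), nrow = 1)
  w <- sweep(world, 2, vol$origin, `-`) %*% vol$orientation
  sweep(w, 2, vol$spacing, `/`)
}

# 0-based index grid of a volume as an n x 3 matrix (x fastest), matching
# R's linear array order.
grid_indices <- function(dm) {
  cbind(
    rep.int(seq_len(dm[1]) - 1L, times = dm[2] * dm[3]),
    rep.int(rep(seq_len(dm[2]) - 1L, each = dm[1]), times = dm[3]),
    rep(seq_len(dm[3]) - 1L, each = dm[1] * dm[2])
  )
}

# World coordinates of every voxel of `vol`, linear order.
grid_world <- function(vol) {
  world_coordinates(vol, grid_indices(dim(vol$values)), check = FALSE)
}

same_grid <- function(a, b, tol = 1e-6) {
  all(dim(a$values) == dim(b$values)) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol &&
    max(abs(a$orientation - b$orientation)) < tol
}

# Clone geometry with new values (and optionally new modality).
with_values <- function(vol, values, modality = vol$modality) {
  scalar_volume(array(values, dim(vol$values)), vol$spacing, vol$origin,
                vol$orientation, modality)
}
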