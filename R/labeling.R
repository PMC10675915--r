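#' Label lesions in a binary mask
#'
#' Connected-component labeling of the lesion mask with a 3D structuring
#' element of connectivity 2 by default: face- and edge-adjacent voxels (the
#' 18-neighborhood) connect, corner-only contact does not. Labels are
#' assigned in raster-scan order (first voxel encountered, x fastest) and
#' run 1..n_lesions.
#'
#' @param mask a `scalar_volume` whose values are all 0/1.
#' @param connectivity 1 (6-neighborhood), 2 (18, default) or 3 (26).
#' @return a `lesion_label_map`: list with `labels` (a `scalar_volume` of
#'   modality `LABEL`) and `n_lesions`.
#' @export
label_lesions <- function(mask, connectivity = 2L) {
  if (!inherits(mask, "scalar_volume") || !all(mask$values %in% c(0, 1)))
    stop("`mask` must be a binary scalar_volume", call. = FALSE)
  if (!connectivity %in% 1:3)
    stop("`connectivity` must be 1, 2 or 3", call. = FALSE)
  dm <- dim(mask$values)
  lab <- cpp_label_components(as.integer(mask$values), dm, as.integer(connectivity))
  n <- max(lab)
  structure(list(labels = with_values(mask, array(as.numeric(lab), dm), "LABEL"),
                 n_lesions = as.integer(n)),
            class = "lesion_label_map")
}

#' @export
print.lesion_label_map <- function(x, ...) {
  cat(sprintf("<lesion_label_map> %d lesion(s) on a %s grid\n", x$n_lesions,
              paste(dim(x$labels$values), collapse = "x")))
  invisible(x)
}

# label ids actually present (transferred maps may have dropped some)
labels_present <- function(labelmap) {
  u <- sort(unique(as.integer(labelmap$labels$values)))
  u[u > 0]
}

#' Lesion volume in ml
#'
#' Voxel count of the label times the voxel volume (product of spacings,
#' mm^3), divided by 1000.
#'
#' @param labelmap a `lesion_label_map`.
#' @param label integer label id (1-based).
#' @return volume in ml.
#' @export
lesion_volume_ml <- function(labelmap, label) {
  n <- sum(labelmap$labels$values == label)
  if (n == 0) stop("label ", label, " not present in the label map", call. = FALSE)
  n * voxel_volume_mm3(labelmap$labels) / 1000
}

#' Dilate a binary mask
#'
#' @param mask a `scalar_volume` of modality `MASK`.
#' @param voxels number of dilation iterations (default 1).
#' @param connectivity structuring-element connectivity (default 3, the full
#'   26-neighborhood).
#' @return the dilated `scalar_volume` mask.
#' @export
dilate_mask <- function(mask, voxels = 1L, connectivity = 3L) {
  dm <- dim(mask$values)
  out <- cpp_binary_dilate(as.integer(mask$values), dm,
                           as.integer(connectivity), as.integer(voxels))
  with_values(mask, array(as.numeric(out), dm), "MASK")
}

#' Scale per-subject total lesion counts to the 0-1 range
#'
#' Divides each subject's total lesion count by the maximum count within the
#' (single-sex) subset, so that at least one subject maps to 1. Applied
#' per sex subset to improve comparability of the subject-level feature maps
#' between subsets.
#'
#' @param counts named numeric vector of per-subject lesion counts for one
#'   sex subset.
#' @return named numeric vector in [0, 1].
#' @export
total_lesion_count_scaled <- function(counts) {
  if (length(counts) == 0) stop("empty subset", call. = FALSE)
  m <- max(counts)
  if (m <= 0) stop("degenerate subset: all lesion counts are zero", call. = FALSE)
  counts / m
}
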