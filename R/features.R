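#' Build subject-space lesion feature maps
#'
#' Constructs the three exemplified feature maps on the subject grid:
#' \describe{
#'   \item{voxel_level}{PET SUV at lesion voxels, 0 elsewhere (metabolic
#'     activity).}
#'   \item{lesion_level}{each lesion's metabolic volume in ml painted as a
#'     constant over its own support.}
#'   \item{subject_level}{one subject-level scalar (e.g. the scaled total
#'     lesion count) painted over all lesion voxels.}
#' }
#' All maps are zero exactly where the lesion support is zero. Lesion-level
#' values are measured in subject space and carried as constants through any
#' later transfer.
#'
#' @param subject a `subject_record` (needs `pet` and its grid).
#' @param labelmap a `lesion_label_map` on the subject grid.
#' @param subject_scalar the subject-level feature value (default `NA`, to
#'   be filled once the subset maximum is known; see
#'   [total_lesion_count_scaled()]).
#' @return a `subject_feature_maps` list: `voxel_level`, `lesion_level`,
#'   `subject_level`, `support` (all `scalar_volume`s).
#' @export
build_feature_maps <- function(subject, labelmap, subject_scalar = NA_real_) {
  if (!same_grid(subject$pet, labelmap$labels))
    stop("label map and PET are not on the same grid", call. = FALSE)
  lab <- labelmap$labels$values
  support <- lab > 0
  dm <- dim(lab)
  voxel <- array(0, dm)
  voxel[support] <- subject$pet$values[support]
  lesion <- array(0, dm)
  for (l in labels_present(labelmap))
    lesion[lab == l] <- lesion_volume_ml(labelmap, l)
  subj <- array(0, dm)
  subj[support] <- subject_scalar
  structure(list(
    voxel_level = with_values(labelmap$labels, voxel, "FEATURE"),
    lesion_level = with_values(labelmap$labels, lesion, "FEATURE"),
    subject_level = with_values(labelmap$labels, subj, "FEATURE"),
    support = with_values(labelmap$labels, array(as.numeric(support), dm), "MASK")),
    class = "subject_feature_maps")
}

#' Transfer lesion feature maps to template space
#'
#' Transfers each lesion's binary support to the template grid individually
#' with nearest-neighbor resampling, then overlays the per-lesion results.
#' Per-lesion transfer preserves lesion identity even when two lesions touch
#' after warping; a template voxel claimed by two lesions of the same
#' subject is assigned to the lesion whose transformed center of mass is
#' nearer. Feature values are carried with nearest-neighbor sampling so
#' lesion-level constants stay piecewise-constant. Lesions that map entirely
#' outside the template field of view are dropped and reported.
#'
#' @param maps a `subject_feature_maps` on the subject grid.
#' @param labelmap the subject-space `lesion_label_map`.
#' @param transform a `spatial_transform` whose forward direction maps
#'   template world coordinates to subject world coordinates.
#' @param template_grid a `scalar_volume` defining the template geometry.
#' @return a list: `maps` (`subject_feature_maps` on the template grid),
#'   `labelmap` (template-space `lesion_label_map` keeping the original
#'   label ids), `exclusions` (data.frame label/reason for dropped lesions).
#' @export
transfer_to_template <- function(maps, labelmap, transform, template_grid) {
  if (!inherits(transform, "spatial_transform"))
    stop("missing transform", call. = FALSE)
  dm_t <- dim(template_grid$values)
  dm_s <- dim(labelmap$labels$values)
  lab_s <- labelmap$labels$values
  n_t <- prod(dm_t)

  out_lab <- numeric(n_t)
  out_voxel <- numeric(n_t)
  out_lesion <- numeric(n_t)
  out_subject <- numeric(n_t)
  owner_dist <- rep(Inf, n_t)
  exclusions <- list()

  labels <- labels_present(labelmap)
  tw_all <- NULL # lazily computed full template world grid

  for (l in labels) {
    sel <- which(lab_s == l)
    # subject-space voxel world coords of this lesion
    sub_idx <- cbind((sel - 1) %% dm_s[1],
                     ((sel - 1) %/% dm_s[1]) %% dm_s[2],
                     (sel - 1) %/% (dm_s[1] * dm_s[2]))
    sw <- world_coordinates(labelmap$labels, sub_idx, check = FALSE)
    # bounding box in template space via the inverse mapping
    tw_lesion <- transform_points(transform, sw, "inverse")
    com_t <- colMeans(tw_lesion)
    ti <- index_coordinates(template_grid, tw_lesion)
    lo <- pmax(floor(apply(ti, 2, min)) - 2, 0)
    hi <- pmin(ceiling(apply(ti, 2, max)) + 2, dm_t - 1)
    if (any(hi < lo)) {
      exclusions[[length(exclusions) + 1]] <-
        data.frame(label = l, reason = "outside_template_fov")
      next
    }
    ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
    box_idx <- as.matrix(expand.grid(ix, iy, iz))
    colnames(box_idx) <- NULL
    tw <- world_coordinates(template_grid, box_idx, check = FALSE)
    sw_box <- transform_points(transform, tw, "forward")
    si <- index_coordinates(labelmap$labels, sw_box)
    hit <- cpp_sample_volume(as.numeric(lab_s == l), dm_s, si, 1L, 0) > 0.5
    if (!any(hit)) {
      exclusions[[length(exclusions) + 1]] <-
        data.frame(label = l, reason = "outside_template_fov")
      next
    }
    lin_t <- 1 + box_idx[hit, 1] + dm_t[1] * (box_idx[hit, 2] +
                                                dm_t[2] * box_idx[hit, 3])
    d2 <- rowSums(sweep(tw[hit, , drop = FALSE], 2, com_t, `-`)^2)
    vox <- cpp_sample_volume(as.numeric(maps$voxel_level$values), dm_s,
                             si[hit, , drop = FALSE], 1L, 0)
    lesv <- lesion_volume_ml(labelmap, l)
    subjv <- {
      v <- maps$subject_level$values[lab_s == l]
      v[1]
    }
    win <- d2 < owner_dist[lin_t]
    lt <- lin_t[win]
    out_lab[lt] <- l
    out_voxel[lt] <- vox[win]
    out_lesion[lt] <- lesv
    out_subject[lt] <- subjv
    owner_dist[lt] <- d2[win]
  }

  lab_vol <- with_values(template_grid, array(out_lab, dm_t), "LABEL")
  tmpl_labelmap <- structure(list(labels = lab_vol,
                                  n_lesions = labelmap$n_lesions),
                             class = "lesion_label_map")
  support <- array(as.numeric(out_lab > 0), dm_t)
  tmpl_maps <- structure(list(
    voxel_level = with_values(template_grid, array(out_voxel, dm_t), "FEATURE"),
    lesion_level = with_values(template_grid, array(out_lesion, dm_t), "FEATURE"),
    subject_level = with_values(template_grid, array(out_subject, dm_t), "FEATURE"),
    support = with_values(template_grid, support, "MASK")),
    class = "subject_feature_maps")
  excl <- if (length(exclusions)) do.call(rbind, exclusions) else
    data.frame(label = integer(0), reason = character(0))
  list(maps = tmpl_maps, labelmap = tmpl_labelmap, exclusions = excl)
}
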