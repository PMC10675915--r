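#' Body mask from CT
#'
#' Labels the air (voxels at or below `threshold_hu`) and removes every air
#' component that touches the volume border; the body is the complement, so
#' enclosed air spaces such as the lungs stay inside the mask. Of the
#' resulting tissue components, the largest is kept. Robust on phantoms;
#' for real data a curated body mask can be supplied to the downstream
#' functions instead.
#'
#' @param ct a `scalar_volume` of modality `CT_HU`.
#' @param threshold_hu voxels at or below this HU are air candidates
#'   (default -500, between air and soft tissue).
#' @param connectivity labeling connectivity (1 = faces, 2 = faces+edges,
#'   3 = full); default 1.
#' @return a `scalar_volume` of modality `MASK`.
#' @export
body_mask_from_ct <- function(ct, threshold_hu = -500, connectivity = 1L) {
  dm <- dim(ct$values)
  air <- as.integer(ct$values <= threshold_hu)
  alab <- cpp_label_components(air, dm, connectivity)
  alab <- array(alab, dm)
  border <- unique(c(alab[c(1, dm[1]), , ], alab[, c(1, dm[2]), ],
                     alab[, , c(1, dm[3])]))
  border <- border[border > 0]
  body <- !(alab %in% border) # tissue plus enclosed air
  blab <- cpp_label_components(as.integer(body), dm, connectivity)
  if (all(blab == 0L)) return(with_values(ct, array(0, dm), "MASK"))
  keep <- which.max(tabulate(blab))
  with_values(ct, array(as.numeric(blab == keep), dm), "MASK")
}

#' Torso mask from a body mask and axial landmarks
#'
#' Restricts the body mask to an inferior-superior slab. The torso, rather
#' than the whole image, is used for body-fat measurement because
#' field-of-view differences between studies otherwise bias the comparison.
#'
#' @param ct a `scalar_volume` (geometry reference; values unused).
#' @param body_mask a `scalar_volume` of modality `MASK` on the same grid.
#' @param landmarks inclusive pair of 0-based axial (third-axis) indices,
#'   `c(inferior, superior)` with `inferior <= superior` (pelvic floor up to
#'   shoulder level).
#' @return a `scalar_volume` of modality `MASK`.
#' @export
torso_mask <- function(ct, body_mask, landmarks) {
  if (!same_grid(ct, body_mask))
    stop("`ct` and `body_mask` must share one grid", call. = FALSE)
  dm <- dim(body_mask$values)
  lm <- as.integer(landmarks)
  if (length(lm) != 2L || any(is.na(lm)) || lm[1] > lm[2] ||
      lm[1] < 0L || lm[2] > dm[3] - 1L)
    stop("invalid landmarks: need 0-based axial indices c(inferior, superior) ",
         "inside the volume with inferior <= superior", call. = FALSE)
  out <- array(0, dm)
  rng <- (lm[1] + 1L):(lm[2] + 1L)
  out[, , rng] <- body_mask$values[, , rng]
  if (sum(out) == 0)
    stop("torso slab contains no body voxels", call. = FALSE)
  with_values(body_mask, out, "MASK")
}

#' Image body-fat percentage
#'
#' Percentage of torso voxels whose CT value falls in the adipose HU window
#' (both endpoints inclusive).
#'
#' @param ct a `scalar_volume` of modality `CT_HU`.
#' @param torso a `scalar_volume` of modality `MASK` on the same grid.
#' @param hu_window ordered HU pair; default c(-190, -30), the conventional
#'   adipose band.
#' @return percentage in [0, 100].
#' @export
body_fat_percentage <- function(ct, torso, hu_window = c(-190, -30)) {
  if (!same_grid(ct, torso))
    stop("`ct` and `torso` must share one grid", call. = FALSE)
  if (length(hu_window) != 2L || hu_window[1] > hu_window[2])
    stop("`hu_window` must be an ordered pair", call. = FALSE)
  sel <- torso$values > 0
  n_torso <- sum(sel)
  if (n_torso == 0) stop("empty torso region", call. = FALSE)
  hu <- ct$values[sel]
  100 * sum(hu >= hu_window[1] & hu <= hu_window[2]) / n_torso
}

#' Fat report for one subject
#'
#' @param subject_id subject identifier.
#' @param ct CT `scalar_volume`.
#' @param body_mask optional body `scalar_volume` mask; computed from the CT
#'   if `NULL`.
#' @param landmarks axial slab indices passed to [torso_mask()].
#' @param hu_window adipose HU window.
#' @return one-row data.frame: subject_id, torso_voxel_count,
#'   adipose_voxel_count, fat_percentage.
#' @export
fat_report <- function(subject_id, ct, body_mask = NULL, landmarks,
                       hu_window = c(-190, -30)) {
  if (is.null(body_mask)) body_mask <- body_mask_from_ct(ct)
  torso <- torso_mask(ct, body_mask, landmarks)
  p <- body_fat_percentage(ct, torso, hu_window)
  n <- sum(torso$values > 0)
  data.frame(subject_id = subject_id, torso_voxel_count = n,
             adipose_voxel_count = as.integer(round(p / 100 * n)),
             fat_percentage = p, stringsAsFactors = FALSE)
}

#' Select a template subject by body-fat percentage
#'
#' Computes the median fat percentage of the reports, restricts candidates
#' to those within `tolerance_pp` percentage points of the median, and
#' returns the candidate closest to the median (ties broken by
#' lexicographically smallest subject id). An explicit `override` id skips
#' the rule, mirroring the manual screening step used on real cohorts.
#'
#' @param reports data.frame with columns `subject_id` and `fat_percentage`
#'   (one row per negative-control subject of one sex).
#' @param tolerance_pp candidate window half-width in percentage points
#'   (default 2).
#' @param override optional subject_id to select manually.
#' @return a list: `subject_id`, `median_fat_percentage`, `candidates`.
#' @export
select_template <- function(reports, tolerance_pp = 2, override = NULL) {
  if (!is.data.frame(reports) || nrow(reports) == 0)
    stop("at least one fat report is required", call. = FALSE)
  med <- median(reports$fat_percentage)
  if (!is.null(override)) {
    if (!override %in% reports$subject_id)
      stop("override subject not among the reports", call. = FALSE)
    return(list(subject_id = override, median_fat_percentage = med,
                candidates = reports$subject_id))
  }
  dev <- abs(reports$fat_percentage - med)
  cand <- reports[dev <= tolerance_pp + 1e-12, , drop = FALSE]
  if (nrow(cand) == 0)
    stop("no candidate within ", tolerance_pp,
         " percentage points of the median", call. = FALSE)
  cdev <- abs(cand$fat_percentage - med)
  best <- cand[cdev <= min(cdev) + 1e-12, , drop = FALSE]
  sel <- best$subject_id[order(best$subject_id)][1]
  list(subject_id = sel, median_fat_percentage = med,
       candidates = cand$subject_id)
}
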