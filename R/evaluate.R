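#' Center of mass of a labeled lesion
#'
#' Unweighted mean of the world coordinates of the label's voxels.
#'
#' @param labelmap a `lesion_label_map`.
#' @param label label id.
#' @return length-3 world mm coordinate.
#' @export
center_of_mass <- function(labelmap, label) {
  sel <- which(labelmap$labels$values == label)
  if (length(sel) == 0)
    stop("label ", label, " is empty", call. = FALSE)
  dm <- dim(labelmap$labels$values)
  idx <- cbind((sel - 1) %% dm[1],
               ((sel - 1) %/% dm[1]) %% dm[2],
               (sel - 1) %/% (dm[1] * dm[2]))
  colMeans(world_coordinates(labelmap$labels, idx, check = FALSE))
}

#' All pair-wise center-of-mass distances between lesions
#'
#' Euclidean distances in world mm between lesion centers of mass, reported
#' in cm, for all unordered label pairs.
#'
#' @param labelmap a `lesion_label_map`.
#' @return data.frame with columns `label_a`, `label_b`, `dist_cm`
#'   (n(n-1)/2 rows; empty for fewer than 2 lesions).
#' @export
pairwise_distances <- function(labelmap) {
  labs <- labels_present(labelmap)
  if (length(labs) < 2)
    return(data.frame(label_a = integer(0), label_b = integer(0),
                      dist_cm = numeric(0)))
  coms <- t(vapply(labs, function(l) center_of_mass(labelmap, l), numeric(3)))
  pairs <- t(utils::combn(length(labs), 2))
  d <- sqrt(rowSums((coms[pairs[, 1], , drop = FALSE] -
                       coms[pairs[, 2], , drop = FALSE])^2))
  data.frame(label_a = labs[pairs[, 1]], label_b = labs[pairs[, 2]],
             dist_cm = d / 10)
}

#' Maximum within-patient lesion distance
#'
#' The largest pair-wise center-of-mass distance between lesions of one
#' subject; a measure of lesion dissemination in space. Undefined (NA) for
#' fewer than two lesions.
#'
#' @param labelmap a `lesion_label_map`.
#' @return distance in cm, or `NA` if fewer than 2 lesions.
#' @export
max_within_patient_distance <- function(labelmap) {
  pd <- pairwise_distances(labelmap)
  if (nrow(pd) == 0) return(NA_real_)
  max(pd$dist_cm)
}

#' Total metabolic volume
#'
#' Summed volume (ml) of all metabolically active lesion voxels of a
#' subject; equals the sum of per-lesion volumes for disjoint lesions.
#'
#' @param labelmap a `lesion_label_map`.
#' @return volume in ml (0 for an empty mask).
#' @export
total_metabolic_volume <- function(labelmap) {
  sum(labelmap$labels$values > 0) * voxel_volume_mm3(labelmap$labels) / 1000
}

#' Compare lesion-mask spatial properties between subject and template space
#'
#' Quantifies how the mapping to template space perturbs the lesion masks:
#' per-lesion volumes, per-subject total metabolic volume, all pair-wise
#' lesion distances and the maximum within-patient lesion distance, each
#' measured in subject space and re-measured in template space. Lesion
#' identity across spaces is carried by the per-lesion transfer; lesions
#' dropped at the template field-of-view boundary are excluded (and pairs
#' involving them at the pair level). Pearson correlations (two-sided) are
#' reported for lesion volume, total metabolic volume and maximum distance.
#'
#' @param results list with one element per subject: a list holding
#'   `subject_id`, `labelmap_subject` (subject-space `lesion_label_map`) and
#'   `labelmap_template` (template-space map with carried label ids).
#' @return a list of data.frames `lesions`, `subjects`, `pairs` plus
#'   `summary` (per-variable Pearson r, p, and mean/median/SD change).
#' @export
compare_spaces <- function(results) {
  lesion_rows <- list(); subject_rows <- list(); pair_rows <- list()
  for (res in results) {
    id <- res$subject_id
    lm_s <- res$labelmap_subject
    lm_t <- res$labelmap_template
    kept <- intersect(labels_present(lm_s), labels_present(lm_t))
    if (length(kept) == 0) next
    vol_s <- vapply(kept, function(l) lesion_volume_ml(lm_s, l), numeric(1))
    vol_t <- vapply(kept, function(l) lesion_volume_ml(lm_t, l), numeric(1))
    lesion_rows[[id]] <- data.frame(subject_id = id, label = kept,
                                    volume_subject_ml = vol_s,
                                    volume_template_ml = vol_t)
    # restrict both spaces to the retained lesions before measuring
    keep_only <- function(lm) {
      v <- lm$labels$values
      v[!(v %in% kept)] <- 0
      structure(list(labels = with_values(lm$labels, v, "LABEL"),
                     n_lesions = lm$n_lesions), class = "lesion_label_map")
    }
    lm_s_k <- keep_only(lm_s); lm_t_k <- lm_t
    pd_s <- pairwise_distances(lm_s_k)
    pd_t <- pairwise_distances(lm_t_k)
    if (nrow(pd_s) > 0) {
      key <- function(d) paste(d$label_a, d$label_b)
      m <- match(key(pd_s), key(pd_t))
      okp <- !is.na(m)
      if (any(okp))
        pair_rows[[id]] <- data.frame(
          subject_id = id, label_a = pd_s$label_a[okp],
          label_b = pd_s$label_b[okp],
          dist_subject_cm = pd_s$dist_cm[okp],
          dist_template_cm = pd_t$dist_cm[m[okp]])
    }
    subject_rows[[id]] <- data.frame(
      subject_id = id,
      tmv_subject_ml = total_metabolic_volume(lm_s_k),
      tmv_template_ml = total_metabolic_volume(lm_t_k),
      maxdist_subject_cm = max_within_patient_distance(lm_s_k),
      maxdist_template_cm = max_within_patient_distance(lm_t_k))
  }
  lesions <- do.call(rbind, c(lesion_rows,
                              list(data.frame(subject_id = character(0),
                                              label = integer(0),
                                              volume_subject_ml = numeric(0),
                                              volume_template_ml = numeric(0)))))
  subjects <- do.call(rbind, subject_rows)
  pairs <- do.call(rbind, pair_rows)
  rownames(lesions) <- NULL
  if (!is.null(subjects)) rownames(subjects) <- NULL
  if (!is.null(pairs)) rownames(pairs) <- NULL

  if (is.null(lesions) || nrow(lesions) < 3)
    stop("insufficient data for correlation (need >= 3 points)", call. = FALSE)
  # per-variable correlations degrade to NA when a variable has fewer than 3
  # defined points (e.g. too few multi-lesion subjects for distance measures)
  corr <- function(x, y) {
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0)
      return(list(r = NA_real_, p = NA_real_, n = sum(ok)))
    ct <- cor.test(x[ok], y[ok], alternative = "two.sided", method = "pearson")
    list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
  }
  chg <- function(after, before) {
    d <- after - before
    d <- d[!is.na(d)]
    list(mean = mean(d), median = median(d), sd = if (length(d) > 1) sd(d) else 0)
  }
  summary <- list(
    lesion_volume = c(corr(lesions$volume_subject_ml, lesions$volume_template_ml),
                      change = list(chg(lesions$volume_template_ml,
                                        lesions$volume_subject_ml))),
    total_metabolic_volume =
      c(corr(subjects$tmv_subject_ml, subjects$tmv_template_ml),
        change = list(chg(subjects$tmv_template_ml, subjects$tmv_subject_ml))),
    max_within_patient_distance =
      c(corr(subjects$maxdist_subject_cm, subjects$maxdist_template_cm),
        change = list(chg(subjects$maxdist_template_cm,
                          subjects$maxdist_subject_cm))),
    pairwise_distance = list(
      n = if (is.null(pairs)) 0L else nrow(pairs),
      change = if (is.null(pairs)) NULL else
        chg(pairs$dist_template_cm, pairs$dist_subject_cm)))
  list(lesions = lesions, subjects = subjects, pairs = pairs, summary = summary)
}
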