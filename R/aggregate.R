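#' Voxel-wise lesion frequency map
#'
#' Counts, at every template voxel, how many subjects of the subset have a
#' lesion there. Each subject contributes at most 1 per voxel (multi-lesion
#' overlap is resolved upstream by the per-lesion transfer).
#'
#' @param template_masks list of binary `scalar_volume`s on one template
#'   grid, one per subject.
#' @return a `scalar_volume` of integer counts.
#' @export
frequency_map <- function(template_masks) {
  if (length(template_masks) == 0)
    stop("empty subset: no template-space masks", call. = FALSE)
  ref <- template_masks[[1]]
  acc <- array(0, dim(ref$values))
  for (m in template_masks) {
    if (!same_grid(m, ref))
      stop("all masks must share the template grid", call. = FALSE)
    acc <- acc + (m$values > 0)
  }
  with_values(ref, acc, "FEATURE")
}

#' Percentage-frequency map
#'
#' @param freq frequency `scalar_volume` from [frequency_map()].
#' @param n_subjects number of subjects in the subset (>= 1).
#' @return a `scalar_volume` in percent (0-100).
#' @export
percentage_frequency_map <- function(freq, n_subjects) {
  if (!is.numeric(n_subjects) || n_subjects < 1)
    stop("`n_subjects` must be >= 1", call. = FALSE)
  with_values(freq, 100 * freq$values / n_subjects, "FEATURE")
}

#' Voxel-wise mean and coefficient of variation of a lesion feature
#'
#' At each template voxel the sample is the set of feature values from the
#' subjects whose lesion support covers that voxel; subjects with no lesion
#' there do not contribute. The mean and the coefficient of variation
#' (sample SD with the n-1 denominator, divided by the mean) are reported
#' only where the sample size reaches `min_occurrences`; where the mean is
#' 0 the CV is undefined and stored as `NA`.
#'
#' @param feature_maps list of `subject_feature_maps` on one template grid.
#' @param feature `"voxel_level"`, `"lesion_level"` or `"subject_level"`.
#' @param min_occurrences minimum lesion sample size per voxel (default 2).
#' @return a list: `mean_map`, `cv_map` (both `NA` outside the analysis
#'   mask), `analysis_mask` (`scalar_volume` MASK), `n_map` (per-voxel
#'   sample size).
#' @export
aggregate_mean_cv <- function(feature_maps,
                              feature = c("voxel_level", "lesion_level",
                                          "subject_level"),
                              min_occurrences = 2L) {
  feature <- match.arg(feature)
  if (length(feature_maps) == 0)
    stop("empty subset: no feature maps", call. = FALSE)
  ref <- feature_maps[[1]]$support
  dm <- dim(ref$values)
  n <- array(0, dm); s1 <- array(0, dm); s2 <- array(0, dm)
  for (fm in feature_maps) {
    if (!same_grid(fm$support, ref))
      stop("all maps must share the template grid", call. = FALSE)
    sup <- fm$support$values > 0
    v <- fm[[feature]]$values
    n <- n + sup
    s1 <- s1 + ifelse(sup, v, 0)
    s2 <- s2 + ifelse(sup, v^2, 0)
  }
  ok <- n >= min_occurrences
  if (!any(ok))
    warning("analysis mask is empty at min_occurrences = ", min_occurrences)
  mean_map <- array(NA_real_, dm)
  mean_map[ok] <- s1[ok] / n[ok]
  var_map <- array(NA_real_, dm)
  var_map[ok] <- pmax(0, (s2[ok] - n[ok] * mean_map[ok]^2) / (n[ok] - 1))
  cv_map <- array(NA_real_, dm)
  nz <- ok & !is.na(mean_map) & mean_map != 0
  cv_map[nz] <- sqrt(var_map[nz]) / mean_map[nz]
  list(mean_map = with_values(ref, mean_map, "FEATURE"),
       cv_map = with_values(ref, cv_map, "FEATURE"),
       analysis_mask = with_values(ref, array(as.numeric(ok), dm), "MASK"),
       n_map = with_values(ref, n, "FEATURE"))
}

#' Aggregate one subset end to end
#'
#' Convenience wrapper producing the full template-space stack for one
#' (sex, diagnosis) subset: frequency, percentage frequency, per-feature
#' mean / CV maps, the analysis mask, and whole-map summaries.
#'
#' @param feature_maps list of template-space `subject_feature_maps`.
#' @param subset description list (e.g. sex / diagnosis), stored in the
#'   output.
#' @param min_occurrences minimum per-voxel lesion sample size (default 2).
#' @return an `aggregated_maps` list.
#' @export
aggregate_subset <- function(feature_maps, subset = list(),
                             min_occurrences = 2L) {
  masks <- lapply(feature_maps, function(fm) fm$support)
  freq <- frequency_map(masks)
  n_subjects <- length(feature_maps)
  pct <- percentage_frequency_map(freq, n_subjects)
  feats <- c("voxel_level", "lesion_level", "subject_level")
  agg <- lapply(setNames(feats, feats), function(f)
    aggregate_mean_cv(feature_maps, f, min_occurrences))
  peak <- which.max(freq$values)
  structure(list(
    frequency = freq, percentage = pct, features = agg,
    analysis_mask = agg[[1]]$analysis_mask,
    subset = c(subset, list(n_subjects = n_subjects,
                            min_occurrences = min_occurrences)),
    summary = list(
      peak_frequency = max(freq$values),
      peak_frequency_index = as.integer(arrayInd(peak, dim(freq$values)) - 1L),
      map_summaries = lapply(agg, function(a) {
        v <- a$mean_map$values[a$analysis_mask$values > 0]
        list(mean = mean(v), sd = sd(v))
      }))),
    class = "aggregated_maps")
}

#' @export
print.aggregated_maps <- function(x, ...) {
  cat(sprintf("<aggregated_maps> n=%d subjects, peak frequency %g\n",
              x$subset$n_subjects, x$summary$peak_frequency))
  invisible(x)
}
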