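# Canonical whole-body phantom model.
#
# The canonical body of each sex is an analytic function of world
# coordinates (mm): a stack of geometric primitives (leg cylinders, a torso
# with an elliptical cross-section whose half-widths vary linearly from hips
# to shoulders, lungs, a spine, a neck and a head). Because the model is
# analytic, a warped subject can be rendered by evaluating the canonical
# intensity at inverse-warped voxel coordinates, with no resampling error.
#
# Sex differences: females have wider hips, narrower shoulders, and a higher
# body-fat range; males the opposite. Subcutaneous adipose tissue is a ring
# between the full torso ellipse and the same ellipse scaled by
# sqrt(1 - fat_fraction), so the adipose area fraction of each torso
# cross-section equals fat_fraction exactly in the continuum.

# z-band fractions of the body length L (= z extent of the grid)
.bands <- list(feet = 0.02, hip = 0.45, shoulder = 0.80, neck_top = 0.86,
               head_top = 0.97, lung_lo = 0.60, lung_hi = 0.78)

# sex-specific silhouette parameters as fractions of the x extent
.silhouette <- function(sex) {
  if (sex == "female") list(a_hip = 0.36, a_sh = 0.32)
  else list(a_hip = 0.31, a_sh = 0.37)
}

# Geometry bundle for a grid extent (Ex, Ey, Ez) and sex.
canonical_geometry <- function(extent, sex) {
  Ex <- extent[1]; Ey <- extent[2]; L <- extent[3]
  sil <- .silhouette(sex)
  cx <- Ex / 2; cy <- Ey / 2
  a_hip <- sil$a_hip * Ex; a_sh <- sil$a_sh * Ex
  zm <- 0.5 * (.bands$lung_lo + .bands$lung_hi) * L
  a_lung <- a_hip + (a_sh - a_hip) *
    (zm / L - .bands$hip) / (.bands$shoulder - .bands$hip)
  list(sex = sex, Ex = Ex, Ey = Ey, L = L, cx = cx, cy = cy,
       a_hip = a_hip, a_sh = a_sh, b_ratio = 0.60,
       leg_dx = 0.50 * a_hip, leg_a = 0.40 * a_hip,
       neck_r = 0.38 * 0.60 * a_sh,
       head_a = 0.50 * a_sh, head_b = 0.55 * a_sh, head_c = 0.050 * L,
       head_zc = 0.915 * L,
       lung_zc = zm, lung_dx = 0.32 * a_lung, lung_sa = 0.26 * a_lung,
       lung_sb = 0.42 * 0.60 * a_lung, lung_sc = 0.09 * L,
       spine_dy = 0.45, spine_r = 0.15)
}

# torso half-widths at height z (vectorized)
.torso_ab <- function(geo, z) {
  u <- (z / geo$L - .bands$hip) / (.bands$shoulder - .bands$hip)
  a <- geo$a_hip + (geo$a_sh - geo$a_hip) * u
  list(a = a, b = geo$b_ratio * a)
}

# Region membership of world points (n x 3 matrix) in canonical space.
# Returns a list of logical vectors.
canonical_regions <- function(pts, geo, fat_fraction = 0) {
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  L <- geo$L; zf <- z / L
  dx <- x - geo$cx; dy <- y - geo$cy

  in_torso_band <- zf >= .bands$hip & zf < .bands$shoulder
  ab <- .torso_ab(geo, z)
  r2 <- (dx / ab$a)^2 + (dy / ab$b)^2
  torso <- in_torso_band & r2 <= 1

  in_leg_band <- zf >= .bands$feet & zf < .bands$hip
  taper <- 0.55 + 0.45 * (zf - .bands$feet) / (.bands$hip - .bands$feet)
  la <- geo$leg_a * taper; lb <- 0.85 * la
  legs <- in_leg_band &
    (((abs(dx) - geo$leg_dx) / la)^2 + (dy / lb)^2 <= 1)

  neck <- zf >= .bands$shoulder & zf < .bands$neck_top &
    (dx^2 + dy^2 <= geo$neck_r^2)
  head <- (dx / geo$head_a)^2 + (dy / geo$head_b)^2 +
    ((z - geo$head_zc) / geo$head_c)^2 <= 1
  head <- head & zf < .bands$head_top

  lung_r <- ((x - (geo$cx - geo$lung_dx)) / geo$lung_sa)^2 +
    (dy / geo$lung_sb)^2 + ((z - geo$lung_zc) / geo$lung_sc)^2 <= 1
  lung_l <- ((x - (geo$cx + geo$lung_dx)) / geo$lung_sa)^2 +
    (dy / geo$lung_sb)^2 + ((z - geo$lung_zc) / geo$lung_sc)^2 <= 1

  spine_band <- zf >= .bands$hip & zf < .bands$neck_top
  sb <- .torso_ab(geo, pmin(pmax(z, .bands$hip * L),
                            .bands$shoulder * L * 0.999))
  spine <- spine_band &
    (dx^2 + (dy - geo$spine_dy * sb$b)^2 <= (geo$spine_r * sb$b)^2)

  fat <- torso & r2 > (1 - fat_fraction)

  body <- torso | legs | neck | head
  list(body = body, torso = torso, legs = legs, neck = neck, head = head,
       lung_right = lung_r & torso, lung_left = lung_l & torso,
       spine = spine & (torso | neck), fat = fat)
}

# Noise-free canonical CT (HU) at world points.
canonical_ct_values <- function(pts, geo, fat_fraction, hu_means) {
  rg <- canonical_regions(pts, geo, fat_fraction)
  hu <- rep(hu_means$air, nrow(pts))
  hu[rg$body] <- hu_means$soft
  hu[rg$fat] <- hu_means$adipose
  hu[rg$lung_right | rg$lung_left] <- hu_means$lung
  hu[rg$spine] <- hu_means$bone
  hu
}

# Inclusive 0-based z-index slab [shoulder level down to hips] of the torso
# on a grid with z origin `z0` and spacing `sz` (nz voxels).
canonical_torso_slab <- function(geo, z0, sz, nz) {
  lo <- ceiling((.bands$hip * geo$L - z0) / sz)
  hi <- floor((.bands$shoulder * geo$L - z0) / sz - 1e-9)
  c(max(0L, as.integer(lo)), min(nz - 1L, as.integer(hi)))
}

#' Per-diagnosis lesion placement priors
#'
#' Spatial placement densities over canonical body regions, emulating the
#' characteristic distributions of the three cancer types: lung cancer
#' (lesions in the lung fields, right-weighted 60:40), lymphoma
#' (mediastinal and neck nodal regions), melanoma (scattered through the
#' whole body). Each prior also carries the expected number of additional
#' lesions beyond the first (Poisson; means anchored to the per-subject
#' lesion counts of the emulated cohorts, halved for the desk-scale grid)
#' and a per-diagnosis scaling of the upper end of the cohort-level lesion
#' size / SUV ranges (the lower size bound is never scaled, so lesions stay
#' resolvable on the grid).
#'
#' @param diagnosis one of `"lung_cancer"`, `"lymphoma"`, `"melanoma"`,
#'   `"negative"`.
#' @return a `diagnosis_prior` list with fields `diagnosis`, `lambda`,
#'   `regions` (named weights summing to 1), `radius_scale`, `suv_scale`.
#' @export
diagnosis_prior <- function(diagnosis = c("lung_cancer", "lymphoma",
                                          "melanoma", "negative")) {
  diagnosis <- match.arg(diagnosis)
  pr <- switch(diagnosis,
    lung_cancer = list(lambda = 4.5,
                       regions = c(lung_right = 0.6, lung_left = 0.4),
                       radius_scale = 1.0, suv_scale = 1.0),
    lymphoma = list(lambda = 10,
                    regions = c(mediastinum = 0.35, neck = 0.25,
                                abdomen = 0.40),
                    radius_scale = 0.7, suv_scale = 1.1),
    melanoma = list(lambda = 8.5,
                    regions = c(whole_body = 1),
                    radius_scale = 0.6, suv_scale = 0.9),
    negative = list(lambda = 0, regions = c(whole_body = 1),
                    radius_scale = 1, suv_scale = 1))
  structure(c(list(diagnosis = diagnosis), pr), class = "diagnosis_prior")
}

# Rejection-sample one lesion center (canonical world mm) from a named region.
sample_center_in_region <- function(region, geo, fat_fraction) {
  bbox <- switch(region,
    lung_right = rbind(c(geo$cx - geo$lung_dx - geo$lung_sa,
                         geo$cy - geo$lung_sb, geo$lung_zc - geo$lung_sc),
                       c(geo$cx - geo$lung_dx + geo$lung_sa,
                         geo$cy + geo$lung_sb, geo$lung_zc + geo$lung_sc)),
    lung_left = rbind(c(geo$cx + geo$lung_dx - geo$lung_sa,
                        geo$cy - geo$lung_sb, geo$lung_zc - geo$lung_sc),
                      c(geo$cx + geo$lung_dx + geo$lung_sa,
                        geo$cy + geo$lung_sb, geo$lung_zc + geo$lung_sc)),
    mediastinum = rbind(c(geo$cx - 0.5 * geo$lung_dx, geo$cy - 0.6 * geo$lung_sb,
                          geo$lung_zc - geo$lung_sc),
                        c(geo$cx + 0.5 * geo$lung_dx, geo$cy + 0.6 * geo$lung_sb,
                          geo$lung_zc + geo$lung_sc)),
    abdomen = rbind(c(geo$cx - geo$a_hip, geo$cy - geo$b_ratio * geo$a_hip,
                      .bands$hip * geo$L),
                    c(geo$cx + geo$a_hip, geo$cy + geo$b_ratio * geo$a_hip,
                      (.bands$lung_lo - 0.02) * geo$L)),
    neck = rbind(c(geo$cx - 1.6 * geo$neck_r, geo$cy - 1.6 * geo$neck_r,
                   (.bands$shoulder - 0.04) * geo$L),
                 c(geo$cx + 1.6 * geo$neck_r, geo$cy + 1.6 * geo$neck_r,
                   (.bands$neck_top + 0.02) * geo$L)),
    whole_body = rbind(c(geo$cx - geo$a_hip, geo$cy - geo$b_ratio * geo$a_hip,
                         .bands$feet * geo$L),
                       c(geo$cx + geo$a_hip, geo$cy + geo$b_ratio * geo$a_hip,
                         .bands$head_top * geo$L)),
    stop("unknown prior region: ", region, call. = FALSE))
  inside <- function(p) {
    rg <- canonical_regions(matrix(p, nrow = 1), geo, fat_fraction)
    switch(region,
           lung_right = rg$lung_right, lung_left = rg$lung_left,
           mediastinum = rg$torso && !rg$lung_right && !rg$lung_left,
           neck = rg$neck || rg$head || rg$torso,
           abdomen = rg$torso && !rg$lung_right && !rg$lung_left,
           whole_body = rg$body)
  }
  for (i in 1:200) {
    p <- runif(3, bbox[1, ], bbox[2, ])
    if (isTRUE(inside(p))) return(p)
  }
  stop("prior region '", region, "' incompatible with the body geometry",
       call. = FALSE)
}

#' Canonical-region mask on the template grid
#'
#' Renders one of the canonical body regions as a binary mask on the
#' configured grid; used to interrogate template-space maps regionally
#' (e.g. right- vs left-lung lesion frequency).
#'
#' @param config a [cohort_config()].
#' @param sex `"female"` or `"male"`.
#' @param region one of `"body"`, `"torso"`, `"lung_right"`, `"lung_left"`,
#'   `"legs"`, `"head"`, `"neck"`, `"spine"`.
#' @return a `scalar_volume` of modality `MASK`. Patient right is rendered
#'   at low x indices.
#' @export
canonical_region_mask <- function(config, sex = c("female", "male"),
                                  region = c("body", "torso", "lung_right",
                                             "lung_left", "legs", "head",
                                             "neck", "spine")) {
  sex <- match.arg(sex)
  region <- match.arg(region)
  ext <- config$grid_shape * config$spacing_mm
  geo <- canonical_geometry(ext, sex)
  grid <- config_grid(config)
  rg <- canonical_regions(grid_world(grid), geo, 0)
  with_values(grid, array(as.numeric(rg[[region]]), dim(grid$values)), "MASK")
}
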