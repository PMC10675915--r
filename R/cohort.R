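#' Configuration of the synthetic whole-body cohort
#'
#' Bundles every tunable of the phantom generator. Defaults put a whole
#' body (feet to head) on a 64 x 64 x 160 grid at 4 mm isotropic spacing,
#' with CT tissue classes at conventional HU values, PET background near
#' SUV 1 with focal lesion uptake, smooth invertible anatomical warps, and
#' sex-specific torso fat fractions.
#'
#' @param n_subjects_per_sex_per_diagnosis subjects generated per
#'   (sex, diagnosis) cell.
#' @param grid_shape voxel triple.
#' @param spacing_mm voxel size triple (mm).
#' @param hu_means named list of tissue HU means
#'   (`air`, `lung`, `adipose`, `soft`, `bone`, `tumor`).
#' @param hu_noise_sd additive Gaussian CT noise (HU).
#' @param suv_background_mean PET background SUV inside the body.
#' @param suv_noise_sd additive Gaussian PET noise (SUV).
#' @param lesion_radius_range_mm range of ellipsoid semi-axes (mm); the lower
#'   bound must be at least twice the largest voxel size so lesions survive
#'   resampling.
#' @param lesion_suv_range range of lesion SUV.
#' @param warp_control_point_spacing_mm spacing of the Gaussian radial-basis
#'   control points of the anatomical warp.
#' @param warp_max_displacement_mm bound on the warp displacement magnitude;
#'   must stay below half the control-point spacing to keep warps invertible.
#' @param fat_fraction_range range of torso adipose fraction (0-1) from which
#'   each subject draws.
#' @param fov_jitter_slices maximum number of axial slices randomly cropped
#'   from each end of the field of view (0 = identical grids).
#' @param seed cohort-level RNG seed; per-subject seeds derive from it.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_subjects_per_sex_per_diagnosis = 2L,
                          grid_shape = c(64L, 64L, 160L),
                          spacing_mm = c(4, 4, 4),
                          hu_means = list(air = -1000, lung = -750,
                                          adipose = -100, soft = 40,
                                          bone = 700, tumor = 55),
                          hu_noise_sd = 15,
                          suv_background_mean = 1.0,
                          suv_noise_sd = 0.1,
                          lesion_radius_range_mm = c(8, 16),
                          lesion_suv_range = c(4, 10),
                          warp_control_point_spacing_mm = 64,
                          warp_max_displacement_mm = 8,
                          fat_fraction_range = c(0.25, 0.50),
                          fov_jitter_slices = 0L,
                          seed = 1L) {
  cfg <- list(n_subjects_per_sex_per_diagnosis =
                as.integer(n_subjects_per_sex_per_diagnosis),
              grid_shape = as.integer(grid_shape), spacing_mm = spacing_mm,
              hu_means = hu_means, hu_noise_sd = hu_noise_sd,
              suv_background_mean = suv_background_mean,
              suv_noise_sd = suv_noise_sd,
              lesion_radius_range_mm = lesion_radius_range_mm,
              lesion_suv_range = lesion_suv_range,
              warp_control_point_spacing_mm = warp_control_point_spacing_mm,
              warp_max_displacement_mm = warp_max_displacement_mm,
              fat_fraction_range = fat_fraction_range,
              fov_jitter_slices = as.integer(fov_jitter_slices),
              seed = as.integer(seed))
  if (cfg$warp_max_displacement_mm >= cfg$warp_control_point_spacing_mm / 2)
    stop("warp_max_displacement_mm must be < warp_control_point_spacing_mm / 2 ",
         "(invertibility)", call. = FALSE)
  if (cfg$lesion_radius_range_mm[1] < 2 * max(cfg$spacing_mm))
    stop("lesion radii must be >= 2 x the largest voxel size", call. = FALSE)
  ordered <- function(r) length(r) == 2 && r[1] <= r[2]
  if (!ordered(cfg$lesion_radius_range_mm) || !ordered(cfg$lesion_suv_range) ||
      !ordered(cfg$fat_fraction_range))
    stop("all ranges must be ordered pairs", call. = FALSE)
  structure(cfg, class = "cohort_config")
}

# grid (all zero) of the configured shape, optionally FOV-jittered
config_grid <- function(config, drop_lo = 0L, drop_hi = 0L) {
  dm <- config$grid_shape
  nz <- dm[3] - drop_lo - drop_hi
  scalar_volume(array(0, c(dm[1], dm[2], nz)), config$spacing_mm,
                origin = c(0, 0, drop_lo * config$spacing_mm[3]))
}

# Draw a bounded smooth RBF warp: control points on a jittered coarse grid
# spanning the body bounding box, amplitudes rescaled so that the maximum
# displacement magnitude (probed on a dense grid) hits `target_max` mm.
draw_warp <- function(config, geo, target_max) {
  s <- config$warp_control_point_spacing_mm
  ext <- config$grid_shape * config$spacing_mm
  xs <- seq(geo$cx - geo$a_hip, geo$cx + geo$a_hip, by = s)
  ys <- seq(geo$cy - geo$b_ratio * geo$a_hip, geo$cy + geo$b_ratio * geo$a_hip,
            by = s)
  zs <- seq(0.02 * ext[3], 0.97 * ext[3], by = s)
  ctr <- as.matrix(expand.grid(xs, ys, zs))
  colnames(ctr) <- NULL
  ctr <- ctr + matrix(runif(length(ctr), -s / 4, s / 4), ncol = 3)
  amps <- matrix(runif(length(ctr), -1, 1), ncol = 3)
  sdv <- s / 2
  probe <- as.matrix(expand.grid(
    seq(0, ext[1], by = sdv / 2), seq(0, ext[2], by = sdv / 2),
    seq(0, ext[3], by = sdv / 2)))
  colnames(probe) <- NULL
  d <- cpp_rbf_displacement(probe, ctr, amps, sdv)
  m <- max(sqrt(rowSums(d^2)))
  amps <- amps * (target_max / m)
  spatial_transform("rbf", "synthetic_ground_truth",
                    centers = ctr, amps = amps, sd = sdv)
}

#' Generate one synthetic subject
#'
#' Renders a whole-body CT (body silhouette with subcutaneous adipose ring,
#' lungs, spine), a PET volume (background near SUV 1 plus focal ellipsoidal
#' lesion uptake), and the binary lesion mask, together with the smooth
#' invertible ground-truth warp that relates the subject's anatomy to the
#' sex-matched canonical body.
#'
#' @param config a [cohort_config()].
#' @param sex `"female"` or `"male"`.
#' @param diagnosis `"lung_cancer"`, `"lymphoma"`, `"melanoma"` or
#'   `"negative"`.
#' @param prior a [diagnosis_prior()]; defaults to the diagnosis's own.
#' @param seed integer RNG seed; identical seeds give bit-identical output.
#' @return a list with elements `record` (subject id, sex, diagnosis, age and
#'   the three `scalar_volume`s on one grid), `transform` (the ground-truth
#'   canonical-to-subject warp) and `meta` (true lesion parameters, fat
#'   fraction, torso slab indices).
#' @export
generate_subject <- function(config, sex = c("female", "male"),
                             diagnosis = c("lung_cancer", "lymphoma",
                                           "melanoma", "negative"),
                             prior = NULL, seed = config$seed) {
  sex <- match.arg(sex)
  diagnosis <- match.arg(diagnosis)
  if (is.null(prior)) prior <- diagnosis_prior(diagnosis)
  set.seed(seed)
  ext <- config$grid_shape * config$spacing_mm
  geo <- canonical_geometry(ext, sex)
  fat <- runif(1, config$fat_fraction_range[1], config$fat_fraction_range[2])
  age <- round(min(90, max(18, rnorm(1, 60, 13))))

  drop_lo <- drop_hi <- 0L
  if (config$fov_jitter_slices > 0) {
    drop_lo <- sample.int(config$fov_jitter_slices + 1L, 1L) - 1L
    drop_hi <- sample.int(config$fov_jitter_slices + 1L, 1L) - 1L
  }
  grid <- config_grid(config, drop_lo, drop_hi)

  transform <- if (config$warp_max_displacement_mm > 0) {
    draw_warp(config, geo, config$warp_max_displacement_mm)
  } else identity_transform()

  pts <- grid_world(grid)
  cpts <- transform_points(transform, pts, "inverse", tol = 0.01, maxit = 60L)
  hu0 <- canonical_ct_values(cpts, geo, fat, config$hu_means)
  in_body <- hu0 > config$hu_means$air + 1
  n <- length(hu0)
  ct_vals <- hu0 + rnorm(n, 0, config$hu_noise_sd)
  pet_vals <- numeric(n)
  pet_vals[in_body] <- pmax(0, rnorm(sum(in_body), config$suv_background_mean,
                                     config$suv_noise_sd))

  # lesions: centers drawn from the diagnosis prior in canonical space,
  # mapped to subject space; ellipsoids rendered on the subject grid
  lesions <- NULL
  mask_vals <- numeric(n)
  n_lesions <- if (diagnosis == "negative") 0L else 1L + rpois(1, prior$lambda)
  if (n_lesions > 0) {
    dm <- dim(grid$values)
    rr <- config$lesion_radius_range_mm
    rr[2] <- rr[1] + prior$radius_scale * (rr[2] - rr[1])
    sr <- config$lesion_suv_range * prior$suv_scale
    regions <- names(prior$regions)
    les <- vector("list", n_lesions)
    for (i in seq_len(n_lesions)) {
      region <- sample(regions, 1, prob = prior$regions)
      c_can <- sample_center_in_region(region, geo, fat)
      c_sub <- transform_points(transform, matrix(c_can, nrow = 1), "forward")
      c_sub <- as.numeric(c_sub)
      radii <- runif(3, rr[1], rr[2])
      suv <- runif(1, sr[1], sr[2])
      # voxel support within the lesion bounding box only
      lo <- floor(index_coordinates(grid, c_sub - radii)) - 1
      hi <- ceiling(index_coordinates(grid, c_sub + radii)) + 1
      lo <- pmin(pmax(as.integer(lo), 0L), dm - 1L)
      hi <- pmin(pmax(as.integer(hi), 0L), dm - 1L)
      if (any(hi < lo)) next
      ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
      sub_idx <- as.matrix(expand.grid(ix, iy, iz))
      colnames(sub_idx) <- NULL
      w <- world_coordinates(grid, sub_idx, check = FALSE)
      inside <- ((w[, 1] - c_sub[1]) / radii[1])^2 +
        ((w[, 2] - c_sub[2]) / radii[2])^2 +
        ((w[, 3] - c_sub[3]) / radii[3])^2 <= 1
      lin <- 1 + sub_idx[, 1] + dm[1] * (sub_idx[, 2] + dm[2] * sub_idx[, 3])
      sel <- lin[inside]
      mask_vals[sel] <- 1
      # soft-tissue-density tumor on CT (high contrast inside lung fields)
      ct_vals[sel] <- rnorm(length(sel), config$hu_means$tumor,
                            config$hu_noise_sd)
      pet_vals[sel] <- pmax(0, suv + rnorm(length(sel), 0, config$suv_noise_sd))
      les[[i]] <- data.frame(lesion = i, region = region,
                             cx = c_sub[1], cy = c_sub[2], cz = c_sub[3],
                             can_x = c_can[1], can_y = c_can[2], can_z = c_can[3],
                             rx = radii[1], ry = radii[2], rz = radii[3],
                             suv = suv, n_voxels = length(sel))
    }
    lesions <- do.call(rbind, les)
  }

  dmg <- dim(grid$values)
  slab <- canonical_torso_slab(geo, grid$origin[3], grid$spacing[3], dmg[3])
  record <- structure(list(
    subject_id = NA_character_, sex = sex, diagnosis = diagnosis, age = age,
    ct = with_values(grid, array(ct_vals, dmg), "CT_HU"),
    pet = with_values(grid, array(pet_vals, dmg), "PET_SUV"),
    lesion_mask = with_values(grid, array(mask_vals, dmg), "MASK")),
    class = "subject_record")
  list(record = record, transform = transform,
       meta = list(fat_fraction = fat, torso_slab = slab, seed = seed,
                   lesions = lesions))
}

#' Generate a stratified synthetic cohort
#'
#' Produces `n_subjects_per_sex_per_diagnosis` subjects for every requested
#' (sex, diagnosis) cell, including negative controls for template
#' selection. Per-subject seeds are drawn reproducibly from `config$seed`.
#'
#' @param config a [cohort_config()].
#' @param sexes sexes to include.
#' @param diagnoses diagnoses to include.
#' @return a list of subjects as returned by [generate_subject()], each with
#'   a unique `subject_id` of the form `f_lymphoma_03`.
#' @export
generate_cohort <- function(config,
                            sexes = c("female", "male"),
                            diagnoses = c("lung_cancer", "lymphoma",
                                          "melanoma", "negative")) {
  n <- config$n_subjects_per_sex_per_diagnosis
  if (n < 1L || length(sexes) == 0L || length(diagnoses) == 0L)
    stop("empty cohort requested", call. = FALSE)
  cells <- expand.grid(i = seq_len(n), diagnosis = diagnoses, sex = sexes,
                       stringsAsFactors = FALSE)
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, nrow(cells))
  out <- vector("list", nrow(cells))
  for (r in seq_len(nrow(cells))) {
    s <- generate_subject(config, cells$sex[r], cells$diagnosis[r],
                          seed = seeds[r])
    s$record$subject_id <- sprintf("%s_%s_%02d", substr(cells$sex[r], 1, 1),
                                   cells$diagnosis[r], cells$i[r])
    out[[r]] <- s
  }
  names(out) <- vapply(out, function(s) s$record$subject_id, character(1))
  out
}

#' Canonical body of one sex as a subject record
#'
#' The canonical (unwarped) body rendered on the configured grid. This is
#' the template space used when mapping with ground-truth transforms, and a
#' convenient noise-free reference for registration experiments.
#'
#' @param config a [cohort_config()].
#' @param sex `"female"` or `"male"`.
#' @param fat_fraction torso adipose fraction; defaults to the midpoint of
#'   the configured range.
#' @param noise add acquisition noise if `TRUE` (default `FALSE`).
#' @param seed RNG seed used when `noise = TRUE`.
#' @return a `subject_record` with an all-zero lesion mask.
#' @export
canonical_subject <- function(config, sex = c("female", "male"),
                              fat_fraction = mean(config$fat_fraction_range),
                              noise = FALSE, seed = config$seed) {
  sex <- match.arg(sex)
  ext <- config$grid_shape * config$spacing_mm
  geo <- canonical_geometry(ext, sex)
  grid <- config_grid(config)
  pts <- grid_world(grid)
  hu <- canonical_ct_values(pts, geo, fat_fraction, config$hu_means)
  in_body <- hu > config$hu_means$air + 1
  pet <- numeric(length(hu))
  pet[in_body] <- config$suv_background_mean
  if (noise) {
    set.seed(seed)
    hu <- hu + rnorm(length(hu), 0, config$hu_noise_sd)
    pet[in_body] <- pmax(0, pet[in_body] +
                           rnorm(sum(in_body), 0, config$suv_noise_sd))
  }
  dmg <- dim(grid$values)
  structure(list(
    subject_id = paste0("canonical_", sex), sex = sex, diagnosis = "negative",
    age = NA_real_,
    ct = with_values(grid, array(hu, dmg), "CT_HU"),
    pet = with_values(grid, array(pet, dmg), "PET_SUV"),
    lesion_mask = with_values(grid, array(0, dmg), "MASK")),
    class = "subject_record")
}
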