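test_that("subject generation is deterministic and honors degenerate settings", {
  cfg <- test_config()
  a <- generate_subject(cfg, "female", "lymphoma", seed = 21)
  b <- generate_subject(cfg, "female", "lymphoma", seed = 21)
  expect_identical(a$record$ct$values, b$record$ct$values)
  expect_identical(a$record$pet$values, b$record$pet$values)
  expect_identical(a$record$lesion_mask$values, b$record$lesion_mask$values)
  expect_identical(a$meta, b$meta)

  neg <- generate_subject(cfg, "male", "negative", seed = 22)
  expect_true(all(neg$record$lesion_mask$values == 0))

  cfg0 <- test_config(warp_max_displacement_mm = 0)
  z <- generate_subject(cfg0, "male", "negative", seed = 23)
  expect_identical(z$transform$type, "identity")
  can <- canonical_subject(cfg0, "male", fat_fraction = z$meta$fat_fraction)
  # equals the canonical body up to acquisition noise
  expect_lt(mean(abs(z$record$ct$values - can$ct$values)),
            cfg0$hu_noise_sd)
  expect_gt(cor(as.numeric(z$record$ct$values), as.numeric(can$ct$values)),
            0.99)
})

test_that("cohort generation stratifies, shares grids and spans fat range", {
  cfg <- test_config(n_subjects_per_sex_per_diagnosis = 2, seed = 5)
  coh <- generate_cohort(cfg)
  expect_length(coh, 16)
  cells <- table(vapply(coh, function(s) s$record$sex, character(1)),
                 vapply(coh, function(s) s$record$diagnosis, character(1)))
  expect_true(all(cells == 2))
  dims <- vapply(coh, function(s) dim(s$record$ct$values), integer(3))
  expect_true(all(dims == dims[, 1]))

  expect_error(generate_cohort(test_config(n_subjects_per_sex_per_diagnosis = 0)),
               "empty cohort")

  # recomputed (image-derived) fat percentages of zero-warp negatives fall in
  # the configured range up to voxelization error and span most of it
  cfg0 <- test_config(n_subjects_per_sex_per_diagnosis = 10,
                      warp_max_displacement_mm = 0, seed = 6)
  negs <- generate_cohort(cfg0, sexes = "male", diagnoses = "negative")
  fr <- vapply(negs, function(s)
    fat_report(s$record$subject_id, s$record$ct,
               landmarks = s$meta$torso_slab)$fat_percentage, numeric(1))
  lo <- 100 * cfg0$fat_fraction_range[1]; hi <- 100 * cfg0$fat_fraction_range[2]
  expect_gte(min(fr), lo - 1.5)
  expect_lte(max(fr), hi + 1.5)
  expect_gt(max(fr) - min(fr), 0.5 * (hi - lo))
})

test_that("config invariants are enforced", {
  expect_error(cohort_config(warp_max_displacement_mm = 40,
                             warp_control_point_spacing_mm = 64),
               "invertibility")
  expect_error(cohort_config(lesion_radius_range_mm = c(4, 16)),
               "voxel size")
  expect_error(cohort_config(lesion_suv_range = c(9, 4)), "ordered")
})

test_that("ground-truth warps recover masks with Dice > 0.95", {
  cfg <- test_config()
  for (seed in c(31, 32, 33)) {
    s <- generate_subject(cfg, "male", "melanoma", seed = seed)
    mask <- s$record$lesion_mask
    tmpl <- canonical_subject(cfg, "male")$ct
    fwd <- resample_onto_grid(mask, tmpl, s$transform, "nearest")
    back <- resample_onto_grid(fwd, mask, invert_transform(s$transform),
                               "nearest")
    expect_gt(dice_coefficient(back$values, mask$values), 0.95)
  }
})

test_that("torso adipose fraction rises monotonically with configured fat", {
  cfg <- test_config()
  fr <- vapply(c(0.25, 0.35, 0.45), function(f) {
    cs <- canonical_subject(cfg, "female", fat_fraction = f)
    slab <- lesionmapr:::canonical_torso_slab(
      lesionmapr:::canonical_geometry(cfg$grid_shape * cfg$spacing_mm, "female"),
      0, cfg$spacing_mm[3], cfg$grid_shape[3])
    fat_report("c", cs$ct, landmarks = slab)$fat_percentage
  }, numeric(1))
  expect_true(all(diff(fr) > 0))
})

test_that("a synthetic cohort writes to disk and reads back consistently", {
  cfg <- cohort_config(grid_shape = c(24L, 24L, 60L), spacing_mm = c(4, 4, 4),
                       n_subjects_per_sex_per_diagnosis = 1, seed = 9)
  coh <- generate_cohort(cfg, sexes = "female",
                         diagnoses = c("negative", "melanoma"))
  dir <- tempfile("cohort")
  mpath <- write_cohort(coh, dir)
  man <- read_manifest(mpath)
  expect_equal(nrow(man), 2)
  s <- coh[[man$subject_id[1]]]
  ct <- read_volume(file.path(dir, man$ct_path[1]), "CT_HU")
  expect_equal(ct$values, s$record$ct$values, tolerance = 1e-5)
  warp <- load_transform(file.path(dir, paste0(man$subject_id[2], "_warp.json")))
  pts <- matrix(runif(30, 20, 150), ncol = 3)
  expect_equal(transform_points(warp, pts),
               transform_points(coh[[man$subject_id[2]]]$transform, pts),
               tolerance = 1e-6)
})
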