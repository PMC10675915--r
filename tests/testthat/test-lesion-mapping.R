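test_that("labeling follows the 18-neighborhood (connectivity 2) convention", {
  m <- array(0, c(3, 3, 3))
  m[1, 1, 1] <- 1; m[2, 2, 1] <- 1 # edge-adjacent
  lm <- label_lesions(scalar_volume(m, c(1, 1, 1), modality = "MASK"))
  expect_equal(lm$labels$values[1, 1, 1], lm$labels$values[2, 2, 1])

  m2 <- array(0, c(2, 2, 2))
  m2[1, 1, 1] <- 1; m2[2, 2, 2] <- 1 # corner-only contact
  lm2 <- label_lesions(scalar_volume(m2, c(1, 1, 1), modality = "MASK"))
  expect_equal(lm2$n_lesions, 2L)

  empty <- label_lesions(scalar_volume(array(0, c(4, 4, 4)), c(1, 1, 1),
                                       modality = "MASK"))
  expect_equal(empty$n_lesions, 0L)

  bad <- scalar_volume(array(2, c(2, 2, 2)), c(1, 1, 1), modality = "LABEL")
  expect_error(label_lesions(bad), "binary")
})

test_that("label count is invariant under axis permutations", {
  set.seed(50)
  arr <- array(as.numeric(runif(10^3) < 0.2), c(10, 10, 10))
  v <- scalar_volume(arr, c(1, 1, 1), modality = "MASK")
  n0 <- label_lesions(v)$n_lesions
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    vp <- scalar_volume(aperm(arr, perm), c(1, 1, 1), modality = "MASK")
    expect_equal(label_lesions(vp)$n_lesions, n0)
  }
})

test_that("lesion volumes follow voxel count x voxel volume", {
  m <- array(0, c(6, 6, 6)); m[1:10] <- 1
  lm <- label_lesions(scalar_volume(m, c(2, 2, 3), modality = "MASK"))
  expect_equal(lesion_volume_ml(lm, 1), 10 * 12 / 1000)

  m1 <- array(0, c(3, 3, 3)); m1[2, 2, 2] <- 1
  lm1 <- label_lesions(scalar_volume(m1, c(4, 4, 4), modality = "MASK"))
  expect_equal(lesion_volume_ml(lm1, 1), 0.064)
  expect_error(lesion_volume_ml(lm1, 9), "not present")

  # analytic sphere: within 10% of 4/3 pi r^3
  s <- sphere_mask(dm = c(16, 16, 16), spacing = c(2, 2, 2), radius_mm = 8)
  lms <- label_lesions(s)
  expect_equal(lesion_volume_ml(lms, 1), 4 / 3 * pi * 0.512, tolerance = 0.1)

  # volumes over labels sum to total foreground volume
  set.seed(51)
  arr <- array(as.numeric(runif(12^3) < 0.1), c(12, 12, 12))
  lmr <- label_lesions(scalar_volume(arr, c(2, 2, 2), modality = "MASK"))
  if (lmr$n_lesions > 0) {
    tot <- sum(vapply(seq_len(lmr$n_lesions),
                      function(l) lesion_volume_ml(lmr, l), numeric(1)))
    expect_equal(tot, sum(arr) * 8 / 1000)
    expect_equal(tot, total_metabolic_volume(lmr))
  }
})

test_that("total lesion counts scale to the subset maximum", {
  expect_equal(unname(total_lesion_count_scaled(c(a = 5, b = 10, c = 2))),
               c(0.5, 1.0, 0.2))
  expect_equal(unname(total_lesion_count_scaled(c(solo = 4))), 1)
  expect_equal(unname(total_lesion_count_scaled(c(x = 7, y = 7))), c(1, 1))
  expect_error(total_lesion_count_scaled(c(x = 0, y = 0)), "degenerate")
  expect_error(total_lesion_count_scaled(numeric(0)), "empty")
})

test_that("feature maps paint SUV, volume and subject scalars over support", {
  dm <- c(8, 8, 8)
  mask <- array(0, dm); mask[2:3, 2:3, 2:3] <- 1; mask[6, 6, 6] <- 1
  mv <- scalar_volume(mask, c(2, 2, 3), modality = "MASK")
  lm <- label_lesions(mv)
  expect_equal(lm$n_lesions, 2L)
  rec <- list(pet = scalar_volume(array(5, dm), c(2, 2, 3),
                                  modality = "PET_SUV"))
  fm <- build_feature_maps(rec, lm, subject_scalar = 0.5)
  sup <- fm$support$values > 0
  expect_true(all(fm$voxel_level$values[sup] == 5))
  expect_true(all(fm$voxel_level$values[!sup] == 0))
  expect_equal(unique(fm$lesion_level$values[lm$labels$values == 1]),
               8 * 12 / 1000)
  expect_equal(unique(fm$lesion_level$values[lm$labels$values == 2]),
               1 * 12 / 1000)
  expect_true(all(fm$subject_level$values[sup] == 0.5))
  expect_true(all(fm$lesion_level$values[!sup] == 0))
})

test_that("identity transfer is exact and matches whole-mask transfer", {
  cfg <- test_config()
  s <- generate_subject(cfg, "female", "melanoma", seed = 61)
  lm <- label_lesions(s$record$lesion_mask)
  fm <- build_feature_maps(s$record, lm, 1)
  out <- transfer_to_template(fm, lm, identity_transform(), s$record$ct)
  expect_equal(out$labelmap$labels$values, lm$labels$values)
  expect_equal(out$maps$voxel_level$values, fm$voxel_level$values)
  expect_equal(out$maps$lesion_level$values, fm$lesion_level$values)
  expect_equal(nrow(out$exclusions), 0L)

  # equivalence with a single whole-mask nearest resample under identity
  whole <- resample_onto_grid(lm$labels, s$record$ct, identity_transform(),
                              "nearest")
  expect_equal(out$labelmap$labels$values, whole$values)

  # template-space volumes equal subject-space volumes exactly
  for (l in seq_len(lm$n_lesions))
    expect_equal(lesion_volume_ml(out$labelmap, l), lesion_volume_ml(lm, l))
})

test_that("lesions outside the template field of view are dropped and reported", {
  dm <- c(10, 10, 20)
  mask <- array(0, dm)
  mask[4:5, 4:5, 2:3] <- 1   # inferior lesion
  mask[4:5, 4:5, 16:17] <- 1 # superior lesion
  mv <- scalar_volume(mask, c(4, 4, 4), modality = "MASK")
  lm <- label_lesions(mv)
  rec <- list(pet = scalar_volume(array(3, dm), c(4, 4, 4),
                                  modality = "PET_SUV"))
  fm <- build_feature_maps(rec, lm, 1)
  # template grid covering only the superior half of the subject
  tmpl <- scalar_volume(array(0, c(10, 10, 8)), c(4, 4, 4),
                        origin = c(0, 0, 48))
  out <- transfer_to_template(fm, lm, identity_transform(), tmpl)
  expect_equal(out$exclusions$label, 1L)
  expect_identical(out$exclusions$reason, "outside_template_fov")
  expect_setequal(lesionmapr:::labels_present(out$labelmap), 2L)
})

test_that("transferred volumes scale as s^3 under a global scaling transform", {
  s3 <- function(spacing) {
    m <- sphere_mask(dm = c(24, 24, 24), spacing = rep(spacing, 3),
                     center_mm = rep(spacing * 23 / 2, 3), radius_mm = 10)
    lm <- label_lesions(m)
    rec <- list(pet = with(m, scalar_volume(array(1, dim(values)), spacing,
                                            origin, orientation, "PET_SUV")))
    fm <- build_feature_maps(rec, lm, 1)
    sc <- 1.25
    # template world is sc x larger: forward maps template -> subject by 1/sc
    tr <- spatial_transform("affine", "identity", A = diag(rep(1 / sc, 3)),
                            b = c(0, 0, 0))
    tmpl <- with(m, scalar_volume(array(0, dim(values)), spacing * sc,
                                  origin, orientation))
    out <- transfer_to_template(fm, lm, tr, tmpl)
    lesion_volume_ml(out$labelmap, 1) / (lesion_volume_ml(lm, 1) * sc^3)
  }
  r4 <- s3(4); r2 <- s3(2)
  expect_lt(abs(r2 - 1), abs(r4 - 1) + 1e-9) # converges with resolution
  expect_lt(abs(r2 - 1), 0.1)
})
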