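test_that("scalar_volume enforces its geometric and value invariants", {
  expect_error(scalar_volume(array(0, c(2, 2)), c(1, 1, 1)), "3D")
  expect_error(scalar_volume(array(0, c(2, 2, 2)), c(1, -1, 1)), "positive")
  expect_error(scalar_volume(array(0.5, c(2, 2, 2)), c(1, 1, 1),
                             modality = "MASK"), "MASK")
  expect_error(scalar_volume(array(-1, c(2, 2, 2)), c(1, 1, 1),
                             modality = "LABEL"), "LABEL")
  skew <- diag(3); skew[1, 2] <- 0.2
  expect_error(scalar_volume(array(0, c(2, 2, 2)), c(1, 1, 1),
                             orientation = skew), "orthonormal")
})

test_that("world_coordinates matches its affine definition", {
  v <- scalar_volume(array(0, c(8, 8, 8)), spacing = c(2, 2, 3))
  expect_equal(world_coordinates(v, c(1, 1, 1)), c(2, 2, 3))
  expect_equal(world_coordinates(v, c(0, 0, 0)), c(0, 0, 0))
  v2 <- scalar_volume(array(0, c(8, 8, 8)), spacing = c(2, 2, 3),
                      origin = c(10, 0, 0))
  expect_equal(world_coordinates(v2, c(5, 0, 0)), c(20, 0, 0))
  expect_error(world_coordinates(v, c(8, 0, 0)), "out of bounds")

  # affine in the index; index differences are origin-independent
  i1 <- c(1, 2, 3); i2 <- c(4, 0, 5)
  d1 <- world_coordinates(v, i2) - world_coordinates(v, i1)
  d2 <- world_coordinates(v2, i2) - world_coordinates(v2, i1)
  expect_equal(d1, d2)

  # with an oblique orientation, index_coordinates inverts world_coordinates
  th <- pi / 7
  rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  vo <- scalar_volume(array(0, c(6, 6, 6)), c(1.5, 2, 2.5),
                      origin = c(5, -3, 2), orientation = rot)
  idx <- rbind(c(0, 0, 0), c(1, 2, 3), c(5, 5, 5))
  expect_equal(index_coordinates(vo, world_coordinates(vo, idx, check = FALSE)),
               idx, ignore_attr = TRUE)
})

test_that("slice-thickness resampling preserves values, extent and value sets", {
  # constant volume stays constant under interpolation
  v <- scalar_volume(array(7, c(4, 4, 10)), c(2, 2, 6))
  out <- resample_to_slice_thickness(v, 3)
  expect_true(all(out$values == 7))
  expect_equal(out$spacing, c(2, 2, 3))
  # world extent preserved within one voxel
  old_top <- world_coordinates(v, c(0, 0, 9))[3]
  new_top <- world_coordinates(out, c(0, 0, dim(out$values)[3] - 1))[3]
  expect_lt(abs(old_top - new_top), 3)

  # nearest mode keeps a mask binary
  m <- sphere_mask(dm = c(8, 8, 8), spacing = c(2, 2, 6), radius_mm = 8)
  mo <- resample_to_slice_thickness(m, 3, "nearest")
  expect_true(all(mo$values %in% c(0, 1)))

  # hand-computed linear interpolation: profile 0,10 at 6 mm -> 0,5,10 at 3 mm
  p <- scalar_volume(array(c(0, 10), c(1, 1, 2)), c(4, 4, 6))
  po <- resample_to_slice_thickness(p, 3)
  expect_equal(as.numeric(po$values), c(0, 5, 10))

  expect_error(resample_to_slice_thickness(v, 0), "positive")
  expect_error(resample_to_slice_thickness(v, -3), "positive")
})

test_that("grid resampling honors the identity, translations and label sets", {
  set.seed(1)
  v <- scalar_volume(array(sample(0:9, 4^3, TRUE), c(4, 4, 4)), c(2, 2, 2))
  # identity resampling onto the same grid is the identity on values
  out <- resample_onto_grid(v, v, identity_transform())
  expect_equal(out$values, v$values)

  # translating by exactly one voxel shifts content by one voxel (oracle by
  # direct index arithmetic); border fills with 0
  tr <- spatial_transform("translation", "identity", offset = c(2, 0, 0))
  sh <- resample_onto_grid(v, v, tr, "nearest")
  expect_equal(sh$values[1:3, , ], v$values[2:4, , ])
  expect_true(all(sh$values[4, , ] == 0))

  # nearest resampling cannot invent labels
  lv <- scalar_volume(array(sample(c(0, 3, 7), 6^3, TRUE), c(6, 6, 6)),
                      c(2, 2, 2), modality = "LABEL")
  ref <- scalar_volume(array(0, c(5, 5, 5)), c(2.7, 2.7, 2.7))
  lo <- resample_onto_grid(lv, ref, identity_transform(), "nearest")
  expect_true(all(lo$values %in% c(0, 3, 7)))

  expect_error(resample_onto_grid(v, v, NULL), "missing transform")
})

test_that("oblique volumes resample correctly through the identity", {
  th <- pi / 5
  rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  set.seed(2)
  v <- scalar_volume(array(rnorm(5^3), c(5, 5, 5)), c(2, 2, 2),
                     origin = c(3, 1, -2), orientation = rot)
  out <- resample_onto_grid(v, v, identity_transform())
  expect_equal(out$values, v$values, tolerance = 1e-10)
})

test_that("sub-voxel mask translation changes counts by at most the boundary", {
  m <- sphere_mask(dm = c(14, 14, 14), spacing = c(2, 2, 2), radius_mm = 9)
  n0 <- sum(m$values)
  b <- boundary_voxel_count(m$values)
  for (off in list(c(0.6, 0, 0), c(0, -0.9, 0.4), c(0.3, 0.3, 0.3))) {
    tr <- spatial_transform("translation", "identity", offset = off)
    mo <- resample_onto_grid(m, m, tr, "nearest")
    expect_lte(abs(sum(mo$values) - n0), b)
  }
})

test_that("volumes round-trip through NIfTI including oblique geometry", {
  th <- 0.3
  rot <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  set.seed(3)
  v <- scalar_volume(array(rnorm(4 * 5 * 6), c(4, 5, 6)), c(1.5, 2, 2.5),
                     origin = c(-10, 4, 7), orientation = rot)
  f <- tempfile(fileext = ".nii.gz")
  write_volume(v, f)
  r <- read_volume(f)
  expect_equal(r$values, v$values, tolerance = 1e-6)
  expect_equal(r$spacing, v$spacing, tolerance = 1e-6)
  expect_equal(r$origin, v$origin, tolerance = 1e-5)
  expect_equal(r$orientation, v$orientation, tolerance = 1e-6)
})
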