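label_fixture <- function(coords_list, spacing = c(2, 2, 2), dm = c(20, 20, 20)) {
  arr <- array(0, dm)
  for (i in seq_along(coords_list)) {
    cc <- coords_list[[i]]
    for (r in seq_len(nrow(cc))) arr[cc[r, 1], cc[r, 2], cc[r, 3]] <- i
  }
  structure(list(labels = scalar_volume(arr, spacing, modality = "LABEL"),
                 n_lesions = length(coords_list)),
            class = "lesion_label_map")
}

test_that("centers of mass are unweighted voxel-coordinate means", {
  lm <- label_fixture(list(rbind(c(2, 2, 2))), spacing = c(2, 2, 3))
  expect_equal(center_of_mass(lm, 1), c(2, 2, 3)) # single voxel at its world
  lm2 <- label_fixture(list(rbind(c(1, 1, 1), c(3, 1, 1))), spacing = c(2, 2, 2))
  expect_equal(center_of_mass(lm2, 1), c(2, 0, 0)) # midpoint
  expect_error(center_of_mass(lm2, 5), "empty")
})

test_that("pairwise distances follow world geometry (3-4-5 triangle)", {
  lm <- label_fixture(list(rbind(c(1, 1, 1)), rbind(c(4, 5, 1))),
                      spacing = c(10, 10, 10))
  pd <- pairwise_distances(lm)
  expect_equal(nrow(pd), 1)
  expect_equal(pd$dist_cm, 5) # centers (0,0,0) and (30,40,0) mm
  expect_equal(max_within_patient_distance(lm), 5)

  lm4 <- label_fixture(list(rbind(c(1, 1, 1)), rbind(c(5, 1, 1)),
                            rbind(c(1, 8, 1)), rbind(c(9, 9, 9))))
  expect_equal(nrow(pairwise_distances(lm4)), 6) # 4 lesions -> 6 pairs

  single <- label_fixture(list(rbind(c(1, 1, 1))))
  expect_equal(nrow(pairwise_distances(single)), 0)
  expect_true(is.na(max_within_patient_distance(single)))
})

test_that("vectorized distances equal the double-loop oracle", {
  set.seed(80)
  for (rep in 1:5) {
    n <- sample(3:10, 1)
    # one voxel per lesion at distinct random sites
    sites <- unique(matrix(sample(1:18, n * 3, TRUE), ncol = 3))
    lm <- label_fixture(lapply(seq_len(nrow(sites)),
                               function(i) sites[i, , drop = FALSE]),
                        spacing = c(3, 3, 3))
    centers <- t(vapply(seq_len(lm$n_lesions),
                        function(l) center_of_mass(lm, l), numeric(3)))
    oracle <- pairwise_oracle(centers)
    pd <- pairwise_distances(lm)
    expect_equal(pd$dist_cm, oracle[, 3])
    expect_equal(max_within_patient_distance(lm), max(oracle[, 3]))
  }
})

test_that("distances are invariant under rigid world transformations", {
  lm <- label_fixture(list(rbind(c(2, 3, 4), c(3, 3, 4)), rbind(c(10, 12, 6))),
                      spacing = c(2, 2, 2))
  pd0 <- pairwise_distances(lm)
  th <- 0.6
  rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  lmr <- lm
  lmr$labels <- scalar_volume(lm$labels$values, c(2, 2, 2),
                              origin = c(50, -20, 5), orientation = rot,
                              modality = "LABEL")
  expect_equal(pairwise_distances(lmr)$dist_cm, pd0$dist_cm, tolerance = 1e-10)
})

test_that("total metabolic volume is additive and matches lesion sums", {
  lm <- label_fixture(list(rbind(c(1, 1, 1), c(2, 1, 1)), rbind(c(9, 9, 9))),
                      spacing = c(4, 4, 4))
  expect_equal(total_metabolic_volume(lm), 3 * 64 / 1000)
  expect_equal(total_metabolic_volume(lm),
               lesion_volume_ml(lm, 1) + lesion_volume_ml(lm, 2))
  empty <- structure(list(labels = scalar_volume(array(0, c(3, 3, 3)),
                                                 c(4, 4, 4),
                                                 modality = "LABEL"),
                          n_lesions = 0L), class = "lesion_label_map")
  expect_equal(total_metabolic_volume(empty), 0)
})

test_that("compare_spaces yields r = 1 and zero change under identity", {
  set.seed(81)
  results <- lapply(1:4, function(i) {
    # subjects differ in lesion count and size so every summarized variable
    # has real variance across the cohort
    lm <- label_fixture(lapply(seq_len(1 + i), function(l)
      cbind(sample(3:18, 1 + l + i, TRUE), sample(3:18, 1 + l + i, TRUE),
            sample(3:18, 1 + l + i, TRUE))))
    list(subject_id = paste0("s", i), labelmap_subject = lm,
         labelmap_template = lm)
  })
  cmp <- compare_spaces(results)
  expect_equal(cmp$summary$lesion_volume$r, 1)
  expect_equal(cmp$summary$total_metabolic_volume$r, 1)
  expect_equal(cmp$summary$max_within_patient_distance$r, 1)
  expect_equal(cmp$summary$lesion_volume$change$mean, 0)
  expect_equal(cmp$summary$pairwise_distance$change$mean, 0)
  expect_true(all(cmp$lesions$volume_subject_ml == cmp$lesions$volume_template_ml))
})

test_that("a perfect linear volume relation gives r = 1 and the stated mean", {
  lm1 <- label_fixture(list(rbind(c(1, 1, 1)), rbind(c(5, 5, 5), c(6, 5, 5))),
                       spacing = c(2, 2, 2))
  # doubling volumes: same voxels on a grid with doubled voxel volume
  dbl <- lm1
  dbl$labels <- scalar_volume(lm1$labels$values, c(2, 2, 4), modality = "LABEL")
  lm2 <- label_fixture(list(rbind(c(2, 1, 1), c(3, 1, 1)), rbind(c(8, 8, 8))),
                       spacing = c(2, 2, 2))
  dbl2 <- lm2
  dbl2$labels <- scalar_volume(lm2$labels$values, c(2, 2, 4), modality = "LABEL")
  res <- list(list(subject_id = "a", labelmap_subject = lm1,
                   labelmap_template = dbl),
              list(subject_id = "b", labelmap_subject = lm2,
                   labelmap_template = dbl2))
  cmp <- compare_spaces(res)
  expect_equal(cmp$summary$lesion_volume$r, 1)
  expect_equal(cmp$summary$lesion_volume$change$mean,
               mean(cmp$lesions$volume_subject_ml))
})

test_that("Pearson r matches the closed-form oracle on a 5-point table", {
  x <- c(1.2, 3.4, 2.2, 5.0, 4.1)
  y <- c(0.9, 3.9, 2.0, 4.4, 4.6)
  lms <- lapply(seq_along(x), function(i) {
    nx <- round(x[i] * 10); ny <- round(y[i] * 10)
    mk <- function(n) {
      arr <- array(0, c(500, 1, 1)); arr[1:n] <- 1
      structure(list(labels = scalar_volume(arr, c(10, 10, 10),
                                            modality = "LABEL"),
                     n_lesions = 1L), class = "lesion_label_map")
    }
    list(subject_id = paste0("s", i), labelmap_subject = mk(nx),
         labelmap_template = mk(ny))
  })
  cmp <- compare_spaces(lms)
  expect_equal(cmp$summary$lesion_volume$r, pearson_oracle(x, y),
               tolerance = 1e-10)
  expect_lt(cmp$summary$lesion_volume$p, 1)
  expect_error(compare_spaces(lms[1:2]), "insufficient data")
})
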