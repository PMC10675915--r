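#' Registration specification
#'
#' Parameters of the baseline deformable registration: a multiresolution
#' demons-style scheme on CT intensities with Gaussian (elastic + fluid)
#' regularization of the displacement field and optional cost-function
#' masking around lesions. The estimated transform maps template world
#' coordinates to subject world coordinates (the direction used to pull
#' subject data onto the template grid).
#'
#' @param levels integer shrink factors, coarse to fine (default `c(4, 2)`).
#' @param iterations per-level iteration caps (recycled; default `c(60, 30)`).
#' @param metric similarity metric identifier; only `"ssd_demons"` is
#'   implemented.
#' @param regularization_sigma elastic smoothing of the displacement field,
#'   in voxels of the current level (default 1.5). Higher = smoother field.
#' @param fluid_sigma smoothing of each update before it is added, in voxels
#'   (default 1).
#' @param mask_policy `"exclude_lesion_voxels_from_cost"` (default) or
#'   `"none"`.
#' @param mask_dilation_voxels dilation margin of the lesion mask before
#'   exclusion (default 1).
#' @param tolerance convergence threshold on the mean update magnitude in mm
#'   (default 0.01).
#' @param max_step_mm per-iteration cap on the update magnitude (default 2).
#' @return a `registration_spec` list.
#' @export
registration_spec <- function(levels = c(4L, 2L), iterations = c(60L, 30L),
                              metric = "ssd_demons",
                              regularization_sigma = 1.5, fluid_sigma = 1,
                              mask_policy = c("exclude_lesion_voxels_from_cost",
                                              "none"),
                              mask_dilation_voxels = 1L,
                              tolerance = 0.01, max_step_mm = 2) {
  mask_policy <- match.arg(mask_policy)
  if (length(levels) < 1 || any(levels < 1))
    stop("need at least one level with shrink factor >= 1", call. = FALSE)
  iterations <- rep_len(as.integer(iterations), length(levels))
  if (any(iterations <= 0)) stop("iterations must be > 0", call. = FALSE)
  if (tolerance <= 0) stop("tolerance must be > 0", call. = FALSE)
  structure(list(levels = as.integer(levels), iterations = iterations,
                 metric = metric,
                 regularization_sigma = regularization_sigma,
                 fluid_sigma = fluid_sigma, mask_policy = mask_policy,
                 mask_dilation_voxels = as.integer(mask_dilation_voxels),
                 tolerance = tolerance, max_step_mm = max_step_mm),
            class = "registration_spec")
}

# coarse copy of `vol`: presmoothed then sampled on a grid shrunk by `shrink`
shrink_volume <- function(vol, shrink) {
  if (shrink == 1) return(vol)
  sm <- with_values(vol, array(
    cpp_gaussian_smooth3(as.numeric(vol$values), dim(vol$values),
                         rep(shrink / 2, 3)), dim(vol$values)),
    "FEATURE")
  dm <- dim(vol$values)
  dmc <- pmax(2L, as.integer(ceiling(dm / shrink)))
  ref <- scalar_volume(array(0, dmc), vol$spacing * shrink, vol$origin,
                       vol$orientation)
  resample_onto_grid(sm, ref, identity_transform(), "linear")
}

#' Deformable registration of a subject CT to a template CT
#'
#' Estimates a smooth displacement field with a multiresolution demons
#' scheme. With the default mask policy, voxels inside the (dilated) lesion
#' mask contribute no force to the similarity cost, so abnormal tissue does
#' not drive the deformation and lesion shapes are preserved. The initial
#' alignment is a translation matching the centers of mass of the two body
#' masks. The result is deterministic given identical inputs and spec.
#'
#' @param subject_ct subject CT `scalar_volume` (3 mm slice thickness
#'   recommended; see [resample_to_slice_thickness()]).
#' @param template_ct template CT `scalar_volume`.
#' @param lesion_mask binary lesion `scalar_volume` on the subject grid (an
#'   all-zero mask for negative subjects), or `NULL`.
#' @param spec a [registration_spec()].
#' @return a `spatial_transform` of type `dfield` on the template grid
#'   (provenance `"estimated"`), with convergence diagnostics in
#'   `attr(, "diagnostics")`.
#' @export
register <- function(subject_ct, template_ct, lesion_mask = NULL,
                     spec = registration_spec()) {
  stopifnot(inherits(subject_ct, "scalar_volume"),
            inherits(template_ct, "scalar_volume"))
  body_s <- body_mask_from_ct(subject_ct)
  body_t <- body_mask_from_ct(template_ct)
  com <- function(m) {
    sel <- which(m$values > 0)
    dm <- dim(m$values)
    idx <- cbind((sel - 1) %% dm[1], ((sel - 1) %/% dm[1]) %% dm[2],
                 (sel - 1) %/% (dm[1] * dm[2]))
    colMeans(world_coordinates(m, idx, check = FALSE))
  }
  if (sum(body_s$values) == 0 || sum(body_t$values) == 0)
    stop("registration failure: empty body mask", call. = FALSE)
  t0 <- com(body_s) - com(body_t)

  # field-of-view sanity: the two scanner fields of view must intersect;
  # disjoint world extents indicate mismatched data that no translation
  # initialization should silently absorb
  bb <- function(vol) rbind(world_coordinates(vol, c(0, 0, 0)),
                            world_coordinates(vol, dim(vol$values) - 1L))
  bs <- bb(subject_ct); bt <- bb(template_ct)
  lo <- pmax(pmin(bt[1, ], bt[2, ]), pmin(bs[1, ], bs[2, ]))
  hi <- pmin(pmax(bt[1, ], bt[2, ]), pmax(bs[1, ], bs[2, ]))
  if (any(hi <= lo))
    stop("registration failure: fields of view do not overlap (center-of-mass",
         " offset ", paste(signif(t0, 3), collapse = ", "), " mm)",
         call. = FALSE)

  use_mask <- spec$mask_policy == "exclude_lesion_voxels_from_cost" &&
    !is.null(lesion_mask) && sum(lesion_mask$values) > 0
  if (use_mask)
    dil <- dilate_mask(lesion_mask, spec$mask_dilation_voxels, 3L)

  mov_dm <- dim(subject_ct$values)
  mov_vals <- as.numeric(subject_ct$values)
  u <- NULL # displacement field array on the current level grid
  prev_grid <- NULL
  diagnostics <- list()

  for (li in seq_along(spec$levels)) {
    shrink <- spec$levels[li]
    fix_c <- shrink_volume(template_ct, shrink)
    mov_sm <- if (shrink > 1) array(
      cpp_gaussian_smooth3(mov_vals, mov_dm, rep(shrink / 2, 3)), mov_dm)
      else subject_ct$values
    dmc <- dim(fix_c$values)
    wpts <- grid_world(fix_c)
    n <- nrow(wpts)
    if (is.null(u)) {
      u <- matrix(rep(t0, each = n), ncol = 3)
    } else {
      u <- vapply(1:3, function(c3)
        cpp_sample_volume(as.numeric(prev_grid$field[, , , c3]),
                          dim(prev_grid$grid$values),
                          index_coordinates(prev_grid$grid, wpts), 0L, 0),
        numeric(n))
      # outside the previous coarse grid, fall back to the global offset
      out <- rowSums(abs(u)) == 0
      if (any(out)) u[out, ] <- matrix(rep(t0, each = sum(out)), ncol = 3)
    }
    gfix <- cpp_gradient3(as.numeric(fix_c$values), dmc, fix_c$spacing)
    g2 <- rowSums(gfix^2)
    s2 <- mean(fix_c$spacing)^2
    sig_f <- rep(spec$fluid_sigma, 3)
    sig_e <- rep(spec$regularization_sigma, 3)
    iters_run <- 0; mean_update <- NA_real_
    for (it in seq_len(spec$iterations[li])) {
      q <- wpts + u
      qi <- index_coordinates(subject_ct, q)
      mov <- cpp_sample_volume(as.numeric(mov_sm), mov_dm, qi, 0L,
                               min(mov_sm))
      diff <- as.numeric(fix_c$values) - mov
      denom <- g2 + diff^2 / s2
      w <- ifelse(denom > 1e-8, diff / denom, 0)
      force <- gfix * w
      if (use_mask) {
        inles <- cpp_sample_volume(as.numeric(dil$values), mov_dm, qi, 1L, 0) > 0.5
        force[inles, ] <- 0
      }
      mag <- sqrt(rowSums(force^2))
      cap <- spec$max_step_mm
      over <- mag > cap
      if (any(over)) force[over, ] <- force[over, ] * (cap / mag[over])
      force <- vapply(1:3, function(c3)
        cpp_gaussian_smooth3(force[, c3], dmc, sig_f), numeric(n))
      u <- u + force
      u <- vapply(1:3, function(c3)
        cpp_gaussian_smooth3(u[, c3], dmc, sig_e), numeric(n))
      iters_run <- it
      mean_update <- mean(sqrt(rowSums(force^2)))
      if (mean_update < spec$tolerance) break
    }
    diagnostics[[li]] <- list(shrink = shrink, iterations = iters_run,
                              mean_update_mm = mean_update)
    prev_grid <- list(field = array(u, c(dmc, 3L)), grid = fix_c)
  }

  # interpolate the final level's field onto the full template grid
  wfull <- grid_world(template_ct)
  ufull <- vapply(1:3, function(c3)
    cpp_sample_volume(as.numeric(prev_grid$field[, , , c3]),
                      dim(prev_grid$grid$values),
                      index_coordinates(prev_grid$grid, wfull), 0L, 0),
    numeric(nrow(wfull)))
  out <- rowSums(abs(ufull)) == 0
  if (any(out)) ufull[out, ] <- matrix(rep(t0, each = sum(out)), ncol = 3)
  dmt <- dim(template_ct$values)
  tr <- spatial_transform("dfield", "estimated",
                          field = array(ufull, c(dmt, 3L)),
                          grid = with_values(template_ct,
                                             array(0, dmt), "FEATURE"))
  attr(tr, "diagnostics") <- diagnostics
  tr
}

#' Mean displacement magnitude of a transform over a grid
#'
#' @param t a `spatial_transform`.
#' @param grid a `scalar_volume`.
#' @return mean mm displacement of the forward map over all grid voxels.
#' @export
mean_displacement <- function(t, grid) {
  w <- grid_world(grid)
  mean(sqrt(rowSums((transform_points(t, w, "forward") - w)^2)))
}
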