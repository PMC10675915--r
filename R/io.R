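#' Read / write volumes as NIfTI
#'
#' Geometry is carried in the NIfTI sform affine: the 3x3 block is
#' `orientation %*% diag(spacing)` and the last column is the origin, so
#' files round-trip spacing, origin and orientation exactly.
#'
#' @param vol a `scalar_volume`.
#' @param path output file (`.nii` or `.nii.gz`).
#' @return `write_volume` invisibly returns `path`; `read_volume` returns a
#'   `scalar_volume`.
#' @export
write_volume <- function(vol, path) {
  aff <- rbind(cbind(vol$orientation %*% diag(vol$spacing), vol$origin),
               c(0, 0, 0, 1))
  img <- RNifti::asNifti(vol$values)
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @param modality modality to stamp on the volume read back (NIfTI does not
#'   store it). Values are rounded for `MASK`/`LABEL` to absorb float storage.
#' @export
read_volume <- function(path, modality = c("FEATURE", "CT_HU", "PET_SUV",
                                           "MASK", "LABEL")) {
  modality <- match.arg(modality)
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  sp <- sqrt(colSums(aff[1:3, 1:3]^2))
  orient <- sweep(aff[1:3, 1:3, drop = FALSE], 2, sp, `/`)
  vals <- as.array(img)
  vals <- array(as.numeric(vals), dim(vals)) # drop NIfTI attributes
  if (length(dim(vals)) == 2L) dim(vals) <- c(dim(vals), 1L)
  if (modality %in% c("MASK", "LABEL")) vals <- round(vals)
  scalar_volume(vals, sp, aff[1:3, 4], orient, modality)
}

#' Save / load spatial transforms
#'
#' `rbf` transforms are stored as a JSON parameter file; `dfield`,
#' `translation` and `identity` transforms as a 4D vector-displacement NIfTI
#' (x/y/z components in the 4th dimension) next to a JSON sidecar holding
#' provenance. `path` is the JSON file; the displacement NIfTI, if any, is
#' `paste0(path, ".field.nii.gz")`.
#'
#' @param t a `spatial_transform`.
#' @param path path of the JSON transform file.
#' @param grid for non-dfield, non-rbf transforms: grid on which to sample
#'   the displacement field before saving.
#' @return `save_transform` invisibly returns `path`; `load_transform`
#'   returns a `spatial_transform`.
#' @export
save_transform <- function(t, path, grid = NULL) {
  stopifnot(inherits(t, "spatial_transform"))
  if (t$type == "rbf") {
    jsonlite::write_json(
      list(format = "lesionmapr-transform", type = "rbf",
           provenance = t$provenance,
           centers = t$pars$centers, amps = t$pars$amps, sd = t$pars$sd),
      path, auto_unbox = TRUE, digits = NA)
    return(invisible(path))
  }
  if (t$type != "dfield") {
    if (is.null(grid))
      stop("`grid` is required to save a ", t$type, " transform", call. = FALSE)
    t <- as_displacement_field(t, grid)
  }
  g <- t$pars$grid
  field_path <- paste0(path, ".field.nii.gz")
  aff <- rbind(cbind(g$orientation %*% diag(g$spacing), g$origin),
               c(0, 0, 0, 1))
  img <- RNifti::asNifti(t$pars$field)
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, field_path)
  jsonlite::write_json(
    list(format = "lesionmapr-transform", type = "dfield",
         provenance = t$provenance, field = basename(field_path),
         dim = dim(g$values)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_transform
#' @export
load_transform <- function(path) {
  meta <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                   error = function(e) NULL)
  if (is.null(meta) || !identical(meta$format, "lesionmapr-transform") ||
      is.null(meta$type))
    stop("not a lesionmapr transform file: ", path, call. = FALSE)
  prov <- meta$provenance
  if (meta$type == "rbf") {
    return(spatial_transform("rbf", prov,
                             centers = matrix(meta$centers, ncol = 3),
                             amps = matrix(meta$amps, ncol = 3),
                             sd = meta$sd))
  }
  if (meta$type != "dfield")
    stop("unknown transform type in ", path, call. = FALSE)
  field_path <- file.path(dirname(path), meta$field)
  img <- RNifti::readNifti(field_path)
  vals <- as.array(img)
  vals <- array(as.numeric(vals), dim(vals))
  if (length(dim(vals)) != 4L || dim(vals)[4] != 3L)
    stop("displacement field in ", field_path, " is not a 3-component 4D volume",
         call. = FALSE)
  if (!all(dim(vals)[1:3] == unlist(meta$dim)))
    stop("displacement field grid does not match the declared reference grid",
         call. = FALSE)
  aff <- RNifti::xform(img)
  sp <- sqrt(colSums(aff[1:3, 1:3]^2))
  orient <- sweep(aff[1:3, 1:3, drop = FALSE], 2, sp, `/`)
  grid <- scalar_volume(array(0, dim(vals)[1:3]), sp, aff[1:3, 4], orient)
  spatial_transform("dfield", prov, field = vals, grid = grid)
}

#' Read / write a cohort manifest
#'
#' The manifest is a CSV with columns `subject_id`, `sex`, `diagnosis`,
#' `age`, `ct_path`, `pet_path`, `mask_path` (paths relative to the manifest
#' location).
#'
#' @param path CSV file path.
#' @return a data.frame.
#' @export
read_manifest <- function(path) {
  m <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "sex", "diagnosis", "age",
            "ct_path", "pet_path", "mask_path")
  miss <- setdiff(need, names(m))
  if (length(miss))
    stop("manifest is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  m
}

#' Write a synthetic cohort to disk
#'
#' Writes per-subject CT / PET / lesion-mask NIfTI volumes, a manifest CSV,
#' ground-truth transforms (RBF JSON), and a JSON of true lesion parameters
#' for oracle tests.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort, function(s) {
    id <- s$record$subject_id
    write_volume(s$record$ct, file.path(dir, paste0(id, "_ct.nii.gz")))
    write_volume(s$record$pet, file.path(dir, paste0(id, "_pet.nii.gz")))
    write_volume(s$record$lesion_mask, file.path(dir, paste0(id, "_mask.nii.gz")))
    save_transform(s$transform, file.path(dir, paste0(id, "_warp.json")),
                   grid = s$record$ct)
    data.frame(subject_id = id, sex = s$record$sex,
               diagnosis = s$record$diagnosis, age = s$record$age,
               ct_path = paste0(id, "_ct.nii.gz"),
               pet_path = paste0(id, "_pet.nii.gz"),
               mask_path = paste0(id, "_mask.nii.gz"),
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.csv")
  write.csv(manifest, mpath, row.names = FALSE)
  truth <- lapply(cohort, function(s) s$meta)
  names(truth) <- vapply(cohort, function(s) s$record$subject_id, character(1))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(mpath)
}
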