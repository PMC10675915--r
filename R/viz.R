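#' Maximum intensity projection
#'
#' Projects a 3D volume onto a 2D image by taking the per-pixel maximum
#' along the anterior-posterior axis (`"coronal"`) or the left-right axis
#' (`"sagittal"`). Missing values are ignored; pixels with no finite voxel
#' along the ray are `NA`. The result carries the in-plane mm scale as the
#' `pixel_spacing` attribute.
#'
#' @param vol a `scalar_volume`.
#' @param plane `"coronal"` or `"sagittal"`.
#' @return a numeric matrix (first in-plane axis x rows, z columns) with a
#'   `pixel_spacing` attribute (mm per pixel along each matrix dimension).
#' @export
mip <- function(vol, plane = c("coronal", "sagittal")) {
  if (!inherits(vol, "scalar_volume") || length(dim(vol$values)) != 3L)
    stop("`vol` must be a 3D scalar_volume", call. = FALSE)
  plane <- tryCatch(match.arg(plane),
                    error = function(e) stop("unknown projection plane",
                                             call. = FALSE))
  axis <- if (plane == "coronal") 2L else 1L
  keep <- setdiff(1:3, axis)
  img <- apply(vol$values, keep, function(v) {
    v <- v[is.finite(v)]
    if (length(v) == 0) NA_real_ else max(v)
  })
  attr(img, "pixel_spacing") <- vol$spacing[keep]
  attr(img, "plane") <- plane
  img
}

#' Render a projection image to PNG
#'
#' Renders a [mip()] matrix with the package's figure conventions: for
#' frequency / mean maps, high values map to dark gray; for CV maps, a
#' diverging palette with high variation in blue and low variation in
#' yellow. Missing pixels render white.
#'
#' @param img matrix from [mip()].
#' @param path output PNG path.
#' @param palette `"dark_high"` (default) or `"cv_blue_yellow"`.
#' @param title optional plot title.
#' @return invisibly, `path`.
#' @export
render_mip_png <- function(img, path, palette = c("dark_high",
                                                  "cv_blue_yellow"),
                           title = NULL) {
  palette <- match.arg(palette)
  cols <- if (palette == "dark_high")
    grDevices::gray(seq(1, 0, length.out = 256))
  else grDevices::colorRampPalette(c("#f7e84a", "#8fbf5a", "#2a7fbf",
                                     "#14337f"))(256)
  sp <- attr(img, "pixel_spacing")
  if (is.null(sp)) sp <- c(1, 1)
  grDevices::png(path, width = 480, height = 480 * 1.2)
  op <- graphics::par(mar = c(2, 2, if (is.null(title)) 1 else 3, 1))
  on.exit({ graphics::par(op); grDevices::dev.off() }, add = TRUE)
  z <- img
  graphics::image(x = seq(0, by = sp[1], length.out = nrow(z)),
                  y = seq(0, by = sp[2], length.out = ncol(z)),
                  z = z, col = cols, useRaster = TRUE, asp = 1,
                  xlab = "mm", ylab = "mm", main = title)
  invisible(path)
}
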