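#' Spatial transforms between template and subject world coordinates
#'
#' A `spatial_transform` maps world coordinates of the template space to
#' world coordinates of a subject (the *forward* direction, the one used to
#' pull subject data onto a template grid) and back (*inverse*). Supported
#' representations:
#' \describe{
#'   \item{identity}{the trivial map.}
#'   \item{translation}{`x + t` for a fixed mm offset `t`.}
#'   \item{rbf}{a smooth invertible warp `x + d(x)` where `d` is a sum of
#'     Gaussian radial-basis displacements (the synthetic ground-truth
#'     representation); the inverse is obtained by fixed-point iteration.}
#'   \item{dfield}{a dense displacement field sampled on a reference grid
#'     (the estimated-registration representation); off-grid points use
#'     trilinear interpolation of the field, points outside the field grid
#'     get zero displacement; the inverse is obtained by fixed-point
#'     iteration on the interpolated field.}
#'   \item{affine}{`A x + b` with an invertible 3x3 matrix `A` (analytic
#'     inverse); covers global scalings and rigid maps.}
#' }
#'
#' @param type one of `"identity"`, `"translation"`, `"rbf"`, `"dfield"`,
#'   `"affine"`.
#' @param provenance one of `"identity"`, `"synthetic_ground_truth"`,
#'   `"estimated"`.
#' @param ... representation parameters: `offset` (translation); `centers`,
#'   `amps` (K x 3 matrices, mm) and `sd` (mm) for `rbf`; `field` (4D array
#'   nx x ny x nz x 3, mm displacement) and `grid` (a `scalar_volume`
#'   supplying the field geometry) for `dfield`.
#' @return an object of class `spatial_transform`.
#' @export
spatial_transform <- function(type = c("identity", "translation", "rbf",
                                       "dfield", "affine"),
                              provenance = c("identity", "synthetic_ground_truth",
                                             "estimated"),
                              ...) {
  type <- match.arg(type)
  provenance <- match.arg(provenance)
  pars <- list(...)
  if (type == "translation") {
    stopifnot(length(pars$offset) == 3L)
    pars$offset <- as.numeric(pars$offset)
  }
  if (type == "rbf") {
    stopifnot(is.matrix(pars$centers), is.matrix(pars$amps),
              ncol(pars$centers) == 3L, ncol(pars$amps) == 3L,
              nrow(pars$centers) == nrow(pars$amps),
              is.numeric(pars$sd), pars$sd > 0)
  }
  if (type == "affine") {
    stopifnot(is.matrix(pars$A), all(dim(pars$A) == c(3L, 3L)),
              abs(det(pars$A)) > 1e-12)
    if (is.null(pars$b)) pars$b <- c(0, 0, 0)
  }
  if (type == "dfield") {
    stopifnot(length(dim(pars$field)) == 4L, dim(pars$field)[4] == 3L,
              inherits(pars$grid, "scalar_volume"),
              all(dim(pars$field)[1:3] == dim(pars$grid$values)))
  }
  structure(list(type = type, provenance = provenance, pars = pars),
            class = "spatial_transform")
}

#' @export
print.spatial_transform <- function(x, ...) {
  cat(sprintf("<spatial_transform %s, provenance %s>\n", x$type, x$provenance))
  invisible(x)
}

#' Identity transform
#' @return a `spatial_transform` of type identity.
#' @export
identity_transform <- function() spatial_transform("identity", "identity")

# displacement (n x 3 mm) of a dfield transform at world points
dfield_displacement <- function(t, pts) {
  g <- t$pars$grid
  idx <- index_coordinates(g, pts)
  dm <- dim(g$values)
  vapply(1:3, function(c3) {
    cpp_sample_volume(as.numeric(t$pars$field[, , , c3]), dm, idx, 0L, 0)
  }, numeric(nrow(pts)))
}

#' Apply a spatial transform to world points
#'
#' @param t a `spatial_transform`.
#' @param pts n x 3 matrix (or length-3 vector) of world mm points.
#' @param direction `"forward"` (template -> subject) or `"inverse"`.
#' @param tol fixed-point tolerance in mm for iterative inverses.
#' @param maxit iteration cap for iterative inverses.
#' @return n x 3 matrix of mapped points (or length-3 vector for vector input).
#' @export
transform_points <- function(t, pts, direction = c("forward", "inverse"),
                             tol = 0.05, maxit = 50L) {
  direction <- match.arg(direction)
  if (is.null(t)) stop("missing transform", call. = FALSE)
  if (!inherits(t, "spatial_transform")) stop("missing transform", call. = FALSE)
  single <- !is.matrix(pts)
  if (single) pts <- matrix(as.numeric(pts), nrow = 1)
  out <- switch(
    t$type,
    identity = pts,
    translation = {
      s <- if (direction == "forward") 1 else -1
      sweep(pts, 2, s * t$pars$offset, `+`)
    },
    affine = {
      if (direction == "forward")
        sweep(pts %*% t(t$pars$A), 2, t$pars$b, `+`)
      else
        sweep(pts, 2, t$pars$b, `-`) %*% t(solve(t$pars$A))
    },
    inverted = {
      transform_points(t$pars$base, pts,
                       if (direction == "forward") "inverse" else "forward",
                       tol = tol, maxit = maxit)
    },
    rbf = {
      if (direction == "forward") {
        pts + cpp_rbf_displacement(pts, t$pars$centers, t$pars$amps, t$pars$sd)
      } else {
        cpp_rbf_inverse(pts, t$pars$centers, t$pars$amps, t$pars$sd, tol, maxit)
      }
    },
    dfield = {
      if (direction == "forward") {
        pts + dfield_displacement(t, pts)
      } else {
        # solve y + d(y) = p by fixed point y <- p - d(y)
        y <- pts
        for (it in seq_len(maxit)) {
          ynew <- pts - dfield_displacement(t, y)
          if (max(abs(ynew - y)) < tol) { y <- ynew; break }
          y <- ynew
        }
        y
      }
    },
    stop("unknown transform type", call. = FALSE)
  )
  if (single) as.numeric(out) else out
}

#' Swap the directions of a transform
#'
#' Returns a transform whose forward map is `t`'s inverse and vice versa;
#' used e.g. to resample template-space data back onto a subject grid.
#'
#' @param t a `spatial_transform`.
#' @return a `spatial_transform` of type `inverted` wrapping `t`.
#' @export
invert_transform <- function(t) {
  stopifnot(inherits(t, "spatial_transform"))
  if (t$type == "inverted") return(t$pars$base)
  structure(list(type = "inverted", provenance = t$provenance,
                 pars = list(base = t)),
            class = "spatial_transform")
}

#' Invertibility check on sampled points
#'
#' Verifies `forward(inverse(x)) ~ x` on a sample of points; used by tests
#' and by pipeline sanity checks.
#'
#' @param t a `spatial_transform`.
#' @param pts n x 3 matrix of world points.
#' @return numeric: maximum round-trip error in mm.
#' @export
roundtrip_error <- function(t, pts) {
  back <- transform_points(t, transform_points(t, pts, "inverse"), "forward")
  max(sqrt(rowSums((back - pts)^2)))
}

#' Convert any transform to a dense displacement field on a grid
#'
#' Samples the forward displacement on every voxel of `grid`. Used to save
#' estimated transforms and to compare transforms numerically.
#'
#' @param t a `spatial_transform`.
#' @param grid a `scalar_volume` defining the target geometry.
#' @return a `spatial_transform` of type `dfield` on `grid`.
#' @export
as_displacement_field <- function(t, grid) {
  w <- grid_world(grid)
  disp <- transform_points(t, w, "forward") - w
  dm <- dim(grid$values)
  spatial_transform("dfield", t$provenance,
                    field = array(disp, c(dm, 3L)), grid = grid)
}
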