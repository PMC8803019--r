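#' Axial orientation map
#'
#' The central currency of the pipeline: a 2-D grid of axial (mod-180
#' degree) fiber orientations with a validity mask and physical pixel
#' spacing.  Matrices are indexed `[row = y, col = x]`; the y axis points
#' down the image and angles are measured from +x toward +y, in radians,
#' folded into `[0, pi)`.  Invalid pixels carry `NA` in `values` and `FALSE`
#' in `valid`; they propagate through every windowed operation as mask bits
#' rather than sentinel angles.
#'
#' @param values Numeric matrix of orientations in radians (any range; folded).
#' @param valid Logical matrix of the same shape, or `NULL` to mark every
#'   non-`NA` value valid.
#' @param spacing_x,spacing_y Physical pixel pitch in micrometers.
#' @return An object of class `axial_map`.
#' @export
axial_map <- function(values, valid = NULL, spacing_x = 1, spacing_y = 1) {
  stopifnot(is.matrix(values), spacing_x > 0, spacing_y > 0)
  if (is.null(valid)) valid <- !is.na(values)
  stopifnot(is.logical(valid), all(dim(valid) == dim(values)))
  valid <- valid & !is.na(values)
  values <- fold_axial(values)
  values[!valid] <- NA_real_
  structure(
    list(values = values, valid = valid,
         spacing_x = spacing_x, spacing_y = spacing_y),
    class = "axial_map"
  )
}

#' @export
print.axial_map <- function(x, ...) {
  cat(sprintf(
    "<axial_map> %d x %d px (%.1f x %.1f um), %.1f%% valid\n",
    nrow(x$values), ncol(x$values), x$spacing_x, x$spacing_y,
    100 * mean(x$valid)
  ))
  invisible(x)
}

#' @export
dim.axial_map <- function(x) dim(x$values)

#' Weight map
#'
#' A per-pixel weight companion to an [axial_map()], dimensionless in
#' `[0, 1]`.  Values outside the range are an error, not clamped here:
#' clamping is the responsibility of the operation that derives the weights.
#'
#' @param values Numeric matrix in `[0, 1]` (`NA` treated as 0).
#' @return A matrix of class `weight_map`.
#' @export
weight_map <- function(values) {
  stopifnot(is.matrix(values))
  values[is.na(values)] <- 0
  if (any(values < 0 | values > 1)) stop("weights must lie in [0, 1]")
  structure(values, class = c("weight_map", "matrix", "array"))
}

#' Eye geometry for an en-face scan
#'
#' Positions of the fovea and optic nerve head (ONH) center in pixel
#' coordinates (`x` = column, `y` = row, 1-based), the ONH entry-circle
#' radius in degrees of visual angle, the retinal scale (micrometers per
#' degree, nominally 300), and the pixel pitch.
#'
#' @param fovea_xy,onh_xy Length-2 numeric `(x, y)` pixel coordinates.
#' @param onh_radius_deg Radius of the ONH entry circle, degrees (default 4).
#' @param um_per_deg Retinal scale in micrometers per degree (default 300).
#' @param spacing_x,spacing_y Pixel pitch, micrometers.
#' @return An object of class `retinal_geometry`.
#' @export
retinal_geometry <- function(fovea_xy, onh_xy, onh_radius_deg = 4,
                             um_per_deg = 300, spacing_x = 1, spacing_y = 1) {
  stopifnot(length(fovea_xy) == 2, length(onh_xy) == 2,
            onh_radius_deg > 0, um_per_deg > 0,
            spacing_x > 0, spacing_y > 0)
  if (all(fovea_xy == onh_xy)) stop("fovea and ONH center must differ")
  structure(
    list(fovea_xy = as.numeric(fovea_xy), onh_xy = as.numeric(onh_xy),
         onh_radius_deg = onh_radius_deg, um_per_deg = um_per_deg,
         spacing_x = spacing_x, spacing_y = spacing_y),
    class = "retinal_geometry"
  )
}

#' @export
print.retinal_geometry <- function(x, ...) {
  cat(sprintf(
    "<retinal_geometry> fovea (%.1f, %.1f) px, ONH (%.1f, %.1f) px, ONH radius %g deg, %g um/deg\n",
    x$fovea_xy[1], x$fovea_xy[2], x$onh_xy[1], x$onh_xy[2],
    x$onh_radius_deg, x$um_per_deg
  ))
  invisible(x)
}

## pixel (x, y) -> micrometer coordinates and back
px_to_um <- function(xy, geometry) {
  cbind(xy[, 1] * geometry$spacing_x, xy[, 2] * geometry$spacing_y)
}
um_to_px <- function(xy, geometry) {
  cbind(xy[, 1] / geometry$spacing_x, xy[, 2] / geometry$spacing_y)
}

#' Bilinear sampling of an orientation map
#'
#' Samples an [axial_map()] at fractional pixel positions.  Interpolation is
#' always bilinear on the doubled-angle components `(sin 2 phi, cos 2 phi)`
#' with the validity mask as weight; interpolating raw angles would break at
#' the 0/180 degree wraparound.
#'
#' @param m An [axial_map()].
#' @param x,y Fractional pixel coordinates (x = column, y = row, 1-based).
#' @param min_weight Minimum total bilinear weight carried by valid
#'   neighbors for the sample to count as valid (default 0.5).
#' @return A list with numeric `angle` (radians, `NA` where invalid) and
#'   logical `valid`, each the length of `x`.
#' @export
sample_axial <- function(m, x, y, min_weight = 0.5) {
  make_axial_sampler(m)(x, y, min_weight)
}

## precomputes the doubled-angle component grids once and returns a fast
## bilinear sampler closure; used by the tracer and streamline renderer,
## which sample one position at a time many thousands of times
make_axial_sampler <- function(m) {
  nr <- nrow(m$values); nc <- ncol(m$values)
  s <- sin(2 * m$values); s[!m$valid] <- 0
  c <- cos(2 * m$values); c[!m$valid] <- 0
  v <- matrix(0, nr, nc); v[m$valid] <- 1
  dxs <- c(0, 1, 0, 1); dys <- c(0, 0, 1, 1)
  function(x, y, min_weight = 0.5) {
    x0 <- floor(x); y0 <- floor(y)
    fx <- x - x0; fy <- y - y0
    acc_s <- acc_c <- acc_w <- numeric(length(x))
    for (k in 1:4) {
      xx <- x0 + dxs[k]; yy <- y0 + dys[k]
      w <- (if (dxs[k] == 0) 1 - fx else fx) *
        (if (dys[k] == 0) 1 - fy else fy)
      ok <- xx >= 1 & xx <= nc & yy >= 1 & yy <= nr & !is.na(w)
      if (!any(ok)) next
      idx <- yy[ok] + (xx[ok] - 1) * nr
      wk <- w[ok] * v[idx]
      acc_s[ok] <- acc_s[ok] + wk * s[idx]
      acc_c[ok] <- acc_c[ok] + wk * c[idx]
      acc_w[ok] <- acc_w[ok] + wk
    }
    valid <- acc_w >= min_weight & sqrt(acc_s^2 + acc_c^2) > 1e-9
    angle <- rep(NA_real_, length(x))
    angle[valid] <- (0.5 * atan2(acc_s[valid], acc_c[valid])) %% pi
    list(angle = angle, valid = valid)
  }
}

#' Rotate an orientation map about a point
#'
#' Resamples the grid by rotation about `center` (in physical, micrometer
#' space so anisotropic pixels rotate correctly) and adds the rotation angle
#' to every orientation value: rotating the image plane by `alpha` turns
#' every fiber by `alpha` as well, so the stored angles must be compensated.
#'
#' @param m An [axial_map()].
#' @param alpha Rotation in radians, measured from +x toward +y (the same
#'   convention as the stored angles).
#' @param center Length-2 `(x, y)` pixel coordinates of the rotation center.
#' @return The rotated [axial_map()].
#' @export
rotate_map <- function(m, alpha, center) {
  nr <- nrow(m$values); nc <- ncol(m$values)
  xs <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  ys <- matrix(rep(seq_len(nr), nc), nr, nc)
  ## target pixel -> source pixel via inverse rotation in um space
  dx <- (xs - center[1]) * m$spacing_x
  dy <- (ys - center[2]) * m$spacing_y
  ca <- cos(-alpha); sa <- sin(-alpha)
  sx <- (ca * dx - sa * dy) / m$spacing_x + center[1]
  sy <- (sa * dx + ca * dy) / m$spacing_y + center[2]
  smp <- sample_axial(m, as.vector(sx), as.vector(sy), min_weight = 0.999)
  vals <- matrix(fold_axial(smp$angle + alpha), nr, nc)
  axial_map(vals, matrix(smp$valid, nr, nc), m$spacing_x, m$spacing_y)
}
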