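#' RNFL intensity projection
#'
#' Collapses an OCT intensity volume into an en-face image of the retinal
#' nerve fiber layer by averaging, at every lateral position, the band of
#' voxels immediately above the RNFL/GCL boundary.  Bundles reflect more
#' strongly than their surround, so this projection shows the fiber bundles
#' as bright ridges.  The band height is the RNFL thickness clamped at
#' `max_len` voxels, which keeps the band from crossing the inner limiting
#' membrane; 15 gives good bundle contrast on typical data.
#'
#' @param volume 3-D intensity array `[y, x, z]`.
#' @param boundaries List with z-index matrices `ilm` and `rnfl_gcl`.
#' @param max_len Maximum band height in voxels (default 15).
#' @param vessel_mask Optional logical matrix, `TRUE` = vessel (excluded
#'   downstream; carried along).
#' @param spacing_x,spacing_y Lateral pixel pitch, micrometers.
#' @return An object of class `projection_image`: list with `values`
#'   (matrix, `NA` where the band is empty), `vessel_mask`, `valid`,
#'   `band`, `max_len`, `spacing_x`, `spacing_y`.
#' @export
project_rnfl <- function(volume, boundaries, max_len = 15,
                         vessel_mask = NULL, spacing_x = 1, spacing_y = 1) {
  stopifnot(length(dim(volume)) == 3, max_len >= 1)
  bng <- boundaries$rnfl_gcl
  ilm <- boundaries$ilm
  stopifnot(all(dim(bng) == dim(volume)[1:2]))
  be <- pmin(bng - ilm, max_len)
  acc <- matrix(0, dim(volume)[1], dim(volume)[2])
  nz <- dim(volume)[3]
  for (i in seq_len(max_len)) {
    z <- bng - i
    inc <- i <= be & z >= 1 & z <= nz
    if (!any(inc)) next
    lin <- which(inc) + (z[inc] - 1) * prod(dim(volume)[1:2])
    acc[inc] <- acc[inc] + volume[lin]
  }
  valid <- be > 0
  acc[valid] <- acc[valid] / be[valid]
  acc[!valid] <- NA_real_
  if (is.null(vessel_mask)) {
    vessel_mask <- matrix(FALSE, nrow(acc), ncol(acc))
  }
  structure(
    list(values = acc, vessel_mask = vessel_mask, valid = valid,
         band = be, max_len = max_len,
         spacing_x = spacing_x, spacing_y = spacing_y),
    class = "projection_image"
  )
}

#' @export
print.projection_image <- function(x, ...) {
  cat(sprintf("<projection_image> %d x %d px, %.1f%% vessel\n",
              nrow(x$values), ncol(x$values), 100 * mean(x$vessel_mask)))
  invisible(x)
}

#' Background-subtracted, rescaled projection
#'
#' Removes slow intensity trends (illumination, tissue reflectivity) by
#' subtracting the local mean in a large sliding window, then rescales to
#' `[0, 1]` using the 1st/99th percentiles (robust against vessel shadows
#' and specular pixels) with clipping.  Vessel and invalid pixels are
#' excluded from both the background estimate and the percentiles.  A
#' constant input has no structure to rescale; it comes back all 0.5 with
#' attribute `degenerate = TRUE`.
#'
#' @param img A [project_rnfl()] result (or compatible list).
#' @param window Full background-window width in pixels, odd (default 145).
#' @return A `projection_image` with `values` in `[0, 1]`.
#' @export
normalize_projection <- function(img, window = 145) {
  stopifnot(window >= 3, window %% 2 == 1)
  h <- (window - 1) / 2
  usable <- img$valid & !img$vessel_mask & !is.na(img$values)
  bg <- box_mean_masked(img$values, usable, h, h)
  out <- img$values - bg
  qs <- stats::quantile(out[usable], c(0.01, 0.99), na.rm = TRUE)
  degenerate <- !is.finite(qs[1]) || qs[2] - qs[1] < 1e-12
  if (degenerate) {
    out[] <- 0.5
  } else {
    out <- (out - qs[1]) / (qs[2] - qs[1])
    out <- pmin(pmax(out, 0), 1)
  }
  res <- img
  res$values <- out
  attr(res, "degenerate") <- degenerate
  res
}

#' Initial ridge orientation from the structure tensor
#'
#' Fingerprint-style orientation estimation: 3x3 Sobel gradients (computed
#' in physical units so anisotropic pixels do not bias the angle), windowed
#' gradient-product sums `Gxx`, `Gyy`, `Gxy` over a `(2N+1)^2` window, and
#' the ridge orientation as the direction perpendicular to the dominant
#' gradient, \eqn{\phi = \frac{1}{2}\mathrm{atan2}(2 G_{xy}, G_{xx} -
#' G_{yy}) + 90^\circ}.  Vessel pixels contribute nothing to any window
#' sum; pixels whose window carries no gradient energy are invalid.
#'
#' @param img A normalized [projection_image].
#' @param N Tensor window half-size in pixels (default 7).
#' @return An [axial_map()] of initial ridge orientations.
#' @export
initial_orientation <- function(img, N = 7) {
  usable <- img$valid & !img$vessel_mask & !is.na(img$values)
  g <- sobel_gradients(img$values, usable, img$spacing_x, img$spacing_y)
  gx <- g$gx; gy <- g$gy
  gx[!g$valid] <- 0; gy[!g$valid] <- 0
  gxx <- box_sum(gx * gx, N, N)
  gyy <- box_sum(gy * gy, N, N)
  gxy <- box_sum(gx * gy, N, N)
  energy <- gxx + gyy
  ok <- energy > 1e-12 * max(energy, 1e-300)
  phi <- matrix(NA_real_, nrow(gxx), ncol(gxx))
  phi[ok] <- fold_axial(0.5 * atan2(2 * gxy[ok], gxx[ok] - gyy[ok]) + pi / 2)
  axial_map(phi, ok, img$spacing_x, img$spacing_y)
}

#' Distance of an orientation field to the model field
#'
#' Per-pixel doubled-angle component distance between the initial estimate
#' and the trajectory-model field, in `[0, 2]` (0 parallel, 2
#' perpendicular).  `NA` where either map is invalid.
#'
#' @param phi_fi,phi_m Aligned [axial_map()]s.
#' @return A numeric matrix.
#' @export
model_distance_map <- function(phi_fi, phi_m) {
  stopifnot(all(dim(phi_fi$values) == dim(phi_m$values)))
  axial_distance(phi_fi$values, phi_m$values)
}

#' Distance of each orientation to its neighborhood
#'
#' How well the orientation at a pixel agrees with the window-mean
#' orientation around it: the Euclidean distance between the pixel's
#' doubled-angle components and their mask-aware window means.  Zero for
#' locally parallel fields, up to 2 for a pixel perpendicular to a
#' coherent neighborhood.
#'
#' @param phi_fi An [axial_map()].
#' @param N Window half-size in pixels.
#' @return A numeric matrix in `[0, 2]`.
#' @export
neighbor_distance_map <- function(phi_fi, N = 7) {
  s <- sin(2 * phi_fi$values); c <- cos(2 * phi_fi$values)
  ms <- box_mean_masked(s, phi_fi$valid, N, N)
  mc <- box_mean_masked(c, phi_fi$valid, N, N)
  sqrt((s - ms)^2 + (c - mc)^2)
}

#' Reliability weights from model and neighborhood distances
#'
#' Combines sliding-window-averaged versions of the model distance and the
#' neighborhood distance into a per-pixel weight
#' \eqn{W = 1 - \frac{1}{2}\sqrt{\bar{D}_m^2 + \bar{D}_n^2}}, clamped to
#' `[0, 1]`.  Pixels that disagree with both the model and their neighbors
#' get no say in the subsequent smoothing.
#'
#' @param dstm,dstn Matrices from [model_distance_map()] /
#'   [neighbor_distance_map()].
#' @param avg_window Full width of the averaging window, pixels (default 15).
#' @return A [weight_map()] (`NA` distances contribute weight 0).
#' @export
estimation_weights <- function(dstm, dstn, avg_window = 15) {
  stopifnot(all(dim(dstm) == dim(dstn)))
  h <- floor(avg_window / 2)
  mbar <- box_mean_masked(dstm, !is.na(dstm), h, h)
  nbar <- box_mean_masked(dstn, !is.na(dstn), h, h)
  w <- 1 - 0.5 * sqrt(mbar^2 + nbar^2)
  w[is.na(w)] <- 0
  weight_map(pmin(pmax(w, 0), 1))
}

#' Weighted orientation smoothing with fovea-aware windows
#'
#' The final intensity-based orientation map: a large weighted window
#' average of the doubled-angle components of the initial estimate, with
#' [estimation_weights()] as weights.  Near the fovea, bundles converge
#' from all directions, and a large window would average incompatible
#' orientations away; the window half-size therefore shrinks for pixels
#' close to the fovea so that the window never contains the fovea pixel
#' (unless centered within 1 px of it, where shrinking is impossible).
#'
#' @param phi_fi An [axial_map()] (initial orientation).
#' @param W A [weight_map()] (invalid pixels of `phi_fi` count as weight 0).
#' @param N_max Maximum window half-size in pixels (default 30).
#' @param fovea_xy `(x, y)` pixel coordinates of the fovea.
#' @return An [axial_map()]; pixels whose window holds zero total weight
#'   are invalid.
#' @export
smooth_orientation <- function(phi_fi, W, N_max = 30, fovea_xy) {
  nr <- nrow(phi_fi$values); nc <- ncol(phi_fi$values)
  w <- unclass(W)
  w[!phi_fi$valid] <- 0
  s <- sin(2 * phi_fi$values); s[!phi_fi$valid] <- 0
  c <- cos(2 * phi_fi$values); c[!phi_fi$valid] <- 0
  xs <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  ys <- matrix(rep(seq_len(nr), nc), nr, nc)
  ## Chebyshev pixel distance to the fovea; window half-size <= d - 1 keeps
  ## the fovea pixel outside the window
  d <- pmax(abs(xs - round(fovea_xy[1])), abs(ys - round(fovea_xy[2])))
  n <- pmin(N_max, pmax(d - 1, 0))
  n[d <= 1] <- N_max
  ws <- box_sum(w * s, n, n)
  wc <- box_sum(w * c, n, n)
  ww <- box_sum(w, n, n)
  ok <- ww > 1e-12 & sqrt(ws^2 + wc^2) > 1e-12
  vals <- matrix(NA_real_, nr, nc)
  vals[ok] <- fold_axial(0.5 * atan2(ws[ok], wc[ok]))
  axial_map(vals, ok, phi_fi$spacing_x, phi_fi$spacing_y)
}

#' Intensity-based orientation pipeline
#'
#' Convenience wrapper chaining [normalize_projection()],
#' [initial_orientation()], the model/neighbor distances,
#' [estimation_weights()] and [smooth_orientation()].
#'
#' @param img A [project_rnfl()] result.
#' @param phi_m Model orientation map ([axial_map()]) aligned with `img`.
#' @param fovea_xy Fovea pixel coordinates.
#' @param bg_window Background window width (default 145 px).
#' @param tensor_N Structure-tensor window half-size (default 7 px).
#' @param dstn_N Neighborhood-distance window half-size (default 7 px).
#' @param weight_window Distance-averaging window width (default 15 px).
#' @param N_max Final smoothing window half-size (default 30 px).
#' @return List with elements `phi_f` (the final [axial_map()]), `phi_fi`,
#'   `weights`, `normalized`.
#' @export
orient_intensity <- function(img, phi_m, fovea_xy, bg_window = 145,
                             tensor_N = 7, dstn_N = 7, weight_window = 15,
                             N_max = 30) {
  nrm <- normalize_projection(img, window = bg_window)
  phi_fi <- initial_orientation(nrm, N = tensor_N)
  dstm <- model_distance_map(phi_fi, phi_m)
  dstn <- neighbor_distance_map(phi_fi, N = dstn_N)
  W <- estimation_weights(dstm, dstn, avg_window = weight_window)
  phi_f <- smooth_orientation(phi_fi, W, N_max = N_max, fovea_xy = fovea_xy)
  list(phi_f = phi_f, phi_fi = phi_fi, weights = W, normalized = nrm)
}
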