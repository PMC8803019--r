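#' Average nerve fiber bundle trajectory model
#'
#' A parametric model of the average path of retinal nerve fiber bundles
#' (Jansonius-type).  A trajectory is described in a polar frame centered on
#' the optic nerve head (ONH) by
#' \deqn{\psi(\psi_0, r) = \psi_0 + b(\psi_0) (r - r_0)^{c(\psi_0)},}
#' where \eqn{r} is the eccentricity from the ONH center in degrees,
#' \eqn{r_0} the starting-circle radius (4 degrees), and \eqn{\psi_0} the
#' angular position where the bundle crosses that circle.  The coefficient
#' \eqn{b} and exponent \eqn{c} are smooth (tanh) functions of \eqn{\psi_0},
#' fitted separately per hemifield: \eqn{b > 0} in the superior hemifield
#' (\eqn{\psi_0 \in (0, 180)} degrees) and \eqn{b < 0} in the inferior one
#' (\eqn{\psi_0 \in (-180, 0)}).
#'
#' Angle convention of the model frame: the fovea sits at the origin with
#' the ONH center 15 degrees along +x; \eqn{\psi} is measured from the +x
#' direction at the ONH (the nasal horizontal, pointing away from the
#' fovea), counterclockwise positive toward the superior retina, so the
#' temporal raphe lies at \eqn{\psi = \pm 180} degrees.  With this reading
#' the papillomacular bundle (\eqn{|\psi_0|} near 180) is nearly straight
#' while arcuate bundles curve toward the raphe, matching fundus anatomy.
#'
#' @param phi0 Starting angle(s) \eqn{\psi_0} in degrees.
#' @param hemifield `"superior"` or `"inferior"`.
#' @return `model_constants()` returns a list with vectors `b` and `c`.
#' @export
model_constants <- function(phi0, hemifield = c("superior", "inferior")) {
  hemifield <- match.arg(hemifield)
  if (hemifield == "superior") {
    if (any(phi0 <= 0 | phi0 >= 180)) {
      stop("superior hemifield requires phi0 in (0, 180) degrees")
    }
    c <- 1.9 + 1.4 * tanh((phi0 - 121) / 14)
    b <- exp(-1.9 + 3.9 * tanh(-(phi0 - 121) / 14))
  } else {
    if (any(phi0 >= 0 | phi0 <= -180)) {
      stop("inferior hemifield requires phi0 in (-180, 0) degrees")
    }
    c <- 1.0 + 0.5 * tanh((-phi0 - 90) / 25)
    b <- -exp(0.7 + 1.5 * tanh(-(-phi0 - 90) / 25))
  }
  list(b = b, c = c)
}

#' @rdname model_constants
#' @param r0 Starting-circle radius in degrees (default 4).
#' @return `trajectory_params()` returns a `trajectory_params` object
#'   holding `phi0`, `b`, `c`, `r0` and the hemifield.
#' @export
trajectory_params <- function(phi0, hemifield = NULL, r0 = 4) {
  stopifnot(length(phi0) == 1, r0 > 0)
  if (is.null(hemifield)) {
    hemifield <- if (phi0 > 0) "superior" else "inferior"
  }
  k <- model_constants(phi0, hemifield)
  structure(
    list(phi0 = phi0, b = k$b, c = k$c, r0 = r0, hemifield = hemifield),
    class = "trajectory_params"
  )
}

#' Evaluate a model trajectory
#'
#' Angular position of the bundle at eccentricity `r`, in the model polar
#' frame.  At `r = r0` the trajectory passes exactly through `phi0`.
#'
#' @param params A [trajectory_params()] object.
#' @param r Eccentricity from the ONH center, degrees; must be `>= r0`.
#' @return Angular position(s) in degrees.
#' @export
trajectory <- function(params, r) {
  if (any(r < params$r0)) stop("r must be >= r0")
  params$phi0 + params$b * (r - params$r0)^params$c
}

#' Tangent direction of a model trajectory
#'
#' Axial direction of the trajectory at eccentricity `r`, in the model
#' frame (radians, measured from +x toward +y with y pointing superior).
#' Derived analytically from the curve \eqn{P(r) = r\,u(\psi(r))} around the
#' ONH center, where \eqn{u} is the radial unit vector, so
#' \eqn{dP/dr = u + r \psi'(r) (\pi/180)\, u_\perp}.
#'
#' @inheritParams trajectory
#' @return Axial angle(s) in `[0, pi)` radians (model frame).
#' @export
trajectory_tangent <- function(params, r) {
  if (any(r <= params$r0)) stop("r must be > r0")
  psi <- trajectory(params, r) * pi / 180
  dpsi_dr <- params$b * params$c * (r - params$r0)^(params$c - 1) * pi / 180
  dx <- cos(psi) - r * sin(psi) * dpsi_dr
  dy <- sin(psi) + r * cos(psi) * dpsi_dr
  fold_axial(atan2(dy, dx))
}

#' Similarity fit of the model frame to an eye
#'
#' Places the canonical model frame (fovea at the origin, ONH center 15
#' degrees along +x) onto an image: the fovea is matched by translation,
#' then the ONH center by rotation and scaling about the fixed fovea.  Left
#' eyes are mirrored to the right-eye convention before fitting and results
#' are mirrored back.  The transform works in physical (micrometer)
#' coordinates so anisotropic pixels are handled exactly.
#'
#' @param fovea_xy,onh_xy Landmark `(x, y)` pixel coordinates.
#' @param geometry A [retinal_geometry()] (supplies pixel spacing); its
#'   landmark fields are ignored in favor of the explicit arguments.
#' @param eye `"right"` (default) or `"left"`.
#' @return An object of class `rnfb_model_fit` with fields
#'   `fovea_um`, `rotation` (radians), `scale` (micrometers per model
#'   degree), `eye`, and `geometry`.
#' @export
fit_to_eye <- function(fovea_xy, onh_xy, geometry, eye = c("right", "left")) {
  eye <- match.arg(eye)
  if (all(fovea_xy == onh_xy)) stop("fovea and ONH center coincide")
  f_um <- c(fovea_xy[1] * geometry$spacing_x, fovea_xy[2] * geometry$spacing_y)
  o_um <- c(onh_xy[1] * geometry$spacing_x, onh_xy[2] * geometry$spacing_y)
  v <- o_um - f_um
  if (eye == "left") v[1] <- -v[1]
  structure(
    list(fovea_um = f_um,
         rotation = atan2(v[2], v[1]),
         scale = sqrt(sum(v^2)) / 15,
         eye = eye,
         geometry = geometry),
    class = "rnfb_model_fit"
  )
}

#' @export
print.rnfb_model_fit <- function(x, ...) {
  cat(sprintf(
    "<rnfb_model_fit> %s eye, rotation %.2f deg, scale %.1f um/deg\n",
    x$eye, x$rotation * 180 / pi, x$scale
  ))
  invisible(x)
}

## model-frame point (x_m, y_m in degrees, y up) -> image um (y down)
model_to_image_um <- function(fit, xy_m) {
  x <- xy_m[, 1]; y <- -xy_m[, 2]            # flip: model y up, image y down
  if (fit$eye == "left") x <- -x
  ca <- cos(fit$rotation); sa <- sin(fit$rotation)
  cbind(fit$fovea_um[1] + fit$scale * (ca * x - sa * y),
        fit$fovea_um[2] + fit$scale * (sa * x + ca * y))
}

## image um -> model-frame degrees (y up)
image_um_to_model <- function(fit, xy_um) {
  dx <- xy_um[, 1] - fit$fovea_um[1]
  dy <- xy_um[, 2] - fit$fovea_um[2]
  ca <- cos(-fit$rotation); sa <- sin(-fit$rotation)
  x <- (ca * dx - sa * dy) / fit$scale
  y <- (sa * dx + ca * dy) / fit$scale
  if (fit$eye == "left") x <- -x
  cbind(x, -y)
}

## model-frame axial angle -> image-frame axial angle.  The y flip negates
## the angle; mirroring (left eye) maps theta -> pi - theta; the rotation
## adds itself (rotating an orientation map means rotating its values too).
model_angle_to_image <- function(fit, theta_m) {
  th <- -theta_m
  if (fit$eye == "left") th <- pi - th
  fold_axial(th + fit$rotation)
}

#' Sample points along every model trajectory of a fitted eye
#'
#' Generates trajectories at `traces_per_degree` starting angles around the
#' ONH, samples them radially at `dr` degrees, and transforms positions (to
#' image pixels) and tangents (to image axial angles) through the fit.
#' Trajectories are truncated where they reach the temporal raphe
#' (`|psi| >= 180` degrees).
#'
#' @param fit An [fit_to_eye()] result.
#' @param r_max Maximum eccentricity to sample, degrees.
#' @param traces_per_degree Density of starting angles (default 1).
#' @param dr Radial sampling step, degrees (default 0.1).
#' @return A tibble with columns `phi0`, `hemifield`, `r`, `psi`,
#'   `x_px`, `y_px`, `angle` (image-frame axial radians).
#' @export
model_trace_samples <- function(fit, r_max, traces_per_degree = 1, dr = 0.1) {
  step <- 1 / traces_per_degree
  phi0s <- c(seq(step / 2, 180 - step / 2, by = step),
             seq(-180 + step / 2, -step / 2, by = step))
  rs <- seq(fit$geometry$onh_radius_deg + dr, r_max, by = dr)
  out <- purrr::map(phi0s, function(p0) {
    hemi <- if (p0 > 0) "superior" else "inferior"
    par <- trajectory_params(p0, hemi, r0 = fit$geometry$onh_radius_deg)
    psi <- trajectory(par, rs)
    keep <- abs(psi) < 180
    if (!any(keep)) return(NULL)
    ## truncate at first raphe crossing to keep trajectories contiguous
    keep <- seq_along(rs) < (which.min(keep)[1]) | all(keep)
    if (!any(keep)) return(NULL)
    r <- rs[keep]; psi <- psi[keep]
    th_m <- trajectory_tangent(par, r)
    xy_m <- cbind(15 + r * cos(psi * pi / 180), r * sin(psi * pi / 180))
    xy_um <- model_to_image_um(fit, xy_m)
    tibble::tibble(
      phi0 = p0, hemifield = hemi, r = r, psi = psi,
      x_px = xy_um[, 1] / fit$geometry$spacing_x,
      y_px = xy_um[, 2] / fit$geometry$spacing_y,
      angle = model_angle_to_image(fit, th_m)
    )
  })
  dplyr::bind_rows(out)
}

#' Rasterize the trajectory model into an orientation map
#'
#' Generates trajectories around the ONH (1 per degree by default), then
#' interpolates their tangent orientations onto the pixel grid: each trace
#' sample splats its doubled-angle components onto nearby pixels with
#' inverse-distance weights inside a 1-degree radius.  Pixels farther than
#' that from any trace sample stay invalid (nothing to interpolate from).
#'
#' @param fit An [fit_to_eye()] result.
#' @param shape Integer `(nrow, ncol)` of the output map.
#' @param traces_per_degree Starting-angle density (default 1).
#' @param dr Radial sampling step along each trace, degrees (default 0.1).
#' @param idw_radius_deg Gather radius for the inverse-distance
#'   interpolation, degrees (default 1).
#' @return An [axial_map()] (the model orientation map, often called the
#'   "model field").
#' @export
rasterize_model <- function(fit, shape, traces_per_degree = 1, dr = 0.1,
                            idw_radius_deg = 1) {
  if (fit$scale <= 0) stop("degenerate fit: scale must be positive")
  g <- fit$geometry
  nr <- shape[1]; nc <- shape[2]
  ## eccentricity of the farthest image corner from the ONH, in model degrees
  corners_um <- cbind(c(1, 1, nc, nc) * g$spacing_x,
                      c(1, nr, 1, nr) * g$spacing_y)
  r_max <- max(sqrt((corners_um[, 1] - g$onh_xy[1] * g$spacing_x)^2 +
                    (corners_um[, 2] - g$onh_xy[2] * g$spacing_y)^2)) /
    fit$scale + 1
  smp <- model_trace_samples(fit, r_max, traces_per_degree, dr)

  radius_um <- idw_radius_deg * fit$scale
  rx <- ceiling(radius_um / g$spacing_x)
  ry <- ceiling(radius_um / g$spacing_y)
  px <- round(smp$x_px); py <- round(smp$y_px)
  keep <- px >= 1 & px <= nc & py >= 1 & py <= nr
  smp <- smp[keep, ]; px <- px[keep]; py <- py[keep]

  ## bin sample components into their containing pixels, then gather with an
  ## inverse-distance-squared kernel over the 1-degree disc: pixels on a
  ## trace are dominated by that trace's own samples, pixels between traces
  ## interpolate smoothly
  s2 <- sin(2 * smp$angle); c2 <- cos(2 * smp$angle)
  lin <- py + (px - 1) * nr
  agg <- rowsum(cbind(s2, c2, rep(1, length(lin))), lin)
  idx <- as.integer(rownames(agg))
  bs <- matrix(0, nr, nc); bc <- matrix(0, nr, nc); bn <- matrix(0, nr, nc)
  bs[idx] <- agg[, 1]; bc[idx] <- agg[, 2]; bn[idx] <- agg[, 3]

  acc_s <- matrix(0, nr, nc); acc_c <- matrix(0, nr, nc)
  acc_w <- matrix(0, nr, nc)
  eps_um <- 0.25 * min(g$spacing_x, g$spacing_y)
  for (dyp in -ry:ry) {
    for (dxp in -rx:rx) {
      d_um <- sqrt((dxp * g$spacing_x)^2 + (dyp * g$spacing_y)^2)
      if (d_um > radius_um) next
      w <- 1 / (d_um^2 + eps_um^2)
      acc_s <- acc_s + w * shift_mat(bs, dyp, dxp)
      acc_c <- acc_c + w * shift_mat(bc, dyp, dxp)
      acc_w <- acc_w + w * shift_mat(bn, dyp, dxp)
    }
  }
  valid <- acc_w > 0
  vals <- axial_from_components(acc_s, acc_c)
  vals[!valid] <- NA_real_
  axial_map(vals, valid & !is.na(vals), g$spacing_x, g$spacing_y)
}

#' Find the model trajectory through a point
#'
#' Inverts the trajectory model at an image location: finds the starting
#' angle `phi0` whose trajectory passes through the given pixel, by dense
#' grid search over starting angles refined with root bracketing.  Useful as
#' an analytic reference for traced entry angles.
#'
#' @param point_xy `(x, y)` pixel coordinates.
#' @param fit An [fit_to_eye()] result.
#' @param grid_step Starting-angle search resolution, degrees.
#' @return A list with `phi0` (degrees, model convention), `psi` and `r`
#'   (the point's polar position around the ONH), `residual_deg` (angular
#'   mismatch of the best trajectory at that radius) and `entry_angle`
#'   (degrees, 0 at the temporal horizontal, superior positive).
#' @export
solve_trajectory_through <- function(point_xy, fit, grid_step = 0.05) {
  g <- fit$geometry
  xy_um <- cbind(point_xy[1] * g$spacing_x, point_xy[2] * g$spacing_y)
  m <- image_um_to_model(fit, xy_um)
  dx <- m[1, 1] - 15; dy <- m[1, 2]
  r_s <- sqrt(dx^2 + dy^2)
  psi_s <- atan2(dy, dx) * 180 / pi
  if (r_s <= g$onh_radius_deg) stop("point lies inside the ONH circle")
  hemi <- if (psi_s >= 0) "superior" else "inferior"
  sgn <- if (hemi == "superior") 1 else -1
  cand <- seq(grid_step / 2, 180 - grid_step / 2, by = grid_step) * sgn
  k <- model_constants(cand, hemi)
  psi_at <- cand + k$b * (r_s - g$onh_radius_deg)^k$c
  resid <- abs(psi_at - psi_s)
  i <- which.min(resid)
  phi0 <- cand[i]
  ## refine by bisection on the signed residual if a bracket exists
  f <- function(p) {
    kk <- model_constants(p, hemi)
    p + kk$b * (r_s - g$onh_radius_deg)^kk$c - psi_s
  }
  lo <- cand[max(1, i - 1)]; hi <- cand[min(length(cand), i + 1)]
  if (is.finite(f(lo)) && is.finite(f(hi)) && f(lo) * f(hi) < 0) {
    phi0 <- stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
  }
  list(phi0 = phi0, psi = psi_s, r = r_s,
       residual_deg = abs(f(phi0)),
       entry_angle = wrap180(180 - phi0))
}
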