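#' Axis-offset calibration of the polarization orientation map
#'
#' The optic-axis orientation from PS-OCT is a relative angle: the whole
#' map may be rotated by an unknown constant.  The offset is recovered by
#' comparing the polarization map against the intensity-based map inside a
#' broad circular band around the ONH (where retardation, and hence axis
#' reliability, is high): for every candidate offset from -90 to +90
#' degrees in 1-degree steps, the sum of squared differences of the
#' doubled-angle sine and cosine components is evaluated over the jointly
#' valid band pixels, and the minimizing offset wins (ties break toward the
#' smallest magnitude).
#'
#' @param phi_p,phi_f Aligned [axial_map()]s (polarization / intensity).
#' @param geometry A [retinal_geometry()].
#' @param band_inner,band_outer Annulus radii around the ONH center,
#'   degrees (defaults 5 and 10).
#' @param step_deg Search step (default 1 degree).
#' @param min_pixels Minimum jointly valid band pixels (default 100).
#' @return An object of class `rnfb_offset_search`: list with `ofs`
#'   (degrees), `objective_curve` (tibble `offset`, `ssd`), `n_pixels`.
#' @export
find_axis_offset <- function(phi_p, phi_f, geometry, band_inner = 5,
                             band_outer = 10, step_deg = 1,
                             min_pixels = 100) {
  stopifnot(all(dim(phi_p$values) == dim(phi_f$values)))
  nr <- nrow(phi_p$values); nc <- ncol(phi_p$values)
  xs <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  ys <- matrix(rep(seq_len(nr), nc), nr, nc)
  r_um <- sqrt(((xs - geometry$onh_xy[1]) * geometry$spacing_x)^2 +
               ((ys - geometry$onh_xy[2]) * geometry$spacing_y)^2)
  r_deg <- r_um / geometry$um_per_deg
  band <- r_deg >= band_inner & r_deg <= band_outer &
    phi_p$valid & phi_f$valid
  n <- sum(band)
  if (n < min_pixels) {
    stop(sprintf("only %d jointly valid band pixels (need >= %d)",
                 n, min_pixels))
  }
  dphi <- phi_p$values[band] - phi_f$values[band]
  offsets <- seq(-90, 90, by = step_deg)
  ## ssd(ofs) = sum over pixels of |e^{i2(phi_p+ofs)} - e^{i2 phi_f}|^2
  ##          = 2 n - 2 sum cos(2 dphi + 2 ofs)
  A <- sum(cos(2 * dphi)); B <- sum(sin(2 * dphi))
  o_rad <- offsets * pi / 180
  ssd <- 2 * n - 2 * (A * cos(2 * o_rad) - B * sin(2 * o_rad))
  best <- min(ssd)
  cand <- which(ssd <= best + 1e-9 * max(1, abs(best)))
  i <- cand[which.min(abs(offsets[cand]))]
  structure(
    list(ofs = offsets[i],
         objective_curve = tibble::tibble(offset = offsets, ssd = ssd),
         n_pixels = n),
    class = "rnfb_offset_search"
  )
}

#' @export
print.rnfb_offset_search <- function(x, ...) {
  cat(sprintf("<rnfb_offset_search> ofs = %+g deg over %d band pixels\n",
              x$ofs, x$n_pixels))
  invisible(x)
}

#' Apply an axis offset to an orientation map
#'
#' @param phi_p An [axial_map()].
#' @param ofs_deg Offset in degrees (added to every valid angle, mod 180).
#' @return The shifted [axial_map()].
#' @export
apply_axis_offset <- function(phi_p, ofs_deg) {
  vals <- fold_axial(phi_p$values + ofs_deg * pi / 180)
  axial_map(vals, phi_p$valid, phi_p$spacing_x, phi_p$spacing_y)
}

#' Agreement weight of a source map against the model
#'
#' Per-pixel weight `1 - axial_distance(phi, phi_m) / 2`: 1 where a source
#' agrees with the trajectory model, 0 where it is perpendicular to it.
#' Invalid source pixels get weight 0.
#'
#' @param phi Source [axial_map()].
#' @param phi_m Model [axial_map()].
#' @return A [weight_map()].
#' @export
source_weight <- function(phi, phi_m) {
  stopifnot(all(dim(phi$values) == dim(phi_m$values)))
  w <- 1 - 0.5 * axial_distance(phi$values, phi_m$values)
  w[!phi$valid | !phi_m$valid | is.na(w)] <- 0
  weight_map(pmin(pmax(w, 0), 1))
}

#' Fuse polarization and intensity orientation maps
#'
#' The final orientation map: a per-pixel weighted axial mean of the
#' (offset-corrected) polarization map and the intensity map, with the
#' model-agreement weights smoothed by a sliding average filter first.
#' Where exactly one source is valid the output equals that source; where
#' neither is valid (or the two sources oppose each other exactly and the
#' resultant vanishes) the trajectory model is blended in: such pixels take
#' the model orientation, with a linear ramp over `blend_px` pixels at the
#' validity boundary to avoid orientation seams.
#'
#' @param phi_p,phi_f Source [axial_map()]s.
#' @param w_p,w_f [weight_map()]s (see [source_weight()]).
#' @param phi_m Optional model [axial_map()] used for gap filling.
#' @param smoothing_window Full width of the weight-smoothing window,
#'   pixels (default 15).
#' @param blend_px Ramp width of the model blend, pixels (default 10).
#' @return An [axial_map()] with a logical attribute `model_filled`
#'   marking pixels that took (part of) their value from the model.
#' @export
fuse_maps <- function(phi_p, phi_f, w_p, w_f, phi_m = NULL,
                      smoothing_window = 15, blend_px = 10) {
  stopifnot(all(dim(phi_p$values) == dim(phi_f$values)))
  nr <- nrow(phi_p$values); nc <- ncol(phi_p$values)
  h <- floor(smoothing_window / 2)
  wp <- box_sum(unclass(w_p), h, h) / box_sum(matrix(1, nr, nc), h, h)
  wf <- box_sum(unclass(w_f), h, h) / box_sum(matrix(1, nr, nc), h, h)
  wp[!phi_p$valid] <- 0
  wf[!phi_f$valid] <- 0
  sp <- sin(2 * phi_p$values); sp[!phi_p$valid] <- 0
  cp <- cos(2 * phi_p$values); cp[!phi_p$valid] <- 0
  sf <- sin(2 * phi_f$values); sf[!phi_f$valid] <- 0
  cf <- cos(2 * phi_f$values); cf[!phi_f$valid] <- 0
  s <- wp * sp + wf * sf
  c <- wp * cp + wf * cf
  wsum <- wp + wf
  ok <- wsum > 1e-12 & sqrt(s^2 + c^2) > 1e-9 * pmax(wsum, 1e-300)
  vals <- matrix(NA_real_, nr, nc)
  vals[ok] <- fold_axial(0.5 * atan2(s[ok], c[ok]))
  filled <- !ok
  if (!is.null(phi_m) && any(filled)) {
    ## integer chamfer-by-dilation distance (in steps of one pixel) from
    ## every fused pixel to the nearest model-filled pixel
    d <- matrix(Inf, nr, nc)
    d[filled & phi_m$valid] <- 0
    reach <- filled & phi_m$valid
    for (k in seq_len(blend_px)) {
      grown <- box_sum(matrix(as.numeric(reach), nr, nc), 1, 1) > 0
      d[grown & !reach] <- k
      reach <- grown
    }
    lam <- pmin(d / blend_px, 1)          # 0 at fill, 1 far away
    mix <- !is.na(phi_m$values) & (filled | lam < 1)
    sm <- sin(2 * phi_m$values); cm <- cos(2 * phi_m$values)
    s_out <- sin(2 * vals); c_out <- cos(2 * vals)
    s_out[filled] <- 0; c_out[filled] <- 0
    sb <- lam * s_out + (1 - lam) * sm
    cb <- lam * c_out + (1 - lam) * cm
    upd <- mix & sqrt(sb^2 + cb^2) > 1e-12
    vals[upd] <- fold_axial(0.5 * atan2(sb[upd], cb[upd]))
    ok <- ok | (filled & phi_m$valid)
  }
  out <- axial_map(vals, ok, phi_p$spacing_x, phi_p$spacing_y)
  attr(out, "model_filled") <- filled
  out
}
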