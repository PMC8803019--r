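#' Streamline integration of the orientation map
#'
#' A trace follows the fused orientation map in fixed physical steps.  An
#' axial angle gives a line, not a heading, so every step has two antipodal
#' candidates `pos +/- r * (cos phi, sin phi)`; the candidate is selected
#' by a distance rule with respect to the ONH center (inward tracing keeps
#' the candidate closer to the ONH, outward the farther one).  After the
#' first step an anti-reversal rule takes precedence: the candidate with
#' the larger dot product against the previous heading wins, which prevents
#' 180-degree oscillation where the field runs perpendicular to the radial
#' direction (e.g. near the raphe).  Positions are kept in micrometers
#' internally so steps are isotropic on anisotropic pixel grids; the map is
#' sampled with bilinear doubled-angle interpolation.
#'
#' @name tracing
#' @keywords internal
NULL

## one step; pos_um length-2, prev_dir unit vector or NULL; `sampler` is a
## make_axial_sampler() closure
trace_step_um <- function(pos_um, sampler, geometry, r_um,
                          choose = c("min_dist", "max_dist"),
                          prev_dir = NULL) {
  choose <- match.arg(choose)
  px <- pos_um[1] / geometry$spacing_x
  py <- pos_um[2] / geometry$spacing_y
  smp <- sampler(px, py)
  if (!smp$valid) return(NULL)
  dir <- c(cos(smp$angle), sin(smp$angle))
  cand <- rbind(pos_um + r_um * dir, pos_um - r_um * dir)
  onh_um <- c(geometry$onh_xy[1] * geometry$spacing_x,
              geometry$onh_xy[2] * geometry$spacing_y)
  d <- sqrt(rowSums((cand - rep(onh_um, each = 2))^2))
  pick_dist <- if (choose == "min_dist") which.min(d) else which.max(d)
  if (is.null(prev_dir)) {
    pick <- pick_dist
  } else {
    dots <- c(sum(dir * prev_dir), -sum(dir * prev_dir))
    pick <- which.max(dots)              # heading rule wins on conflict
  }
  list(pos = cand[pick, ], dir = (cand[pick, ] - pos_um) / r_um)
}

#' Single tracing step
#'
#' Exposes one integration step: samples the orientation map at `pos`,
#' forms the two antipodal candidates at distance `r` pixels, and picks one
#' by the distance rule relative to the ONH center (ties with a previous
#' heading are resolved by the heading; see the package tracing notes).
#'
#' @param pos `(x, y)` pixel position.
#' @param om The orientation [axial_map()].
#' @param geometry A [retinal_geometry()].
#' @param r Step length in pixels (of the x pitch; steps are isotropic in
#'   micrometers).
#' @param choose `"min_dist"` (toward the ONH) or `"max_dist"` (away).
#' @param prev_dir Optional previous heading (unit vector, micrometers).
#' @return `(x, y)` pixel position of the accepted candidate.
#' @export
trace_step <- function(pos, om, geometry, r = 1,
                       choose = c("min_dist", "max_dist"), prev_dir = NULL) {
  choose <- match.arg(choose)
  pos_um <- c(pos[1] * geometry$spacing_x, pos[2] * geometry$spacing_y)
  st <- trace_step_um(pos_um, make_axial_sampler(om), geometry,
                      r * geometry$spacing_x, choose, prev_dir)
  if (is.null(st)) stop("position lies on an invalid pixel")
  c(st$pos[1] / geometry$spacing_x, st$pos[2] / geometry$spacing_y)
}

trace_result <- function(pts_um, geometry, r, seed, mode, termination) {
  pts <- if (length(pts_um)) do.call(rbind, pts_um) else
    matrix(numeric(0), 0, 2)
  tb <- tibble::tibble(
    x_px = pts[, 1] / geometry$spacing_x,
    y_px = pts[, 2] / geometry$spacing_y
  )
  structure(
    list(points = tb, step_px = r, seed = seed, direction_mode = mode,
         termination = termination, geometry = geometry),
    class = "rnfb_trace"
  )
}

#' @export
print.rnfb_trace <- function(x, ...) {
  cat(sprintf("<rnfb_trace> %s, %d points, terminated: %s\n",
              x$direction_mode, nrow(x$points), x$termination))
  invisible(x)
}

trace_core <- function(seed, om, geometry, r, max_steps, choose) {
  onh_um <- c(geometry$onh_xy[1] * geometry$spacing_x,
              geometry$onh_xy[2] * geometry$spacing_y)
  r_onh_um <- geometry$onh_radius_deg * geometry$um_per_deg
  lim_x <- ncol(om$values) * geometry$spacing_x
  lim_y <- nrow(om$values) * geometry$spacing_y
  pos <- c(seed[1] * geometry$spacing_x, seed[2] * geometry$spacing_y)
  inward <- choose == "min_dist"
  if (inward && sqrt(sum((pos - onh_um)^2)) <= r_onh_um) {
    return(trace_result(list(), geometry, r, seed, "inward", "onh_reached"))
  }
  pts <- vector("list", max_steps + 1)
  pts[[1]] <- pos
  np <- 1
  prev <- NULL
  term <- "max_steps"
  r_um <- r * geometry$spacing_x
  sampler <- make_axial_sampler(om)
  for (k in seq_len(max_steps)) {
    st <- trace_step_um(pos, sampler, geometry, r_um, choose, prev)
    if (is.null(st)) { term <- "invalid_pixel"; break }
    pos <- st$pos; prev <- st$dir
    if (pos[1] < geometry$spacing_x || pos[1] > lim_x ||
        pos[2] < geometry$spacing_y || pos[2] > lim_y) {
      term <- "boundary"; break
    }
    np <- np + 1
    pts[[np]] <- pos
    if (inward && sqrt(sum((pos - onh_um)^2)) <= r_onh_um) {
      term <- "onh_reached"; break
    }
  }
  mode <- if (inward) "inward" else "outward"
  trace_result(pts[seq_len(np)], geometry, r, seed, mode, term)
}

#' Trace a nerve fiber bundle inward to the ONH
#'
#' Integrates the orientation map from a seed toward the optic nerve head.
#' Inward tracing is the robust direction: bundle paths converge on the
#' ONH, so orientation errors shrink along the way instead of diverging.
#' The trace terminates on entering the ONH circle
#' (`geometry$onh_radius_deg`), on leaving the valid region, or after
#' `max_steps` steps.
#'
#' @param seed `(x, y)` seed pixel position (must be on a valid pixel).
#' @param om The orientation [axial_map()].
#' @param geometry A [retinal_geometry()].
#' @param r Step length in pixels (default 1).
#' @param max_steps Step budget (default 20000).
#' @return An `rnfb_trace`: ordered points (periphery first), step size,
#'   seed, mode and termination reason.
#' @export
trace_inward <- function(seed, om, geometry, r = 1, max_steps = 20000) {
  trace_core(seed, om, geometry, r, max_steps, "min_dist")
}

#' @rdname trace_inward
#' @export
trace_outward <- function(seed, om, geometry, r = 1, max_steps = 20000) {
  trace_core(seed, om, geometry, r, max_steps, "max_dist")
}

#' Trace the bundle passing through a point
#'
#' The practical use case: a position of interest (e.g. a visual field
#' test coordinate) is given and the whole bundle through it is wanted.
#' Two sub-traces are integrated -- one away from the ONH, one toward it --
#' and concatenated (reversed outward part, then the inward part), so the
#' result runs periphery to ONH with the seed appearing exactly once.
#'
#' @inheritParams trace_inward
#' @return An `rnfb_trace` with `direction_mode = "bidirectional"`; its
#'   termination reason is the inward sub-trace's.
#' @export
trace_through_point <- function(seed, om, geometry, r = 1,
                                max_steps = 20000) {
  out <- trace_outward(seed, om, geometry, r, max_steps)
  inw <- trace_inward(seed, om, geometry, r, max_steps)
  pts_out <- out$points[rev(seq_len(nrow(out$points))), ]
  pts <- rbind(pts_out[-nrow(pts_out), ], inw$points)
  res <- trace_result(list(), geometry, r, seed, "bidirectional",
                      inw$termination)
  res$points <- pts
  res
}

#' Map visual-field test coordinates onto the image
#'
#' Places 24-2 visual field test locations on the en-face image by the
#' similarity transform that superimposes the fovea and ONH centers: a
#' field point `(x_deg, y_deg)` (right-eye chart convention, temporal
#' field positive x, superior field positive y) lands on the retina at the
#' matching angular offset from the fovea, with the nasal field direction
#' aligned to the fovea-to-ONH axis and the superior field mapping to the
#' inferior retina (image inversion through the nodal point).
#'
#' @param vf Tibble with columns `x_deg`, `y_deg` (see [vf_grid_24_2()]).
#' @param geometry A [retinal_geometry()].
#' @return The input tibble with `x_px`, `y_px` columns added.
#' @export
vf_to_image <- function(vf, geometry) {
  f_um <- c(geometry$fovea_xy[1] * geometry$spacing_x,
            geometry$fovea_xy[2] * geometry$spacing_y)
  o_um <- c(geometry$onh_xy[1] * geometry$spacing_x,
            geometry$onh_xy[2] * geometry$spacing_y)
  u <- o_um - f_um
  scale <- sqrt(sum(u^2)) / 15          # um per degree from the landmarks
  u <- u / sqrt(sum(u^2))               # nasal retina direction
  v <- c(-u[2], u[1])                   # inferior retina direction (y down)
  ## VF temporal field (+x) -> nasal retina; VF superior (+y) -> inferior
  x_um <- f_um[1] + scale * (vf$x_deg * u[1] + vf$y_deg * v[1])
  y_um <- f_um[2] + scale * (vf$x_deg * u[2] + vf$y_deg * v[2])
  dplyr::mutate(vf,
                x_px = x_um / geometry$spacing_x,
                y_px = y_um / geometry$spacing_y)
}
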