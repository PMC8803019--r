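#' Phantom specification
#'
#' Describes a synthetic eye phantom: grid shape and physical spacing, eye
#' geometry, ridge texture parameters for the projection rendering, vessel
#' count, the true polarization parameters (axis offset and retardation),
#' volume depth and the RNG seed.  Identical spec + seed always produces
#' bit-identical outputs.
#'
#' The default phantom covers a 50 x 44 degree field at 32.8 micrometers
#' per pixel (the native fast-axis pitch of a 1024-A-scan 28-degree raster
#' downsampled 4x, used for both axes so the ridge texture stays resolved
#' on both: at the native slow-axis pitch of ~100 micrometers, realistic
#' bundle striations of 200-300 micrometer period would be at or under the
#' two-sample limit vertically and the rendered texture would alias).
#' The fovea sits 28.5 degrees from the left edge on the vertical midline
#' and the ONH 15 degrees nasal of it.  Ridge period 300 micrometers and
#' contrast 0.5 give bundle striations of the strength seen in good-SNR
#' projections; retardation 0.35 rad is typical peribundle RNFL
#' retardation, and the default 30-degree axis offset exercises the offset
#' calibration well inside the +/-90 degree search window.
#'
#' @param shape `(nrow, ncol)` of the en-face grid.
#' @param spacing_um Pixel pitch (isotropic), micrometers.
#' @param um_per_deg Retinal scale (default 300).
#' @param fovea_deg_from_left Fovea x position, degrees from the left edge.
#' @param ridge_period_um Center-to-center bundle spacing, micrometers.
#' @param ridge_contrast Ridge amplitude in `[0, 1]`.
#' @param noise_sigma Additive intensity noise SD (image units).
#' @param vessel_count Number of synthetic vessels.
#' @param axis_offset_true True polarization axis offset, degrees.
#' @param retardation_true True RNFL retardation, radians.
#' @param depth Volume depth in voxels.
#' @param rng_seed Integer seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(402, 457), spacing_um = 32.8,
                         um_per_deg = 300, fovea_deg_from_left = 28.5,
                         ridge_period_um = 300, ridge_contrast = 0.5,
                         noise_sigma = 0, vessel_count = 6,
                         axis_offset_true = 30, retardation_true = 0.35,
                         depth = 48, rng_seed = 1L) {
  px_per_deg <- um_per_deg / spacing_um
  fovea <- c(fovea_deg_from_left * px_per_deg, shape[1] / 2)
  onh <- fovea + c(15 * px_per_deg, 0)
  geometry <- retinal_geometry(fovea, onh, onh_radius_deg = 4,
                               um_per_deg = um_per_deg,
                               spacing_x = spacing_um,
                               spacing_y = spacing_um)
  structure(
    list(shape = shape, geometry = geometry,
         ridge_period_um = ridge_period_um, ridge_contrast = ridge_contrast,
         noise_sigma = noise_sigma, vessel_count = vessel_count,
         axis_offset_true = axis_offset_true,
         retardation_true = retardation_true, depth = depth,
         rng_seed = as.integer(rng_seed)),
    class = "phantom_spec"
  )
}

#' Ground-truth orientation field of a phantom
#'
#' Rasterizes the average-trajectory model for the phantom geometry and
#' fills the small regions the trajectory fan does not cover (the wedge on
#' the nasal horizontal just beyond the ONH, the raphe line and the ONH
#' interior) by doubled-angle diffusion from the surrounding field, giving
#' a dense valid field over the whole phantom extent that equals the model
#' field wherever trajectories exist.
#'
#' @param spec A [phantom_spec()].
#' @return A dense [axial_map()].
#' @export
make_truth_field <- function(spec) {
  g <- spec$geometry
  fit <- fit_to_eye(g$fovea_xy, g$onh_xy, g)
  m <- rasterize_model(fit, spec$shape)
  diffuse_fill_axial(m)
}

## stamp gaussian blobs at points (px coords) onto an accumulator matrix
stamp_points <- function(nr, nc, x, y, sigma_px, radius_px, amp = 1) {
  acc <- matrix(0, nr, nc)
  px <- round(x); py <- round(y)
  keep <- px >= 1 - radius_px & px <= nc + radius_px &
    py >= 1 - radius_px & py <= nr + radius_px
  x <- x[keep]; y <- y[keep]; px <- px[keep]; py <- py[keep]
  if (!length(x)) return(acc)
  for (dy in -radius_px:radius_px) {
    for (dx in -radius_px:radius_px) {
      tx <- px + dx; ty <- py + dy
      ok <- tx >= 1 & tx <= nc & ty >= 1 & ty <= nr
      if (!any(ok)) next
      d2 <- (x[ok] - tx[ok])^2 + (y[ok] - ty[ok])^2
      w <- amp * exp(-d2 / (2 * sigma_px^2))
      lin <- ty[ok] + (tx[ok] - 1) * nr
      agg <- rowsum(w, lin)
      idx <- as.integer(rownames(agg))
      acc[idx] <- acc[idx] + agg[, 1]
    }
  }
  acc
}

## evenly-spaced streamline seeding and integration through an axial field;
## returns sample points (px) every `step_px` along each line
streamlines_through_field <- function(truth, sep_px, step_px = 0.75,
                                      max_len_px = 4000) {
  nr <- nrow(truth$values); nc <- ncol(truth$values)
  cell <- max(1, floor(sep_px))
  occ_nr <- ceiling(nr / cell); occ_nc <- ceiling(nc / cell)
  occ <- matrix(FALSE, occ_nr, occ_nc)
  occ_idx <- function(x, y) {
    cbind(pmin(pmax(ceiling(y / cell), 1), occ_nr),
          pmin(pmax(ceiling(x / cell), 1), occ_nc))
  }
  seeds_x <- seq(1, nc, by = sep_px)
  seeds_y <- seq(1, nr, by = sep_px)
  seeds <- expand.grid(x = seeds_x, y = seeds_y)
  seeds <- seeds[sample.int(nrow(seeds)), ]       # randomized seeding order
  out_x <- list(); out_y <- list(); li <- 0
  sampler <- make_axial_sampler(truth)
  n_max <- round(max_len_px / step_px)
  check_every <- max(1, round(cell / step_px))

  integrate_dir <- function(x0, y0, sgn) {
    xs <- numeric(n_max); ys <- numeric(n_max); n <- 0
    x <- x0; y <- y0; prev <- NULL
    for (i in seq_len(n_max)) {
      smp <- sampler(x, y)
      if (!smp$valid) break
      d <- c(cos(smp$angle), sin(smp$angle))
      if (!is.null(prev) && sum(d * prev) < 0) d <- -d
      if (is.null(prev)) d <- sgn * d
      x <- x + step_px * d[1]; y <- y + step_px * d[2]
      if (x < 1 || x > nc || y < 1 || y > nr) break
      if (i %% check_every == 0 && occ[occ_idx(x, y)]) break
      n <- n + 1
      xs[n] <- x; ys[n] <- y
      prev <- d
    }
    list(x = xs[seq_len(n)], y = ys[seq_len(n)])
  }
  for (si in seq_len(nrow(seeds))) {
    x0 <- seeds$x[si]; y0 <- seeds$y[si]
    if (occ[occ_idx(x0, y0)]) next
    fwd <- integrate_dir(x0, y0, 1)
    bwd <- integrate_dir(x0, y0, -1)
    xs <- c(rev(bwd$x), x0, fwd$x)
    ys <- c(rev(bwd$y), y0, fwd$y)
    if (length(xs) < 3) next
    li <- li + 1
    out_x[[li]] <- xs; out_y[[li]] <- ys
    occ[occ_idx(xs, ys)] <- TRUE
  }
  list(x = unlist(out_x), y = unlist(out_y))
}

#' Render a ridge-textured RNFL projection from a truth field
#'
#' Emulates the en-face RNFL intensity projection: nerve fiber bundles
#' appear as bright ridges along the streamlines of the orientation field.
#' Streamlines are placed with even spacing (one ridge period apart),
#' integrated through the truth field with the same doubled-angle sampling
#' the tracer uses, and stroked with a Gaussian cross-profile -- so the
#' local orientation of the rendered texture equals the truth field by
#' construction.  Dark vessel curves are stamped on top and recorded in
#' the vessel mask, and additive Gaussian noise is applied last.
#'
#' @param truth A dense [axial_map()] (see [make_truth_field()]).
#' @param spec A [phantom_spec()].
#' @return A `projection_image` whose `values` lie in `[0, 1]`.
#' @export
render_projection <- function(truth, spec) {
  g <- spec$geometry
  nr <- spec$shape[1]; nc <- spec$shape[2]
  withr::local_seed(spec$rng_seed)
  period_px <- spec$ridge_period_um / g$spacing_x
  sigma_px <- period_px / 4
  img <- matrix(0.35, nr, nc)
  if (spec$ridge_contrast > 0) {
    sl <- streamlines_through_field(truth, sep_px = period_px)
    blob <- stamp_points(nr, nc, sl$x, sl$y, sigma_px,
                         radius_px = ceiling(3 * sigma_px))
    ## normalize the stroke accumulation to a unit ridge profile
    blob <- blob / stats::quantile(blob[blob > 0], 0.9)
    blob <- pmin(blob, 1.2)
    img <- img + spec$ridge_contrast * 0.5 * (blob - mean(blob))
  }
  vessel_mask <- matrix(FALSE, nr, nc)
  if (spec$vessel_count > 0) {
    onh <- g$onh_xy
    width_px <- max(2, round(60 / g$spacing_x))     # ~60 um vessels
    for (v in seq_len(spec$vessel_count)) {
      ## arcades: curves leaving the ONH up/down, arcing temporally
      side <- if (v %% 2 == 0) 1 else -1
      bend <- stats::runif(1, 0.004, 0.012)
      t <- seq(0, 1.2 * max(nr, nc), by = 1)
      ang0 <- side * stats::runif(1, 55, 100) * pi / 180
      vx <- onh[1] - t * cos(ang0) * 0.35 - bend * t^1.5
      vy <- onh[2] + t * sin(ang0) * sign(side) * 0.8
      keep <- vx >= 1 & vx <= nc & vy >= 1 & vy <= nr
      vb <- stamp_points(nr, nc, vx[keep], vy[keep], width_px / 2,
                         radius_px = width_px)
      vessel_mask <- vessel_mask | vb > 0.3
      img <- img - 0.5 * pmin(vb, 1)
    }
  }
  if (spec$noise_sigma > 0) {
    img <- img + matrix(stats::rnorm(nr * nc, 0, spec$noise_sigma), nr, nc)
  }
  img <- pmin(pmax(img, 0), 1)
  structure(
    list(values = img, vessel_mask = vessel_mask,
         valid = matrix(TRUE, nr, nc), band = matrix(1, nr, nc),
         max_len = NA_integer_, spacing_x = g$spacing_x,
         spacing_y = g$spacing_y),
    class = "projection_image"
  )
}

#' Render a PS-OCT stack from a truth field
#'
#' Emulates the polarization volumes: the optic axis is constant in depth,
#' rotated away from the truth orientation by the phantom's axis offset
#' (expressed in the instrument's Stokes convention, i.e. including its
#' fixed quarter-turn, so that [extract_polarization_maps()] yields
#' `truth - axis_offset_true` -- the calibration search then recovers
#' `+axis_offset_true` as the compensating offset), the retardation is
#' depth-constant at the
#' true value, and optional per-voxel angular noise is added to both.
#' Layer boundaries are smooth synthetic surfaces with the RNFL thickness
#' varying between about 5 and 40 voxels (thick near the ONH, thin at the
#' periphery and fovea).  The intensity volume carries the projection
#' image (if given) as a bright band just above the RNFL/GCL boundary so
#' that [project_rnfl()] recovers it.
#'
#' @param truth A dense [axial_map()].
#' @param spec A [phantom_spec()].
#' @param projection Optional `projection_image` to embed in the
#'   intensity volume.
#' @param axis_noise_sd Per-voxel angular noise SD on the axis volume,
#'   radians (default 0).
#' @param ret_noise_sd Per-voxel retardation noise SD, radians (default 0).
#' @return A [psoct_stack()].
#' @export
render_psoct <- function(truth, spec, projection = NULL,
                         axis_noise_sd = 0, ret_noise_sd = 0) {
  g <- spec$geometry
  nr <- spec$shape[1]; nc <- spec$shape[2]
  nz <- spec$depth
  withr::local_seed(spec$rng_seed + 1L)
  xs <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  ys <- matrix(rep(seq_len(nr), nc), nr, nc)
  r_onh_deg <- sqrt(((xs - g$onh_xy[1]) * g$spacing_x)^2 +
                    ((ys - g$onh_xy[2]) * g$spacing_y)^2) / g$um_per_deg
  r_fov_deg <- sqrt(((xs - g$fovea_xy[1]) * g$spacing_x)^2 +
                    ((ys - g$fovea_xy[2]) * g$spacing_y)^2) / g$um_per_deg
  ilm <- matrix(3, nr, nc) + round(2 * sin(xs / 40) * cos(ys / 40))
  thick <- round(5 + 35 * exp(-r_onh_deg / 10) * pmin(r_fov_deg / 3, 1))
  thick <- pmin(pmax(thick, 5), 40)
  bng <- ilm + thick
  boo <- pmin(bng + 12, nz)
  theta0 <- fold_axial(truth$values + (90 - spec$axis_offset_true) * pi / 180)
  axis <- array(rep(theta0, nz), dim = c(nr, nc, nz))
  ret <- array(spec$retardation_true, dim = c(nr, nc, nz))
  if (axis_noise_sd > 0) {
    axis <- fold_axial(axis + array(stats::rnorm(length(axis), 0,
                                                 axis_noise_sd),
                                    dim = dim(axis)))
  }
  if (ret_noise_sd > 0) {
    ret <- ret + array(stats::rnorm(length(ret), 0, ret_noise_sd),
                       dim = dim(ret))
    ret <- pmin(pmax(ret, 0), pi / 2)
  }
  intensity <- array(0.1, dim = c(nr, nc, nz))
  if (!is.null(projection)) {
    for (i in 1:8) {
      z <- bng - i
      inc <- z >= 1
      lin <- which(inc) + (z[inc] - 1) * nr * nc
      intensity[lin] <- projection$values[inc]
    }
  }
  psoct_stack(intensity, ret, axis,
              list(ilm = ilm, rnfl_gcl = bng, opl_onl = boo),
              spacing_x = g$spacing_x, spacing_y = g$spacing_y)
}

#' Degrade data with calibrated noise and dropout
#'
#' Adds Gaussian noise calibrated to a target signal-to-noise ratio and
#' knocks out a random fraction of the support (invalid regions for
#' orientation maps, `NA` blocks for plain matrices/arrays).  The noise SD
#' is `rms(signal - mean) / 10^(snr_db / 20)`; for orientation maps the
#' noise is angular (radians on the axial angle, with sigma such that the
#' doubled-angle components have the target SNR).  Deterministic for a
#' given seed.
#'
#' @param x A matrix, 3-D array or [axial_map()].
#' @param snr_db Signal-to-noise ratio in dB (`Inf` = no noise).
#' @param dropout_fraction Fraction of pixels invalidated in random blocks.
#' @param seed Integer seed.
#' @return Same type as `x`.
#' @export
degrade <- function(x, snr_db = Inf, dropout_fraction = 0, seed = 1L) {
  UseMethod("degrade")
}

dropout_mask <- function(nr, nc, fraction) {
  drop <- matrix(FALSE, nr, nc)
  if (fraction <= 0) return(drop)
  block <- max(3, round(sqrt(nr * nc) / 40))
  target <- fraction * nr * nc
  guard <- 0
  while (sum(drop) < target && guard < 100000) {
    cx <- sample.int(nc, 1); cy <- sample.int(nr, 1)
    xs <- max(1, cx - block):min(nc, cx + block)
    ys <- max(1, cy - block):min(nr, cy + block)
    drop[ys, xs] <- TRUE
    guard <- guard + 1
  }
  drop
}

#' @export
degrade.matrix <- function(x, snr_db = Inf, dropout_fraction = 0,
                           seed = 1L) {
  withr::local_seed(as.integer(seed))
  out <- x
  if (is.finite(snr_db)) {
    sig <- stats::sd(as.vector(x), na.rm = TRUE)
    out <- out + matrix(stats::rnorm(length(x), 0,
                                     sig / 10^(snr_db / 20)),
                        nrow(x), ncol(x))
  }
  drop <- dropout_mask(nrow(x), ncol(x), dropout_fraction)
  out[drop] <- NA_real_
  out
}

#' @export
degrade.array <- function(x, snr_db = Inf, dropout_fraction = 0,
                          seed = 1L) {
  withr::local_seed(as.integer(seed))
  out <- x
  if (is.finite(snr_db)) {
    sig <- stats::sd(as.vector(x), na.rm = TRUE)
    out <- out + array(stats::rnorm(length(x), 0, sig / 10^(snr_db / 20)),
                       dim = dim(x))
  }
  if (dropout_fraction > 0) {
    drop <- dropout_mask(dim(x)[1], dim(x)[2], dropout_fraction)
    out[rep(drop, length.out = length(out))] <- NA_real_
  }
  out
}

#' @export
degrade.axial_map <- function(x, snr_db = Inf, dropout_fraction = 0,
                              seed = 1L) {
  withr::local_seed(as.integer(seed))
  vals <- x$values
  if (is.finite(snr_db)) {
    ## unit doubled-angle vectors have RMS amplitude 1; component noise of
    ## sd 10^(-snr/20) corresponds to angular noise of half that (radians)
    ang_sd <- 0.5 * 10^(-snr_db / 20)
    vals <- fold_axial(vals + matrix(stats::rnorm(length(vals), 0, ang_sd),
                                     nrow(vals), ncol(vals)))
  }
  valid <- x$valid & !dropout_mask(nrow(vals), ncol(vals), dropout_fraction)
  vals[!valid] <- NA_real_
  axial_map(vals, valid, x$spacing_x, x$spacing_y)
}

#' Generate a complete phantom dataset
#'
#' Runs [make_truth_field()], [render_projection()] and [render_psoct()]
#' and returns everything a pipeline run needs, optionally writing the
#' standard file formats to a directory.
#'
#' @param spec A [phantom_spec()].
#' @param dir Optional output directory.
#' @param axis_noise_sd,ret_noise_sd Per-voxel polarization noise
#'   (radians), passed to [render_psoct()].
#' @return List with `truth`, `projection`, `stack`, `geometry`, `spec`.
#' @export
simulate_phantom <- function(spec, dir = NULL, axis_noise_sd = 0,
                             ret_noise_sd = 0) {
  truth <- make_truth_field(spec)
  proj <- render_projection(truth, spec)
  stack <- render_psoct(truth, spec, projection = proj,
                        axis_noise_sd = axis_noise_sd,
                        ret_noise_sd = ret_noise_sd)
  out <- list(truth = truth, projection = proj, stack = stack,
              geometry = spec$geometry, spec = spec)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_axial_map(truth, file.path(dir, "truth"))
    write_geometry(spec$geometry, file.path(dir, "geometry.json"))
    tiff::writeTIFF(proj$values, file.path(dir, "projection.tif"),
                    bits.per.sample = 32L)
    tiff::writeTIFF(proj$vessel_mask * 1, file.path(dir, "vessels.tif"),
                    bits.per.sample = 8L)
  }
  out
}
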