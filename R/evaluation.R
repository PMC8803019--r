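#' Polar resampling of a trace around the ONH
#'
#' Transforms a trace to polar coordinates centered on the ONH: radius in
#' degrees of eccentricity and angle in degrees, with 0 at the temporal
#' horizontal (the fovea direction) and superior positive (right-eye
#' convention).  Angles are unwrapped along the trace so consecutive
#' samples never jump by 360 degrees, then linearly interpolated onto a
#' fixed radial grid (step `dr`) from the ONH entry circle outward.  The
#' entry angle (EA) is the angle at which the trace crosses the entry
#' circle (`geometry$onh_radius_deg`); it is `NA`, flagged, for traces
#' that never reach it.
#'
#' @param trace An `rnfb_trace` (or a 2-column matrix / tibble of x, y
#'   pixel coordinates ordered along the trace).
#' @param geometry A [retinal_geometry()].
#' @param dr Radial grid step in degrees (default 0.1).
#' @return An object of class `rnfb_polar_trace`: tibble `samples`
#'   (`r`, `angle`, degrees; angle on a continuous, unwrapped scale),
#'   `entry_angle` (degrees in (-180, 180], or `NA`), `reaches_entry`.
#' @export
to_polar <- function(trace, geometry, dr = 0.1) {
  pts <- if (inherits(trace, "rnfb_trace")) {
    cbind(trace$points$x_px, trace$points$y_px)
  } else {
    as.matrix(trace)[, 1:2, drop = FALSE]
  }
  if (nrow(pts) == 0) stop("empty trace")
  f_um <- c(geometry$fovea_xy[1] * geometry$spacing_x,
            geometry$fovea_xy[2] * geometry$spacing_y)
  o_um <- c(geometry$onh_xy[1] * geometry$spacing_x,
            geometry$onh_xy[2] * geometry$spacing_y)
  u_t <- (f_um - o_um) / sqrt(sum((f_um - o_um)^2))   # temporal direction
  vx <- pts[, 1] * geometry$spacing_x - o_um[1]
  vy <- pts[, 2] * geometry$spacing_y - o_um[2]
  r_deg <- sqrt(vx^2 + vy^2) / geometry$um_per_deg
  ## signed angle from the temporal direction, superior (image up) positive
  ang <- atan2(u_t[1] * vy - u_t[2] * vx, u_t[1] * vx + u_t[2] * vy) *
    180 / pi
  if (length(ang) > 1) {
    ang <- ang[1] + c(0, cumsum(wrap180(diff(ang))))   # unwrap along trace
  }
  r0 <- geometry$onh_radius_deg
  ## follow the polyline from its ONH-side endpoint outward, keeping only
  ## strictly increasing radii: this yields a single-valued angle(r) even
  ## when the peripheral end of a trace curls back (e.g. at the raphe),
  ## instead of mixing the branches of a radius-non-monotone path
  n_pts <- length(r_deg)
  idx <- if (r_deg[n_pts] <= r_deg[1]) seq(n_pts, 1) else seq(1, n_pts)
  rr <- r_deg[idx]
  cm <- cummax(rr)
  sel <- rr == cm & !duplicated(cm)
  r_s <- rr[sel]; a_s <- ang[idx][sel]
  grid <- seq(r0, max(r_s), by = dr)
  grid <- grid[grid >= min(r_s) - 1e-9]
  samples <- if (length(grid) >= 1 && length(unique(r_s)) >= 2) {
    tibble::tibble(
      r = grid,
      angle = stats::approx(r_s, a_s, xout = grid, ties = mean,
                            rule = 1)$y
    )
  } else {
    tibble::tibble(r = numeric(0), angle = numeric(0))
  }
  samples <- samples[is.finite(samples$angle), ]
  reaches <- r_deg[idx[1]] <= r0 + 1e-9
  ea <- if (reaches && nrow(samples) > 0 && abs(samples$r[1] - r0) < dr) {
    wrap180(samples$angle[1])
  } else if (reaches) {
    wrap180(ang[idx[1]])
  } else {
    NA_real_
  }
  structure(
    list(samples = samples, entry_angle = ea, reaches_entry = reaches),
    class = "rnfb_polar_trace"
  )
}

#' @export
print.rnfb_polar_trace <- function(x, ...) {
  cat(sprintf("<rnfb_polar_trace> %d radial samples, EA = %s\n",
              nrow(x$samples),
              if (is.na(x$entry_angle)) "undefined"
              else sprintf("%.1f deg", x$entry_angle)))
  invisible(x)
}

#' Entry-angle range and offset of a trace group
#'
#' Agreement statistics for the entry angles of one trace observed by
#' several raters (or repetitions): the range is the maximum pairwise
#' circular distance (the max-minus-min spread compensated for the
#' 360-degree wraparound) and the offset is the mean circular distance of
#' each entry angle from their circular mean.
#'
#' @param eas Numeric vector of entry angles in degrees (length >= 2).
#' @return List with `range` and `offset`, degrees.
#' @export
entry_angle_stats <- function(eas) {
  stopifnot(length(eas) >= 2, all(is.finite(eas)))
  pair <- outer(eas, eas, function(a, b) abs(wrap180(a - b)))
  mu <- circ_mean_deg(eas)
  list(range = max(pair), offset = mean(abs(wrap180(eas - mu))))
}

#' Intraclass correlation ICC(A,k) of entry angles
#'
#' Two-way random-effects, absolute-agreement, average-of-k-raters
#' intraclass correlation of an entry-angle matrix (rows = traces,
#' columns = raters), computed from the classical mean squares:
#' \deqn{ICC(A,k) = \frac{MS_R - MS_E}{MS_R + (MS_C - MS_E) / n},}
#' with \eqn{MS_R}, \eqn{MS_C}, \eqn{MS_E} the row, column and residual
#' mean squares and \eqn{n} the number of traces.  Before the ANOVA each
#' trace's angles are wraparound-compensated: unwrapped to lie within 180
#' degrees of that trace's circular mean, so a rater reporting 359 and one
#' reporting 1 degree disagree by 2 degrees, not 358.
#'
#' @param ea_matrix Numeric matrix of entry angles, degrees,
#'   traces x raters (>= 2 of each, no missing values).
#' @return The ICC(A,k) value.
#' @export
icc_ak <- function(ea_matrix) {
  m <- as.matrix(ea_matrix)
  stopifnot(nrow(m) >= 2, ncol(m) >= 2, all(is.finite(m)))
  ## wraparound compensation per trace
  for (i in seq_len(nrow(m))) {
    mu <- circ_mean_deg(m[i, ])
    m[i, ] <- mu + wrap180(m[i, ] - mu)
  }
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ss_r <- k * sum((row_m - grand)^2)
  ss_c <- n * sum((col_m - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_e <- ss_tot - ss_r - ss_c
  ms_r <- ss_r / (n - 1)
  ms_c <- ss_c / (k - 1)
  ms_e <- ss_e / ((n - 1) * (k - 1))
  if (ms_r < 1e-12 * max(1, abs(grand))) {
    stop("undefined ICC: no between-trace variance")
  }
  (ms_r - ms_e) / (ms_r + (ms_c - ms_e) / n)
}

#' Root-mean-square distance between traces in polar resampling
#'
#' Compares traces along their shared radial support: at every shared
#' radial sample the wraparound-minimal angular difference is converted to
#' arc length (`angle_rad * r_deg * um_per_deg`) and squared; each
#' comparison trace gets the square root of its mean squared arc distance
#' to the reference, and the returned RMSE is the mean over comparison
#' traces.
#'
#' @param reference An `rnfb_polar_trace` (e.g. the rater-average trace).
#' @param others One `rnfb_polar_trace` or a list of them.
#' @param geometry A [retinal_geometry()].
#' @param min_overlap_deg Minimum shared radial support (default 1 degree).
#' @return List with `rmse_um` (mean over traces) and `per_trace_um`.
#' @export
trace_rmse <- function(reference, others, geometry, min_overlap_deg = 1) {
  if (inherits(others, "rnfb_polar_trace")) others <- list(others)
  per <- vapply(others, function(tr) {
    merged <- dplyr::inner_join(reference$samples, tr$samples, by = "r",
                                suffix = c("_a", "_b"))
    if (nrow(merged) == 0 ||
        diff(range(merged$r)) < min_overlap_deg - 1e-9) {
      stop("traces share less than the minimum radial overlap")
    }
    d_deg <- wrap180(merged$angle_a - merged$angle_b)
    arc <- abs(d_deg) * pi / 180 * merged$r * geometry$um_per_deg
    sqrt(mean(arc^2))
  }, numeric(1))
  list(rmse_um = mean(per), per_trace_um = per)
}

#' Per-radius circular average of polar traces
#'
#' The rater-average trace: at every radial grid value covered by at least
#' `min_traces` traces, the circular mean of their angles.
#'
#' @param traces List of `rnfb_polar_trace`.
#' @param min_traces Minimum contributing traces per radius (default 2).
#' @return An `rnfb_polar_trace`.
#' @export
mean_polar_trace <- function(traces, min_traces = 2) {
  all_s <- dplyr::bind_rows(lapply(traces, function(t) t$samples))
  avg <- all_s |>
    dplyr::group_by(.data$r) |>
    dplyr::summarise(
      n = dplyr::n(),
      angle = atan2(mean(sin(.data$angle * pi / 180)),
                    mean(cos(.data$angle * pi / 180))) * 180 / pi,
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n >= min_traces) |>
    dplyr::select("r", "angle")
  eas <- vapply(traces, function(t) t$entry_angle, numeric(1))
  ea <- if (all(is.finite(eas))) wrap180(circ_mean_deg(eas)) else NA_real_
  structure(
    list(samples = avg, entry_angle = ea, reaches_entry = !is.na(ea)),
    class = "rnfb_polar_trace"
  )
}

#' Agreement report across raters and ONH sectors
#'
#' Builds the per-sector agreement table for a set of traces observed by
#' several raters (or algorithm repetitions -- the reproducibility question
#' over repeated datasets is the same question as the variability of
#' several graders on one dataset).  Traces are grouped into the six
#' Garway-Heath ONH sectors by their visual-field starting point; each
#' sector row carries the mean (and SD over traces) of the entry-angle
#' range and offset, the polar trace RMSE against the reference, the
#' entry-angle ICC(A,k), and the trace count.  An `overall` row aggregates
#' every trace.
#'
#' @param trace_sets Named list (one element per rater) of lists of
#'   `rnfb_polar_trace`, each keyed / ordered by visual-field point id.
#' @param vf Tibble with columns `id`, `sector` ([vf_grid_24_2()]).
#' @param geometry A [retinal_geometry()].
#' @param reference External reference traces (same keying) or `NULL`
#'   (default) for the per-radius circular mean of the raters.
#' @return A tibble of class `rnfb_agreement` with one row per sector plus
#'   `overall`: columns `sector`, `n`, `ea_range`, `ea_range_sd`,
#'   `ea_offset`, `ea_offset_sd`, `rmse_um`, `rmse_sd`, `ea_icc`, `note`.
#' @export
build_report <- function(trace_sets, vf, geometry, reference = NULL) {
  stopifnot(length(trace_sets) >= 2)
  raters <- names(trace_sets)
  ids <- vf$id
  per_point <- purrr::map(ids, function(id) {
    polars <- purrr::map(trace_sets, ~ .x[[as.character(id)]])
    if (any(vapply(polars, is.null, logical(1)))) return(NULL)
    eas <- vapply(polars, function(p) p$entry_angle, numeric(1))
    if (any(!is.finite(eas))) return(NULL)
    st <- entry_angle_stats(eas)
    ref <- if (is.null(reference)) {
      mean_polar_trace(polars)
    } else {
      reference[[as.character(id)]]
    }
    rmse <- tryCatch(trace_rmse(ref, polars, geometry)$rmse_um,
                     error = function(e) NA_real_)
    tibble::tibble(id = id, ea_range = st$range, ea_offset = st$offset,
                   rmse_um = rmse,
                   !!!stats::setNames(as.list(eas), paste0("ea_", raters)))
  })
  pts <- dplyr::bind_rows(per_point)
  if (nrow(pts) == 0) stop("no visual-field point has a full set of traces")
  pts <- dplyr::left_join(pts, vf[, c("id", "sector")], by = "id")

  sector_row <- function(df, label) {
    n <- nrow(df)
    if (n < 2) {
      return(tibble::tibble(
        sector = label, n = n, ea_range = NA_real_, ea_range_sd = NA_real_,
        ea_offset = NA_real_, ea_offset_sd = NA_real_, rmse_um = NA_real_,
        rmse_sd = NA_real_, ea_icc = NA_real_,
        note = "insufficient traces"))
    }
    ea_mat <- as.matrix(df[, paste0("ea_", raters)])
    icc <- tryCatch(icc_ak(ea_mat), error = function(e) NA_real_)
    tibble::tibble(
      sector = label, n = n,
      ea_range = mean(df$ea_range), ea_range_sd = stats::sd(df$ea_range),
      ea_offset = mean(df$ea_offset), ea_offset_sd = stats::sd(df$ea_offset),
      rmse_um = mean(df$rmse_um, na.rm = TRUE),
      rmse_sd = stats::sd(df$rmse_um, na.rm = TRUE),
      ea_icc = icc, note = ""
    )
  }
  sectors <- c("T", "ST", "IT", "SN", "IN", "N")
  rows <- purrr::map(sectors, function(s) {
    sector_row(dplyr::filter(pts, .data$sector == s), s)
  })
  rows <- c(rows, list(sector_row(pts, "overall")))
  out <- dplyr::bind_rows(rows)
  class(out) <- c("rnfb_agreement", class(out))
  attr(out, "per_point") <- pts
  out
}

#' The 24-2 visual field test grid with Garway-Heath sectors
#'
#' The 52 non-blind-spot locations of the 24-2 test pattern (degrees,
#' right-eye chart convention: temporal field positive x, superior field
#' positive y; the two blind-spot points at (15, +/-3) are excluded), each
#' labeled with the Garway-Heath ONH sector its nerve fiber bundle enters:
#' temporal (T), superior temporal (ST), inferior temporal (IT), superior
#' nasal (SN), inferior nasal (IN), nasal (N).  The sector labels ship as
#' an editable CSV (`garway_heath_24-2_sectors_synthetic.csv`); the copy
#' installed with the package was derived from the average-trajectory
#' model by binning each point's model entry angle into the published
#' sector boundaries on the ONH circle (temporal 311--40, ST 41--80,
#' SN 81--120, nasal 121--230, IN 231--270, IT 271--310 degrees), so it is
#' a model-derived stand-in for the original hand-drawn map.
#'
#' @param sector_csv Path to an alternative sector CSV (columns `id`,
#'   `sector`); default the installed fixture.
#' @return Tibble with columns `id`, `x_deg`, `y_deg`, `sector`.
#' @export
vf_grid_24_2 <- function(sector_csv = NULL) {
  rows <- list(
    list(y = 21,  x = seq(-9, 9, by = 6)),
    list(y = 15,  x = seq(-15, 15, by = 6)),
    list(y = 9,   x = seq(-21, 21, by = 6)),
    list(y = 3,   x = seq(-27, 21, by = 6)),
    list(y = -3,  x = seq(-27, 21, by = 6)),
    list(y = -9,  x = seq(-21, 21, by = 6)),
    list(y = -15, x = seq(-15, 15, by = 6)),
    list(y = -21, x = seq(-9, 9, by = 6))
  )
  g <- dplyr::bind_rows(purrr::map(rows, function(rw) {
    tibble::tibble(x_deg = rw$x, y_deg = rw$y)
  }))
  g <- dplyr::filter(g, !(.data$x_deg == 15 & abs(.data$y_deg) == 3))
  g <- dplyr::arrange(g, dplyr::desc(.data$y_deg), .data$x_deg)
  g$id <- seq_len(nrow(g))
  if (is.null(sector_csv)) {
    sector_csv <- system.file("extdata",
                              "garway_heath_24-2_sectors_synthetic.csv",
                              package = "rnfbtrace")
  }
  sec <- tibble::as_tibble(utils::read.csv(sector_csv))
  dplyr::left_join(g[, c("id", "x_deg", "y_deg")], sec, by = "id")
}

#' Garway-Heath sector of an ONH entry angle
#'
#' @param ea_deg Entry angle(s), degrees, 0 at the temporal horizontal,
#'   superior positive.
#' @return Character vector of sector labels.
#' @export
sector_of_entry_angle <- function(ea_deg) {
  a <- wrap180(ea_deg)
  dplyr::case_when(
    a > -50 & a <= 40 ~ "T",
    a > 40 & a <= 80 ~ "ST",
    a > 80 & a <= 120 ~ "SN",
    a > 120 | a <= -130 ~ "N",
    a > -130 & a <= -90 ~ "IN",
    TRUE ~ "IT"
  )
}
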