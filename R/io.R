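#' Read and write the package's file formats
#'
#' Orientation maps travel as a pair of TIFFs: a 2-channel 32-bit float
#' image holding the doubled-angle components `(sin 2 phi, cos 2 phi)` --
#' which round-trips exactly through the wraparound -- and an 8-bit
#' validity image.  Geometry goes to JSON; traces to CSV polylines plus a
#' JSON bundle with termination metadata; volumes to multi-page float
#' TIFF stacks.
#'
#' @param m An [axial_map()].
#' @param path Base path; `write_axial_map()` writes `<path>.tif` and
#'   `<path>_valid.tif`.
#' @return `read_axial_map()` returns an [axial_map()].
#' @export
write_axial_map <- function(m, path) {
  nr <- nrow(m$values); nc <- ncol(m$values)
  s <- sin(2 * m$values); c <- cos(2 * m$values)
  s[!m$valid] <- 0; c[!m$valid] <- 0
  ## components live in [-1, 1]; TIFF samples are clamped to [0, 1], so
  ## store (x + 1) / 2 (one page per channel) and undo on read
  tiff::writeTIFF(list((s + 1) / 2, (c + 1) / 2), paste0(path, ".tif"),
                  bits.per.sample = 32L, reduce = FALSE)
  tiff::writeTIFF(matrix(as.numeric(m$valid), nr, nc),
                  paste0(path, "_valid.tif"), bits.per.sample = 8L)
  ## spacing sidecar
  jsonlite::write_json(list(spacing_x = m$spacing_x,
                            spacing_y = m$spacing_y),
                       paste0(path, "_meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_axial_map
#' @export
read_axial_map <- function(path) {
  pages <- tiff::readTIFF(paste0(path, ".tif"), all = TRUE)
  valid <- tiff::readTIFF(paste0(path, "_valid.tif")) > 0.5
  meta <- jsonlite::read_json(paste0(path, "_meta.json"))
  vals <- axial_from_components(pages[[1]] * 2 - 1, pages[[2]] * 2 - 1)
  vals <- matrix(vals, nrow(valid), ncol(valid))
  vals[!valid] <- NA_real_
  axial_map(vals, valid, meta$spacing_x, meta$spacing_y)
}

#' @rdname write_axial_map
#' @param geometry A [retinal_geometry()].
#' @export
write_geometry <- function(geometry, path) {
  jsonlite::write_json(
    list(fovea_xy = geometry$fovea_xy, onh_xy = geometry$onh_xy,
         onh_radius_deg = geometry$onh_radius_deg,
         um_per_deg = geometry$um_per_deg,
         spacing_um = c(geometry$spacing_x, geometry$spacing_y)),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_axial_map
#' @export
read_geometry <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  retinal_geometry(j$fovea_xy, j$onh_xy, j$onh_radius_deg, j$um_per_deg,
                   j$spacing_um[1], j$spacing_um[2])
}

#' @rdname write_axial_map
#' @param traces Named list of `rnfb_trace` objects.
#' @param dir Output directory for the CSV polylines and JSON bundle.
#' @export
write_traces <- function(traces, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- purrr::imap(traces, function(tr, nm) {
    utils::write.csv(tr$points,
                     file.path(dir, paste0("trace_", nm, ".csv")),
                     row.names = FALSE)
    list(id = nm, n_points = nrow(tr$points), step_px = tr$step_px,
         seed = tr$seed, direction_mode = tr$direction_mode,
         termination = tr$termination)
  })
  jsonlite::write_json(unname(meta), file.path(dir, "traces.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_axial_map
#' @param volume 3-D array `[y, x, z]`, values scaled into `[0, 1]` by the
#'   caller.
#' @export
write_volume <- function(volume, path) {
  pages <- lapply(seq_len(dim(volume)[3]), function(i) volume[, , i])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' @rdname write_axial_map
#' @export
read_volume <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
}
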