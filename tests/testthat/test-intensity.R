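## render a sinusoidal grating with ridges along axial angle `theta`
grating <- function(theta, n = 80, period = 8, spacing = 1) {
  xs <- matrix(rep(seq_len(n), each = n), n, n)
  ys <- matrix(rep(seq_len(n), n), n, n)
  ## phase varies along the ridge normal
  phase <- (-sin(theta) * xs + cos(theta) * ys) * 2 * pi / period
  structure(
    list(values = 0.5 + 0.4 * sin(phase),
         vessel_mask = matrix(FALSE, n, n),
         valid = matrix(TRUE, n, n), band = matrix(1, n, n),
         max_len = NA, spacing_x = spacing, spacing_y = spacing),
    class = "projection_image"
  )
}

test_that("project_rnfl averages exactly the band above the boundary", {
  nr <- 6; nc <- 7; nz <- 20
  vol <- array(7, c(nr, nc, nz))
  bnd <- list(ilm = matrix(2, nr, nc), rnfl_gcl = matrix(14, nr, nc))
  p <- project_rnfl(vol, bnd, max_len = 15)
  expect_equal(p$values, matrix(7, nr, nc))
  ## thickness 10 < max_len 15: band clamps to 10
  bnd2 <- list(ilm = matrix(4, nr, nc), rnfl_gcl = matrix(14, nr, nc))
  p2 <- project_rnfl(vol, bnd2, max_len = 15)
  expect_equal(p2$band, matrix(10, nr, nc))

  ## bright lamina at BNG - 1 only, verified against a direct loop
  withr::with_seed(14, vol3 <- array(runif(nr * nc * nz), c(nr, nc, nz)))
  bng <- matrix(sample(8:14, nr * nc, TRUE), nr, nc)
  bnd3 <- list(ilm = matrix(1, nr, nc), rnfl_gcl = bng)
  p3 <- project_rnfl(vol3, bnd3, max_len = 5)
  oracle <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    be <- min(bng[i, j] - 1, 5)
    oracle[i, j] <- mean(vol3[i, j, (bng[i, j] - be):(bng[i, j] - 1)])
  }
  expect_equal(p3$values, oracle, tolerance = 1e-12)

  ## zero band -> invalid
  bnd4 <- list(ilm = matrix(5, nr, nc), rnfl_gcl = matrix(5, nr, nc))
  p4 <- project_rnfl(vol, bnd4)
  expect_true(all(is.na(p4$values)))
  expect_false(any(p4$valid))
})

test_that("normalization removes slow trends and fixes the range", {
  n <- 101
  xs <- matrix(rep(seq_len(n), each = n), n, n)
  g <- grating(pi / 6, n = n, period = 8)
  g$values <- g$values + 0.01 * xs           # smooth ramp
  out <- normalize_projection(g, window = 31)
  expect_true(all(out$values >= 0 & out$values <= 1))
  expect_equal(min(out$values), 0)
  expect_equal(max(out$values), 1)
  ## ramp suppressed: local means hover around mid-scale
  loc <- box_mean_masked(out$values, matrix(TRUE, n, n), 15, 15)
  inner <- loc[20:80, 20:80]
  expect_lt(max(abs(inner - 0.5)), 0.07)

  ## constant image flagged degenerate
  g2 <- g; g2$values <- matrix(0.3, n, n)
  out2 <- normalize_projection(g2, window = 31)
  expect_true(attr(out2, "degenerate"))
  expect_equal(out2$values, matrix(0.5, n, n))
  expect_error(normalize_projection(g, window = 30), "window")
})

test_that("structure tensor recovers grating orientation", {
  for (th in c(30, 75, 120) * pi / 180) {
    g <- normalize_projection(grating(th), window = 31)
    phi <- initial_orientation(g, N = 7)
    inner <- phi$values[20:60, 20:60]
    err <- axial_err_deg(inner, matrix(th, 41, 41))
    expect_lt(stats::median(err), 1)
  }
  ## rotating the grating by 90 degrees rotates the estimate by 90
  g1 <- normalize_projection(grating(0.4), window = 31)
  g2 <- normalize_projection(grating(0.4 + pi / 2), window = 31)
  p1 <- initial_orientation(g1); p2 <- initial_orientation(g2)
  d <- axial_err_deg(p1$values[25:55, 25:55] + pi / 2,
                     p2$values[25:55, 25:55])
  expect_lt(stats::median(d), 2)

  ## uniform image: no gradients anywhere, everything invalid
  u <- grating(0.3); u$values <- matrix(0.5, 80, 80)
  expect_false(any(initial_orientation(u)$valid))
})

test_that("windowed operations ignore vessel pixels entirely", {
  g <- normalize_projection(grating(pi / 3), window = 31)
  mask <- matrix(FALSE, 80, 80); mask[30:35, 30:35] <- TRUE
  g1 <- g; g1$vessel_mask <- mask
  g2 <- g1
  g2$values[mask] <- 123  # arbitrary garbage under the mask
  p1 <- initial_orientation(g1)
  p2 <- initial_orientation(g2)
  expect_equal(p1$values, p2$values)
  expect_equal(p1$valid, p2$valid)
})

test_that("model and neighbor distance maps behave as distances", {
  withr::with_seed(15, v <- matrix(runif(400, 0, pi), 20, 20))
  m1 <- axial_map(v)
  expect_equal(model_distance_map(m1, m1), matrix(0, 20, 20))
  m2 <- axial_map(fold_axial(v + pi / 2))
  expect_equal(model_distance_map(m1, m2), matrix(2, 20, 20),
               tolerance = 1e-12)
  ## random pair vs the per-pixel scalar oracle
  withr::with_seed(16, w <- matrix(runif(400, 0, pi), 20, 20))
  d <- model_distance_map(m1, axial_map(w))
  oracle <- matrix(axial_distance(as.vector(v), as.vector(w)), 20, 20)
  expect_equal(d, oracle)

  ## neighbor distance: zero for constant, peaked at a flipped pixel
  cm <- axial_map(matrix(0.6, 21, 21))
  expect_equal(neighbor_distance_map(cm, 3), matrix(0, 21, 21),
               tolerance = 1e-12)
  fl <- matrix(0.6, 21, 21); fl[11, 11] <- fold_axial(0.6 + pi / 2)
  dn <- neighbor_distance_map(axial_map(fl), 3)
  expect_equal(which.max(dn), 11 + 10 * 21)
  expect_true(all(dn <= 2 + 1e-12))
})

test_that("estimation weights combine and clamp correctly", {
  z <- matrix(0, 9, 9)
  expect_equal(unclass(estimation_weights(z, z, 5)), z + 1)
  two <- matrix(2, 9, 9)
  expect_equal(unclass(estimation_weights(two, z, 5)), z)
  ## 1 - sqrt(8)/2 < 0 clamps to 0
  expect_equal(unclass(estimation_weights(two, two, 5)), z)
})

test_that("weighted smoothing denoises and respects the fovea window", {
  n <- 81
  base <- matrix(pi / 6, n, n)
  withr::with_seed(17, flip <- matrix(runif(n * n) < 0.1, n, n))
  noisy <- base; noisy[flip] <- fold_axial(pi / 6 + pi / 2)
  sm <- smooth_orientation(axial_map(noisy), weight_map(matrix(1, n, n)),
                           N_max = 10, fovea_xy = c(-100, -100))
  inner <- sm$values[20:60, 20:60]
  expect_lt(stats::median(axial_err_deg(inner, matrix(pi / 6, 41, 41))), 2)

  ## constant field passes through unchanged
  sm2 <- smooth_orientation(axial_map(base), weight_map(matrix(1, n, n)),
                            N_max = 10, fovea_xy = c(-100, -100))
  expect_equal(sm2$values, base, tolerance = 1e-12)

  ## windows near the fovea shrink so they exclude the fovea pixel:
  ## a perpendicular spike AT the fovea must not leak into neighbors
  spike <- base
  fov <- c(41, 41)
  spike[fov[2], fov[1]] <- fold_axial(pi / 6 + pi / 2)
  sm3 <- smooth_orientation(axial_map(spike), weight_map(matrix(1, n, n)),
                            N_max = 10, fovea_xy = fov)
  off <- sm3$values[41, 44]   # 3 px from the fovea, window half-size <= 2
  expect_equal(off, pi / 6, tolerance = 1e-12)

  ## all-zero weights -> invalid pixels
  sm4 <- smooth_orientation(axial_map(base), weight_map(matrix(0, n, n)),
                            N_max = 5, fovea_xy = c(-100, -100))
  expect_false(any(sm4$valid))
})

test_that("ridge phantom recovery stays under the accuracy budget", {
  ## end-to-end on the rendered phantom, away from fovea and raphe
  oi <- ph_orient()
  tf <- ph_truth()
  keep <- oi$phi_f$valid & tf$valid & ph_interior_mask(2)
  err <- axial_err_deg(oi$phi_f$values[keep], tf$values[keep])
  expect_lt(stats::median(err), 2)
})
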