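test_that("model constants take their tanh-midpoint values", {
  sup <- model_constants(121, "superior")
  expect_equal(sup$c, 1.9)
  expect_equal(log(sup$b), -1.9)
  inf <- model_constants(-90, "inferior")
  expect_equal(inf$c, 1.0)
  expect_equal(log(-inf$b), 0.7)
  ## derived scalar check away from the midpoint
  expect_equal(model_constants(135, "superior")$c, 1.9 + 1.4 * tanh(1),
               tolerance = 1e-12)
  ## hemifield sign structure
  withr::with_seed(1, p <- runif(200, 1, 179))
  expect_true(all(model_constants(p, "superior")$b > 0))
  expect_true(all(model_constants(-p, "inferior")$b < 0))
  expect_true(all(model_constants(p, "superior")$c > 0))
})

test_that("model constants reject phi0 outside the hemifield", {
  expect_error(model_constants(-10, "superior"), "superior")
  expect_error(model_constants(10, "inferior"), "inferior")
  expect_error(model_constants(181, "superior"))
})

test_that("trajectories start exactly at phi0 and curve with sign(b)", {
  withr::with_seed(4, p0s <- c(runif(1000, 0.01, 179.99),
                               -runif(1000, 0.01, 179.99)))
  for (p0 in p0s[c(1:5, 1001:1005)]) {
    par <- trajectory_params(p0)
    expect_identical(trajectory(par, par$r0), p0)
  }
  ## vectorized identity over the full random set
  starts <- vapply(p0s, function(p0) trajectory(trajectory_params(p0), 4),
                   numeric(1))
  expect_equal(starts, p0s, tolerance = 1e-13)
  ## superior trajectories increase, inferior decrease, beyond r0
  for (p0 in c(30, 100, 170)) {
    par <- trajectory_params(p0)
    expect_true(all(diff(trajectory(par, seq(4, 12, 0.5))) > 0))
    par_i <- trajectory_params(-p0)
    expect_true(all(diff(trajectory(par_i, seq(4, 12, 0.5))) < 0))
  }
  expect_error(trajectory(trajectory_params(45), 3.9), "r0")
})

test_that("b = 0 yields a purely radial trajectory and tangent", {
  par <- structure(list(phi0 = 50, b = 0, c = 1.5, r0 = 4,
                        hemifield = "superior"),
                   class = "trajectory_params")
  expect_equal(trajectory(par, c(5, 10, 20)), rep(50, 3))
  tang <- trajectory_tangent(par, c(5, 10, 20))
  expect_equal(tang, rep(fold_axial(50 * pi / 180), 3), tolerance = 1e-12)
})

test_that("analytic tangents agree with central differences", {
  dr <- 1e-5
  for (p0 in c(20, 75, 121, 150, -20, -90, -160)) {
    par <- trajectory_params(p0)
    for (r in c(4.5, 6, 10, 18)) {
      psi1 <- trajectory(par, r - dr) * pi / 180
      psi2 <- trajectory(par, r + dr) * pi / 180
      p1 <- c((r - dr) * cos(psi1), (r - dr) * sin(psi1))
      p2 <- c((r + dr) * cos(psi2), (r + dr) * sin(psi2))
      fd <- fold_axial(atan2(p2[2] - p1[2], p2[1] - p1[1]))
      an <- trajectory_tangent(par, r)
      expect_lt(axial_err_deg(an, fd) * pi / 180, 1e-6)
    }
  }
  expect_error(trajectory_tangent(trajectory_params(45), 4), "r0")
})

test_that("similarity fit lands the landmarks and inverts cleanly", {
  g <- retinal_geometry(c(100, 80), c(150, 80), spacing_x = 10,
                        spacing_y = 10)
  fit <- fit_to_eye(c(100, 80), c(150, 80), g)
  expect_equal(fit$rotation, 0)
  expect_equal(fit$scale, 500 / 15)
  onh_img <- model_to_image_um(fit, cbind(15, 0))
  expect_equal(as.numeric(onh_img), c(1500, 800), tolerance = 1e-9)

  ## forward-construct a rotated and scaled eye, then recover it
  rot <- 10 * pi / 180; sc <- 1.2
  onh2 <- c(1000, 800) + sc * 500 * c(cos(rot), sin(rot))
  fit2 <- fit_to_eye(c(100, 80), onh2 / 10, g)
  expect_equal(fit2$rotation, rot, tolerance = 1e-6)
  expect_equal(fit2$scale, sc * 500 / 15, tolerance = 1e-6)
  ## round trip of arbitrary points through the transform
  pts <- cbind(c(0, 10, -5), c(0, 4, -8))
  back <- image_um_to_model(fit2, model_to_image_um(fit2, pts))
  expect_equal(back, pts, tolerance = 1e-9, ignore_attr = TRUE)

  ## mirrored (left-eye) landmarks: ONH temporal-to-the-left
  fitL <- fit_to_eye(c(100, 80), c(50, 80), g, eye = "left")
  onhL <- model_to_image_um(fitL, cbind(15, 0))
  expect_equal(as.numeric(onhL), c(500, 800), tolerance = 1e-9)
  expect_error(fit_to_eye(c(1, 1), c(1, 1), g), "coincide")
})

test_that("rasterized model reproduces analytic tangents on trace points", {
  tf <- ph_phi_m()
  fit <- ph_fit()
  g <- ph_spec()$geometry
  errs <- c()
  for (phi0 in c(30, 70, 121, 150, -30, -90, -150)) {
    par <- trajectory_params(phi0)
    for (r in c(5, 6, 8, 10, 15, 20)) {
      psi <- trajectory(par, r)
      if (abs(psi) >= 170) next    # raphe region: field is discontinuous
      psir <- psi * pi / 180
      xy_um <- model_to_image_um(fit, cbind(15 + r * cos(psir),
                                            r * sin(psir)))
      px <- xy_um[1] / g$spacing_x; py <- xy_um[2] / g$spacing_y
      if (px < 2 || px > ncol(tf$values) - 1 ||
          py < 2 || py > nrow(tf$values) - 1) next
      smp <- sample_axial(tf, px, py)
      expect_true(smp$valid)
      expected <- model_angle_to_image(fit, trajectory_tangent(par, r))
      errs <- c(errs, axial_err_deg(smp$angle, expected))
    }
  }
  expect_gt(length(errs), 20)
  expect_lt(max(errs), 0.5)
  ## contract: values folded, mask nonempty
  expect_true(all(tf$values[tf$valid] >= 0 & tf$values[tf$valid] < pi))
  expect_gt(sum(tf$valid), 0)
})

test_that("rasterize_model rejects a degenerate fit", {
  fit <- ph_fit()
  fit$scale <- 0
  expect_error(rasterize_model(fit, c(50, 50)), "scale")
})

test_that("papillomacular midline orientation is near horizontal", {
  ## between fovea and ONH the bundle runs nearly straight to the disc
  tf <- ph_phi_m()
  g <- ph_spec()$geometry
  mid <- (g$fovea_xy + g$onh_xy) / 2
  smp <- sample_axial(tf, mid[1], mid[2] - 3)
  expect_true(smp$valid)
  expect_lt(min(smp$angle, pi - smp$angle) * 180 / pi, 10)
})

test_that("solve_trajectory_through inverts the forward model", {
  fit <- ph_fit()
  g <- ph_spec()$geometry
  for (phi0 in c(25, 80, 140, -40, -95, -155)) {
    par <- trajectory_params(phi0)
    r <- 12
    psi <- trajectory(par, r) * pi / 180
    xy_um <- model_to_image_um(fit, cbind(15 + r * cos(psi),
                                          r * sin(psi)))
    sol <- solve_trajectory_through(c(xy_um[1] / g$spacing_x,
                                      xy_um[2] / g$spacing_y), fit)
    expect_lt(abs(sol$phi0 - phi0), 0.05)
    expect_equal(sol$entry_angle, wrap180(180 - phi0), tolerance = 0.05)
  }
})
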