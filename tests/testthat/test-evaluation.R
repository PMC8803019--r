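eval_geom <- function() {
  retinal_geometry(c(10, 61), c(61, 61), um_per_deg = 300,
                   spacing_x = 30, spacing_y = 30)   # 10 px per degree
}

## straight radial trace leaving the ONH at image angle `beta` (EA deg)
radial_trace <- function(beta, g, r_from = 2, r_to = 12, n = 200) {
  u_t <- c(-1, 0)                       # temporal: toward the fovea
  th <- beta * pi / 180
  dir <- c(u_t[1] * cos(th), -sin(th))  # superior (up) positive
  rr <- seq(r_from, r_to, length.out = n) * 10
  cbind(61 + rr * dir[1], 61 + rr * dir[2])[order(-rr), ]
}

test_that("polar resampling of a radial trace is constant in angle", {
  g <- eval_geom()
  for (beta in c(0, 45, -120, 179)) {
    p <- to_polar(radial_trace(beta, g), g)
    expect_true(p$reaches_entry)
    expect_equal(p$entry_angle, beta, tolerance = 0.2)
    expect_lt(max(abs(wrap180(p$samples$angle - beta))), 0.2)
    expect_true(all(diff(p$samples$r) > 0))
  }
})

test_that("angles unwrap across the +/-180 cut", {
  g <- eval_geom()
  ## an arc crossing the temporal-opposite meridian while moving outward
  rr <- seq(4, 10, length.out = 120)
  ang <- seq(170, 190, length.out = 120) * pi / 180
  pts <- cbind(61 - cos(ang) * rr * 10 * -1, 61 - sin(ang) * rr * 10)
  ## note: construct directly from the EA convention used by to_polar
  u_t <- c(-1, 0)
  pts <- cbind(61 + rr * 10 * (u_t[1] * cos(ang)),
               61 + rr * 10 * (-sin(ang)))
  p <- to_polar(pts[order(-rr), ], g)
  expect_lt(max(abs(diff(p$samples$angle))), 5)
  expect_gt(diff(range(p$samples$angle)), 15)
})

test_that("degenerate traces are flagged", {
  g <- eval_geom()
  ## circular arc at fixed radius: no radial support
  ang <- seq(0.3, 1.2, length.out = 50)
  pts <- cbind(61 + 60 * cos(ang), 61 + 60 * sin(ang))
  p <- to_polar(pts, g)
  expect_false(p$reaches_entry)
  expect_true(is.na(p$entry_angle))
  expect_error(to_polar(matrix(numeric(0), 0, 2), g), "empty")
})

test_that("entry-angle stats match brute-force circular arithmetic", {
  s <- entry_angle_stats(c(359, 1, 3))
  expect_equal(s$range, 4)
  s2 <- entry_angle_stats(c(10, 10, 10))
  expect_equal(s2$range, 0)
  expect_equal(s2$offset, 0)
  ## random sets against an explicit pairwise oracle
  withr::with_seed(51, eas <- replicate(20, runif(4, -180, 180),
                                        simplify = FALSE))
  for (e in eas) {
    s3 <- entry_angle_stats(e)
    oracle <- 0
    for (i in 1:3) for (j in (i + 1):4) {
      oracle <- max(oracle, abs(wrap180(e[i] - e[j])))
    }
    expect_equal(s3$range, oracle)
    expect_gte(s3$range, s3$offset)
  }
  expect_error(entry_angle_stats(c(0, 120, 240)), "undefined")
})

test_that("icc_ak matches an explicit ANOVA oracle", {
  icc_oracle <- function(m) {
    ## brute-force two-way mean squares via explicit sums
    n <- nrow(m); k <- ncol(m); gm <- mean(m)
    msr <- sum((rowMeans(m) - gm)^2) * k / (n - 1)
    msc <- sum((colMeans(m) - gm)^2) * n / (k - 1)
    sse <- 0
    for (i in 1:n) for (j in 1:k) {
      sse <- sse + (m[i, j] - rowMeans(m)[i] - colMeans(m)[j] + gm)^2
    }
    mse <- sse / ((n - 1) * (k - 1))
    (msr - mse) / (msr + (msc - mse) / n)
  }
  withr::with_seed(52, mats <- replicate(20, matrix(rnorm(15, 50, 10), 5, 3),
                                         simplify = FALSE))
  for (m in mats) {
    expect_equal(icc_ak(m), icc_oracle(m), tolerance = 1e-10)
  }
  ## identical raters: perfect agreement
  base <- matrix(rep(c(10, 20, 30, 40, 55), 3), 5, 3)
  expect_equal(icc_ak(base), 1)
  ## wraparound compensation: +360 on one rater changes nothing
  m1 <- mats[[1]]
  m2 <- m1; m2[, 2] <- m2[, 2] + 360
  expect_equal(icc_ak(m2), icc_ak(m1), tolerance = 1e-10)
  ## angles straddling the cut are reconciled before the ANOVA
  m3 <- matrix(c(359, 1, 3, 178, 182, 180, 90, 92, 88, 269, 271, 270),
               4, 3, byrow = TRUE)
  expect_gt(icc_ak(m3), 0.99)
  expect_error(icc_ak(matrix(5, 3, 3)), "variance")
})

test_that("trace RMSE matches the closed-form constant-offset case", {
  g <- eval_geom()
  ta <- to_polar(radial_trace(30, g, r_from = 3.8, r_to = 10.05), g)
  tb <- to_polar(radial_trace(31, g, r_from = 3.8, r_to = 10.05), g)
  res <- trace_rmse(ta, list(tb), g)
  rr <- ta$samples$r[ta$samples$r %in% tb$samples$r]
  oracle <- sqrt(mean((1 * pi / 180 * rr * 300)^2))
  expect_equal(res$rmse_um, oracle, tolerance = 0.06 * oracle)
  ## identity and symmetry
  expect_equal(trace_rmse(ta, list(ta), g)$rmse_um, 0)
  expect_equal(trace_rmse(tb, list(ta), g)$rmse_um, res$rmse_um)
  ## rotating both traces together changes nothing
  ta2 <- to_polar(radial_trace(120, g, r_from = 3.8, r_to = 10.05), g)
  tb2 <- to_polar(radial_trace(121, g, r_from = 3.8, r_to = 10.05), g)
  expect_equal(trace_rmse(ta2, list(tb2), g)$rmse_um, res$rmse_um,
               tolerance = 1e-6)
  ## no overlap errors out
  tc <- to_polar(radial_trace(30, g, r_from = 10.6, r_to = 12), g)
  expect_error(trace_rmse(ta, list(tc), g), "overlap")
})

test_that("the 24-2 grid has 52 sector-labeled points", {
  vf <- vf_grid_24_2()
  expect_equal(nrow(vf), 52)
  expect_false(any(vf$x_deg == 15 & abs(vf$y_deg) == 3))
  expect_setequal(unique(vf$sector), c("T", "ST", "IT", "SN", "IN", "N"))
  expect_false(any(is.na(vf$sector)))
  ## sector binning of entry angles follows the published boundaries
  expect_equal(sector_of_entry_angle(c(0, 60, 100, 170, -110, -70)),
               c("T", "ST", "SN", "N", "IN", "IT"))
})

test_that("agreement reports aggregate raters and sectors", {
  g <- ph_spec()$geometry
  vf <- vf_grid_24_2()
  seeds <- ph_vf_seeds()
  tf <- ph_truth()
  ## one rater: traces on the exact truth field
  base <- list()
  for (i in seq_len(nrow(seeds))) {
    tr <- trace_inward(c(seeds$x_px[i], seeds$y_px[i]), tf, g, r = 1)
    base[[as.character(seeds$id[i])]] <- to_polar(tr, g)
  }
  ## duplicated raters: all statistics collapse to perfect agreement
  rep3 <- list(a = base, b = base, c = base)
  rpt <- build_report(rep3, vf, g)
  ov <- rpt[rpt$sector == "overall", ]
  expect_equal(ov$ea_range, 0)
  expect_equal(ov$ea_offset, 0)
  expect_equal(ov$rmse_um, 0, tolerance = 1e-9)
  expect_equal(ov$n, sum(rpt$n[rpt$sector != "overall"]))

  ## perturbed raters: offsets grow with the perturbation scale
  perturb <- function(sigma, seed) {
    withr::with_seed(seed, {
      lapply(base, function(p) {
        p$entry_angle <- p$entry_angle + rnorm(1, 0, sigma)
        p$samples$angle <- p$samples$angle + rnorm(1, 0, sigma)
        p
      })
    })
  }
  offs <- vapply(c(1, 2, 4), function(sg) {
    sets <- list(a = perturb(sg, 100 + sg), b = perturb(sg, 200 + sg),
                 c = perturb(sg, 300 + sg))
    r <- build_report(sets, vf, g)
    r$ea_offset[r$sector == "overall"]
  }, numeric(1))
  expect_true(all(diff(offs) > 0))
})
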