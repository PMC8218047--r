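test_that("counts are conserved per view without attenuation", {
  ph <- disc_phantom()
  geom <- test_geom()
  expected <- volume_total(ph$activity) * 1000 *  # kBq -> Bq
    geom$sensitivity_cps_per_bq * geom$dwell_s_per_view
  # with the (normalized) PSF: conserved up to kernel truncation at the rim
  p <- forward_project(ph$activity, model = system_model(zero_mu(), geom))
  view_totals <- apply(p$peak, 3, sum)
  expect_lt(max(abs(view_totals - expected)) / expected, 1e-6)
  # without PSF the splatting projector conserves counts exactly
  p0 <- forward_project(ph$activity,
                        model = system_model(zero_mu(), geom, psf = FALSE))
  view_totals0 <- apply(p0$peak, 3, sum)
  expect_lt(max(abs(view_totals0 - expected)) / expected, 1e-12)
})

test_that("a uniform slab attenuates a ray by exp(-mu L)", {
  # single active voxel behind m voxels of uniform mu, head-on view, no PSF
  n <- 16L
  act <- array(0, rep(n, 3)); act[8, 5, 8] <- 1000  # Bq/ml
  mu <- array(0, rep(n, 3))
  m_vox <- 6L
  mu0 <- 0.153
  mu[8, 6:(5 + m_vox), 8] <- mu0
  geom <- acquisition_geometry(n_views = 1, arc_deg = 360,
                               detector_pixel_mm = 2.4, dwell_s_per_view = 1,
                               sensitivity_cps_per_bq = 1e-3,
                               orbit_radius_mm = 100)
  vol <- sv_volume(act, 2.4, "Bq/ml")
  model <- system_model(sv_volume(mu, 2.4, "1/cm"), geom, psf = FALSE)
  p <- forward_project(vol, model = model)
  unatten <- 1000 * voxel_ml(vol) * 1e-3  # Bq x ml-to-activity x sens x dwell
  expect_equal(sum(p$peak), unatten * exp(-mu0 * m_vox * 0.24),
               tolerance = 1e-9)
})

test_that("the forward model is linear and scales with dwell time", {
  ph <- disc_phantom()
  g1 <- test_geom(dwell = 1)
  g2 <- test_geom(dwell = 2)
  p1 <- forward_project(ph$activity, ph$mu, g1)
  p2 <- forward_project(ph$activity, ph$mu, g2)
  expect_equal(p2$peak, 2 * p1$peak, tolerance = 1e-12)
  model <- system_model(ph$mu, g1)
  x <- ph$activity
  z <- sv_volume(array(runif(24^3), rep(24, 3)), 2.4, "kBq/ml")
  comb <- sv_volume(2.5 * x$data + 0.3 * z$data, 2.4, "kBq/ml")
  lhs <- forward_project(comb, model = model)$peak
  rhs <- 2.5 * forward_project(x, model = model)$peak +
    0.3 * forward_project(z, model = model)$peak
  expect_lt(max(abs(lhs - rhs)) / max(rhs), 1e-9)
})

test_that("back projection is the exact adjoint of forward projection", {
  set.seed(101)
  ph <- disc_phantom()
  for (geom in list(test_geom(24), test_geom(12, dwell = 3, radius = 200))) {
    model <- system_model(ph$mu, geom)
    x <- sv_volume(array(runif(24^3), rep(24, 3)), 2.4, "arb")
    Ax <- forward_project(x, model = model)
    y <- array(runif(length(Ax$peak)), dim(Ax$peak))
    Aty <- back_project(sv_projections(y, geom), model = model, units = "arb")
    lhs <- sum(Ax$peak * y)
    rhs <- sum(x$data * Aty$data)
    expect_lt(abs(lhs - rhs) /
                (sqrt(sum(Ax$peak^2)) * sqrt(sum(y^2))), 1e-6)
  }
})

test_that("back projection of zeros is zero and of uniform data is flat inside", {
  geom <- test_geom()
  model <- system_model(zero_mu(), geom, psf = FALSE)
  z <- back_project(sv_projections(array(0, c(24, 24, 24)), geom),
                    model = model)
  expect_true(all(z$data == 0))
  u <- back_project(sv_projections(array(1, c(24, 24, 24)), geom),
                    model = model, units = "arb")
  # sampling rows sum to 1: every fully-sampled voxel sees every view once
  expected <- geom$n_views * model$scale
  inner <- u$data[9:16, 9:16, 9:16]
  expect_lt(max(abs(inner - expected)) / expected, 1e-9)
})

test_that("Poisson noise has the right moments and is seed-reproducible", {
  g <- test_geom(1)
  p0 <- sv_projections(array(0, c(24, 24, 1)), g)
  expect_true(all(add_poisson_noise(p0, seed = 1)$peak == 0))
  lam <- sv_projections(array(50, c(50, 40, 50)), g)  # 1e5 bins at lambda 50
  draw <- add_poisson_noise(lam, seed = 7)$peak
  se <- sqrt(50 / length(draw))
  expect_lt(abs(mean(draw) - 50), 3 * se)
  expect_identical(add_poisson_noise(lam, seed = 7)$peak, draw)
  bad <- sv_projections(array(1, c(4, 4, 1)), g)
  bad$peak[1] <- -1
  expect_error(add_poisson_noise(bad, seed = 1), ">= 0")
})

test_that("the simulated lower window preserves mass and broadens impulses", {
  g <- test_geom(2)
  ph <- disc_phantom()
  pe <- forward_project(ph$activity, ph$mu, g)
  z <- simulate_lower_window(pe, scatter_fraction = 0, poisson = FALSE)
  expect_true(all(z$lower == 0))
  s <- simulate_lower_window(pe, scatter_fraction = 0.35, poisson = FALSE)
  expect_equal(sum(s$lower), 0.35 * sum(pe$peak), tolerance = 1e-9)
  # impulse broadened to the stated FWHM (+/- one pixel)
  imp <- sv_projections(array(0, c(33, 33, 1)), test_geom(1))
  imp$peak[17, 17, 1] <- 1000
  b <- simulate_lower_window(imp, scatter_fraction = 1,
                             broadening_fwhm_mm = 12, poisson = FALSE)
  prof <- b$lower[, 17, 1]
  half <- max(prof) / 2
  above <- which(prof >= half)
  width_mm <- (max(above) - min(above)) * 2.4
  expect_lt(abs(width_mm - 12), 2.4 + 1e-9)
  expect_error(simulate_lower_window(pe, scatter_fraction = -1), ">= 0")
})

test_that("projector rejects mismatched grids and bad inputs", {
  ph <- disc_phantom()
  geom <- test_geom()
  model <- system_model(ph$mu, geom)
  small <- sv_volume(array(1, c(16, 16, 16)), 2.4, "kBq/ml")
  expect_error(forward_project(small, model = model), "grid")
  expect_error(sv_volume(array(NaN, c(4, 4, 4)), 2.4), "non-finite")
})
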