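# Shared small-scale fixtures, built once per test run.

test_geom <- function(n_views = 24L, dwell = 1, sens = 1e-4, radius = 120) {
  acquisition_geometry(n_views = n_views, detector_pixel_mm = 2.4,
                       dwell_s_per_view = dwell,
                       sensitivity_cps_per_bq = sens,
                       orbit_radius_mm = radius)
}

# warm soft-tissue ball with a hot cortical core, 24^3
disc_phantom <- function(n = 24L) {
  make_digital_phantom(phantom_spec(
    rep(n, 3), 2.4,
    list(ellipsoid(c(0, 0, 0), c(18, 18, 12), 3, 10),
         ellipsoid(c(0, 0, 0), c(7, 7, 7), 5, 50))))
}

# uniform soft-tissue cylinder-ish ellipsoid, 32^3, 100 kBq/ml
cylinder_phantom <- function() {
  make_digital_phantom(phantom_spec(
    c(32, 32, 32), 2.4,
    list(ellipsoid(c(0, 0, 0), c(24, 24, 30), 3, 100))))
}

zero_mu <- function(n = 24L) {
  sv_volume(array(0, rep(n, 3)), 2.4, units = "1/cm")
}

# noiseless point source in air plus its calibration acquisition
point_source_calibration <- function(geom, n = 32L, activity_bq = 111e6) {
  src <- sv_volume(array(0, rep(n, 3)), 2.4, units = "Bq/ml")
  ctr <- (n + 1L) %/% 2L
  src$data[ctr, ctr, ctr] <- activity_bq / voxel_ml(src)
  air <- sv_volume(array(0, rep(n, 3)), 2.4, units = "1/cm")
  calibrate_sensitivity(forward_project(src, air, geom),
                        known_activity_bq = activity_bq)
}

# cylindrical interior mask (radius mm, z-slab) on an n^3 2.4 mm grid
interior_mask <- function(n, radius_mm, z_range) {
  cx <- (seq_len(n) - (n + 1) / 2) * 2.4
  m <- array(FALSE, rep(n, 3))
  disk <- outer(cx^2, cx^2, "+") < radius_mm^2
  for (k in z_range) m[, , k] <- disk
  m
}
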