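#' Parallel-hole SPECT acquisition geometry
#'
#' Defaults emulate a clinical bone protocol: 120 views over 360 degrees,
#' 2.4 mm detector pixels, 20 s dwell per view, and an LEHR-like
#' distance-dependent Gaussian response FWHM(d) = sqrt(fwhm_int^2 +
#' (slope * d)^2) (about 7.4 mm at 10 cm with the defaults). The orbit is
#' circular by default; a per-view radius vector is accepted.
#'
#' @param n_views number of views (>= 1).
#' @param arc_deg angular coverage in degrees, in (0, 360].
#' @param detector_matrix nominal detector matrix size (metadata; projections
#'   are sampled on the volume grid, whose voxel size must equal
#'   `detector_pixel_mm`).
#' @param detector_pixel_mm detector pixel size (mm).
#' @param dwell_s_per_view acquisition time per view (s).
#' @param orbit_radius_mm radius of rotation (scalar, or one value per view).
#' @param psf_intrinsic_fwhm_mm collimator/detector intrinsic FWHM (mm).
#' @param psf_slope_mm_per_mm FWHM growth per mm of source-detector distance.
#' @param sensitivity_cps_per_bq system sensitivity (counts/s per Bq).
#' @return object of class `sv_geometry`.
#' @export
acquisition_geometry <- function(n_views = 120L, arc_deg = 360,
                                 detector_matrix = 256L,
                                 detector_pixel_mm = 2.4,
                                 dwell_s_per_view = 20,
                                 orbit_radius_mm = 250,
                                 psf_intrinsic_fwhm_mm = 3.8,
                                 psf_slope_mm_per_mm = 0.047,
                                 sensitivity_cps_per_bq = 1e-4) {
  if (n_views < 1) stop("`n_views` must be >= 1")
  if (arc_deg <= 0 || arc_deg > 360) stop("`arc_deg` must lie in (0, 360]")
  if (detector_pixel_mm <= 0) stop("`detector_pixel_mm` must be > 0")
  if (psf_intrinsic_fwhm_mm < 0 || psf_slope_mm_per_mm < 0) {
    stop("PSF parameters must be >= 0")
  }
  if (dwell_s_per_view <= 0 || sensitivity_cps_per_bq <= 0) {
    stop("dwell and sensitivity must be > 0")
  }
  if (!length(orbit_radius_mm) %in% c(1L, n_views) || any(orbit_radius_mm <= 0)) {
    stop("`orbit_radius_mm` must be positive, length 1 or n_views")
  }
  structure(list(n_views = as.integer(n_views), arc_deg = arc_deg,
                 detector_matrix = as.integer(detector_matrix),
                 detector_pixel_mm = detector_pixel_mm,
                 dwell_s_per_view = dwell_s_per_view,
                 orbit_radius_mm = orbit_radius_mm,
                 psf_intrinsic_fwhm_mm = psf_intrinsic_fwhm_mm,
                 psf_slope_mm_per_mm = psf_slope_mm_per_mm,
                 sensitivity_cps_per_bq = sensitivity_cps_per_bq),
            class = "sv_geometry")
}

#' Projection data container
#'
#' Peak-window (and optionally lower scatter-window) count arrays indexed
#' `[u, v, view]`, with the geometry and optionally a scatter projection
#' estimate (SPE) of the same shape as the peak window.
#'
#' @param peak numeric array `[u, v, view]` of peak-window counts (>= 0).
#' @param geometry an [acquisition_geometry()].
#' @param lower optional lower-energy-window counts, same shape.
#' @param spe optional scatter projection estimate, same shape.
#' @return object of class `sv_projections`.
#' @export
sv_projections <- function(peak, geometry, lower = NULL, spe = NULL) {
  if (length(dim(peak)) != 3L) stop("`peak` must be a [u, v, view] array")
  if (any(peak < 0)) stop("counts must be >= 0")
  for (nm in c("lower", "spe")) {
    x <- get(nm)
    if (!is.null(x) && !identical(dim(x), dim(peak))) {
      stop("`", nm, "` must match the peak-window shape")
    }
  }
  structure(list(peak = peak, lower = lower, spe = spe, geometry = geometry),
            class = "sv_projections")
}

#' Total peak-window counts in millions (Mc)
#' @param proj an `sv_projections`.
#' @return total counts / 1e6.
#' @export
total_counts_mc <- function(proj) sum(proj$peak) / 1e6

#' @export
print.sv_projections <- function(x, ...) {
  d <- dim(x$peak)
  cat(sprintf("<sv_projections> %d x %d bins x %d views, %.3f Mc peak%s%s\n",
              d[1], d[2], d[3], total_counts_mc(x),
              if (!is.null(x$lower)) ", lower window" else "",
              if (!is.null(x$spe)) ", SPE" else ""))
  invisible(x)
}

view_angles_deg <- function(geom) {
  geom$arc_deg / geom$n_views * (seq_len(geom$n_views) - 1)
}

# Symmetric banded Gaussian convolution matrix on n samples.
# normalize = "kernel": zero-padded convolution, kernel sums to 1 (symmetric
#   matrix; exact transpose of itself -- used inside the system model).
# normalize = "mass": columns renormalized to sum to 1 (mass-preserving at
#   the borders -- used for scatter-estimate smoothing).
gauss_conv_matrix <- function(n, sigma_px, normalize = c("kernel", "mass")) {
  normalize <- match.arg(normalize)
  if (sigma_px <= 1e-12) return(diag(n))
  r <- max(1L, ceiling(4 * sigma_px))
  k <- stats::dnorm(-r:r, sd = sigma_px)
  k <- k / sum(k)
  B <- matrix(0, n, n)
  for (off in -r:r) {
    idx <- seq_len(n)
    src <- idx + off
    ok <- src >= 1 & src <= n
    B[cbind(idx[ok], src[ok])] <- k[off + r + 1]
  }
  if (normalize == "mass") B <- sweep(B, 2, colSums(B), "/")
  B
}

# Sparse bilinear in-plane rotation operator for one view angle.
# Rows index rotated-frame voxels, columns scanner-frame voxels; row sums are
# 1 in the interior (sampling: reproduces constants, used for the mu-map and
# the back projection) while the transpose has unit column sums (splatting:
# conserves counts, used to rotate the activity in the forward model). Zero
# outside the field of view; the exact adjoint is the matrix transpose.
rotation_operator <- function(nx, ny, spacing_mm, angle_deg) {
  th <- angle_deg * pi / 180
  cxs <- axis_coords_mm(nx, spacing_mm)
  cys <- axis_coords_mm(ny, spacing_mm)
  x <- rep(cxs, times = ny)
  y <- rep(cys, each = nx)
  # source point in the unrotated frame for each rotated-frame voxel
  xs <- cos(th) * x + sin(th) * y
  ys <- -sin(th) * x + cos(th) * y
  fi <- xs / spacing_mm + (nx + 1) / 2
  fj <- ys / spacing_mm + (ny + 1) / 2
  i0 <- floor(fi); j0 <- floor(fj)
  wi <- fi - i0;   wj <- fj - j0
  tgt <- seq_len(nx * ny)
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  for (di in 0:1) for (dj in 0:1) {
    ii <- i0 + di; jj <- j0 + dj
    w <- (if (di == 0) 1 - wi else wi) * (if (dj == 0) 1 - wj else wj)
    ok <- ii >= 1 & ii <= nx & jj >= 1 & jj <= ny & w > 0
    rows <- c(rows, tgt[ok])
    cols <- c(cols, ii[ok] + (jj[ok] - 1L) * nx)
    vals <- c(vals, w[ok])
  }
  Matrix::sparseMatrix(i = rows, j = cols, x = vals,
                       dims = c(nx * ny, nx * ny))
}

# reverse cumulative sum along the y (2nd) axis of a 3-D array:
# out[i,j,k] = sum over j' >= j of arr[i,j',k]
rev_cumsum_y <- function(arr) {
  d <- dim(arr)
  out <- arr
  if (d[2] > 1) {
    for (j in (d[2] - 1):1) out[, j, ] <- out[, j, ] + out[, j + 1, ]
  }
  out
}

#' Build the per-view system model (internal, reusable)
#'
#' Precomputes the sparse rotation operators, the rotated-frame attenuation
#' factors (discrete Beer-Lambert toward the detector with half-voxel
#' self-attenuation), and the depth-dependent PSF convolution matrices. The
#' returned object is accepted by [forward_project()] and [back_project()]
#' so iterative reconstruction pays the setup cost once.
#'
#' @param mu attenuation `sv_volume` (1/cm at 140 keV).
#' @param geom an [acquisition_geometry()].
#' @param psf if `FALSE`, the PSF is an identity (useful for oracles).
#' @return object of class `sv_system_model`.
#' @export
system_model <- function(mu, geom, psf = TRUE) {
  stopifnot(inherits(mu, "sv_volume"), inherits(geom, "sv_geometry"))
  if (any(!is.finite(mu$data)) || any(mu$data < 0)) {
    stop("mu-map must be finite and nonnegative")
  }
  d <- dim(mu$data)
  vs <- mu$spacing
  if (max(abs(vs - vs[1])) > 1e-9) stop("projector requires isotropic voxels")
  vs <- vs[1]
  if (abs(vs - geom$detector_pixel_mm) > 1e-9) {
    stop("detector pixel (", geom$detector_pixel_mm,
         " mm) must equal the voxel size (", vs, " mm)")
  }
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  angles <- view_angles_deg(geom)
  radii <- rep(geom$orbit_radius_mm, length.out = geom$n_views)
  rot <- lapply(angles, function(a) rotation_operator(nx, ny, vs, a))
  mumat <- matrix(mu$data, nx * ny, nz)
  att <- vector("list", geom$n_views)
  for (v in seq_len(geom$n_views)) {
    murot <- array(as.matrix(rot[[v]] %*% mumat), c(nx, ny, nz))
    path <- rev_cumsum_y(murot) - 0.5 * murot  # voxel lengths of mu
    att[[v]] <- exp(-(vs / 10) * path)          # vs in mm -> cm
  }
  cy <- axis_coords_mm(ny, vs)
  fwhm_at <- function(dist_mm) {
    sqrt(geom$psf_intrinsic_fwhm_mm^2 +
           (geom$psf_slope_mm_per_mm * pmax(dist_mm, 0))^2)
  }
  sigma_px_for <- function(radius) {
    if (!psf) return(rep(0, ny))
    fwhm_at(radius - cy) / (2 * sqrt(2 * log(2))) / vs
  }
  # PSF matrices per depth slab; shared across views on a circular orbit
  unique_r <- unique(radii)
  psf_by_radius <- lapply(unique_r, function(r) {
    sig <- sigma_px_for(r)
    list(Bu = lapply(sig, function(s) gauss_conv_matrix(nx, s)),
         Bv = lapply(sig, function(s) gauss_conv_matrix(nz, s)))
  })
  names(psf_by_radius) <- as.character(unique_r)
  structure(list(dims = d, spacing = vs, geom = geom, rot = rot, att = att,
                 psf_by_radius = psf_by_radius, radii = radii,
                 scale = geom$dwell_s_per_view * geom$sensitivity_cps_per_bq *
                   voxel_ml(rep(vs, 3))),
            class = "sv_system_model")
}

units_to_bq_ml <- function(units) {
  switch(units,
         "kBq/ml" = 1000,
         "Bq/ml" = 1,
         1)  # arbitrary units pass through
}

#' Attenuated, resolution-modeled forward projection
#'
#' Expected (noiseless) peak-window counts: for each view the volume is
#' rotated so the detector sits along +y, attenuated by the discrete
#' Beer-Lambert factor from each voxel to the detector, blurred slab-by-slab
#' with the distance-dependent Gaussian response, summed along the ray axis,
#' and scaled by dwell time, system sensitivity and voxel volume.
#'
#' @param activity activity `sv_volume` (kBq/ml or Bq/ml).
#' @param mu attenuation `sv_volume` on the same grid (ignored when `model`
#'   is supplied).
#' @param geom an [acquisition_geometry()] (ignored when `model` supplied).
#' @param model optional prebuilt [system_model()].
#' @param psf passed to [system_model()] when building one here.
#' @return `sv_projections` with the expected peak-window counts.
#' @export
forward_project <- function(activity, mu = NULL, geom = NULL, model = NULL,
                            psf = TRUE) {
  stopifnot(inherits(activity, "sv_volume"))
  if (is.null(model)) model <- system_model(mu, geom, psf = psf)
  if (!identical(dim(activity$data), model$dims) ||
      max(abs(activity$spacing - model$spacing)) > 1e-9) {
    stop("activity grid does not match the system model grid")
  }
  if (any(!is.finite(activity$data))) stop("activity contains non-finite values")
  d <- model$dims; nx <- d[1]; ny <- d[2]; nz <- d[3]
  amat <- matrix(activity$data, nx * ny, nz)
  scale <- model$scale * units_to_bq_ml(activity$units)
  out <- array(0, c(nx, nz, model$geom$n_views))
  for (v in seq_len(model$geom$n_views)) {
    arot <- array(as.matrix(Matrix::crossprod(model$rot[[v]], amat)),
                  c(nx, ny, nz))
    w <- arot * model$att[[v]]
    psf_v <- model$psf_by_radius[[as.character(model$radii[v])]]
    p <- matrix(0, nx, nz)
    for (j in seq_len(ny)) {
      p <- p + psf_v$Bu[[j]] %*% w[, j, ] %*% psf_v$Bv[[j]]
    }
    out[, , v] <- as.matrix(p)
  }
  sv_projections(pmax(out * scale, 0), model$geom)
}

#' Matched back projection (exact adjoint of [forward_project()])
#'
#' Applies the transpose of every linear step of the forward model in
#' reverse order, so that `<A x, y> == <x, A^T y>` to machine precision.
#'
#' @param proj `sv_projections` (peak window used).
#' @param mu,geom,model,psf as in [forward_project()].
#' @param units unit label attached to the result.
#' @return `sv_volume` back-projection.
#' @export
back_project <- function(proj, mu = NULL, geom = NULL, model = NULL,
                         psf = TRUE, units = "arb") {
  stopifnot(inherits(proj, "sv_projections"))
  if (is.null(model)) model <- system_model(mu, geom, psf = psf)
  d <- model$dims; nx <- d[1]; ny <- d[2]; nz <- d[3]
  if (!identical(dim(proj$peak), c(nx, nz, model$geom$n_views))) {
    stop("projection shape does not match the system model")
  }
  back_project_raw(proj$peak, model, seq_len(model$geom$n_views),
                   scale = model$scale * units_to_bq_ml(units)) |>
    sv_volume(model$spacing, units = units)
}

# transpose-model accumulation over a subset of views; `scale` multiplies the
# result (must mirror the forward scale for a true adjoint)
back_project_raw <- function(peak, model, views, scale) {
  d <- model$dims; nx <- d[1]; ny <- d[2]; nz <- d[3]
  acc <- matrix(0, nx * ny, nz)
  buf <- array(0, c(nx, ny, nz))
  for (v in views) {
    yv <- peak[, , v]
    psf_v <- model$psf_by_radius[[as.character(model$radii[v])]]
    for (j in seq_len(ny)) {
      buf[, j, ] <- as.matrix(psf_v$Bu[[j]] %*% yv %*% psf_v$Bv[[j]])
    }
    acc <- acc + model$rot[[v]] %*% matrix(buf * model$att[[v]], nx * ny, nz)
  }
  array(as.matrix(acc) * scale, d)
}

#' Add Poisson counting noise to expected projections
#'
#' @param proj `sv_projections` holding expected counts.
#' @param seed RNG seed (reproducible realization).
#' @return `sv_projections` with independent Poisson draws per bin in the
#'   peak (and, if present, lower) window. The SPE, being an estimate rather
#'   than data, is carried through unchanged.
#' @export
add_poisson_noise <- function(proj, seed = 1L) {
  stopifnot(inherits(proj, "sv_projections"))
  if (any(proj$peak < 0)) stop("expected counts must be >= 0")
  withr_seed(seed, {
    peak <- array(stats::rpois(length(proj$peak), proj$peak), dim(proj$peak))
    lower <- proj$lower
    if (!is.null(lower)) {
      if (any(lower < 0)) stop("expected counts must be >= 0")
      lower <- array(stats::rpois(length(lower), lower), dim(lower))
    }
    sv_projections(peak, proj$geometry, lower = lower, spe = proj$spe)
  })
}

#' Simulate the lower (scatter) energy window
#'
#' A simple generative stand-in for the adjacent 15% lower energy window:
#' the expected lower-window image is `scatter_fraction` times the expected
#' peak image convolved per view with a mass-preserving 2-D Gaussian of the
#' stated FWHM, optionally Poisson-sampled.
#'
#' @param proj `sv_projections` with expected peak counts.
#' @param scatter_fraction total scatter-to-peak ratio (>= 0, default 0.35).
#' @param broadening_fwhm_mm spatial broadening of scatter (default 30 mm).
#' @param seed RNG seed for the Poisson draw.
#' @param poisson if `FALSE`, return the noiseless expectation.
#' @return `sv_projections` with the lower window filled in.
#' @export
simulate_lower_window <- function(proj, scatter_fraction = 0.35,
                                  broadening_fwhm_mm = 30, seed = 1L,
                                  poisson = TRUE) {
  stopifnot(inherits(proj, "sv_projections"))
  if (scatter_fraction < 0) stop("`scatter_fraction` must be >= 0")
  if (broadening_fwhm_mm < 0) stop("`broadening_fwhm_mm` must be >= 0")
  d <- dim(proj$peak)
  px <- proj$geometry$detector_pixel_mm
  sig <- broadening_fwhm_mm / (2 * sqrt(2 * log(2))) / px
  Bu <- gauss_conv_matrix(d[1], sig, normalize = "mass")
  Bv <- gauss_conv_matrix(d[2], sig, normalize = "mass")
  lower <- array(0, d)
  for (v in seq_len(d[3])) {
    lower[, , v] <- scatter_fraction * (Bu %*% proj$peak[, , v] %*% t(Bv))
  }
  if (poisson) {
    lower <- withr_seed(seed,
      array(stats::rpois(length(lower), lower), d))
  }
  sv_projections(proj$peak, proj$geometry, lower = lower, spe = proj$spe)
}
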