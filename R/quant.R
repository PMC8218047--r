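#' Calibrate system sensitivity from a point-source acquisition
#'
#' With the reference source (nominal 111 MBq, stated accuracy +/- 3% at 99%
#' CL) positioned at the center of the field of view and negligible
#' attenuation, the system sensitivity is the total detected count rate per
#' unit activity: `sum(counts) / (activity * dwell * n_views)`.
#'
#' @param proj `sv_projections` of the point-source acquisition.
#' @param known_activity_bq source activity in Bq (default 111e6).
#' @param tolerance stated relative accuracy of the source (default 0.03).
#' @return object of class `calibration_factor` with fields
#'   `sensitivity_cps_per_bq`, `source_activity_bq`, `tolerance`, `timestamp`.
#' @export
calibrate_sensitivity <- function(proj, known_activity_bq = 111e6,
                                  tolerance = 0.03) {
  stopifnot(inherits(proj, "sv_projections"))
  if (known_activity_bq <= 0) stop("`known_activity_bq` must be > 0")
  total <- sum(proj$peak)
  if (total <= 0) stop("point-source acquisition has zero counts")
  g <- proj$geometry
  sens <- total / (known_activity_bq * g$dwell_s_per_view * g$n_views)
  structure(list(sensitivity_cps_per_bq = sens,
                 source_activity_bq = known_activity_bq,
                 tolerance = tolerance,
                 timestamp = Sys.time()),
            class = "calibration_factor")
}

#' SUV context: dose, timing and body weight
#'
#' @param injected_dose_mbq injected activity (MBq, > 0; nominal 740 for the
#'   bone protocol).
#' @param body_weight_kg patient body weight (kg, > 0).
#' @param injection_to_scan_h hours from injection to acquisition (>= 0).
#' @param half_life_h physical half-life (h); Tc-99m default 6.0067.
#' @return object of class `suv_context`.
#' @export
suv_context <- function(injected_dose_mbq = 740, body_weight_kg = 75,
                        injection_to_scan_h = 3, half_life_h = 6.0067) {
  if (injected_dose_mbq <= 0) stop("`injected_dose_mbq` must be > 0")
  if (body_weight_kg <= 0) stop("`body_weight_kg` must be > 0")
  if (injection_to_scan_h < 0) stop("scan time must not precede injection")
  if (half_life_h <= 0) stop("`half_life_h` must be > 0")
  structure(list(injected_dose_mbq = injected_dose_mbq,
                 body_weight_kg = body_weight_kg,
                 injection_to_scan_h = injection_to_scan_h,
                 half_life_h = half_life_h),
            class = "suv_context")
}

#' Convert a reconstructed count-rate image to activity concentration
#'
#' Divides by the calibrated sensitivity (and, for counts-per-voxel images,
#' the voxel volume) and decay-corrects to the injection time:
#' concentration is multiplied by `2^(dt / half_life)`.
#'
#' @param volume reconstructed `sv_volume`; `units` must be `"cps/ml"`
#'   (reconstruction run with unit sensitivity) or `"cps/voxel"`.
#' @param calib a `calibration_factor` from [calibrate_sensitivity()].
#' @param ctx an [suv_context()] supplying the decay interval.
#' @return `sv_volume` in Bq/ml, decay-corrected to injection time.
#' @export
to_concentration <- function(volume, calib, ctx) {
  stopifnot(inherits(volume, "sv_volume"),
            inherits(calib, "calibration_factor"))
  if (missing(ctx) || !inherits(ctx, "suv_context")) {
    stop("an `suv_context` with the injection-to-scan interval is required")
  }
  per_ml <- switch(volume$units,
                   "cps/ml" = volume$data,
                   "cps/voxel" = volume$data / voxel_ml(volume),
                   stop("expected units 'cps/ml' or 'cps/voxel', got '",
                        volume$units, "'"))
  decay <- 2^(ctx$injection_to_scan_h / ctx$half_life_h)
  sv_volume(per_ml / calib$sensitivity_cps_per_bq * decay,
            volume$spacing, units = "Bq/ml")
}

#' Body-weight standardized uptake value image
#'
#' `SUV = concentration (Bq/ml) * body weight (g) / injected dose (Bq)`,
#' with tissue density taken as 1 g/ml. A uniform distribution of the whole
#' dose over the body mass gives SUV = 1 everywhere.
#'
#' @param conc `sv_volume` in Bq/ml (or kBq/ml).
#' @param ctx an [suv_context()].
#' @return `sv_volume` with units `"SUV"`.
#' @export
suv_bw <- function(conc, ctx) {
  stopifnot(inherits(conc, "sv_volume"), inherits(ctx, "suv_context"))
  bq_ml <- switch(conc$units,
                  "Bq/ml" = conc$data,
                  "kBq/ml" = conc$data * 1000,
                  stop("expected units 'Bq/ml' or 'kBq/ml', got '",
                       conc$units, "'"))
  suv <- bq_ml * (ctx$body_weight_kg * 1000) / (ctx$injected_dose_mbq * 1e6)
  sv_volume(suv, conc$spacing, units = "SUV")
}

#' Axis-aligned ellipsoid VOI
#'
#' @param center_mm VOI center relative to the grid center (mm), length 3.
#' @param semiaxes_mm semi-axes (mm), length 3 (scalar = sphere).
#' @return object of class `sv_voi`.
#' @export
voi_ellipsoid <- function(center_mm, semiaxes_mm) {
  if (length(center_mm) == 1L) center_mm <- rep(center_mm, 3L)
  if (length(semiaxes_mm) == 1L) semiaxes_mm <- rep(semiaxes_mm, 3L)
  if (any(semiaxes_mm <= 0)) stop("VOI semi-axes must be > 0")
  structure(list(center_mm = as.numeric(center_mm),
                 semiaxes_mm = as.numeric(semiaxes_mm)),
            class = "sv_voi")
}

voi_mask <- function(volume, voi) {
  d <- dim(volume$data)
  u2 <- ((axis_coords_mm(d[1], volume$spacing[1]) - voi$center_mm[1]) /
           voi$semiaxes_mm[1])^2
  v2 <- ((axis_coords_mm(d[2], volume$spacing[2]) - voi$center_mm[2]) /
           voi$semiaxes_mm[2])^2
  w2 <- ((axis_coords_mm(d[3], volume$spacing[3]) - voi$center_mm[3]) /
           voi$semiaxes_mm[3])^2
  outer(outer(u2, v2, "+"), w2, "+") <= 1
}

#' 50%-of-maximum VOI lesion statistics
#'
#' Within the VOI, voxels with value >= 50% of the VOI maximum form the
#' lesion segment; the record carries the segmented volume in ml and the
#' mean and maximum over the segment.
#'
#' @param volume `sv_volume` (typically SUV or kBq/ml).
#' @param voi an [voi_ellipsoid()].
#' @param lesion_id identifier copied into the record.
#' @param true_class,joint optional annotations copied into the record.
#' @param threshold segmentation threshold as a fraction of the VOI maximum
#'   (default 0.5, inclusive).
#' @return one-row data.frame: `lesion_id`, `volume_ml`, `mean_value`,
#'   `max_value`, `n_voxels`, `true_class`, `joint`.
#' @export
voi_stats <- function(volume, voi, lesion_id = NA_integer_,
                      true_class = NA_character_, joint = NA,
                      threshold = 0.5) {
  stopifnot(inherits(volume, "sv_volume"), inherits(voi, "sv_voi"))
  inside <- voi_mask(volume, voi)
  if (!any(inside)) stop("VOI does not intersect the volume")
  vals <- volume$data[inside]
  mx <- max(vals)
  if (mx <= 0) stop("all-zero VOI: 50%-of-maximum threshold is undefined")
  seg <- vals[vals >= threshold * mx]
  data.frame(lesion_id = lesion_id,
             volume_ml = length(seg) * voxel_ml(volume),
             mean_value = mean(seg),
             max_value = mx,
             n_voxels = length(seg),
             true_class = true_class,
             joint = joint, row.names = NULL)
}

#' Per-zone uptake tabulation
#'
#' Mean (and SD) of the image within each dominant tissue zone, mirroring
#' the tissue-uptake summary used to check that reconstructed bone-to-soft
#' uptake ratios are sensible.
#'
#' @param volume `sv_volume` (e.g. kBq/ml).
#' @param zonemap `sv_zonemap` on the same grid.
#' @return data.frame with `zone`, `n_voxels`, `mean`, `sd`.
#' @export
zone_uptake <- function(volume, zonemap) {
  stopifnot(inherits(volume, "sv_volume"))
  if (!identical(dim(volume$data), dim(zonemap$dominant))) {
    stop("volume and zone map grids do not match")
  }
  z <- as.vector(zonemap$dominant)
  v <- as.vector(volume$data)
  out <- data.frame(zone = 1:5,
                    n_voxels = tabulate(z, 5L),
                    mean = NA_real_, sd = NA_real_)
  for (k in 1:5) {
    if (out$n_voxels[k] > 0) {
      out$mean[k] <- mean(v[z == k])
      out$sd[k] <- stats::sd(v[z == k])
    }
  }
  out
}
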