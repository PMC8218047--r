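#' Create a 3-D volume container
#'
#' Lightweight container used for activity images, attenuation maps and
#' reconstructions: a 3-D numeric array plus isotropic-or-not voxel spacing in
#' mm and a free-text unit label. Physical coordinates are voxel centers;
#' voxel indices are 1-based along each axis; the axis order is (x, y, z).
#'
#' @param data numeric 3-D array.
#' @param spacing voxel spacing in mm; length 1 (isotropic) or 3.
#' @param units unit label, e.g. `"kBq/ml"`, `"1/cm"`, `"cps/ml"`.
#' @return An object of class `sv_volume`.
#' @export
sv_volume <- function(data, spacing = 2.4, units = "arb") {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3-D array, got rank ", length(dim(data)))
  }
  if (any(!is.finite(data))) stop("volume contains non-finite values")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop("`spacing` must be 1 or 3 positive values (mm)")
  }
  structure(list(data = data, spacing = as.numeric(spacing),
                 units = units),
            class = "sv_volume")
}

#' @export
print.sv_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<sv_volume> %d x %d x %d voxels, %.3g x %.3g x %.3g mm, units [%s]\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3], x$units))
  cat(sprintf("  range [%.4g, %.4g], total %.6g (value x ml)\n",
              min(x$data), max(x$data), volume_total(x)))
  invisible(x)
}

#' Voxel volume in ml
#' @param vol an `sv_volume` (or a numeric spacing vector).
#' @return voxel volume in ml (= cm^3).
#' @export
voxel_ml <- function(vol) {
  sp <- if (inherits(vol, "sv_volume")) vol$spacing else vol
  prod(sp) / 1000
}

#' Integrated total of a volume (value times ml)
#'
#' For an activity volume in kBq/ml this is total activity in kBq.
#' @param vol an `sv_volume`.
#' @return scalar sum of voxel values times voxel volume in ml.
#' @export
volume_total <- function(vol) {
  sum(vol$data) * voxel_ml(vol)
}

# voxel-center physical coordinates (mm) along one axis, centered on grid center
axis_coords_mm <- function(n, spacing_mm) {
  (seq_len(n) - (n + 1) / 2) * spacing_mm
}

stopifnot_same_grid <- function(a, b, what = "volumes") {
  if (!identical(dim(a$data), dim(b$data)) ||
      max(abs(a$spacing - b$spacing)) > 1e-9) {
    stop(what, " must share grid dimensions and spacing")
  }
  invisible(TRUE)
}
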