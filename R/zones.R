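#' Convert an attenuation map into a five-class fractional zone map
#'
#' Threshold-based segmentation of the 140 keV attenuation map into the five
#' tissue zones (1 lung/air, 2 adipose, 3 soft tissue, 4 spongy bone,
#' 5 cortical bone). The conversion is smooth: within
#' `transition_halfwidth` of a class boundary, membership mixes the two
#' adjacent zones through a cubic smoothstep, so voxels containing tissue
#' mixtures carry non-integer memberships. Memberships sum to 1 everywhere.
#'
#' @param mu attenuation `sv_volume` (1/cm, finite, >= 0).
#' @param thresholds four strictly increasing class boundaries (1/cm);
#'   defaults bracket the canonical tissue coefficients.
#' @param transition_halfwidth half-width of the mixing band around each
#'   boundary (1/cm, default 0.01).
#' @return object of class `sv_zonemap`: `membership` is a 4-D array
#'   `[x, y, z, zone]`, `dominant` the integer argmax zone per voxel.
#' @export
mu_to_zonemap <- function(mu, thresholds = c(0.07, 0.147, 0.165, 0.230),
                          transition_halfwidth = 0.01) {
  stopifnot(inherits(mu, "sv_volume"))
  if (any(!is.finite(mu$data)) || any(mu$data < 0)) {
    stop("mu-map must be finite and >= 0")
  }
  if (length(thresholds) != 4L || any(diff(thresholds) <= 0)) {
    stop("`thresholds` must be 4 strictly increasing boundaries")
  }
  h <- transition_halfwidth
  if (h < 0) stop("`transition_halfwidth` must be >= 0")
  # overlapping transition bands are harmless: the telescoping construction
  # below keeps memberships in [0, 1] and summing to 1 (three-way mixing)
  d <- dim(mu$data)
  x <- as.vector(mu$data)
  m <- matrix(0, length(x), 5L)
  # upper-zone weight across each boundary b: 0 below b-h, 1 above b+h,
  # cubic smoothstep in between (exactly 0.5 at the boundary)
  upper_w <- function(x, b) {
    if (h == 0) return(as.numeric(x >= b))
    u <- pmin(pmax((x - (b - h)) / (2 * h), 0), 1)
    u * u * (3 - 2 * u)
  }
  w_up <- sapply(thresholds, function(b) upper_w(x, b))  # n x 4
  # zone z occupies the interval (t[z-1], t[z]); membership = w_up over its
  # lower boundary minus w_up over its upper boundary
  m[, 1] <- 1 - w_up[, 1]
  for (z in 2:4) m[, z] <- w_up[, z - 1] - w_up[, z]
  m[, 5] <- w_up[, 4]
  dominant <- max.col(m, ties.method = "last")
  structure(list(membership = array(m, c(d, 5L)),
                 dominant = array(as.integer(dominant), d),
                 spacing = mu$spacing,
                 thresholds = thresholds,
                 transition_halfwidth = h),
            class = "sv_zonemap")
}

#' @export
print.sv_zonemap <- function(x, ...) {
  d <- dim(x$dominant)
  tab <- tabulate(x$dominant, 5L)
  cat(sprintf("<sv_zonemap> %d x %d x %d voxels; dominant-zone counts: %s\n",
              d[1], d[2], d[3], paste(tab, collapse = "/")))
  invisible(x)
}

#' Downsample a zone map onto a coarser grid by block averaging
#'
#' Emulates the CT-to-SPECT grid relation where each reconstruction voxel
#' contains an integer block of CT voxels (four, for a 512 to 256 in-plane
#' matrix change): the membership of a target voxel is the mean membership
#' of its contained source voxels, so fractional memberships still sum to 1.
#'
#' @param zonemap an `sv_zonemap` on the fine grid.
#' @param factor integer downsampling factor per axis; scalar or length 3
#'   (default `c(2, 2, 1)`, in-plane halving).
#' @return `sv_zonemap` on the coarse grid.
#' @export
resample_zonemap <- function(zonemap, factor = c(2L, 2L, 1L)) {
  stopifnot(inherits(zonemap, "sv_zonemap"))
  if (length(factor) == 1L) factor <- rep(factor, 3L)
  factor <- as.numeric(factor)
  if (any(factor < 1) || any(factor != round(factor))) {
    stop("`factor` must be positive integers (arbitrary-grid resampling is not supported)")
  }
  factor <- as.integer(factor)
  d <- dim(zonemap$dominant)
  if (any(d %% factor != 0L)) {
    stop("grid dimensions (", paste(d, collapse = "x"),
         ") are not divisible by the factor (", paste(factor, collapse = "x"), ")")
  }
  dn <- d %/% factor
  m_new <- array(0, c(dn, 5L))
  # block mean via index mapping: target index of each source voxel
  bi <- (seq_len(d[1]) - 1L) %/% factor[1] + 1L
  bj <- (seq_len(d[2]) - 1L) %/% factor[2] + 1L
  bk <- (seq_len(d[3]) - 1L) %/% factor[3] + 1L
  grp <- array(0L, d)
  grp[] <- bi + (rep(bj, each = d[1]) - 1L) * dn[1] +
    (rep(bk, each = d[1] * d[2]) - 1L) * dn[1] * dn[2]
  nblk <- prod(factor)
  for (z in 1:5) {
    s <- rowsum(as.vector(zonemap$membership[, , , z]), as.vector(grp))
    m_new[, , , z] <- array(s / nblk, dn)
  }
  mm <- matrix(m_new, prod(dn), 5L)
  structure(list(membership = m_new,
                 dominant = array(as.integer(max.col(mm, ties.method = "last")), dn),
                 spacing = zonemap$spacing * factor,
                 thresholds = zonemap$thresholds,
                 transition_halfwidth = zonemap$transition_halfwidth),
            class = "sv_zonemap")
}

#' Bone-dominant voxel mask of a zone map
#'
#' Bone zones are spongy (4) and cortical (5) bone; the bone/non-bone
#' dichotomy drives the zonal smoothing masks.
#'
#' @param zonemap an `sv_zonemap`.
#' @param bone_zones zone indices counted as bone (default `c(4, 5)`).
#' @return logical 3-D array, `TRUE` where the dominant zone is bone.
#' @export
bone_mask <- function(zonemap, bone_zones = c(4L, 5L)) {
  zonemap$dominant %in% bone_zones |> array(dim(zonemap$dominant))
}
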