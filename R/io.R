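#' Write a volume to NIfTI
#'
#' @param vol `sv_volume` (3-D) to write; voxel spacing goes into the NIfTI
#'   pixdim. Files are written as NIfTI-2 so the spacing survives the round
#'   trip at double precision. The unit label is not representable in NIfTI
#'   and must be supplied again on reading.
#' @param path output file path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "sv_volume"))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path, version = 2)
  invisible(path)
}

#' Read a volume from NIfTI
#'
#' @param path NIfTI file path.
#' @param units unit label to attach (default `"arb"`).
#' @return `sv_volume`.
#' @export
read_volume <- function(path, units = "arb") {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) {
    stop("expected a rank-3 volume, got rank ", length(dim(img)),
         " in ", path)
  }
  a <- array(as.numeric(img), dim(img))
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0)) {
    stop("missing or invalid voxel spacing in ", path)
  }
  sv_volume(a, sp, units = units)
}

#' Write a zone map to 4-D NIfTI (zone axis last)
#' @param zonemap `sv_zonemap`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_zonemap <- function(zonemap, path) {
  img <- RNifti::asNifti(zonemap$membership)
  RNifti::pixdim(img) <- c(zonemap$spacing, 1)
  RNifti::writeNifti(img, path, datatype = "double", version = 2)
  invisible(path)
}

#' Read a zone map from 4-D NIfTI
#' @param path NIfTI path holding `[x, y, z, zone]` memberships.
#' @return `sv_zonemap` (thresholds unknown after a round trip).
#' @export
read_zonemap <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 4L || dim(img)[4] != 5L) {
    stop("expected a rank-4 zone map with 5 zones, got dims ",
         paste(dim(img), collapse = "x"), " in ", path)
  }
  m <- array(as.numeric(img), dim(img))
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0)) {
    stop("missing or invalid voxel spacing in ", path)
  }
  d <- dim(m)[1:3]
  mm <- matrix(m, prod(d), 5L)
  structure(list(membership = m,
                 dominant = array(as.integer(max.col(mm, ties.method = "last")), d),
                 spacing = sp, thresholds = NULL, transition_halfwidth = NULL),
            class = "sv_zonemap")
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f, version = 2)  # deterministic serialization of the list
  unname(tools::md5sum(f))
}

#' Default end-to-end pipeline configuration
#'
#' A desk-scale configuration: a 48^3 phantom at 2.4 mm with a bone slab
#' and two bone lesions, 60 views, Poisson noise, dual-window scatter,
#' five-zone segmentation and all three reconstruction variants.
#'
#' @param seed global RNG seed recorded in every output.
#' @param n_updates updates per reconstruction (default 24 for runtime).
#' @return nested configuration list accepted by [run_pipeline()].
#' @export
default_pipeline_config <- function(seed = 1L, n_updates = 24L) {
  list(
    seed = as.integer(seed),
    phantom = phantom_spec(
      grid_shape = c(48, 48, 48), voxel_size_mm = 2.4,
      background_class = 1L,
      ellipsoids = list(
        ellipsoid(c(0, 0, 0), c(45, 45, 45), tissue_class = 3L,
                  activity_kbq_ml = 4),
        ellipsoid(c(0, 0, 0), c(12, 40, 40), tissue_class = 4L,
                  activity_kbq_ml = 30),
        ellipsoid(c(0, 12, 12), c(7, 7, 7), tissue_class = 5L,
                  activity_kbq_ml = 120),
        ellipsoid(c(0, -14, -14), c(5, 5, 5), tissue_class = 5L,
                  activity_kbq_ml = 90)
      )),
    lesion_vois = list(
      list(lesion_id = 1L, center_mm = c(0, 12, 12), semiaxes_mm = c(11, 11, 11)),
      list(lesion_id = 2L, center_mm = c(0, -14, -14), semiaxes_mm = c(9, 9, 9))
    ),
    geometry = list(n_views = 60L, dwell_s_per_view = 20,
                    sensitivity_cps_per_bq = 1e-4),
    scatter = list(scatter_fraction = 0.35, broadening_fwhm_mm = 30,
                   k = 0.5, spe_smoothing_fwhm_mm = 15),
    recon = list(n_updates = as.integer(n_updates)),
    suv = list(injected_dose_mbq = 740, body_weight_kg = 75,
               injection_to_scan_h = 3)
  )
}

#' Run the full simulation-to-statistics pipeline
#'
#' Phantom, forward projection, Poisson noise, lower-window scatter
#' simulation, SPE estimation, zone segmentation, the three reconstruction
#' variants, point-source calibration, conversion to Bq/ml and SUV, per-VOI
#' lesion statistics and per-zone uptake. Fully reproducible from the
#' config's seed; the report embeds the config hash and seed.
#'
#' @param config list as produced by [default_pipeline_config()], or a path
#'   to a YAML file holding the tunable scalar fields.
#' @param out_dir optional directory: volumes are written as NIfTI, the
#'   lesion table as CSV and the report as JSON.
#' @return report list with elements `seed`, `config_hash`, `total_counts_mc`,
#'   `n_updates`, `sensitivity_cps_per_bq`, `lesions` (data.frame),
#'   `zone_uptake` (per variant) and `volumes` (reconstructions, in SUV).
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir = NULL) {
  if (is.character(config)) config <- config_from_yaml(config)
  seed <- config$seed
  ph <- make_digital_phantom(config$phantom)
  geom <- do.call(acquisition_geometry,
                  c(config$geometry,
                    list(detector_pixel_mm = config$phantom$voxel_size_mm)))
  model <- system_model(ph$mu, geom)
  expected <- forward_project(ph$activity, model = model)
  expected <- simulate_lower_window(
    expected, scatter_fraction = config$scatter$scatter_fraction,
    broadening_fwhm_mm = config$scatter$broadening_fwhm_mm,
    seed = seed + 1L, poisson = FALSE)
  noisy <- add_poisson_noise(expected, seed = seed)
  noisy <- estimate_scatter(
    noisy, scatter_config(k = config$scatter$k,
                          spe_smoothing_fwhm_mm = config$scatter$spe_smoothing_fwhm_mm))
  zones <- mu_to_zonemap(ph$mu)
  mc <- total_counts_mc(noisy)
  n_upd <- if (is.null(config$recon$n_updates)) select_updates(mc) else
    config$recon$n_updates

  # reconstruct with unit sensitivity, then calibrate to Bq/ml
  geom_unit <- geom; geom_unit$sensitivity_cps_per_bq <- 1
  model_unit <- system_model(ph$mu, geom_unit)
  recons <- list(
    F3D = recon_osem(noisy, model = model_unit,
                     config = recon_config("OSEM", n_updates = n_upd),
                     units_out = "cps/ml"),
    CGAS = recon_cg(noisy, model = model_unit,
                    config = recon_config("CGAS", n_updates = max(6L, n_upd %/% 4L)),
                    units_out = "cps/ml"),
    CGZAS = recon_zonal(noisy, zonemap = zones, model = model_unit,
                        config = recon_config("CGZAS", n_updates = max(6L, n_upd %/% 4L)),
                        units_out = "cps/ml")
  )
  # point-source calibration acquisition (noiseless air scan)
  src <- sv_volume(array(0, dim(ph$activity$data)), ph$activity$spacing,
                   units = "Bq/ml")
  ctr <- (dim(src$data) + 1) %/% 2
  src$data[ctr[1], ctr[2], ctr[3]] <- 111e6 / voxel_ml(src)
  air <- sv_volume(array(0, dim(src$data)), src$spacing, units = "1/cm")
  calib <- calibrate_sensitivity(
    forward_project(src, air, geom), known_activity_bq = 111e6)
  ctx <- do.call(suv_context, config$suv)

  suvs <- lapply(recons, function(r) suv_bw(to_concentration(r, calib, ctx), ctx))
  lesions <- do.call(rbind, lapply(names(suvs), function(variant) {
    do.call(rbind, lapply(config$lesion_vois, function(lv) {
      rec <- voi_stats(suvs[[variant]],
                       voi_ellipsoid(lv$center_mm, lv$semiaxes_mm),
                       lesion_id = lv$lesion_id)
      rec$variant <- variant
      rec
    }))
  }))
  zu <- lapply(recons, function(r) {
    conc <- to_concentration(r, calib, ctx)
    zone_uptake(sv_volume(conc$data / 1000, conc$spacing, "kBq/ml"), zones)
  })
  report <- list(seed = seed, config_hash = config_hash(config),
                 total_counts_mc = mc, n_updates = n_upd,
                 sensitivity_cps_per_bq = calib$sensitivity_cps_per_bq,
                 lesions = lesions, zone_uptake = zu, volumes = suvs)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(suvs)) {
      write_volume(suvs[[nm]], file.path(out_dir, paste0("suv_", nm, ".nii.gz")))
    }
    utils::write.csv(lesions, file.path(out_dir, "lesions.csv"),
                     row.names = FALSE)
    rep_json <- report[setdiff(names(report), "volumes")]
    rep_json$zone_uptake <- zu
    jsonlite::write_json(rep_json, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

# read the scalar pipeline settings from YAML (ellipsoid lists included)
config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- default_pipeline_config(seed = if (is.null(y$seed)) 1L else y$seed)
  if (!is.null(y$phantom)) {
    ell <- lapply(y$phantom$ellipsoids, function(e) {
      ellipsoid(unlist(e$center_mm), unlist(e$semiaxes_mm),
                e$tissue_class, e$activity_kbq_ml)
    })
    cfg$phantom <- phantom_spec(
      grid_shape = unlist(y$phantom$grid_shape),
      voxel_size_mm = y$phantom$voxel_size_mm,
      ellipsoids = ell,
      background_class = if (is.null(y$phantom$background_class)) 1L else
        y$phantom$background_class)
  }
  if (!is.null(y$lesion_vois)) {
    cfg$lesion_vois <- lapply(y$lesion_vois, function(lv) {
      list(lesion_id = lv$lesion_id, center_mm = unlist(lv$center_mm),
           semiaxes_mm = unlist(lv$semiaxes_mm))
    })
  }
  for (sec in c("geometry", "scatter", "recon", "suv")) {
    if (!is.null(y[[sec]])) cfg[[sec]] <- utils::modifyList(cfg[[sec]], y[[sec]])
  }
  cfg
}
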