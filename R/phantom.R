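#' Canonical 140 keV linear attenuation coefficients by tissue zone
#'
#' Literature-typical values (1/cm) at 140 keV for the five tissue classes
#' used throughout: 1 lung/air, 2 adipose, 3 soft tissue, 4 spongy bone,
#' 5 cortical bone.
#' @return named numeric vector of length 5.
#' @export
zone_mu_values <- function() {
  c(lung_air = 0.03, adipose = 0.140, soft_tissue = 0.153,
    spongy_bone = 0.190, cortical_bone = 0.280)
}

#' Specify a digital ellipsoid phantom
#'
#' An axis-aligned ellipsoid phantom on an isotropic grid. Each ellipsoid
#' carries a tissue class (1-5) and an activity concentration; later
#' ellipsoids override earlier ones where they overlap. The space outside
#' all ellipsoids takes `background_class` with zero activity.
#'
#' @param grid_shape integer vector of 3 voxel counts.
#' @param voxel_size_mm isotropic voxel size (default 2.4 mm).
#' @param ellipsoids list of lists with fields `center_mm` (length 3, relative
#'   to the grid center), `semiaxes_mm` (length 3), `tissue_class` (1-5) and
#'   `activity_kbq_ml` (>= 0).
#' @param background_class tissue class of the background (default 1, lung/air).
#' @param mu_values per-class 140 keV attenuation coefficients (1/cm).
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(128, 128, 128), voxel_size_mm = 2.4,
                         ellipsoids = list(), background_class = 1L,
                         mu_values = zone_mu_values()) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1L)) {
    stop("`grid_shape` must be 3 positive integers")
  }
  if (voxel_size_mm <= 0) stop("`voxel_size_mm` must be > 0")
  if (!background_class %in% 1:5) stop("`background_class` must be in 1..5")
  if (length(mu_values) != 5L || any(mu_values < 0)) {
    stop("`mu_values` must be 5 nonnegative coefficients")
  }
  half_extent <- grid_shape * voxel_size_mm / 2
  for (e in ellipsoids) {
    if (!all(c("center_mm", "semiaxes_mm", "tissue_class", "activity_kbq_ml")
             %in% names(e))) {
      stop("each ellipsoid needs center_mm, semiaxes_mm, tissue_class, activity_kbq_ml")
    }
    if (any(e$semiaxes_mm <= 0)) stop("ellipsoid semi-axes must be > 0")
    if (!e$tissue_class %in% 1:5) stop("tissue_class must be in 1..5")
    if (e$activity_kbq_ml < 0) stop("activity_concentration must be >= 0")
    if (any(abs(e$center_mm) + e$semiaxes_mm > half_extent + 1e-9)) {
      stop("ellipsoid extends outside the grid (center ",
           paste(e$center_mm, collapse = ", "), " mm)")
    }
  }
  structure(list(grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
                 ellipsoids = ellipsoids, background_class = as.integer(background_class),
                 mu_values = mu_values),
            class = "phantom_spec")
}

#' Helper to build one ellipsoid entry for [phantom_spec()]
#' @param center_mm center relative to the grid center (mm), length 3.
#' @param semiaxes_mm semi-axes (mm), length 3 (scalar recycled: a sphere radius).
#' @param tissue_class zone index 1-5.
#' @param activity_kbq_ml activity concentration (kBq/ml).
#' @return list usable inside `ellipsoids = list(...)`.
#' @export
ellipsoid <- function(center_mm, semiaxes_mm, tissue_class, activity_kbq_ml) {
  if (length(center_mm) == 1L) center_mm <- rep(center_mm, 3L)
  if (length(semiaxes_mm) == 1L) semiaxes_mm <- rep(semiaxes_mm, 3L)
  list(center_mm = as.numeric(center_mm), semiaxes_mm = as.numeric(semiaxes_mm),
       tissue_class = as.integer(tissue_class),
       activity_kbq_ml = as.numeric(activity_kbq_ml))
}

#' Rasterize a digital phantom into activity and attenuation volumes
#'
#' Voxel membership is decided by voxel-center containment (no
#' anti-aliasing), so analytic ellipsoid totals are reproduced to within
#' one-voxel discretization. The activity value of a voxel is the
#' concentration of the last ellipsoid drawn over it; the attenuation value
#' is the canonical 140 keV coefficient of the voxel's tissue class.
#'
#' @param spec a [phantom_spec()].
#' @return list with `activity` (`sv_volume`, kBq/ml), `mu` (`sv_volume`,
#'   1/cm) and `tissue_class` (integer 3-D array of zone indices 1-5).
#' @export
make_digital_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  vs <- spec$voxel_size_mm
  act <- array(0, d)
  cls <- array(spec$background_class, d)
  cx <- axis_coords_mm(d[1], vs)
  cy <- axis_coords_mm(d[2], vs)
  cz <- axis_coords_mm(d[3], vs)
  for (e in spec$ellipsoids) {
    # squared normalized distances, separable per axis
    u2 <- ((cx - e$center_mm[1]) / e$semiaxes_mm[1])^2
    v2 <- ((cy - e$center_mm[2]) / e$semiaxes_mm[2])^2
    w2 <- ((cz - e$center_mm[3]) / e$semiaxes_mm[3])^2
    inside <- outer(outer(u2, v2, "+"), w2, "+") <= 1
    act[inside] <- e$activity_kbq_ml
    cls[inside] <- e$tissue_class
  }
  mu <- array(spec$mu_values[cls], d)
  list(activity = sv_volume(act, vs, units = "kBq/ml"),
       mu = sv_volume(mu, vs, units = "1/cm"),
       tissue_class = cls)
}

#' Specify a synthetic lesion population
#'
#' Emulates a bone-lesion cohort: classes malignant / benign / questionable /
#' negative-control with fixed proportions, per-class lognormal SUV
#' distributions, lognormal lesion volumes and a Bernoulli joint-location
#' flag. Defaults follow the study design: 40% malignant, 40% benign,
#' 10% questionable, 10% negative controls.
#'
#' @param n_lesions number of lesions.
#' @param class_proportions named proportions over
#'   `c("malignant","benign","questionable","negative")`; must sum to 1.
#' @param suv_meanlog,suv_sdlog named per-class lognormal parameters of SUV.
#' @param volume_meanlog,volume_sdlog lognormal parameters of lesion volume (ml).
#' @param joint_fraction probability a lesion sits at a joint.
#' @param exact_proportions if `TRUE`, class counts are
#'   `round(n * proportion)` (exact when n is divisible by the proportion
#'   denominators) instead of a multinomial draw.
#' @param seed integer RNG seed.
#' @return object of class `lesion_population_spec`.
#' @export
lesion_population_spec <- function(
    n_lesions,
    class_proportions = c(malignant = 0.4, benign = 0.4,
                          questionable = 0.1, negative = 0.1),
    suv_meanlog = c(malignant = log(14), benign = log(7),
                    questionable = log(9), negative = log(3)),
    suv_sdlog = c(malignant = 0.35, benign = 0.35,
                  questionable = 0.4, negative = 0.4),
    volume_meanlog = log(6), volume_sdlog = 0.8,
    joint_fraction = 0.3, exact_proportions = FALSE, seed = 1L) {
  if (n_lesions < 0) stop("`n_lesions` must be >= 0")
  if (abs(sum(class_proportions) - 1) > 1e-9) {
    stop("class proportions must sum to 1")
  }
  if (any(class_proportions < 0)) stop("class proportions must be >= 0")
  if (joint_fraction < 0 || joint_fraction > 1) {
    stop("`joint_fraction` must be in [0, 1]")
  }
  if (any(suv_sdlog <= 0) || volume_sdlog <= 0) stop("sdlog parameters must be > 0")
  structure(list(n_lesions = as.integer(n_lesions),
                 class_proportions = class_proportions,
                 suv_meanlog = suv_meanlog, suv_sdlog = suv_sdlog,
                 volume_meanlog = volume_meanlog, volume_sdlog = volume_sdlog,
                 joint_fraction = joint_fraction,
                 exact_proportions = isTRUE(exact_proportions),
                 seed = as.integer(seed)),
            class = "lesion_population_spec")
}

#' Draw a synthetic lesion table
#'
#' @param spec a [lesion_population_spec()].
#' @return data.frame with columns `lesion_id`, `true_class`, `suv`,
#'   `volume_ml`, `joint`. Reproducible under the spec's seed.
#' @export
make_lesion_population <- function(spec) {
  stopifnot(inherits(spec, "lesion_population_spec"))
  n <- spec$n_lesions
  classes <- names(spec$class_proportions)
  if (n == 0L) {
    return(data.frame(lesion_id = integer(), true_class = character(),
                      suv = numeric(), volume_ml = numeric(),
                      joint = logical()))
  }
  withr_seed(spec$seed, {
    if (spec$exact_proportions) {
      counts <- round(n * spec$class_proportions)
      if (sum(counts) != n) {
        # distribute rounding remainder to the largest fractional parts
        frac <- n * spec$class_proportions - floor(n * spec$class_proportions)
        counts <- floor(n * spec$class_proportions)
        extra <- order(frac, decreasing = TRUE)[seq_len(n - sum(counts))]
        counts[extra] <- counts[extra] + 1
      }
      cls <- rep(classes, times = counts)
    } else {
      cls <- sample(classes, n, replace = TRUE, prob = spec$class_proportions)
    }
    suv <- stats::rlnorm(n, spec$suv_meanlog[cls], spec$suv_sdlog[cls])
    vol <- stats::rlnorm(n, spec$volume_meanlog, spec$volume_sdlog)
    joint <- stats::runif(n) < spec$joint_fraction
    data.frame(lesion_id = seq_len(n), true_class = cls, suv = suv,
               volume_ml = vol, joint = joint, row.names = NULL)
  })
}

#' Specify a simulated reader panel
#'
#' A deliberately simple generative reader model for exercising the
#' concordance pipeline: for each (reader, lesion, variant) cell the reader
#' gives a confident rating (|r| = 2) with per-variant probability `p_h`,
#' otherwise an equivocal one (-1/0/+1), and the rating's sign matches the
#' lesion's true positivity with per-variant probability `p_correct`
#' (equivocal ratings are 0 with probability 1/3, otherwise signed).
#'
#' @param n_readers number of readers (>= 1).
#' @param p_h named per-variant probability of a confident read; names are
#'   the reconstruction variants, default `c(F3D=, F3DCT=, xB=, xBCT=)`.
#' @param p_correct named per-variant probability the call is correct.
#' @param seed RNG seed.
#' @return object of class `reader_model_spec`.
#' @export
reader_model_spec <- function(n_readers = 9L,
                              p_h = c(F3D = 0.6, F3DCT = 0.7, xB = 0.7, xBCT = 0.75),
                              p_correct = c(F3D = 0.75, F3DCT = 0.85,
                                            xB = 0.8, xBCT = 0.88),
                              seed = 1L) {
  if (n_readers < 1) stop("`n_readers` must be >= 1")
  if (any(p_h < 0 | p_h > 1) || any(p_correct < 0 | p_correct > 1)) {
    stop("probabilities must lie in [0, 1]")
  }
  if (!identical(sort(names(p_h)), sort(names(p_correct)))) {
    stop("`p_h` and `p_correct` must name the same variants")
  }
  structure(list(n_readers = as.integer(n_readers), p_h = p_h,
                 p_correct = p_correct, seed = as.integer(seed)),
            class = "reader_model_spec")
}

#' Simulate a reader-rating study over a lesion table
#'
#' @param truth lesion table from [make_lesion_population()]; lesions with
#'   `true_class` of `"malignant"` or `"questionable"` count as truly positive.
#' @param model a [reader_model_spec()].
#' @return data.frame rating table with columns `reader_id`, `scan_id`,
#'   `lesion_id`, `variant`, `question`, `rating` (-2..2). Three lesions are
#'   grouped per scan in lesion order.
#' @export
simulate_rating_study <- function(truth, model) {
  stopifnot(inherits(model, "reader_model_spec"))
  if (nrow(truth) == 0L) stop("`truth` must be non-empty")
  variants <- names(model$p_h)
  nl <- nrow(truth)
  truth_pos <- truth$true_class %in% c("malignant", "questionable")
  grid <- expand.grid(reader_id = seq_len(model$n_readers),
                      lesion_idx = seq_len(nl),
                      variant = variants,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n <- nrow(grid)
  withr_seed(model$seed, {
    confident <- stats::runif(n) < model$p_h[grid$variant]
    correct <- stats::runif(n) < model$p_correct[grid$variant]
    zero_equiv <- stats::runif(n) < 1 / 3
    truth_sign <- ifelse(truth_pos[grid$lesion_idx], 1L, -1L)
    sign <- ifelse(correct, truth_sign, -truth_sign)
    rating <- ifelse(confident, 2L * sign,
                     ifelse(zero_equiv, 0L, 1L * sign))
    data.frame(reader_id = grid$reader_id,
               scan_id = (truth$lesion_id[grid$lesion_idx] - 1L) %/% 3L + 1L,
               lesion_id = truth$lesion_id[grid$lesion_idx],
               variant = grid$variant,
               question = "detection",
               rating = as.integer(rating), row.names = NULL)
  })
}

# run code under a local RNG seed without disturbing the caller's RNG state
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
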