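#' Reconstruction configuration
#'
#' @param variant one of `"OSEM"` (multiplicative EM, reference method),
#'   `"CGAS"` (conjugate-gradient MLEM with attenuation and scatter
#'   correction) or `"CGZAS"` (zonal CG using the CT-derived zone map).
#' @param n_updates number of updates (one update = one subset pass; with one
#'   subset, updates equal full iterations). See [select_updates()].
#' @param n_subsets OSEM subset count; must divide the number of views.
#'   Default 1, which retains the EM monotonicity guarantee.
#' @param post_fwhm_mm post-reconstruction 3-D Gaussian smoothing FWHM (mm).
#'   Scalar for OSEM/CGAS (default 10); for CGZAS a pair
#'   `c(bone = 5, other = 10)` applied with zonal masking.
#' @param inter_iteration_smoothing CGZAS only: apply a gentle zonal
#'   smoothing between CG iterations (default `TRUE`).
#' @param inter_fwhm_mm CGZAS inter-iteration FWHM pair (bone, other);
#'   default half the post-smoothing pair.
#' @param track_likelihood record the Poisson log-likelihood after every
#'   update (adds one forward projection per update).
#' @return object of class `recon_config`.
#' @export
recon_config <- function(variant = c("OSEM", "CGAS", "CGZAS"),
                         n_updates = 48L, n_subsets = 1L,
                         post_fwhm_mm = NULL,
                         inter_iteration_smoothing = TRUE,
                         inter_fwhm_mm = NULL,
                         track_likelihood = FALSE) {
  variant <- match.arg(variant)
  if (n_updates < 1) stop("`n_updates` must be >= 1")
  if (n_subsets < 1) stop("`n_subsets` must be >= 1")
  if (is.null(post_fwhm_mm)) {
    post_fwhm_mm <- if (variant == "CGZAS") c(bone = 5, other = 10) else 10
  }
  if (any(post_fwhm_mm < 0)) stop("post-smoothing FWHM must be >= 0")
  if (variant == "CGZAS") {
    if (length(post_fwhm_mm) != 2L) {
      stop("CGZAS needs a (bone, other) post-smoothing FWHM pair")
    }
    if (is.null(inter_fwhm_mm)) inter_fwhm_mm <- post_fwhm_mm / 2
  }
  structure(list(variant = variant, n_updates = as.integer(n_updates),
                 n_subsets = as.integer(n_subsets),
                 post_fwhm_mm = post_fwhm_mm,
                 inter_iteration_smoothing = isTRUE(inter_iteration_smoothing),
                 inter_fwhm_mm = inter_fwhm_mm,
                 track_likelihood = isTRUE(track_likelihood)),
            class = "recon_config")
}

#' Update count from the total-count rule
#'
#' Acquisitions with at least 6 Mc total counts use 48 updates; lower-count
#' studies use 24. The 6 Mc boundary itself takes 48 (inclusive convention).
#'
#' @param total_counts_mc total peak-window counts in millions.
#' @return 48L or 24L.
#' @export
select_updates <- function(total_counts_mc) {
  if (total_counts_mc < 0) stop("total counts must be >= 0")
  if (total_counts_mc >= 6) 48L else 24L
}

# forward model restricted to a view subset, raw arrays in/out
forward_raw <- function(xarr, model, views) {
  d <- model$dims; nx <- d[1]; ny <- d[2]; nz <- d[3]
  amat <- matrix(xarr, nx * ny, nz)
  out <- array(0, c(nx, nz, length(views)))
  for (i in seq_along(views)) {
    v <- views[i]
    arot <- array(as.matrix(Matrix::crossprod(model$rot[[v]], amat)),
                  c(nx, ny, nz))
    w <- arot * model$att[[v]]
    psf_v <- model$psf_by_radius[[as.character(model$radii[v])]]
    p <- matrix(0, nx, nz)
    for (j in seq_len(ny)) p <- p + psf_v$Bu[[j]] %*% w[, j, ] %*% psf_v$Bv[[j]]
    out[, , i] <- as.matrix(p)
  }
  out * model$scale
}

# adjoint restricted to a view subset; `arr` indexed [u, v, seq_along(views)]
backward_raw <- function(arr, model, views) {
  d <- model$dims; nx <- d[1]; ny <- d[2]; nz <- d[3]
  acc <- matrix(0, nx * ny, nz)
  buf <- array(0, c(nx, ny, nz))
  for (i in seq_along(views)) {
    v <- views[i]
    psf_v <- model$psf_by_radius[[as.character(model$radii[v])]]
    yv <- arr[, , i]
    for (j in seq_len(ny)) {
      buf[, j, ] <- as.matrix(psf_v$Bu[[j]] %*% yv %*% psf_v$Bv[[j]])
    }
    acc <- acc + model$rot[[v]] %*% matrix(buf * model$att[[v]], nx * ny, nz)
  }
  array(as.matrix(acc) * model$scale, d)
}

#' Poisson log-likelihood of projection data under an image
#'
#' `sum(y * log(ybar) - ybar)` with `ybar = A x + spe`, omitting the
#' factorial constant.
#'
#' @param proj `sv_projections` (counts in the peak window; `spe` used if
#'   present).
#' @param x image `sv_volume` or raw 3-D array.
#' @param model a [system_model()].
#' @return scalar log-likelihood.
#' @export
poisson_loglik <- function(proj, x, model) {
  xarr <- if (inherits(x, "sv_volume")) x$data else x
  s <- if (is.null(proj$spe)) 0 else proj$spe
  yb <- forward_raw(xarr, model, seq_len(model$geom$n_views)) + s
  y <- proj$peak
  sum(y[y > 0] * log(pmax(yb[y > 0], .Machine$double.xmin))) - sum(yb)
}

recon_setup <- function(proj, mu, geom, model) {
  if (is.null(model)) model <- system_model(mu, geom)
  if (!identical(dim(proj$peak), c(model$dims[1], model$dims[3],
                                   model$geom$n_views))) {
    stop("projection data do not match the system-model grid")
  }
  s <- proj$spe
  if (is.null(s)) s <- array(0, dim(proj$peak))
  list(model = model, y = proj$peak, s = s)
}

interleaved_subsets <- function(n_views, n_subsets) {
  if (n_views %% n_subsets != 0) {
    stop("`n_subsets` (", n_subsets, ") must divide n_views (", n_views, ")")
  }
  lapply(seq_len(n_subsets), function(k) seq(k, n_views, by = n_subsets))
}

#' OSEM reconstruction (reference method)
#'
#' Ordered-subset EM with the attenuated, resolution-modeled system matrix
#' and an additive scatter term in the denominator:
#' `x <- x / (A_k^T 1) * A_k^T( y_k / (A_k x + s_k) )` over interleaved view
#' subsets, followed by optional isotropic Gaussian post-smoothing. All
#' iterates are nonnegative; with one subset the Poisson log-likelihood is
#' non-decreasing.
#'
#' @param proj `sv_projections` with measured peak counts (and optionally an
#'   SPE from [estimate_scatter()]).
#' @param mu attenuation `sv_volume` (ignored when `model` given).
#' @param geom an [acquisition_geometry()] (ignored when `model` given).
#' @param config a [recon_config()] with `variant = "OSEM"`.
#' @param model optional prebuilt [system_model()].
#' @param units_out unit label of the returned image (`"cps/ml"` when the
#'   model was built with unit sensitivity; `"Bq/ml"` when the geometry
#'   carries the calibrated sensitivity).
#' @param init optional starting image (`sv_volume` or array); default is a
#'   uniform positive image scaled to the total counts.
#' @return reconstructed `sv_volume`; if `config$track_likelihood`, the
#'   per-update log-likelihoods are attached as attribute `"loglik"`.
#' @export
recon_osem <- function(proj, mu = NULL, geom = NULL,
                       config = recon_config("OSEM"), model = NULL,
                       units_out = "Bq/ml", init = NULL) {
  st <- recon_setup(proj, mu, geom, model)
  model <- st$model; y <- st$y; s <- st$s
  subsets <- interleaved_subsets(model$geom$n_views, config$n_subsets)
  sens <- lapply(subsets, function(vv) {
    backward_raw(array(1, c(model$dims[1], model$dims[3], length(vv))),
                 model, vv)
  })
  sens_all <- Reduce(`+`, sens)
  live <- sens_all > 0
  x <- array(0, model$dims)
  x[live] <- sum(y) / sum(sens_all)
  if (!is.null(init)) {
    xi <- if (inherits(init, "sv_volume")) init$data else init
    x[live] <- xi[live]
  }
  ll <- numeric(0)
  for (u in seq_len(config$n_updates)) {
    k <- (u - 1L) %% config$n_subsets + 1L
    vv <- subsets[[k]]
    yb <- forward_raw(x, model, vv) + s[, , vv, drop = FALSE]
    ratio <- array(0, dim(yb))
    pos <- yb > 0
    ratio[pos] <- y[, , vv, drop = FALSE][pos] / yb[pos]
    bp <- backward_raw(ratio, model, vv)
    x[live] <- x[live] * bp[live] / sens[[k]][live]
    if (config$track_likelihood) ll <- c(ll, poisson_loglik(proj, x, model))
  }
  if (length(config$post_fwhm_mm) == 1L && config$post_fwhm_mm > 0) {
    sm <- masked_gaussian_smoother(array(TRUE, model$dims),
                                   config$post_fwhm_mm, model$spacing)
    x <- sm(x)
  }
  out <- sv_volume(x, model$spacing, units = units_out)
  if (config$track_likelihood) attr(out, "loglik") <- ll
  out
}

# One pass of preconditioned Polak-Ribiere CG on the Poisson log-likelihood.
# `post_iter` is an optional hook applied to the iterate after each update
# (the zonal inter-iteration regularization).
cg_core <- function(proj, model, config, post_iter = NULL, init = NULL) {
  y <- proj$peak
  s <- proj$spe
  if (is.null(s)) s <- array(0, dim(y))
  all_views <- seq_len(model$geom$n_views)
  sens <- backward_raw(array(1, c(model$dims[1], model$dims[3],
                                  length(all_views))), model, all_views)
  live <- sens > 0
  x <- array(0, model$dims)
  x[live] <- sum(y) / sum(sens)
  if (!is.null(init)) {
    xi <- if (inherits(init, "sv_volume")) init$data else init
    x[live] <- xi[live]
  }
  loglik_at <- function(xa) {
    yb <- forward_raw(xa, model, all_views) + s
    sum(y[y > 0] * log(pmax(yb[y > 0], .Machine$double.xmin))) - sum(yb)
  }
  ll_x <- loglik_at(x)
  ll <- numeric(0)
  dir <- NULL; g_prev <- NULL; pg_prev <- NULL
  for (it in seq_len(config$n_updates)) {
    yb <- forward_raw(x, model, all_views) + s
    ratio <- array(0, dim(yb))
    pos <- yb > 0
    ratio[pos] <- y[pos] / yb[pos]
    g <- backward_raw(ratio - 1, model, all_views)
    g[!live] <- 0
    precond <- array(0, model$dims)
    precond[live] <- x[live] / sens[live]
    pg <- precond * g
    if (is.null(dir)) {
      dir <- pg
    } else {
      beta <- max(0, (sum(g * pg) - sum(g * pg_prev)) /
                    max(sum(g_prev * pg_prev), .Machine$double.xmin))
      dir <- pg + beta * dir
      if (sum(dir * g) <= 0) dir <- pg  # restart on non-ascent direction
    }
    g_prev <- g; pg_prev <- pg
    if (max(abs(dir)) == 0) {  # stationary point (e.g. exact fixed point)
      if (config$track_likelihood) ll <- c(ll, ll_x)
      next
    }
    # line search: alpha = 1 is the EM step when dir = precond * g;
    # expand while the likelihood keeps improving, otherwise backtrack
    alpha <- 1
    cand <- pmax(x + alpha * dir, 0)
    ll_cand <- loglik_at(cand)
    if (ll_cand >= ll_x) {
      repeat {
        a2 <- alpha * 2
        c2 <- pmax(x + a2 * dir, 0)
        l2 <- loglik_at(c2)
        if (l2 > ll_cand && a2 <= 16) {
          alpha <- a2; cand <- c2; ll_cand <- l2
        } else break
      }
    } else {
      for (bt in seq_len(25L)) {
        alpha <- alpha / 2
        cand <- pmax(x + alpha * dir, 0)
        ll_cand <- loglik_at(cand)
        if (ll_cand >= ll_x) break
      }
      if (ll_cand < ll_x) {  # no ascent along dir: keep x, restart CG
        dir <- NULL
        if (config$track_likelihood) ll <- c(ll, ll_x)
        next
      }
    }
    x <- cand; ll_x <- ll_cand
    if (!is.null(post_iter)) {
      x <- post_iter(x)
      ll_x <- loglik_at(x)
    }
    if (config$track_likelihood) ll <- c(ll, ll_x)
  }
  list(x = x, loglik = ll)
}

#' Conjugate-gradient MLEM reconstruction (non-zonal variant)
#'
#' Maximizes the same Poisson log-likelihood as OSEM by Polak-Ribiere
#' nonlinear CG with an EM-preconditioned gradient (the first step equals an
#' EM update), an expanding/backtracking monotone line search, and
#' nonnegativity by projection. One CG update is typically worth several
#' OSEM updates. Isotropic Gaussian post-smoothing as configured.
#'
#' @inheritParams recon_osem
#' @param config a [recon_config()] with `variant = "CGAS"`.
#' @return reconstructed `sv_volume` (attribute `"loglik"` when tracked).
#' @export
recon_cg <- function(proj, mu = NULL, geom = NULL,
                     config = recon_config("CGAS"), model = NULL,
                     units_out = "Bq/ml", init = NULL) {
  st <- recon_setup(proj, mu, geom, model)
  res <- cg_core(proj, st$model, config, init = init)
  x <- res$x
  if (length(config$post_fwhm_mm) == 1L && config$post_fwhm_mm > 0) {
    sm <- masked_gaussian_smoother(array(TRUE, st$model$dims),
                                   config$post_fwhm_mm, st$model$spacing)
    x <- sm(x)
  }
  out <- sv_volume(x, st$model$spacing, units = units_out)
  if (config$track_likelihood) attr(out, "loglik") <- res$loglik
  out
}

#' Zonal conjugate-gradient reconstruction
#'
#' CG-MLEM as in [recon_cg()] plus the zone-map information: an optional
#' gentle zonal smoothing between iterations and an edge-preserving zonal
#' post-smoothing (default 5 mm in bone-dominant voxels, 10 mm elsewhere),
#' both with masking so no intensity crosses the bone/non-bone boundary and
#' per-set totals are conserved.
#'
#' @inheritParams recon_cg
#' @param zonemap `sv_zonemap` on the reconstruction grid.
#' @param config a [recon_config()] with `variant = "CGZAS"`.
#' @return reconstructed `sv_volume`.
#' @export
recon_zonal <- function(proj, mu = NULL, geom = NULL, zonemap,
                        config = recon_config("CGZAS"), model = NULL,
                        units_out = "Bq/ml", init = NULL) {
  st <- recon_setup(proj, mu, geom, model)
  if (!identical(dim(zonemap$dominant), st$model$dims)) {
    stop("zone map grid does not match the reconstruction grid")
  }
  post_iter <- NULL
  if (config$inter_iteration_smoothing && any(config$inter_fwhm_mm > 0)) {
    sm_i <- zonal_smoother_pair(zonemap, config$inter_fwhm_mm[1],
                                config$inter_fwhm_mm[2], st$model$spacing)
    post_iter <- sm_i
  }
  res <- cg_core(proj, st$model, config, post_iter = post_iter, init = init)
  x <- zonal_postsmooth(sv_volume(res$x, st$model$spacing, units = units_out),
                        zonemap,
                        fwhm_bone = config$post_fwhm_mm[1],
                        fwhm_other = config$post_fwhm_mm[2])
  if (config$track_likelihood) attr(x, "loglik") <- res$loglik
  x
}

zonal_smoother_pair <- function(zonemap, fwhm_bone, fwhm_other, spacing) {
  mb <- bone_mask(zonemap)
  sb <- masked_gaussian_smoother(mb, fwhm_bone, spacing)
  so <- masked_gaussian_smoother(!mb, fwhm_other, spacing)
  function(x) so(sb(x))
}

#' Edge-preserving zonal post-smoothing
#'
#' Gaussian smoothing computed independently within the bone-dominant and
#' non-bone voxel sets, with the kernel renormalized over same-set
#' neighbors: no intensity crosses the bone/non-bone boundary, constants
#' within a set are reproduced, and each set's total activity is conserved.
#'
#' @param volume `sv_volume` to smooth.
#' @param zonemap `sv_zonemap` on the same grid.
#' @param fwhm_bone FWHM (mm) inside bone-dominant voxels (default 5).
#' @param fwhm_other FWHM (mm) elsewhere (default 10).
#' @return smoothed `sv_volume`.
#' @export
zonal_postsmooth <- function(volume, zonemap, fwhm_bone = 5, fwhm_other = 10) {
  stopifnot(inherits(volume, "sv_volume"))
  if (!identical(dim(volume$data), dim(zonemap$dominant))) {
    stop("volume and zone map grids do not match")
  }
  sm <- zonal_smoother_pair(zonemap, fwhm_bone, fwhm_other, volume$spacing)
  sv_volume(sm(volume$data), volume$spacing, units = volume$units)
}

#' Post-reconstruction voxel isotropization hook
#'
#' Reconstruction here is performed on isotropic grids, so this hook is the
#' identity on them; anisotropic grids are rejected rather than silently
#' resampled.
#'
#' @param volume `sv_volume`.
#' @return `volume` unchanged when already isotropic.
#' @export
isotropize_voxels <- function(volume) {
  stopifnot(inherits(volume, "sv_volume"))
  if (max(abs(volume$spacing - volume$spacing[1])) > 1e-9) {
    stop("anisotropic grid: isotropization resampling is not supported")
  }
  volume
}
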