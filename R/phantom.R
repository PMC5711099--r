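#' Ellipsoidal lesion specification
#'
#' Describes one synthetic lesion: an ellipsoid with a plateau uptake,
#' optionally modulated by spatially correlated heterogeneity.
#'
#' @param center mm triple, lesion center in patient coordinates.
#' @param semiaxes mm triple, ellipsoid semi-axes (> 0).
#' @param uptake plateau SUV inside the lesion (> 0).
#' @param heterogeneity_sd SUV standard deviation of intra-lesion texture
#'   (0 = homogeneous).
#' @param texture_scale mm correlation length of the intra-lesion texture.
#' @return An object of class \code{lesion_spec} with the analytic volume in
#'   ml as \code{analytic_volume_ml}.
#' @export
lesion_spec <- function(center, semiaxes, uptake,
                        heterogeneity_sd = 0, texture_scale = 8) {
  center <- as.numeric(center); semiaxes <- as.numeric(semiaxes)
  stopifnot(length(center) == 3L, length(semiaxes) == 3L)
  if (any(semiaxes <= 0)) stop("semiaxes must be > 0")
  if (uptake <= 0) stop("uptake must be > 0")
  if (heterogeneity_sd < 0) stop("heterogeneity_sd must be >= 0")
  structure(list(center = center, semiaxes = semiaxes, uptake = uptake,
                 heterogeneity_sd = heterogeneity_sd,
                 texture_scale = texture_scale,
                 analytic_volume_ml = 4 / 3 * pi * prod(semiaxes) / 1000),
            class = "lesion_spec")
}

#' Phantom specification: one synthetic patient
#'
#' Generative description of one synthetic PET study: a background SUV field,
#' one or more target lesions inside the analysis ROI, optional confounder
#' structures (bladder-like hot regions) outside the ROI, Gaussian PSF blur,
#' and intensity-dependent reconstruction-like noise.
#'
#' @param lesions list of \code{\link{lesion_spec}} (the targets).
#' @param pet_grid \code{\link{image_grid}}; default 64 x 64 x 48 voxels at
#'   4 mm isotropic, a reduced pelvic field of view.
#' @param background_suv background SUV level (default 2).
#' @param confounders list of \code{\link{lesion_spec}} placed outside
#'   \code{roi} (default none).
#' @param roi \code{\link{roi_box}} for the analysis region; default a box
#'   around the target lesions with a 24 mm margin.
#' @param psf_fwhm mm FWHM of the isotropic Gaussian PSF (default 7).
#' @param noise_sd_at_background SUV noise sd at background intensity
#'   (default 0.15); the local sd scales as sqrt(local mean / background).
#' @param seed integer RNG seed for the noise and texture fields.
#' @return An object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(lesions, pet_grid = NULL, background_suv = 2,
                         confounders = list(), roi = NULL,
                         psf_fwhm = 7, noise_sd_at_background = 0.15,
                         seed = 1L) {
  if (inherits(lesions, "lesion_spec")) lesions <- list(lesions)
  stopifnot(length(lesions) >= 1L,
            all(vapply(lesions, inherits, logical(1), "lesion_spec")))
  if (is.null(pet_grid)) {
    pet_grid <- image_grid(c(64, 64, 48), c(4, 4, 4), c(-126, -126, -94))
  }
  if (is.null(roi)) {
    ctr <- t(vapply(lesions, `[[`, numeric(3), "center"))
    ax <- t(vapply(lesions, `[[`, numeric(3), "semiaxes"))
    roi <- roi_box(apply(ctr - ax, 2, min) - 24, apply(ctr + ax, 2, max) + 24)
  }
  if (psf_fwhm < 0) stop("psf_fwhm must be >= 0")
  if (noise_sd_at_background < 0) stop("noise sd must be >= 0")
  if (background_suv < 0) stop("background_suv must be >= 0")
  for (cf in confounders) {
    if (all(cf$center >= roi$lo & cf$center <= roi$hi))
      stop("confounder centers must lie outside the roi box")
  }
  structure(list(pet_grid = pet_grid, background_suv = background_suv,
                 lesions = lesions, confounders = confounders, roi = roi,
                 psf_fwhm = psf_fwhm,
                 noise_sd_at_background = noise_sd_at_background,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

## logical array of voxel centers inside the ellipsoid
ellipsoid_member <- function(grid, les) {
  cx <- (grid_centers_1d(grid, 1) - les$center[1]) / les$semiaxes[1]
  cy <- (grid_centers_1d(grid, 2) - les$center[2]) / les$semiaxes[2]
  cz <- (grid_centers_1d(grid, 3) - les$center[3]) / les$semiaxes[3]
  q <- outer(outer(cx^2, cy^2, "+"), cz^2, "+")
  q <= 1
}

#' Generate one synthetic PET case from a phantom spec
#'
#' Deterministic given \code{spec$seed}. Pipeline: paint the background SUV,
#' add lesion plateaus (plus correlated Gaussian texture for heterogeneous
#' lesions, clipped at 0), convolve with the isotropic Gaussian PSF
#' (reflective padding, mass conserving), then add voxelwise Gaussian noise
#' whose sd scales with the square root of the local mean, normalized so the
#' background sd equals \code{noise_sd_at_background}; negative values are
#' clipped at 0. The ground-truth mask is the pre-blur rasterization of the
#' target ellipsoids on the PET grid.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @return An object of class \code{phantom_case}: list with \code{spec},
#'   \code{pet} (\code{\link{suv_volume}}), \code{truth}
#'   (\code{\link{binary_mask}}), \code{roi} (\code{\link{roi_box}}).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- spec$pet_grid
  ext <- grid_extent(g)
  truth <- array(FALSE, dim = g$dims)
  with_rng(spec$seed, {
    vals <- array(spec$background_suv, dim = g$dims)
    for (les in c(spec$lesions, spec$confounders)) {
      if (any(les$center < ext$lo) || any(les$center > ext$hi))
        stop("lesion center outside the grid extent")
      mem <- ellipsoid_member(g, les)
      if (!any(mem)) stop("lesion does not cover any voxel center")
      add <- array(0, dim = g$dims)
      add[mem] <- les$uptake - spec$background_suv
      if (les$heterogeneity_sd > 0) {
        wn <- array(stats::rnorm(prod(g$dims)), dim = g$dims)
        tex <- gaussian_blur(wn, 2.355 * les$texture_scale, g$spacing)
        tex <- tex / stats::sd(tex) * les$heterogeneity_sd
        add[mem] <- add[mem] + tex[mem]
      }
      vals <- vals + add
      vals[vals < 0] <- 0
    }
    for (les in spec$lesions) truth <- truth | ellipsoid_member(g, les)
    vals <- gaussian_blur(vals, spec$psf_fwhm, g$spacing)
    if (spec$noise_sd_at_background > 0) {
      sd_loc <- spec$noise_sd_at_background *
        sqrt(pmax(vals, 0) / max(spec$background_suv, 1e-12))
      vals <- vals + array(stats::rnorm(prod(g$dims)), dim = g$dims) * sd_loc
    }
    vals[vals < 0] <- 0
    structure(list(spec = spec,
                   pet = suv_volume(g, vals),
                   truth = binary_mask(g, truth),
                   roi = spec$roi),
              class = "phantom_case")
  })
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("<phantom_case> truth %.2f ml, SUVmax %.2f, seed %d\n",
              mask_volume_ml(x$truth), max(x$pet$values), x$spec$seed))
  invisible(x)
}

#' Default cohort parameter ranges
#'
#' The study conditions for the synthetic cohort: lesion analytic volumes
#' log-normal (meanlog log(20), sdlog 0.85, spanning roughly 4-120 ml),
#' tumor-to-background contrast uniform in [3, 10], half the cohort with
#' heterogeneous uptake, 7 mm PSF, and 0.15 SUV background noise.
#'
#' @return Named list of ranges consumed by \code{\link{generate_cohort}}.
#' @export
cohort_ranges <- function() {
  list(volume_meanlog = log(20), volume_sdlog = 0.85,
       contrast_range = c(3, 10),
       heterogeneous_fraction = 0.5,
       heterogeneity_rel_sd = 0.25,
       aspect_range = c(0.7, 1.4),
       background_suv = 2,
       psf_fwhm = 7,
       noise_sd_at_background = 0.15)
}

#' Generate a synthetic phantom cohort
#'
#' Stand-in for the study population: \code{n} synthetic patients with known
#' ground truth. Lesion analytic volumes are drawn log-normally, contrasts
#' uniformly, ellipsoid aspect ratios mildly anisotropic, and a stated
#' fraction of lesions receives correlated heterogeneity. Deterministic given
#' \code{seed}.
#'
#' @param n number of cases (default 31).
#' @param ranges parameter ranges as from \code{\link{cohort_ranges}}.
#' @param seed integer master seed; per-case seeds are derived from it.
#' @return List of \code{phantom_case} objects (class \code{phantom_cohort}).
#' @export
generate_cohort <- function(n = 31, ranges = cohort_ranges(), seed = 1L) {
  stopifnot(n >= 1)
  if (length(ranges) == 0L) stop("empty ranges")
  specs <- with_rng(seed, {
    lapply(seq_len(n), function(i) {
      v_ml <- stats::rlnorm(1, ranges$volume_meanlog, ranges$volume_sdlog)
      contrast <- stats::runif(1, ranges$contrast_range[1], ranges$contrast_range[2])
      asp <- stats::runif(2, ranges$aspect_range[1], ranges$aspect_range[2])
      # semiaxes a, a*asp1, a*asp2 with 4/3 pi a^3 asp1 asp2 = v
      a <- (v_ml * 1000 * 3 / (4 * pi * prod(asp)))^(1 / 3)
      het <- stats::runif(1) < ranges$heterogeneous_fraction
      uptake <- ranges$background_suv * contrast
      les <- lesion_spec(center = c(0, 0, 0) + stats::runif(3, -6, 6),
                         semiaxes = c(a, a * asp[1], a * asp[2]),
                         uptake = uptake,
                         heterogeneity_sd = if (het) ranges$heterogeneity_rel_sd * uptake else 0)
      case_seed <- sample.int(.Machine$integer.max - 1L, 1)
      phantom_spec(list(les),
                   background_suv = ranges$background_suv,
                   psf_fwhm = ranges$psf_fwhm,
                   noise_sd_at_background = ranges$noise_sd_at_background,
                   seed = case_seed)
    })
  })
  structure(lapply(specs, generate_phantom), class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  v <- vapply(x, function(cs) mask_volume_ml(cs$truth), numeric(1))
  cat(sprintf("<phantom_cohort> %d cases, truth volumes %.1f-%.1f ml (mean %.1f)\n",
              length(x), min(v), max(v), mean(v)))
  invisible(x)
}

#' Planning-CT grid covering an extent
#'
#' Returns the planning-CT-resolution grid: the "fine" kind with
#' 0.59 x 0.59 x 3 mm voxels (the 1024 x 1024 reconstruction) or the
#' "coarse" kind with 1.17 x 1.17 x 3 mm voxels (512 x 512), with just
#' enough voxels to cover the requested extent.
#'
#' @param kind \code{"fine"} or \code{"coarse"}.
#' @param extent list with mm triples \code{lo}, \code{hi} to cover; default
#'   the extent of the default PET grid.
#' @return An \code{\link{image_grid}}.
#' @export
make_ct_grid <- function(kind = c("fine", "coarse"), extent = NULL) {
  kind <- match.arg(kind)
  spacing <- if (kind == "fine") c(0.59, 0.59, 3) else c(1.17, 1.17, 3)
  if (is.null(extent)) {
    extent <- grid_extent(image_grid(c(64, 64, 48), c(4, 4, 4), c(-126, -126, -94)))
  }
  span <- extent$hi - extent$lo
  dims <- pmax(1L, as.integer(ceiling(span / spacing)))
  origin <- extent$lo + spacing / 2
  image_grid(dims, spacing, origin)
}
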