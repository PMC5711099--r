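#' Reference uptake under a software dialect
#'
#' The two commercial-software dialects for the "maximal SUV within the
#' tumor" used by relative thresholding: \code{"max_voxel"} takes the hottest
#' voxel in the ROI; \code{"neighborhood_mean5"} averages the hottest voxel
#' with its 4 hottest 26-neighbors (fewer at image edges), reproducing
#' workstations that threshold against an average of five pixels around the
#' maximum rather than the maximum itself.
#'
#' @param vol a \code{\link{suv_volume}}.
#' @param roi a \code{\link{roi_box}} containing at least one voxel center.
#' @param dialect \code{"max_voxel"} or \code{"neighborhood_mean5"}.
#' @return Scalar reference SUV.
#' @export
reference_uptake <- function(vol, roi, dialect = c("max_voxel", "neighborhood_mean5")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(vol, "suv_volume"))
  rmem <- roi_member(vol$grid, roi)
  if (!any(rmem)) stop("roi contains no voxel centers")
  v <- vol$values
  vin <- ifelse(rmem, v, -Inf)
  lin <- which.max(vin)
  if (dialect == "max_voxel") return(v[lin])
  d <- dim(v)
  kk <- (lin - 1L) %/% (d[1] * d[2])
  jj <- ((lin - 1L) %% (d[1] * d[2])) %/% d[1]
  ii <- (lin - 1L) %% d[1]
  nb <- numeric(0)
  for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
    if (di == 0 && dj == 0 && dk == 0) next
    i <- ii + di; j <- jj + dj; k <- kk + dk
    if (i < 0 || i >= d[1] || j < 0 || j >= d[2] || k < 0 || k >= d[3]) next
    nb <- c(nb, v[k * d[1] * d[2] + j * d[1] + i + 1L])
  }
  top <- sort(nb, decreasing = TRUE)[seq_len(min(4L, length(nb)))]
  mean(c(v[lin], top))
}

#' Keep the connected component holding the hottest ROI voxel
#'
#' Mirrors the physician's exclusion of physiological uptake: of all
#' above-threshold voxels, only the 26-connected component containing the
#' hottest mask voxel inside the ROI is kept. An empty mask passes through
#' empty.
#'
#' @param mask a \code{\link{binary_mask}} (candidate voxels).
#' @param vol the source \code{\link{suv_volume}} (for hotness ranking).
#' @param roi the analysis \code{\link{roi_box}}.
#' @return A \code{\link{binary_mask}} restricted to one component.
#' @export
connected_component_filter <- function(mask, vol, roi) {
  stopifnot(inherits(mask, "binary_mask"), inherits(vol, "suv_volume"))
  if (!any(mask$member)) return(mask)
  rmem <- roi_member(vol$grid, roi)
  cand <- mask$member & rmem
  if (!any(cand)) cand <- mask$member
  vin <- ifelse(cand, vol$values, -Inf)
  seed <- which.max(vin)
  binary_mask(mask$grid, flood26(mask$member, seed))
}

#' Absolute-SUV threshold delineation
#'
#' Voxels inside the ROI whose SUV is greater than or equal to the absolute
#' threshold (default 2.5 SUV), reduced to the component containing the
#' hottest ROI voxel.
#'
#' @param vol a \code{\link{suv_volume}}.
#' @param roi a \code{\link{roi_box}}.
#' @param absolute_suv threshold in SUV units (default 2.5).
#' @return A \code{\link{binary_mask}}; may be empty.
#' @export
segment_fixed_threshold <- function(vol, roi, absolute_suv = 2.5) {
  stopifnot(absolute_suv > 0)
  mem <- roi_member(vol$grid, roi) & vol$values >= absolute_suv
  connected_component_filter(binary_mask(vol$grid, mem), vol, roi)
}

#' Relative-threshold delineation (percentage of the reference uptake)
#'
#' Voxels inside the ROI at or above \code{fraction} times the reference
#' uptake (default 45 percent), where the reference is computed under the
#' chosen software dialect; reduced to the hottest connected component.
#'
#' @inheritParams reference_uptake
#' @param fraction threshold fraction in (0,1), default 0.45.
#' @return A \code{\link{binary_mask}}.
#' @export
segment_relative_threshold <- function(vol, roi, fraction = 0.45,
                                       dialect = c("max_voxel", "neighborhood_mean5")) {
  stopifnot(fraction > 0, fraction < 1)
  dialect <- match.arg(dialect)
  thr <- fraction * reference_uptake(vol, roi, dialect)
  mem <- roi_member(vol$grid, roi) & vol$values >= thr
  connected_component_filter(binary_mask(vol$grid, mem), vol, roi)
}

#' Delineation arm configuration
#'
#' Bundles a method name with its parameters; the six default study arms are
#' built by \code{\link{default_arms}}.
#'
#' @param method one of \code{"fixed_threshold"}, \code{"relative_threshold"},
#'   \code{"flab"}, \code{"gbm"}.
#' @param label display label for report tables.
#' @param absolute_suv,fraction,dialect threshold-arm parameters.
#' @param flab_params list(n_fuzzy_levels, max_iter, tol); see
#'   \code{\link{segment_flab}}.
#' @param gbm_params list(spatial_sigma, range_sigma, decon_iters, psf_fwhm);
#'   see \code{\link{segment_gbm}}.
#' @return An object of class \code{seg_config}.
#' @export
seg_config <- function(method = c("fixed_threshold", "relative_threshold", "flab", "gbm"),
                       label = NULL, absolute_suv = 2.5, fraction = 0.45,
                       dialect = "max_voxel",
                       flab_params = list(n_fuzzy_levels = 3L, max_iter = 100L, tol = 1e-3),
                       gbm_params = list(spatial_sigma = 6, range_sigma = 1,
                                         decon_iters = 10L, psf_fwhm = 7)) {
  method <- match.arg(method)
  if (is.null(label)) label <- method
  structure(list(method = method, label = label, absolute_suv = absolute_suv,
                 fraction = fraction, dialect = dialect,
                 flab_params = flab_params, gbm_params = gbm_params),
            class = "seg_config")
}

#' The six default study arms
#'
#' Two absolute-threshold arms (SUV 2.5) and two relative-threshold arms
#' (45 percent) tagged by reference-uptake dialect — mirroring the two
#' commercial software products — plus the FLAB and gradient-based arms.
#'
#' @param psf_fwhm PSF FWHM (mm) passed to the gradient-based arm's
#'   deconvolution (default 7).
#' @return Named list of \code{\link{seg_config}} objects.
#' @export
default_arms <- function(psf_fwhm = 7) {
  list(
    OA2.5  = seg_config("fixed_threshold", label = "OA2.5", dialect = "max_voxel"),
    PH2.5  = seg_config("fixed_threshold", label = "PH2.5", dialect = "neighborhood_mean5"),
    OA45   = seg_config("relative_threshold", label = "OA45%", dialect = "max_voxel"),
    PH45   = seg_config("relative_threshold", label = "PH45%", dialect = "neighborhood_mean5"),
    FLAB   = seg_config("flab", label = "FLAB"),
    GBM    = seg_config("gbm", label = "GBM",
                        gbm_params = list(spatial_sigma = 6, range_sigma = 1,
                                          decon_iters = 10L, psf_fwhm = psf_fwhm))
  )
}

#' Run one delineation arm
#'
#' Dispatches to the configured method and wraps the mask with its volume and
#' SUV statistics.
#'
#' @param vol a \code{\link{suv_volume}}.
#' @param roi a \code{\link{roi_box}}.
#' @param config a \code{\link{seg_config}}.
#' @return An object of class \code{segmentation_result}: list with
#'   \code{label}, \code{mask}, \code{volume_ml}, \code{suv_max},
#'   \code{suv_mean} (the last two \code{NA} for an empty mask).
#' @export
run_segmentation <- function(vol, roi, config) {
  stopifnot(inherits(config, "seg_config"))
  mask <- switch(config$method,
    fixed_threshold    = segment_fixed_threshold(vol, roi, config$absolute_suv),
    relative_threshold = segment_relative_threshold(vol, roi, config$fraction, config$dialect),
    flab               = segment_flab(vol, roi, config$flab_params),
    gbm                = segment_gbm(vol, roi, config$gbm_params))
  if (any(mask$member)) {
    st <- suv_stats(vol, mask)
  } else {
    st <- list(suv_max = NA_real_, suv_mean = NA_real_)
  }
  structure(list(label = config$label, mask = mask,
                 volume_ml = mask_volume_ml(mask),
                 suv_max = st$suv_max, suv_mean = st$suv_mean),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> %s: %.2f ml, SUVmax %.2f, SUVmean %.2f\n",
              x$label, x$volume_ml, x$suv_max, x$suv_mean))
  invisible(x)
}
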