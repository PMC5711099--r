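#' Resample an SUV volume onto a target grid
#'
#' Emulates the clinical workstation step in which PET images are resampled
#' onto the planning-CT grid before delineation. Each target voxel center is
#' mapped into source space by \code{xf} and the source volume is sampled by
#' trilinear interpolation; points outside the source extent read 0 SUV
#' (background-air assumption).
#'
#' @param vol source \code{\link{suv_volume}}.
#' @param target target \code{\link{image_grid}}.
#' @param xf \code{\link{rigid_transform}} mapping target-space mm points to
#'   source-space mm points. Default identity.
#' @return A \code{\link{suv_volume}} on \code{target}.
#' @export
resample_suv <- function(vol, target, xf = rigid_transform()) {
  stopifnot(inherits(vol, "suv_volume"), inherits(target, "image_grid"))
  pts <- target_points_in_source(target, xf)
  vals <- trilinear_sample(vol, pts)
  suv_volume(target, array(vals, dim = target$dims))
}

#' Resample a binary mask onto a target grid
#'
#' Nearest-neighbor lookup at transformed target voxel centers; centers
#' falling outside the source extent are non-members. Used to compare masks
#' across PET and CT grids.
#'
#' @inheritParams resample_suv
#' @param mask source \code{\link{binary_mask}}.
#' @return A \code{\link{binary_mask}} on \code{target}.
#' @export
resample_mask <- function(mask, target, xf = rigid_transform()) {
  stopifnot(inherits(mask, "binary_mask"), inherits(target, "image_grid"))
  pts <- target_points_in_source(target, xf)
  idx <- world_to_index(mask$grid, pts)
  ijk <- round(idx) + 1  # nearest voxel, 1-based
  d <- mask$grid$dims
  ok <- ijk[, 1] >= 1 & ijk[, 1] <= d[1] &
        ijk[, 2] >= 1 & ijk[, 2] <= d[2] &
        ijk[, 3] >= 1 & ijk[, 3] <= d[3]
  out <- logical(nrow(ijk))
  if (any(ok)) {
    lin <- (ijk[ok, 3] - 1) * d[1] * d[2] + (ijk[ok, 2] - 1) * d[1] + ijk[ok, 1]
    out[ok] <- mask$member[lin]
  }
  binary_mask(target, array(out, dim = target$dims))
}

## all target voxel centers, transformed into source space (n x 3, column-major)
target_points_in_source <- function(target, xf) {
  cx <- grid_centers_1d(target, 1)
  cy <- grid_centers_1d(target, 2)
  cz <- grid_centers_1d(target, 3)
  n <- prod(target$dims)
  pts <- cbind(rep(cx, times = target$dims[2] * target$dims[3]),
               rep(rep(cy, each = target$dims[1]), times = target$dims[3]),
               rep(cz, each = target$dims[1] * target$dims[2]))
  stopifnot(nrow(pts) == n)
  apply_transform(xf, pts)
}

## trilinear interpolation of vol at mm points; outside extent -> 0.
## Interpolation support is the convex hull of voxel centers; between the
## outermost centers and the grid extent the nearest-face value would need
## extrapolation, so values there are taken from the clamped edge cell only
## when the point is still inside the center hull; strictly outside -> 0.
trilinear_sample <- function(vol, pts) {
  g <- vol$grid
  idx <- world_to_index(g, pts)  # continuous 0-based
  d <- g$dims
  inside <- idx[, 1] >= 0 & idx[, 1] <= d[1] - 1 &
            idx[, 2] >= 0 & idx[, 2] <= d[2] - 1 &
            idx[, 3] >= 0 & idx[, 3] <= d[3] - 1
  out <- numeric(nrow(idx))
  if (!any(inside)) return(out)
  ii <- idx[inside, , drop = FALSE]
  i0 <- pmin(floor(ii[, 1]), d[1] - 2 + (d[1] == 1))
  j0 <- pmin(floor(ii[, 2]), d[2] - 2 + (d[2] == 1))
  k0 <- pmin(floor(ii[, 3]), d[3] - 2 + (d[3] == 1))
  i0 <- pmax(i0, 0); j0 <- pmax(j0, 0); k0 <- pmax(k0, 0)
  fx <- ii[, 1] - i0; fy <- ii[, 2] - j0; fz <- ii[, 3] - k0
  i1 <- pmin(i0 + 1, d[1] - 1); j1 <- pmin(j0 + 1, d[2] - 1); k1 <- pmin(k0 + 1, d[3] - 1)
  at <- function(i, j, k) vol$values[k * d[1] * d[2] + j * d[1] + i + 1]
  v <- at(i0, j0, k0) * (1 - fx) * (1 - fy) * (1 - fz) +
       at(i1, j0, k0) * fx       * (1 - fy) * (1 - fz) +
       at(i0, j1, k0) * (1 - fx) * fy       * (1 - fz) +
       at(i1, j1, k0) * fx       * fy       * (1 - fz) +
       at(i0, j0, k1) * (1 - fx) * (1 - fy) * fz +
       at(i1, j0, k1) * fx       * (1 - fy) * fz +
       at(i0, j1, k1) * (1 - fx) * fy       * fz +
       at(i1, j1, k1) * fx       * fy       * fz
  out[inside] <- v
  out
}

#' Extract the sub-volume covered by an ROI box
#'
#' Returns the smallest grid-aligned crop whose voxel centers fall inside the
#' box, as a new volume with an adjusted origin. The delineation arms work on
#' such crops.
#'
#' @param vol a \code{\link{suv_volume}}.
#' @param roi a \code{\link{roi_box}}; must intersect the grid.
#' @param margin integer, extra voxels of context on each side (default 0).
#' @return A list with \code{vol} (cropped \code{suv_volume}) and
#'   \code{offset} (0-based index triple of the crop within the parent grid).
#' @export
crop_to_roi <- function(vol, roi, margin = 0L) {
  g <- vol$grid
  rng <- roi_index_range(g, roi)
  lo <- pmax(c(rng[[1]][1], rng[[2]][1], rng[[3]][1]) - margin, 1L)
  hi <- pmin(c(rng[[1]][2], rng[[2]][2], rng[[3]][2]) + margin, g$dims)
  sub <- vol$values[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  sg <- image_grid(hi - lo + 1L, g$spacing, g$origin + (lo - 1) * g$spacing)
  list(vol = suv_volume(sg, sub), offset = lo - 1L)
}

## paste a mask defined on a crop back onto the parent grid
uncrop_mask <- function(cropmask, parent_grid, offset) {
  full <- array(FALSE, dim = parent_grid$dims)
  d <- cropmask$grid$dims
  full[offset[1] + seq_len(d[1]), offset[2] + seq_len(d[2]), offset[3] + seq_len(d[3])] <-
    cropmask$member
  binary_mask(parent_grid, full)
}
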