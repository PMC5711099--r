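#' Axis-aligned 3-D image grid
#'
#' Defines the geometry every volume and mask in the package lives on: an
#' axis-aligned lattice in patient millimetres. Voxel indices are 0-based;
#' the center of voxel (i,j,k) sits at \code{origin + c(i,j,k) * spacing},
#' and the voxel occupies the half-open box
#' \code{[center - spacing/2, center + spacing/2)}.
#'
#' @param dims integer vector of length 3, voxel counts per axis (all >= 1).
#' @param spacing numeric vector of length 3, voxel edge lengths in mm (> 0).
#' @param origin numeric vector of length 3, patient-mm position of the center
#'   of voxel (0,0,0). Default \code{c(0,0,0)}.
#' @return An object of class \code{image_grid}.
#' @examples
#' g <- image_grid(c(144, 144, 144), c(4, 4, 4))
#' voxel_volume_ml(g)  # 0.064
#' @export
image_grid <- function(dims, spacing, origin = c(0, 0, 0)) {
  dims <- as.integer(dims)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  stopifnot(length(dims) == 3L, length(spacing) == 3L, length(origin) == 3L)
  if (any(dims < 1L)) stop("all grid dims must be >= 1")
  if (any(!is.finite(spacing)) || any(spacing <= 0)) stop("all spacings must be > 0")
  if (any(!is.finite(origin))) stop("origin must be finite")
  structure(list(dims = dims, spacing = spacing, origin = origin),
            class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("<image_grid> %d x %d x %d voxels, spacing %.4g x %.4g x %.4g mm, origin (%.4g, %.4g, %.4g) mm\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Voxel volume of a grid in millilitres
#'
#' @param grid an \code{\link{image_grid}}.
#' @return Scalar volume of one voxel in ml (product of spacings / 1000).
#' @export
voxel_volume_ml <- function(grid) {
  stopifnot(inherits(grid, "image_grid"))
  prod(grid$spacing) / 1000
}

same_grid <- function(a, b, tol = 1e-9) {
  all(a$dims == b$dims) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

#' Physical extent of a grid
#'
#' Returns the patient-mm bounding box covered by the voxel boxes of the grid
#' (outer faces of the edge voxels).
#'
#' @param grid an \code{\link{image_grid}}.
#' @return list with \code{lo} and \code{hi}, mm triples.
#' @export
grid_extent <- function(grid) {
  stopifnot(inherits(grid, "image_grid"))
  list(lo = grid$origin - grid$spacing / 2,
       hi = grid$origin + (grid$dims - 1) * grid$spacing + grid$spacing / 2)
}

## world mm -> continuous 0-based voxel index
world_to_index <- function(grid, xyz) {
  sweep(sweep(xyz, 2, grid$origin, "-"), 2, grid$spacing, "/")
}

## 0-based index triples (matrix n x 3) -> world mm voxel centers
index_to_world <- function(grid, ijk) {
  sweep(sweep(ijk, 2, grid$spacing, "*"), 2, grid$origin, "+")
}

## matrix (n x 3) of world coordinates of every voxel center, column-major order
grid_centers_1d <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$dims[axis]) - 1) * grid$spacing[axis]
}

#' SUV volume on a grid
#'
#' A 3-D scalar field of standardized uptake values (SUV, dimensionless) on
#' an \code{\link{image_grid}}. Values must be finite and non-negative.
#'
#' @param grid an \code{\link{image_grid}}.
#' @param values numeric 3-D array with \code{dim == grid$dims}, or a single
#'   number recycled to the full grid.
#' @return An object of class \code{suv_volume} with fields \code{grid} and
#'   \code{values}.
#' @export
suv_volume <- function(grid, values) {
  stopifnot(inherits(grid, "image_grid"))
  if (length(values) == 1L) values <- array(as.numeric(values), dim = grid$dims)
  if (!is.array(values) || !all(dim(values) == grid$dims))
    stop("values must be an array matching grid dims")
  storage.mode(values) <- "double"
  if (any(!is.finite(values))) stop("SUV values must be finite")
  if (any(values < 0)) stop("SUV values must be >= 0")
  structure(list(grid = grid, values = values), class = "suv_volume")
}

#' @export
print.suv_volume <- function(x, ...) {
  cat(sprintf("<suv_volume> %d x %d x %d, SUV range [%.3g, %.3g]\n",
              x$grid$dims[1], x$grid$dims[2], x$grid$dims[3],
              min(x$values), max(x$values)))
  invisible(x)
}

#' Binary voxel mask on a grid
#'
#' @param grid an \code{\link{image_grid}}.
#' @param member logical 3-D array matching the grid dims (TRUE = member), or
#'   a single logical recycled.
#' @return An object of class \code{binary_mask}.
#' @export
binary_mask <- function(grid, member) {
  stopifnot(inherits(grid, "image_grid"))
  if (length(member) == 1L) member <- array(as.logical(member), dim = grid$dims)
  if (!is.array(member) || !all(dim(member) == grid$dims))
    stop("member must be an array matching grid dims")
  storage.mode(member) <- "logical"
  if (any(is.na(member))) stop("mask may not contain NA")
  structure(list(grid = grid, member = member), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d x %d, %d voxels, %.3f ml\n",
              x$grid$dims[1], x$grid$dims[2], x$grid$dims[3],
              sum(x$member), mask_volume_ml(x)))
  invisible(x)
}

#' Mask volume in millilitres
#'
#' The central measurand of the package: the metabolic tumor volume (MTV) of
#' a segmentation, i.e. member-voxel count times voxel volume.
#'
#' @param mask a \code{\link{binary_mask}}.
#' @return Scalar volume in ml.
#' @export
mask_volume_ml <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  sum(mask$member) * voxel_volume_ml(mask$grid)
}

#' Rigid-body transform
#'
#' A rotation plus translation mapping target-space points into source space
#' for resampling. Registration estimation is out of scope; transforms are
#' known inputs.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1. Default identity.
#' @param translation mm triple. Default zero.
#' @return An object of class \code{rigid_transform}.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  translation <- as.numeric(translation)
  stopifnot(length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8 || abs(det(rotation) - 1) > 1e-8)
    stop("rotation must be orthonormal with det +1")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' Apply a rigid transform to points
#' @param xf a \code{\link{rigid_transform}}.
#' @param xyz n x 3 matrix of mm points.
#' @return n x 3 matrix of transformed points.
#' @export
apply_transform <- function(xf, xyz) {
  stopifnot(inherits(xf, "rigid_transform"))
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  sweep(xyz %*% t(xf$rotation), 2, xf$translation, "+")
}

#' Invert a rigid transform
#' @param xf a \code{\link{rigid_transform}}.
#' @return The inverse \code{rigid_transform}.
#' @export
invert_transform <- function(xf) {
  stopifnot(inherits(xf, "rigid_transform"))
  Rt <- t(xf$rotation)
  rigid_transform(Rt, -as.vector(Rt %*% xf$translation))
}

#' Axis-aligned analysis region (ROI box)
#'
#' The physician's region-restriction role: delineation arms only consider
#' voxels whose centers fall inside this box, which excludes physiological
#' uptake such as the bladder.
#'
#' @param lo,hi mm triples, componentwise \code{lo < hi}.
#' @return An object of class \code{roi_box}.
#' @export
roi_box <- function(lo, hi) {
  lo <- as.numeric(lo); hi <- as.numeric(hi)
  stopifnot(length(lo) == 3L, length(hi) == 3L)
  if (any(lo >= hi)) stop("roi_box requires lo < hi componentwise")
  structure(list(lo = lo, hi = hi), class = "roi_box")
}

## logical array: voxel centers inside the roi box (closed box)
roi_member <- function(grid, roi) {
  stopifnot(inherits(roi, "roi_box"))
  inx <- grid_centers_1d(grid, 1) >= roi$lo[1] & grid_centers_1d(grid, 1) <= roi$hi[1]
  iny <- grid_centers_1d(grid, 2) >= roi$lo[2] & grid_centers_1d(grid, 2) <= roi$hi[2]
  inz <- grid_centers_1d(grid, 3) >= roi$lo[3] & grid_centers_1d(grid, 3) <= roi$hi[3]
  outer(outer(inx, iny, "&"), inz, "&")
}

## 1-based index ranges of voxels whose centers are inside the roi
roi_index_range <- function(grid, roi) {
  rng <- lapply(1:3, function(a) {
    cc <- grid_centers_1d(grid, a)
    w <- which(cc >= roi$lo[a] & cc <= roi$hi[a])
    if (length(w) == 0L) NULL else range(w)
  })
  if (any(vapply(rng, is.null, logical(1)))) stop("roi does not intersect the grid")
  rng
}

#' SUV statistics over a mask
#'
#' @param vol a \code{\link{suv_volume}}.
#' @param mask a non-empty \code{\link{binary_mask}} on the same grid.
#' @return Named list with \code{suv_max} and \code{suv_mean}.
#' @export
suv_stats <- function(vol, mask) {
  stopifnot(inherits(vol, "suv_volume"), inherits(mask, "binary_mask"))
  if (!same_grid(vol$grid, mask$grid)) stop("vol and mask must share a grid")
  if (!any(mask$member)) stop("suv_stats undefined for an empty mask")
  v <- vol$values[mask$member]
  list(suv_max = max(v), suv_mean = mean(v))
}
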