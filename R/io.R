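#' Write an SUV volume or mask as NIfTI
#'
#' Stores the voxel array with the grid spacing in \code{pixdim} and the
#' origin in the sform translation (axis-aligned affine). Masks are stored
#' as 0/1 integers.
#'
#' @param x a \code{\link{suv_volume}} or \code{\link{binary_mask}}.
#' @param path output path (\code{.nii} or \code{.nii.gz}).
#' @return \code{path}, invisibly.
#' @export
write_nifti_volume <- function(x, path) {
  if (inherits(x, "binary_mask")) {
    arr <- array(as.integer(x$member), dim = x$grid$dims)
    grid <- x$grid
  } else if (inherits(x, "suv_volume")) {
    arr <- x$values
    grid <- x$grid
  } else stop("x must be a suv_volume or binary_mask")
  img <- RNifti::asNifti(arr)
  aff <- diag(4)
  diag(aff)[1:3] <- grid$spacing
  aff[1:3, 4] <- grid$origin
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI file as an SUV volume or mask
#'
#' Inverse of \code{\link{write_nifti_volume}}: spacing is taken from
#' \code{pixdim}, origin from the sform translation (absolute values of the
#' diagonal affine; this package uses axis-aligned grids only).
#'
#' @param path NIfTI file path.
#' @param as \code{"suv"} (default) or \code{"mask"}.
#' @return A \code{\link{suv_volume}} or \code{\link{binary_mask}}.
#' @export
read_nifti_volume <- function(path, as = c("suv", "mask")) {
  as <- match.arg(as)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) stop("expected a 3-D NIfTI volume")
  arr <- array(as.numeric(arr), dim = dim(arr))  # drop RNifti attributes
  aff <- RNifti::xform(img)
  offdiag <- aff[1:3, 1:3]; diag(offdiag) <- 0
  if (max(abs(offdiag)) > 1e-6 || any(diag(aff)[1:3] < 0))
    stop("only axis-aligned, unflipped volumes are supported")
  grid <- image_grid(dim(arr), diag(aff)[1:3], aff[1:3, 4])
  if (as == "mask") binary_mask(grid, arr != 0) else suv_volume(grid, arr)
}

#' Read a DICOM image series as an SUV volume
#'
#' Optional ingest path for uncompressed explicit-VR little-endian image
#' slices: position and spacing are taken from the standard attributes
#' (Image Position Patient, Pixel Spacing), slices sorted by z, pixel data
#' rescaled with Rescale Slope/Intercept.
#'
#' @param paths character vector of slice file paths (one file per slice).
#' @return A \code{\link{suv_volume}}.
#' @export
read_dicom_series <- function(paths) {
  stopifnot(length(paths) >= 1L)
  slices <- lapply(paths, read_dicom_slice)
  z <- vapply(slices, `[[`, numeric(1), "z")
  o <- order(z)
  slices <- slices[o]; z <- z[o]
  dz <- if (length(z) > 1L) diff(z) else 1
  if (length(z) > 1L && max(abs(dz - dz[1])) > 1e-4)
    stop("slices are not equally spaced")
  first <- slices[[1L]]
  nx <- ncol(first$pixels); ny <- nrow(first$pixels)
  vals <- array(0, dim = c(nx, ny, length(slices)))
  for (k in seq_along(slices)) {
    if (!all(dim(slices[[k]]$pixels) == dim(first$pixels)))
      stop("inconsistent slice dimensions")
    # DICOM rows advance along -?y; store column-major x,y
    vals[, , k] <- t(slices[[k]]$pixels)
  }
  spacing <- c(first$col_spacing, first$row_spacing,
               if (length(z) > 1L) dz[1] else first$thickness)
  grid <- image_grid(dim(vals), spacing, c(first$pos[1], first$pos[2], z[1]))
  suv_volume(grid, pmax(vals, 0))
}

read_dicom_slice <- function(path) {
  b <- readBin(path, "raw", n = file.info(path)$size)
  if (length(b) < 140L || rawToChar(b[129:132]) != "DICM")
    stop(sprintf("%s: not a DICOM file", path))
  p <- 133L
  glen_el <- parse_one(b, p, "(filemeta)")
  glen <- r_u32(glen_el$el$value, 1L)
  els <- parse_elements(b, glen_el$next_p + glen, length(b), "")
  num <- function(g, e, default = NULL) {
    el <- find_el(els, g, e)
    if (is.null(el)) {
      if (is.null(default)) stop(sprintf("%s: missing element (%04X,%04X)", path, g, e))
      return(default)
    }
    as.numeric(strsplit(el_string(el), "\\\\")[[1L]])
  }
  rows <- {
    el <- find_el(els, 0x0028, 0x0010)
    if (el$vr == "US") r_u16(el$value, 1L) else as.integer(el_string(el))
  }
  cols <- {
    el <- find_el(els, 0x0028, 0x0011)
    if (el$vr == "US") r_u16(el$value, 1L) else as.integer(el_string(el))
  }
  ps <- num(0x0028, 0x0030)           # PixelSpacing: row spacing, col spacing
  pos <- num(0x0020, 0x0032)          # ImagePositionPatient
  slope <- num(0x0028, 0x1053, 1)[1]
  intercept <- num(0x0028, 0x1052, 0)[1]
  thick <- num(0x0018, 0x0050, 1)[1]
  pd <- find_el(els, 0x7FE0, 0x0010)
  if (is.null(pd)) stop(sprintf("%s: missing element (7FE0,0010) PixelData", path))
  raw16 <- readBin(pd$value, "integer", n = rows * cols, size = 2L,
                   signed = FALSE, endian = "little")
  px <- matrix(raw16, nrow = rows, ncol = cols, byrow = TRUE) * slope + intercept
  list(pixels = px, row_spacing = ps[1], col_spacing = ps[2],
       pos = pos[1:2], z = pos[3], thickness = thick)
}
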