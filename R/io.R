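#' Read a 3D scalar NIfTI volume
#'
#' Accepts a NIfTI-1 file holding a single 3D scalar image. Grid spacing is
#' taken from the header pixdim, origin from the sform/qform translation.
#' Axes are assumed axis-aligned (no oblique orientation handling).
#'
#' @param path filesystem path to a `.nii` / `.nii.gz` file.
#' @return a [scalar_volume()].
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) { d <- d[1:3]; dim(img) <- d }
  if (length(d) != 3L)
    stop(sprintf("expected a 3D scalar NIfTI, got %d-dimensional payload %s",
                 length(d), paste(d, collapse = "x")))
  grid <- .grid_from_header(img, d)
  scalar_volume(array(as.numeric(img), dim = d), grid)
}

#' Write a 3D scalar volume as NIfTI
#' @param vol a [scalar_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$values,
    reference = list(pixdim = c(-1, vol$grid$spacing, 1, 1, 0, 0)))
  img <- RNifti::`sform<-`(img, structure(.grid_affine(vol$grid), code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a displacement field from NIfTI
#'
#' Accepts either the 5D "vector" dialect (`x,y,z,1,3`, intent code 1007) or
#' a plain 4D image with 3 components. Vectors are interpreted as physical mm
#' displacements, fixed -> moving.
#'
#' @param path filesystem path.
#' @return a [displacement_field()].
#' @export
read_field <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 5L && d[4] == 1L && d[5] == 3L) {
    arr <- array(as.numeric(img), dim = c(d[1:3], 3L))
  } else if (length(d) == 4L && d[4] == 3L) {
    arr <- array(as.numeric(img), dim = d)
  } else {
    stop(sprintf(
      "expected a 3-vector displacement field (5D x,y,z,1,3 or 4D x,y,z,3), got %s",
      paste(d, collapse = "x")))
  }
  grid <- .grid_from_header(img, d[1:3])
  displacement_field(arr, grid)
}

#' Write a displacement field as NIfTI (5D vector dialect)
#' @param field a [displacement_field()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path) {
  d <- dim(field$vectors)
  arr <- array(field$vectors, dim = c(d[1:3], 1L, 3L))
  img <- RNifti::asNifti(arr,
    reference = list(pixdim = c(-1, field$grid$spacing, 1, 1, 0, 0),
                     intent_code = 1007L))
  img <- RNifti::`sform<-`(img, structure(.grid_affine(field$grid), code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

.grid_affine <- function(grid) {
  rbind(cbind(diag(grid$spacing), grid$origin), c(0, 0, 0, 1))
}

.grid_from_header <- function(img, shape3) {
  hdr <- RNifti::niftiHeader(img)
  spacing <- abs(as.numeric(hdr$pixdim[2:4]))
  if (any(spacing <= 0))
    stop("malformed NIfTI header: non-positive voxel spacing")
  xf <- try(RNifti::xform(img), silent = TRUE)
  origin <- if (inherits(xf, "try-error")) c(0, 0, 0) else {
    # translation of the axis-aligned affine; sign flips (LPS/RAS) are
    # normalized away since this package treats axes as abstract
    o <- as.numeric(xf[1:3, 4])
    flip <- diag(xf[1:3, 1:3, drop = FALSE]) < 0
    o[flip] <- o[flip] - (shape3[flip] - 1) * spacing[flip]
    o
  }
  image_grid(shape3, spacing, origin)
}
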