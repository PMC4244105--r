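#' Construct an image volume
#'
#' A 3D scalar intensity grid indexed `[z, y, x]` (axial slices along z,
#' y increasing anterior to posterior), with voxel spacing in mm. All
#' downstream stages of the pipeline consume this container.
#'
#' @param data numeric 3D array with dim `(nz, ny, nx)`; finite, non-negative.
#' @param spacing numeric triple `(dz, dy, dx)` in mm, strictly positive.
#' @param origin numeric triple, mm position of voxel `[1,1,1]`.
#' @return an object of class `image_volume`.
#' @export
image_volume <- function(data, spacing, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array (z, y, x)")
  if (any(dim(data) < 1L)) stop("all dimensions must be >= 1")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three strictly positive values (dz, dy, dx) in mm")
  if (any(!is.finite(data))) stop("intensities must be finite")
  if (any(data < 0)) stop("intensities must be non-negative")
  structure(
    list(data = data, spacing = spacing, origin = as.numeric(origin),
         orientation = "axial"),
    class = "image_volume"
  )
}

#' Construct a binary mask
#'
#' A `{0,1}` grid sharing the shape and spacing convention of
#' [image_volume()]; used for segmentations, the refined breast mask, the
#' parenchyma region, and reference segmentations.
#'
#' @param data 3D array coercible to integer 0/1, dim `(nz, ny, nx)`.
#' @param spacing numeric triple `(dz, dy, dx)` in mm.
#' @return an object of class `binary_mask`.
#' @export
binary_mask <- function(data, spacing) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array (z, y, x)")
  d <- array(as.integer(data != 0), dim = dim(data))
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three strictly positive values (dz, dy, dx) in mm")
  structure(list(data = d, spacing = spacing), class = "binary_mask")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_volume> %d x %d x %d (z,y,x), spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<binary_mask> %d x %d x %d (z,y,x), %d foreground voxels\n",
              d[1], d[2], d[3], sum(x$data)))
  invisible(x)
}

#' Inclusive slice range
#'
#' The user-selected start and end axial slices; processing is restricted to
#' this range to avoid irrelevant computation on slices without breast tissue.
#'
#' @param z_start,z_end 1-based inclusive slice indices, `z_start <= z_end`.
#' @return an object of class `slice_range`.
#' @export
slice_range <- function(z_start, z_end) {
  z_start <- as.integer(z_start); z_end <- as.integer(z_end)
  if (length(z_start) != 1L || length(z_end) != 1L ||
      is.na(z_start) || is.na(z_end))
    stop("slice indices must be single integers")
  if (z_start < 1L) stop("z_start must be >= 1")
  if (z_start > z_end) stop("z_start must not exceed z_end")
  structure(list(z_start = z_start, z_end = z_end), class = "slice_range")
}

validate_range <- function(r, vol) {
  stopifnot(inherits(r, "slice_range"))
  if (r$z_end > dim(vol$data)[1])
    stop(sprintf("slice range [%d, %d] exceeds volume with %d slices",
                 r$z_start, r$z_end, dim(vol$data)[1]))
  invisible(r)
}

#' Crop a volume to a slice range
#'
#' @param vol an [image_volume()].
#' @param r a [slice_range()] valid for `vol`.
#' @return an `image_volume` with `z_end - z_start + 1` slices; the origin is
#'   shifted by `(z_start - 1) * dz` along z.
#' @export
crop_slices <- function(vol, r) {
  stopifnot(inherits(vol, "image_volume"))
  validate_range(r, vol)
  d <- vol$data[r$z_start:r$z_end, , , drop = FALSE]
  origin <- vol$origin
  origin[1] <- origin[1] + (r$z_start - 1L) * vol$spacing[1]
  image_volume(d, vol$spacing, origin)
}

# (z,y,x) array -> RNifti-style (x,y,z) and back
zyx_to_xyz <- function(a) aperm(a, c(3, 2, 1))
xyz_to_zyx <- function(a) aperm(a, c(3, 2, 1))

#' Read a 3D volume
#'
#' Reads a NIfTI-1 file (`.nii` / `.nii.gz`) or a directory containing a
#' single-frame DICOM series. Spacing is always taken from the file headers.
#' On-disk NIfTI storage is `(x, y, z)`; arrays are permuted to the package's
#' `(z, y, x)` convention.
#'
#' @param path file (NIfTI) or directory (DICOM series).
#' @param format_hint `"auto"`, `"nifti"` or `"dicom"`.
#' @return an [image_volume()].
#' @export
read_volume <- function(path, format_hint = c("auto", "nifti", "dicom")) {
  format_hint <- match.arg(format_hint)
  if (!file.exists(path))
    stop(sprintf("cannot read volume: '%s' does not exist", path))
  fmt <- format_hint
  if (fmt == "auto") fmt <- if (dir.exists(path)) "dicom" else "nifti"
  if (fmt == "dicom") return(read_dicom_series(path))
  img <- RNifti::readNifti(path)
  if (length(dim(img)) == 2L) dim(img) <- c(dim(img), 1L)
  if (length(dim(img)) != 3L)
    stop(sprintf("'%s': expected a 3D volume, got %dD", path, length(dim(img))))
  pd <- RNifti::pixdim(img)
  image_volume(xyz_to_zyx(array(as.numeric(img), dim = dim(img))),
               spacing = rev(pd[1:3]))
}

#' Write a volume as NIfTI
#'
#' @param vol an [image_volume()].
#' @param path output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "image_volume"))
  img <- RNifti::asNifti(zyx_to_xyz(vol$data))
  RNifti::pixdim(img) <- rev(vol$spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a binary mask as NIfTI (uint8 payload)
#'
#' @param mask a [binary_mask()].
#' @param path output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  img <- RNifti::asNifti(zyx_to_xyz(mask$data))
  RNifti::pixdim(img) <- rev(mask$spacing)
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Read a binary mask from NIfTI
#'
#' Any nonzero voxel is treated as foreground.
#'
#' @param path `.nii` / `.nii.gz` file.
#' @return a [binary_mask()].
#' @export
read_mask <- function(path) {
  v <- read_volume(path, "nifti")
  binary_mask(v$data != 0, v$spacing)
}
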