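#' Restrict a segmentation to the refined breast mask
#'
#' Elementwise AND: removes every segmented region outside the breast.
#'
#' @param seg3d,breast [binary_mask()]s of equal shape.
#' @return a [binary_mask()].
#' @export
mask_segmentation <- function(seg3d, breast) {
  stopifnot(inherits(seg3d, "binary_mask"), inherits(breast, "binary_mask"))
  if (!identical(dim(seg3d$data), dim(breast$data)))
    stop("segmentation and breast mask shapes differ")
  binary_mask(seg3d$data & breast$data, breast$spacing)
}

#' Extract the fibroglandular (parenchymal) region
#'
#' The parenchyma is the part of the solid breast mask that the first stage
#' did not classify as bright fatty tissue:
#' `P = breast AND NOT (seg AND breast)`. Together with
#' [mask_segmentation()] this partitions the breast mask exactly into fat
#' and parenchyma.
#'
#' @param seg3d the bright-tissue segmentation ([binary_mask()]).
#' @param breast the refined solid breast mask ([binary_mask()]).
#' @return a [binary_mask()] of the parenchymal region.
#' @export
extract_parenchyma <- function(seg3d, breast) {
  fat <- mask_segmentation(seg3d, breast)
  binary_mask(breast$data & !fat$data, breast$spacing)
}

#' Breast-density report
#'
#' Counts breast (BV) and parenchyma (PV) voxels, converts to liters through
#' the voxel volume, and computes percent density `100 * PV / BV`, with a
#' per-slice table.
#'
#' @param breast,parenchyma [binary_mask()]s of equal shape;
#'   `parenchyma` must be a subset of `breast`.
#' @param spacing optional spacing override `(dz, dy, dx)` mm; defaults to
#'   the mask spacing.
#' @return an object of class `density_report`: `bv_voxels`, `pv_voxels`,
#'   `bv_liters`, `pv_liters`, `density_percent`, and `per_slice`
#'   (data frame z / bv_vox / pv_vox).
#' @export
compute_report <- function(breast, parenchyma, spacing = breast$spacing) {
  stopifnot(inherits(breast, "binary_mask"), inherits(parenchyma, "binary_mask"))
  if (!identical(dim(breast$data), dim(parenchyma$data)))
    stop("mask shapes differ")
  if (any(parenchyma$data & !breast$data))
    stop("parenchyma mask extends outside the breast mask")
  bv <- sum(breast$data)
  pv <- sum(parenchyma$data)
  if (bv == 0) stop("breast mask is empty; density is undefined")
  vox_mm3 <- prod(spacing)
  per_slice <- data.frame(
    z = seq_len(dim(breast$data)[1]),
    bv_vox = apply(breast$data, 1, sum),
    pv_vox = apply(parenchyma$data, 1, sum))
  structure(list(
    bv_voxels = bv, pv_voxels = pv,
    bv_liters = bv * vox_mm3 * 1e-6,
    pv_liters = pv * vox_mm3 * 1e-6,
    density_percent = 100 * pv / bv,
    per_slice = per_slice
  ), class = "density_report")
}

#' @export
print.density_report <- function(x, ...) {
  cat(sprintf("<density_report> BV %.4f L (%d vox), PV %.4f L (%d vox), density %.1f%%\n",
              x$bv_liters, x$bv_voxels, x$pv_liters, x$pv_voxels,
              x$density_percent))
  invisible(x)
}
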