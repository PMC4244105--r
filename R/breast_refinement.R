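#' Parameters of the breast-mask refinement stage
#'
#' All geometric constants of the second pipeline stage. Every value is a
#' configuration knob; the defaults are anatomy-scaled choices for adult
#' breast MRI.
#'
#' @param triple_similarity_frac T in (0, 1): a slice qualifies as reference
#'   when every connected component of its set differences against both
#'   axial neighbours is smaller than `T` times the slice's breast area.
#' @param overlap_frac minimum `overlap / component area` for a watershed
#'   component of a slice to be kept against its already-refined neighbour.
#' @param lower_exclusion_frac rows with `y > frac * ny` (the posterior part
#'   of the image, containing lung and body structures) are excluded.
#' @param nipple_ball_mm,pectoral_ball_mm,side_ball_mm rolling-ball (closing)
#'   radii for the anterior nipple/areola band, the pectoral-adjacent band,
#'   and the remaining breast surface, in mm.
#' @param nipple_band_frac,pectoral_band_frac fraction of the component's
#'   anterior-posterior extent assigned to the nipple and pectoral bands.
#' @param sternum_center_window_frac half-width of the midline window used
#'   for sternum detection, as a fraction of half the component width.
#' @return an object of class `refinement_params`.
#' @export
refinement_params <- function(triple_similarity_frac = 0.05,
                              overlap_frac = 0.5,
                              lower_exclusion_frac = 0.85,
                              nipple_ball_mm = 12,
                              pectoral_ball_mm = 8,
                              side_ball_mm = 3,
                              nipple_band_frac = 0.25,
                              pectoral_band_frac = 0.25,
                              sternum_center_window_frac = 0.15) {
  fr <- c(triple_similarity_frac, overlap_frac, lower_exclusion_frac,
          nipple_band_frac, pectoral_band_frac, sternum_center_window_frac)
  if (any(fr <= 0 | fr >= 1)) stop("all fractions must lie in (0, 1)")
  if (any(c(nipple_ball_mm, pectoral_ball_mm, side_ball_mm) <= 0))
    stop("ball radii must be positive (mm)")
  structure(list(
    triple_similarity_frac = triple_similarity_frac,
    overlap_frac = overlap_frac,
    lower_exclusion_frac = lower_exclusion_frac,
    nipple_ball_mm = nipple_ball_mm, pectoral_ball_mm = pectoral_ball_mm,
    side_ball_mm = side_ball_mm, nipple_band_frac = nipple_band_frac,
    pectoral_band_frac = pectoral_band_frac,
    sternum_center_window_frac = sternum_center_window_frac
  ), class = "refinement_params")
}

# Signed-label breast component: +1 foreground / -1 background, with cached
# centroid and minimal axis-aligned bounding box (voxel coordinates, 1-based).
new_component <- function(fg, spacing) {
  idx <- which(fg, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty component")
  centroid <- colMeans(idx)
  names(centroid) <- c("z", "y", "x")
  bbox <- list(min = apply(idx, 2, min), max = apply(idx, 2, max))
  names(bbox$min) <- names(bbox$max) <- c("z", "y", "x")
  labels <- array(-1L, dim(fg))
  labels[fg] <- 1L
  structure(list(labels = labels, centroid = centroid, bbox = bbox,
                 spacing = spacing),
            class = "breast_component")
}

component_fg <- function(comp) comp$labels == 1L

#' @export
print.breast_component <- function(x, ...) {
  cat(sprintf("<breast_component> %d voxels, centroid (z,y,x) = (%.1f, %.1f, %.1f)\n",
              sum(x$labels == 1L), x$centroid[1], x$centroid[2], x$centroid[3]))
  invisible(x)
}

#' Extract the largest 3D connected component of a segmentation
#'
#' 26-connectivity; ties between equal-sized components are broken by label
#' order (first-encountered component wins) with a warning.
#'
#' @param seg3d a [binary_mask()] from the segmentation stage.
#' @return a `breast_component` with signed labels +1 / -1, cached centroid
#'   and bounding box.
#' @export
extract_largest_component <- function(seg3d) {
  stopifnot(inherits(seg3d, "binary_mask"))
  if (sum(seg3d$data) == 0) stop("empty segmentation: no foreground voxels")
  lab <- label_3d(seg3d$data)
  sizes <- tabulate(lab)
  if (sum(sizes == max(sizes)) > 1)
    warning("tied largest components; keeping the first in label order")
  keep <- which.max(sizes)
  new_component(lab == keep, seg3d$spacing)
}

# per-slice foreground of a component as a list of logical matrices
slice_masks <- function(fg) lapply(seq_len(dim(fg)[1]), function(z) fg[z, , ])

# largest connected-component area among the four set differences of a
# slice against one neighbour
max_diff_component <- function(bi, bj) {
  areas <- c(0)
  for (d in list(bi & !bj, bj & !bi)) {
    if (any(d)) {
      l <- label_2d(d)
      areas <- c(areas, max(tabulate(l)))
    }
  }
  max(areas)
}

#' Find the reference slice for boundary propagation
#'
#' Scans slice triples `(i-1, i, i+1)` starting at the component centroid
#' slice and moving outward, looking for a slice that does not differ
#' significantly from either neighbour: every 2D connected component of the
#' set differences must be smaller than `T` times the slice's own area. The
#' first qualifying slice is returned; if none qualifies, the centroid slice
#' is returned with a warning.
#'
#' @param comp a `breast_component`.
#' @param p a [refinement_params()].
#' @return integer slice index `z_ref`.
#' @export
find_reference_slice <- function(comp, p = refinement_params()) {
  fg <- component_fg(comp)
  occ <- which(apply(fg, 1, any))
  if (length(occ) < 3) stop("need at least 3 slices with foreground")
  zc <- round(comp$centroid["z"])
  zc <- min(max(zc, min(occ) + 1), max(occ) - 1)
  candidates <- unique(c(zc, as.vector(rbind(zc + seq_len(dim(fg)[1]),
                                             zc - seq_len(dim(fg)[1])))))
  candidates <- candidates[candidates > min(occ) & candidates < max(occ)]
  for (i in candidates) {
    bi <- fg[i, , ]
    area <- sum(bi)
    if (area == 0) next
    m <- max(max_diff_component(bi, fg[i - 1, , ]),
             max_diff_component(bi, fg[i + 1, , ]))
    if (m < p$triple_similarity_frac * area) return(as.integer(i))
  }
  warning("no qualifying reference slice; falling back to the centroid slice")
  as.integer(zc)
}

#' Split a slice at necks and keep the components backed by a neighbour
#'
#' The foreground of slice `j` is split into catchment components by a
#' watershed on its inverted Euclidean distance map (regional maxima merged
#' below a depth of one voxel to avoid over-fragmentation). Each component
#' is overlaid with the (already refined) foreground of slice `i`; components
#' with `overlap / area >= overlap_frac` are kept.
#'
#' @param slice_i_mask logical/0-1 matrix, the refined neighbour.
#' @param slice_j_mask logical/0-1 matrix, the slice being refined.
#' @param p a [refinement_params()].
#' @return list of logical component masks (possibly empty).
#' @export
evaluate_components <- function(slice_i_mask, slice_j_mask,
                                p = refinement_params()) {
  sj <- slice_j_mask != 0
  if (!any(sj)) return(list())
  si <- slice_i_mask != 0
  dm <- EBImage::distmap(matrix(as.numeric(sj), nrow(sj)))
  w <- EBImage::watershed(dm, tolerance = 1, ext = 1)
  w <- matrix(as.integer(w), nrow(sj))
  kept <- list()
  for (l in setdiff(unique(as.vector(w)), 0L)) {
    cm <- w == l
    if (sum(cm & si) / sum(cm) >= p$overlap_frac)
      kept[[length(kept) + 1]] <- cm
  }
  kept
}

#' Rebuild a slice from its kept components
#'
#' The union of the kept components is foreground, together with the
#' watershed boundary pixels between two kept components (pixels adjacent,
#' 8-connectivity, to at least two distinct kept components), so that
#' regions split only by the watershed are merged back. When `original` (the
#' slice's pre-split foreground) is given, only its pixels are eligible as
#' boundary pixels — background never enters the mask. Everything else is
#' background.
#'
#' @param kept_components list of logical matrices from
#'   [evaluate_components()].
#' @param shape integer `(ny, nx)`.
#' @param original optional logical matrix restricting boundary pixels.
#' @return signed integer matrix (+1 foreground / -1 background).
#' @export
update_slice <- function(kept_components, shape, original = NULL) {
  out <- matrix(FALSE, shape[1], shape[2])
  for (cm in kept_components) out <- out | cm
  if (length(kept_components) >= 2) {
    adj <- matrix(0L, shape[1], shape[2])
    for (cm in kept_components) adj <- adj + (dilate8(cm) & !out)
    ridge <- adj >= 2
    if (!is.null(original)) ridge <- ridge & original
    out <- out | ridge
  }
  m <- matrix(-1L, shape[1], shape[2])
  m[out] <- 1L
  m
}

# 8-neighborhood binary dilation of a logical matrix
dilate8 <- function(m) {
  ny <- nrow(m); nx <- ncol(m)
  pad <- matrix(FALSE, ny + 2, nx + 2)
  pad[2:(ny + 1), 2:(nx + 1)] <- m
  out <- matrix(FALSE, ny, nx)
  for (dy in 0:2) for (dx in 0:2)
    out <- out | pad[dy + seq_len(ny), dx + seq_len(nx)]
  out
}

#' Propagate the reference-slice boundary through the stack
#'
#' Sweeps from the reference slice toward both ends of the volume; each
#' slice is split by [evaluate_components()] against its already-refined
#' neighbour and rebuilt by [update_slice()], which removes significant
#' oversegmentations such as leakage into the pectoral muscle. The reference
#' slice itself is never modified.
#'
#' @param comp a `breast_component`.
#' @param z_ref reference slice from [find_reference_slice()].
#' @param p a [refinement_params()].
#' @return a refined `breast_component`.
#' @export
propagate_boundaries <- function(comp, z_ref, p = refinement_params()) {
  fg <- component_fg(comp)
  nz <- dim(fg)[1]
  if (z_ref < 1 || z_ref > nz) stop("z_ref outside the slice range")
  refine_one <- function(i, j) {
    kept <- evaluate_components(fg[i, , ], fg[j, , ], p)
    fg[j, , ] <<- update_slice(kept, dim(fg)[2:3], fg[j, , ]) == 1L
  }
  if (z_ref > 1) for (i in z_ref:2) refine_one(i, i - 1)
  if (z_ref < nz) for (i in z_ref:(nz - 1)) refine_one(i, i + 1)
  if (!any(fg)) stop("propagation removed all foreground")
  new_component(fg, comp$spacing)
}

#' Fill in-plane holes and exclude the posterior part of the image
#'
#' Minor holes (e.g. the darker parenchyma enclosed by fat) are closed per
#' slice; then all voxels in the posterior `1 - lower_exclusion_frac` part of
#' the image rows, which contains irrelevant structures such as lung parts,
#' are removed.
#'
#' @param comp a `breast_component`.
#' @param p a [refinement_params()].
#' @return a `breast_component`.
#' @export
fill_holes_and_exclude_lower <- function(comp, p = refinement_params()) {
  fg <- component_fg(comp)
  ny <- dim(fg)[2]
  for (z in seq_len(dim(fg)[1])) {
    sl <- fg[z, , ]
    if (any(sl))
      fg[z, , ] <- EBImage::fillHull(matrix(as.integer(sl), ny)) != 0
  }
  y_cut <- floor(p$lower_exclusion_frac * ny)
  if (y_cut < ny) fg[, (y_cut + 1):ny, ] <- FALSE
  if (!any(fg)) stop("lower-part exclusion removed all foreground")
  new_component(fg, comp$spacing)
}

#' Close surface concavities with region-dependent rolling balls
#'
#' Three bands of the breast surface are closed with metric balls of
#' different radii: the anterior band (nipple and areola concavities) with
#' the largest, the pectoral-adjacent posterior band with an intermediate,
#' and the remaining surface (sides, skin folds) with the smallest radius.
#' Radii are in mm and converted through the voxel spacing; a radius smaller
#' than one voxel is clamped with a warning. The output is a superset of the
#' input.
#'
#' @param comp a `breast_component`.
#' @param p a [refinement_params()].
#' @return a `breast_component`.
#' @export
close_concavities <- function(comp, p = refinement_params()) {
  fg <- component_fg(comp)
  bb <- new_component(fg, comp$spacing)$bbox
  y1 <- bb$min["y"]; y2 <- bb$max["y"]
  yext <- max(y2 - y1, 1)
  y_nip <- y1 + p$nipple_band_frac * yext
  y_pec <- y2 - p$pectoral_band_frac * yext
  yidx <- slice.index(fg, 2)
  bands <- list(
    list(rows = yidx <= y_nip, r = p$nipple_ball_mm),
    list(rows = yidx >= y_pec, r = p$pectoral_ball_mm),
    list(rows = yidx > y_nip & yidx < y_pec, r = p$side_ball_mm))
  out <- fg
  min_vox <- min(comp$spacing)
  for (b in bands) {
    r <- b$r
    if (r < min_vox) {
      warning(sprintf("ball radius %.2f mm is below one voxel; clamped", r))
      r <- min_vox
    }
    closed <- ball_close(fg, r, comp$spacing)
    out <- out | (closed & b$rows)
  }
  new_component(out, comp$spacing)
}

#' Cut the mask at the posterior sternum boundary
#'
#' The posterior-most breast-tissue row within a window around the
#' component's x-centroid approximates the posterior boundary of the
#' sternum; all voxels posterior to it are removed. If the midline window
#' holds no foreground the component is returned unchanged with a warning.
#'
#' @param comp a `breast_component`.
#' @param p a [refinement_params()].
#' @return a `breast_component`; the cut row is attached as attribute
#'   `"y_sternum"`.
#' @export
cut_at_sternum <- function(comp, p = refinement_params()) {
  fg <- component_fg(comp)
  xc <- comp$centroid["x"]
  hw <- p$sternum_center_window_frac *
    (comp$bbox$max["x"] - comp$bbox$min["x"]) / 2
  xidx <- slice.index(fg, 3)
  window <- fg & abs(xidx - xc) <= hw
  if (!any(window)) {
    warning("no foreground in the midline window; sternum cut skipped")
    return(comp)
  }
  y_s <- max(slice.index(fg, 2)[window])
  yidx <- slice.index(fg, 2)
  fg[yidx > y_s] <- FALSE
  out <- new_component(fg, comp$spacing)
  attr(out, "y_sternum") <- y_s
  out
}

#' Build the refined solid breast mask from a raw segmentation
#'
#' Orchestrates the refinement stage: largest 3D component, reference-slice
#' search, boundary propagation, hole filling and posterior exclusion,
#' region-dependent closing, sternum cut.
#'
#' @param seg3d a [binary_mask()] from [segment_volume()].
#' @param p a [refinement_params()].
#' @return a [binary_mask()]; the processing log (`z_ref`, `y_sternum`) is
#'   attached as attribute `"log"`.
#' @export
build_breast_mask <- function(seg3d, p = refinement_params()) {
  comp <- extract_largest_component(seg3d)
  z_ref <- find_reference_slice(comp, p)
  comp <- propagate_boundaries(comp, z_ref, p)
  comp <- fill_holes_and_exclude_lower(comp, p)
  comp <- close_concavities(comp, p)
  comp <- cut_at_sternum(comp, p)
  out <- binary_mask(component_fg(comp), seg3d$spacing)
  attr(out, "log") <- list(z_ref = z_ref,
                           y_sternum = attr(comp, "y_sternum"))
  out
}
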