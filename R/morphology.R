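# Internal morphology built on the compiled anisotropic distance transform.
# EBImage covers the 2D operations (distmap, watershed, fillHull); 3D
# closing with a metric ball and 26-connected labelling are provided here.

# Euclidean distance (mm) from every voxel to the nearest foreground voxel.
distance_to <- function(mask3d, spacing) {
  stopifnot(length(dim(mask3d)) == 3L)
  sqrt(.edt_sq(array(as.integer(mask3d != 0), dim = dim(mask3d)),
               as.numeric(spacing)))
}

# Morphological closing with a Euclidean ball of radius `radius_mm`,
# respecting anisotropic voxel spacing. The volume is padded with
# background so the structuring element behaves correctly at the domain
# boundary (idempotent on convex sets). Output is a superset of the input.
ball_close <- function(mask3d, radius_mm, spacing) {
  r2 <- radius_mm^2
  pad <- ceiling(radius_mm / spacing) + 1L
  d <- dim(mask3d)
  big <- array(0L, d + 2L * pad)
  idx <- lapply(1:3, function(a) pad[a] + seq_len(d[a]))
  big[idx[[1]], idx[[2]], idx[[3]]] <- as.integer(mask3d != 0)
  dil <- .edt_sq(big, as.numeric(spacing)) <= r2
  ero <- .edt_sq(array(as.integer(!dil), dim = dim(dil)),
                 as.numeric(spacing)) > r2
  out <- ero[idx[[1]], idx[[2]], idx[[3]]]
  array(out | (mask3d != 0), dim = d)
}

# 26-connected labelling (8-connected for a single slice passed as nz = 1).
label_3d <- function(mask3d) {
  .label_components(array(as.integer(mask3d != 0), dim = dim(mask3d)))
}

# 8-connected labelling of a 2D logical/integer matrix.
label_2d <- function(mask2d) {
  lab <- label_3d(array(mask2d, dim = c(1L, dim(mask2d))))
  matrix(lab, nrow = dim(mask2d)[1])
}
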