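#' Specification of a synthetic prone-breast phantom
#'
#' Describes a T1-weighted-like axial volume of two pendant half-ellipsoidal
#' breasts of bright fatty tissue attached to a posterior body band, with a
#' sparse darker fibroglandular (parenchymal) structure inside each breast, a
#' dark air background, a smooth multiplicative bias field, and additive
#' Gaussian noise. Defaults emulate the artefact structure of
#' non-fat-suppressed breast MRI at 1.5 T: an anterior-to-posterior intensity
#' decay away from the receiver coil (about a factor of three across the
#' breast) and a weaker left-right modulation from B1 effects.
#'
#' @param shape integer triple `(nz, ny, nx)`.
#' @param spacing voxel size `(dz, dy, dx)` in mm.
#' @param fat_intensity,parenchyma_intensity,body_intensity,air_intensity
#'   class intensities of the noise-free image; must satisfy
#'   `air < parenchyma < fat` (non-fat-suppressed T1 contrast).
#' @param target_density_fraction fraction of breast volume occupied by
#'   parenchyma, in (0, 1); tuned by threshold bisection on a smooth random
#'   blob field.
#' @param bias_ap_strength amplitude of the anterior-to-posterior logistic
#'   decay, in `[0, 1)`; 0.5 gives roughly a 3:1 intensity ratio.
#' @param bias_lr_strength amplitude of the left-right cosine modulation.
#' @param noise_sd standard deviation of the additive Gaussian noise, in
#'   intensity units (default 2\% of the fat intensity).
#' @param seed integer; all phantom randomness flows from this seed.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(40L, 128L, 128L),
                         spacing = c(3.0, 1.7, 1.7),
                         fat_intensity = 400,
                         parenchyma_intensity = 150,
                         body_intensity = 140,
                         air_intensity = 10,
                         target_density_fraction = 0.20,
                         bias_ap_strength = 0.5,
                         bias_lr_strength = 0.1,
                         noise_sd = 8,
                         seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 8L))
  if (!(air_intensity < parenchyma_intensity &&
        parenchyma_intensity < fat_intensity))
    stop("intensity ordering air < parenchyma < fat is required")
  if (air_intensity < 0) stop("intensities must be non-negative")
  if (target_density_fraction <= 0 || target_density_fraction >= 1)
    stop("target_density_fraction must be in (0, 1)")
  if (bias_ap_strength < 0 || bias_ap_strength >= 1 || bias_lr_strength < 0)
    stop("bias strengths must be >= 0 (and A < 1)")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(
    shape = shape, spacing = as.numeric(spacing),
    fat_intensity = fat_intensity,
    parenchyma_intensity = parenchyma_intensity,
    body_intensity = body_intensity, air_intensity = air_intensity,
    target_density_fraction = target_density_fraction,
    bias_ap_strength = bias_ap_strength,
    bias_lr_strength = bias_lr_strength,
    noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "phantom_spec")
}

# Fixed phantom geometry, as fractions of the grid. The chest wall sits at
# 62% of the anterior-posterior extent; breasts are half-ellipsoids based on
# the chest wall; their footprints overlap slightly at the midline so the
# inter-mammary cleft reaches the chest wall, as in prone positioning.
phantom_geometry <- function(shape) {
  nz <- shape[1]; ny <- shape[2]; nx <- shape[3]
  list(
    y_chest = round(0.62 * ny),
    xc = c(0.30, 0.70) * nx,
    zc = (nz + 1) / 2,
    ax = 0.22 * nx, ay = 0.44 * ny, az = 0.42 * nz
  )
}

#' Generate a synthetic prone-breast phantom with known ground truth
#'
#' Builds the noise-free class image, the analytic multiplicative bias field
#' (logistic anterior-to-posterior decay times a low-frequency left-right
#' cosine, normalized to mean one), the true breast and parenchyma masks, and
#' the observed volume `clean * bias + noise`, clipped at zero. Deterministic
#' given `spec$seed`.
#'
#' @param spec a [phantom_spec()].
#' @return an object of class `phantom_truth`: list with elements `volume`
#'   ([image_volume()]), `breast_mask`, `parenchyma_mask` ([binary_mask()]),
#'   `bias_field` and `clean_image` (3D arrays), `z_range` (a
#'   [slice_range()] covering the breast), and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(spec$seed)

  nz <- spec$shape[1]; ny <- spec$shape[2]; nx <- spec$shape[3]
  g <- phantom_geometry(spec$shape)

  z <- slice.index(array(0, spec$shape), 1)
  y <- slice.index(array(0, spec$shape), 2)
  x <- slice.index(array(0, spec$shape), 3)

  ell <- function(xc, sc = 1, ay_sc = 1, y_center = g$y_chest) {
    ((x - xc) / (sc * g$ax))^2 + ((y - y_center) / (ay_sc * sc * g$ay))^2 +
      ((z - g$zc) / (sc * g$az))^2
  }
  breast <- (ell(g$xc[1]) <= 1 | ell(g$xc[2]) <= 1) & y <= g$y_chest - 1
  body <- y > g$y_chest

  # parenchyma support: inner blob region kept clear of the breast surface
  inner <- function(xc) {
    ((x - xc) / (0.6 * g$ax))^2 +
      ((y - (g$y_chest - 0.5 * g$ay)) / (0.5 * g$ay))^2 +
      ((z - g$zc) / (0.6 * g$az))^2 <= 1
  }
  margin <- (ell(g$xc[1], sc = 0.85) <= 1 | ell(g$xc[2], sc = 0.85) <= 1) &
    y <= g$y_chest - 2
  support <- (inner(g$xc[1]) | inner(g$xc[2])) & margin & breast
  max_frac <- sum(support) / sum(breast)
  if (spec$target_density_fraction > 0.95 * max_frac)
    stop(sprintf(paste0("target_density_fraction %.2f is not achievable: ",
                        "at most %.2f of the breast geometry is available"),
                 spec$target_density_fraction, 0.95 * max_frac))

  # smooth blob field on the support, thresholded to hit the target fraction
  idx <- which(support)
  vz <- z[idx]; vy <- y[idx]; vx <- x[idx]
  n_blobs <- 50L
  ctr <- idx[sample.int(length(idx), n_blobs)]
  sds <- cbind(stats::runif(n_blobs, 0.10, 0.22) * g$az,
               stats::runif(n_blobs, 0.10, 0.22) * g$ay * 0.5,
               stats::runif(n_blobs, 0.10, 0.22) * g$ax)
  field <- numeric(length(idx))
  for (b in seq_len(n_blobs)) {
    r2 <- ((vz - z[ctr[b]]) / sds[b, 1])^2 + ((vy - y[ctr[b]]) / sds[b, 2])^2 +
      ((vx - x[ctr[b]]) / sds[b, 3])^2
    field <- field + exp(-r2 / 2)
  }

  close_r <- 2 * spec$spacing[2]
  paren_at <- function(thr) {
    m <- array(FALSE, spec$shape)
    m[idx[field >= thr]] <- TRUE
    ball_close(m, close_r, spec$spacing) & support
  }
  lo <- 0; hi <- max(field); target <- spec$target_density_fraction
  for (it in 1:40) {
    mid <- (lo + hi) / 2
    fr <- sum(paren_at(mid)) / sum(breast)
    if (abs(fr - target) < 0.003) break
    if (fr > target) lo <- mid else hi <- mid
  }
  paren <- paren_at(mid)

  clean <- array(spec$air_intensity, spec$shape)
  clean[body] <- spec$body_intensity
  clean[breast] <- spec$fat_intensity
  clean[paren] <- spec$parenchyma_intensity

  bias <- phantom_bias_field(spec)
  noise <- if (spec$noise_sd > 0)
    array(stats::rnorm(length(clean), 0, spec$noise_sd), spec$shape)
  else 0
  obs <- pmax(clean * bias + noise, 0)

  zs <- which(apply(breast, 1, sum) >= 4)
  structure(list(
    volume = image_volume(obs, spec$spacing),
    breast_mask = binary_mask(breast, spec$spacing),
    parenchyma_mask = binary_mask(paren, spec$spacing),
    bias_field = bias, clean_image = clean,
    z_range = slice_range(min(zs), max(zs)),
    y_chest = g$y_chest, spec = spec
  ), class = "phantom_truth")
}

# Analytic bias field: mean-one product of a strictly decreasing logistic
# along +y (anterior -> posterior) and a cosine along x that brightens the
# lateral edges relative to the midline.
phantom_bias_field <- function(spec) {
  ny <- spec$shape[2]; nx <- spec$shape[3]
  A <- spec$bias_ap_strength; B <- spec$bias_lr_strength
  yt <- (seq_len(ny) - 1) / (ny - 1)
  xt <- (seq_len(nx) - 1) / (nx - 1)
  ly <- (1 - A) + 2 * A / (1 + exp((yt - 0.5) / 0.15))
  cx <- 1 - B * cos(pi * (2 * xt - 1))
  plane <- outer(ly, cx)
  plane <- plane / mean(plane)
  aperm(array(plane, c(ny, nx, spec$shape[1])), c(3, 1, 2))
}

#' Sample a bias field (or any 3D grid) along a voxel line
#'
#' @param field 3D array.
#' @param from,to integer voxel coordinates `(z, y, x)`, 1-based, inclusive.
#'   The line is sampled at nearest-voxel positions; `from == to` is a
#'   zero-length line and raises an error.
#' @return numeric vector of sampled values.
#' @export
bias_profile <- function(field, from, to) {
  stopifnot(length(dim(field)) == 3L, length(from) == 3L, length(to) == 3L)
  from <- as.numeric(from); to <- as.numeric(to)
  if (any(from < 1) || any(to < 1) || any(from > dim(field)) ||
      any(to > dim(field)))
    stop("line endpoints must lie inside the grid")
  if (all(from == to)) stop("zero-length line")
  n <- max(abs(to - from)) + 1
  pts <- sapply(1:3, function(a) round(seq(from[a], to[a], length.out = n)))
  field[cbind(pts[, 1], pts[, 2], pts[, 3])]
}

#' Inject a pectoral leakage lobe into a phantom
#'
#' Adds a fat-bright lobe posterior to the left breast, connected to the
#' breast base by a thin neck, on the listed slices only. The returned truth
#' masks are unchanged (the lobe is not breast tissue); the observed volume
#' shows the lobe at fat intensity under the same bias field, so the
#' first-stage segmentation will include it and the refinement stage is
#' expected to remove it.
#'
#' @param base a `phantom_truth` from [generate_phantom()].
#' @param lobe_radius_mm in-plane radius of the lobe disk, mm.
#' @param neck_width width of the connecting neck in voxels; 0 leaves the
#'   lobe disconnected.
#' @param z_slices integer slice indices carrying the lobe (may be empty).
#' @return a `phantom_truth` whose `volume` carries the lobe; the injected
#'   voxel index set is attached as attribute `"lobe_voxels"`.
#' @export
make_leakage_fixture <- function(base, lobe_radius_mm = 12, neck_width = 2,
                                 z_slices = integer()) {
  stopifnot(inherits(base, "phantom_truth"))
  spec <- base$spec
  nz <- spec$shape[1]; ny <- spec$shape[2]; nx <- spec$shape[3]
  if (length(z_slices) == 0) {
    attr(base, "lobe_voxels") <- integer(0)
    return(base)
  }
  if (any(z_slices < 1 | z_slices > nz)) stop("z_slices out of range")
  g <- phantom_geometry(spec$shape)
  xc <- round(g$xc[1])
  y_lobe <- g$y_chest + round(0.45 * (ny - g$y_chest))
  r_vox <- lobe_radius_mm / spec$spacing[2]
  if (y_lobe + r_vox > ny || r_vox < 1)
    stop("lobe cannot be placed inside the body band")

  yy <- matrix(seq_len(ny), ny, nx)
  xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  disk <- ((yy - y_lobe) / r_vox)^2 +
    ((xx - xc) / (lobe_radius_mm / spec$spacing[3]))^2 <= 1
  neck2d <- matrix(FALSE, ny, nx)
  if (neck_width > 0) {
    hw <- (neck_width - 1) / 2
    neck2d <- yy >= g$y_chest & yy <= y_lobe & abs(xx - xc) <= hw & !disk
  }
  lobe2d <- disk | neck2d

  vol <- base$volume$data
  for (zi in z_slices) {
    sl <- vol[zi, , ]
    b2 <- base$bias_field[zi, , ]
    set <- lobe2d & (base$breast_mask$data[zi, , ] == 0)
    sl[set] <- spec$fat_intensity * b2[set]
    vol[zi, , ] <- sl
  }
  # absolute array indices of the injected voxels, for bookkeeping;
  # the lobe disk and its connecting neck are recorded separately
  abs_idx <- function(mask2d) unlist(lapply(z_slices, function(zi) {
    set <- which(mask2d & (base$breast_mask$data[zi, , ] == 0))
    yv <- (set - 1L) %% ny + 1L
    xv <- (set - 1L) %/% ny + 1L
    (xv - 1L) * nz * ny + (yv - 1L) * nz + zi
  }))
  out <- base
  out$volume <- image_volume(vol, spec$spacing)
  attr(out, "lobe_voxels") <- as.integer(abs_idx(disk))
  attr(out, "neck_voxels") <- as.integer(abs_idx(neck2d))
  out
}

#' Depth of the valleys between intensity-class modes of a histogram
#'
#' Measures how well separated the class modes of an image are: for each
#' adjacent pair of reference class intensities, the peak height near each
#' mode and the minimum bin count between them are found; the reported
#' statistic is the smallest `(min(peaks) - valley)` over the pairs, in
#' counts. A bias-corrected image should show deeper valleys (larger values)
#' than the raw inhomogeneous image.
#'
#' @param values numeric vector of intensities.
#' @param centers increasing numeric vector of expected class intensities.
#' @param n_bins histogram resolution.
#' @return scalar valley-depth statistic.
#' @export
histogram_valley_depth <- function(values, centers, n_bins = 128) {
  stopifnot(length(centers) >= 2, !is.unsorted(centers))
  # robust range: extreme outliers (e.g. bias-floored air voxels of a
  # corrected image) must not stretch the binning
  rng <- stats::quantile(values, c(0.001, 0.999), names = FALSE)
  values <- values[values >= rng[1] & values <= rng[2]]
  br <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- graphics::hist(values, breaks = br, plot = FALSE)$counts
  mids <- (br[-1] + br[-length(br)]) / 2
  half <- min(diff(centers)) / 4
  depths <- vapply(seq_len(length(centers) - 1), function(i) {
    p1 <- max(h[abs(mids - centers[i]) <= half], 0)
    p2 <- max(h[abs(mids - centers[i + 1]) <= half], 0)
    between <- h[mids > centers[i] + half & mids < centers[i + 1] - half]
    if (length(between) == 0) return(0)
    min(p1, p2) - min(between)
  }, 0)
  min(depths)
}
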