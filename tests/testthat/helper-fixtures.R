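# Shared fixtures: phantoms are memoized per (seed, variant) so test files
# can reuse them without regenerating.

.fixture_cache <- new.env(parent = emptyenv())

small_phantom <- function(seed = 11, ...) {
  extra <- list(...)
  key <- paste0("ph_", seed, "_", paste(names(extra), unlist(extra),
                                        collapse = "_"))
  got <- get0(key, envir = .fixture_cache)
  if (!is.null(got)) return(got)
  args <- utils::modifyList(list(shape = c(24L, 64L, 64L), seed = seed), extra)
  ph <- generate_phantom(do.call(phantom_spec, args))
  assign(key, ph, envir = .fixture_cache)
  ph
}

# segmentation of a small phantom, memoized
small_segmentation <- function(seed = 11, ...) {
  key <- paste0("seg_", seed, "_", paste(names(list(...)), unlist(list(...)),
                                         collapse = "_"))
  got <- get0(key, envir = .fixture_cache)
  if (!is.null(got)) return(got)
  ph <- small_phantom(seed, ...)
  out <- list(phantom = ph, seg = segment_volume(ph$volume, ph$z_range))
  assign(key, out, envir = .fixture_cache)
  out
}

# random binary mask pair on a small grid
random_mask_pair <- function(seed, shape = c(4L, 8L, 8L), p = 0.3) {
  set.seed(seed)
  a <- array(stats::rbinom(prod(shape), 1, p), shape)
  m <- array(stats::rbinom(prod(shape), 1, p), shape)
  list(auto = binary_mask(a, c(1, 1, 1)), manual = binary_mask(m, c(1, 1, 1)))
}

# brute-force voxel-loop agreement oracle (independent of agreement_stats)
agreement_oracle <- function(auto, manual) {
  A <- as.vector(auto$data); M <- as.vector(manual$data)
  inter <- 0; na <- 0; nm <- 0; fp <- 0
  for (i in seq_along(A)) {
    if (A[i] == 1) na <- na + 1
    if (M[i] == 1) nm <- nm + 1
    if (A[i] == 1 && M[i] == 1) inter <- inter + 1
    if (A[i] == 1 && M[i] == 0) fp <- fp + 1
  }
  list(dsc = 2 * inter / (na + nm), sens = inter / nm,
       fpvf = fp / (length(A) - nm), spec = 1 - fp / (length(A) - nm))
}

# closed-form OLS oracle via explicit normal equations
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxx <- sum(x^2); sxy <- sum(x * y)
  det <- n * sxx - sx^2
  slope <- (n * sxy - sx * sy) / det
  intercept <- (sy * sxx - sx * sxy) / det
  c(intercept = intercept, slope = slope)
}
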