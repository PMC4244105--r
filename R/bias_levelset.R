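#' Parameters of the joint segmentation / bias-correction stage
#'
#' The first pipeline stage models each axial slice as
#' `U(x) = J(x) * b(x) + n(x)`: a piecewise-constant true image `J` taking
#' one of `n_classes` tissue intensities, a smooth multiplicative bias field
#' `b`, and zero-mean Gaussian noise. It minimizes the clustering energy
#' \deqn{E = \sum_k \int |U(x) - b(x) c_k|^2 m_k(x) dx
#'       + \nu\,\mathrm{Length}(\phi = 0) + \mu\,\mathrm{Reg}(\phi)}
#' jointly over the class centroids `c_k`, the bias coefficients, and a
#' two-phase level-set partition: the embedding `phi` separates the brightest
#' class (fat on non-fat-suppressed T1) from the rest, and the remaining
#' classes are resolved by centroid assignment. The bias is represented in a
#' tensor Legendre polynomial basis, which makes it smooth by construction.
#'
#' @param n_classes number of intensity classes K (>= 2); 3 covers
#'   air / soft tissue / fat.
#' @param bias_basis_order polynomial order per axis (>= 0); `NA` fixes the
#'   bias at 1 (no estimation).
#' @param length_weight nu >= 0, weight of the contour-length penalty; the
#'   slice is normalized to `[0, 1]` internally, so the scale of nu is
#'   comparable across inputs.
#' @param regularity_weight mu >= 0, weight of the penalty on deviation of
#'   `phi` from a signed distance function. The embedding is re-initialized
#'   to a signed distance after every sweep, which keeps this term at its
#'   minimum; it is reported in the energy only when `mu > 0`.
#' @param max_iter,energy_tol stopping rule: at most `max_iter` full sweeps,
#'   or relative energy change below `energy_tol`.
#' @param init_mode initial fat region: `"otsu"` (threshold on the raw
#'   slice), `"checkerboard"`, or `"threshold"` (half of the range).
#' @param fat_class_rule which classes form the bright-tissue foreground of
#'   the emitted segmentation: the brightest, or the two brightest (useful
#'   for very dense breasts).
#' @return an object of class `level_set_params`.
#' @export
level_set_params <- function(n_classes = 3L,
                             bias_basis_order = 4L,
                             length_weight = 1e-3,
                             regularity_weight = 0,
                             max_iter = 200L,
                             energy_tol = 1e-4,
                             init_mode = c("otsu", "checkerboard", "threshold"),
                             fat_class_rule = c("brightest", "brightest_two")) {
  init_mode <- match.arg(init_mode)
  fat_class_rule <- match.arg(fat_class_rule)
  n_classes <- as.integer(n_classes)
  if (n_classes < 2L) stop("n_classes must be >= 2")
  if (!is.na(bias_basis_order) && bias_basis_order < 0)
    stop("bias_basis_order must be >= 0 (or NA for a fixed unit bias)")
  if (length_weight < 0 || regularity_weight < 0)
    stop("weights must be non-negative")
  if (max_iter < 1L) stop("max_iter must be >= 1")
  if (energy_tol <= 0) stop("energy_tol must be > 0")
  structure(list(
    n_classes = n_classes, bias_basis_order = bias_basis_order,
    length_weight = length_weight, regularity_weight = regularity_weight,
    max_iter = as.integer(max_iter), energy_tol = energy_tol,
    init_mode = init_mode, fat_class_rule = fat_class_rule
  ), class = "level_set_params")
}

#' Named parameter profiles per ACR density group
#'
#' Convergence-oriented presets for the four ACR density groups. The four
#' profiles currently share the package defaults; they are exposed so that
#' per-group tuning is a configuration change, not a code change.
#'
#' @param name one of `"acr1" .. "acr4"`.
#' @param ... overrides passed to [level_set_params()].
#' @return a `level_set_params` object.
#' @export
acr_profile <- function(name = c("acr1", "acr2", "acr3", "acr4"), ...) {
  name <- match.arg(name)
  level_set_params(...)
}

BIAS_EPS <- 1e-6

# Tensor Legendre basis on the slice, cached per (ny, nx, order).
.basis_cache <- new.env(parent = emptyenv())

legendre_1d <- function(t, order) {
  # t in [-1, 1]; recurrence (n+1)P_{n+1} = (2n+1) t P_n - n P_{n-1}
  P <- matrix(0, length(t), order + 1)
  P[, 1] <- 1
  if (order >= 1) P[, 2] <- t
  if (order >= 2) for (n in 1:(order - 1))
    P[, n + 2] <- ((2 * n + 1) * t * P[, n + 1] - n * P[, n]) / (n + 1)
  P
}

bias_basis <- function(ny, nx, order) {
  key <- sprintf("%d_%d_%d", ny, nx, order)
  got <- get0(key, envir = .basis_cache)
  if (!is.null(got)) return(got)
  ty <- if (ny > 1) seq(-1, 1, length.out = ny) else 0
  tx <- if (nx > 1) seq(-1, 1, length.out = nx) else 0
  Py <- legendre_1d(ty, order)
  Px <- legendre_1d(tx, order)
  M <- (order + 1)^2
  G <- matrix(0, ny * nx, M)
  m <- 0
  for (i in seq_len(order + 1)) for (j in seq_len(order + 1)) {
    m <- m + 1
    G[, m] <- as.vector(Py[, i] %o% Px[, j])
  }
  assign(key, G, envir = .basis_cache)
  G
}

otsu_threshold <- function(u, n_bins = 256) {
  h <- graphics::hist(u, breaks = seq(min(u), max(u), length.out = n_bins + 1),
                      plot = FALSE)
  w <- h$counts / sum(h$counts)
  mids <- h$mids
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[length(mu)]
  sb <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- 0
  mids[which.max(sb)]
}

# Internal state constructor. `labels` holds the full K-class assignment
# (class K = brightest = fat); `phi` is the signed-distance embedding of the
# fat region, recomputed from the labels.
new_ls_state <- function(labels, centroids, bias_coeffs, G, spacing2d,
                         frozen = rep(FALSE, length(centroids)),
                         energy_trace = numeric(0), scale = 1) {
  structure(list(labels = labels, centroids = centroids,
                 bias_coeffs = bias_coeffs, G = G, spacing2d = spacing2d,
                 frozen = frozen, energy_trace = energy_trace,
                 scale = scale),
            class = "level_set_state")
}

state_bias <- function(state) {
  matrix(state$G %*% state$bias_coeffs, nrow = nrow(state$labels))
}

#' Signed-distance embedding of the current fat region
#'
#' Positive inside the fat (brightest-class) region, negative outside, in mm.
#'
#' @param state a `level_set_state`.
#' @return numeric matrix `phi` of the slice shape.
#' @export
state_phi <- function(state) {
  fat <- state$labels == length(state$centroids)
  sp <- c(1, state$spacing2d)
  a_in <- array(fat, dim = c(1L, dim(state$labels)))
  a_out <- array(!fat, dim = c(1L, dim(state$labels)))
  d_out <- sqrt(.edt_sq(array(as.integer(a_in), dim = dim(a_in)), sp))
  d_in <- sqrt(.edt_sq(array(as.integer(a_out), dim = dim(a_out)), sp))
  matrix(d_in - d_out, nrow = nrow(state$labels))
}

# Initialize state on a normalized slice u in [0, 1]. When `warm` (a list
# with `centroids`, `bias_coeffs`, `fat`) is given — typically the converged
# state of the neighbouring slice — it overrides the cold start; this speeds
# up convergence and stabilizes slices with very little bright tissue, where
# a histogram threshold cannot tell fat from body.
init_state <- function(u, params, spacing2d, warm = NULL) {
  K <- params$n_classes
  order <- params$bias_basis_order
  G <- if (is.na(order)) matrix(1, length(u), 1)
       else bias_basis(nrow(u), ncol(u), order)
  if (!is.null(warm)) {
    # pointwise classification under the neighbour's centroids and bias;
    # copying the neighbour's fat region verbatim would mis-seed slices
    # whose breast cross-section changes quickly
    b <- matrix(G %*% warm$bias_coeffs, nrow = nrow(u))
    cent <- warm$centroids
    lab <- matrix(1L, nrow(u), ncol(u))
    for (k in 2:K)
      lab[(u - b * cent[k])^2 < (u - b * cent[lab])^2] <- k
    return(new_ls_state(lab, cent, warm$bias_coeffs, G, spacing2d))
  }
  qc <- stats::quantile(u, probs = (seq_len(K) - 0.5) / K, names = FALSE)
  qc <- qc + seq(0, 1e-9, length.out = K)  # enforce strict ordering
  lab <- matrix(max.col(-abs(outer(as.vector(u), qc, `-`)), "first"),
                nrow = nrow(u))
  fat0 <- switch(params$init_mode,
    otsu = u > otsu_threshold(u),
    checkerboard = (slice.index(array(0, dim(u)), 1) +
                      slice.index(array(0, dim(u)), 2)) %% 2 == 0,
    threshold = u > (min(u) + max(u)) / 2)
  lab[fat0] <- K
  lab[!fat0 & lab == K] <- K - 1L
  coeffs <- c(1, rep(0, ncol(G) - 1))
  cent <- vapply(seq_len(K), function(k) {
    v <- u[lab == k]
    if (length(v)) mean(v) else qc[k]
  }, 0)
  new_ls_state(lab, cent, coeffs, G, spacing2d)
}

#' Clustering energy of a level-set state
#'
#' Evaluates the objective minimized by the stage: the residual
#' `sum_k sum_x |u(x) - b(x) c_k|^2 m_k(x)` over the class partition, plus
#' `nu` times the contour length of the fat/non-fat interface (measured as
#' 4-neighbor label disagreements), plus, when `mu > 0`, the deviation of the
#' embedding from a signed distance function.
#'
#' @param state a `level_set_state`.
#' @param u the slice the state was built on (normalized scale).
#' @param params a [level_set_params()].
#' @return scalar energy.
#' @export
level_set_energy <- function(state, u, params) {
  b <- state_bias(state)
  res <- (u - b * state$centroids[state$labels])^2
  e <- sum(res)
  if (params$length_weight > 0)
    e <- e + params$length_weight * fat_boundary_length(
      state$labels == length(state$centroids))
  if (params$regularity_weight > 0) {
    phi <- state_phi(state)
    gy <- diff(phi) / state$spacing2d[1]
    gx <- t(diff(t(phi))) / state$spacing2d[2]
    e <- e + params$regularity_weight *
      (sum((abs(gy) - 1)^2) + sum((abs(gx) - 1)^2)) / 2
  }
  e
}

# number of 4-neighbor pairs with differing fat membership
fat_boundary_length <- function(fat) {
  sum(fat[-1, ] != fat[-nrow(fat), ]) + sum(fat[, -1] != fat[, -ncol(fat)])
}

#' Closed-form centroid update
#'
#' Sets each class centroid to its weighted least-squares optimum
#' `c_k = sum(u b m_k) / sum(b^2 m_k)`; with a unit bias this is the class
#' mean, i.e. a k-means step. Classes with no members are frozen and flagged.
#'
#' @param state a `level_set_state`.
#' @param u the slice (normalized scale).
#' @return the updated state; frozen classes are marked in `state$frozen`.
#' @export
update_centroids <- function(state, u) {
  b <- state_bias(state)
  K <- length(state$centroids)
  for (k in seq_len(K)) {
    m <- state$labels == k
    if (!any(m)) {
      state$frozen[k] <- TRUE
      next
    }
    state$centroids[k] <- sum(u[m] * b[m]) / sum(b[m]^2)
  }
  state
}

#' Closed-form bias update
#'
#' Solves the least-squares problem for the bias coefficients within the
#' smooth polynomial basis: with per-pixel centroid `c(x)`, minimizes
#' `sum_x (u(x) - c(x) g(x)' w)^2` by the normal equations. The reconstructed
#' field is smooth by construction of the basis.
#'
#' @param state a `level_set_state`.
#' @param u the slice (normalized scale).
#' @return the updated state.
#' @export
update_bias <- function(state, u) {
  cpx <- state$centroids[state$labels]
  cG <- state$G * as.vector(cpx)
  A <- crossprod(cG)
  rhs <- crossprod(cG, as.vector(u))
  w <- tryCatch(solve(A, rhs),
                error = function(e) stop("bias normal equations are rank-deficient"))
  state$bias_coeffs <- as.vector(w)
  state
}

#' One level-set evolution step
#'
#' Evolves the fat/non-fat interface by one monotone region-competition
#' sweep: in checkerboard order, a pixel changes phase when doing so lowers
#' the sum of its data cost and `nu` times the local interface length. The
#' embedding is then re-initialized to the signed distance of the new region,
#' which keeps the regularity term at its minimum (distance regularization by
#' re-initialization).
#'
#' @param state a `level_set_state`.
#' @param u the slice (normalized scale).
#' @param params a [level_set_params()].
#' @return the updated state.
#' @export
update_levelset <- function(state, u, params) {
  K <- length(state$centroids)
  b <- state_bias(state)
  if (any(!is.finite(b))) stop("non-finite bias field in level-set step")
  cost <- lapply(seq_len(K), function(k) (u - b * state$centroids[k])^2)
  active <- which(!state$frozen[-K])
  if (length(active) == 0) active <- seq_len(K - 1)
  cost_oth <- Reduce(pmin, cost[active])
  k_oth <- matrix(active[1], nrow(u), ncol(u))
  for (k in active) k_oth[cost[[k]] <= cost_oth] <- k
  cost_fat <- cost[[K]]

  nu <- params$length_weight
  ny <- nrow(u); nx <- ncol(u)
  parity <- (slice.index(array(0, dim(u)), 1) +
               slice.index(array(0, dim(u)), 2)) %% 2
  fat <- state$labels == K
  for (p in 0:1) {
    nb_fat <- neighbor_sum(fat)
    nb_n <- neighbor_count(ny, nx)
    d <- ifelse(fat, nb_n - nb_fat, nb_fat)   # differing neighbors
    cur <- ifelse(fat, cost_fat, cost_oth)
    alt <- ifelse(fat, cost_oth, cost_fat)
    dE <- (alt - cur) + nu * (nb_n - 2 * d)
    if (any(!is.finite(dE))) stop("level-set step produced non-finite values")
    flip <- dE < 0 & parity == p
    fat <- xor(fat, flip)
  }
  lab <- state$labels
  lab[fat] <- K
  lab[!fat] <- k_oth[!fat]
  state$labels <- lab
  state
}

neighbor_sum <- function(m) {
  s <- matrix(0, nrow(m), ncol(m))
  s[-1, ] <- s[-1, ] + m[-nrow(m), ]
  s[-nrow(m), ] <- s[-nrow(m), ] + m[-1, ]
  s[, -1] <- s[, -1] + m[, -ncol(m)]
  s[, -ncol(m)] <- s[, -ncol(m)] + m[, -1]
  s
}

neighbor_count <- function(ny, nx) {
  n <- matrix(4, ny, nx)
  n[1, ] <- n[1, ] - 1; n[ny, ] <- n[ny, ] - 1
  n[, 1] <- n[, 1] - 1; n[, nx] <- n[, nx] - 1
  n
}

#' Jointly segment one axial slice and estimate its bias field
#'
#' Alternating minimization of the clustering energy: class reassignment,
#' centroid update, bias update, then one level-set sweep, until the relative
#' energy change drops below `energy_tol` or `max_iter` sweeps are done. The
#' energy trace is non-increasing across sweeps.
#'
#' @param slice2d numeric matrix `(y, x)` with at least two distinct values.
#' @param params a [level_set_params()].
#' @param spacing2d in-plane voxel size `(dy, dx)` in mm (used for the
#'   embedding only).
#' @param warm optional warm start, usually the `state`/`scale` of the
#'   neighbouring slice's result: list with `centroids`, `bias_coeffs` and
#'   logical `fat` matrix. Overrides `init_mode`.
#' @return a `slice_result`: list with `segmented` (0/1 matrix of the bright
#'   fat foreground per `fat_class_rule`), `corrected` (slice divided by the
#'   mean-normalized bias, floored at `1e-6`), `bias` (estimated field,
#'   normalized to slice mean 1), `centroids` (original intensity scale),
#'   `energy_trace`, `iterations`, and the final `state`.
#' @export
segment_slice <- function(slice2d, params = level_set_params(),
                          spacing2d = c(1, 1), warm = NULL) {
  stopifnot(is.matrix(slice2d))
  rng <- range(slice2d)
  if (diff(rng) == 0)
    stop("degenerate input: slice has a single intensity value")
  scale <- max(slice2d)
  u <- slice2d / scale

  state <- init_state(u, params, spacing2d, warm)
  state$scale <- scale
  K <- params$n_classes
  est_bias <- !is.na(params$bias_basis_order)
  e_prev <- level_set_energy(state, u, params)
  trace <- e_prev
  iters <- 0L
  for (it in seq_len(params$max_iter)) {
    iters <- it
    state <- reassign_lower_classes(state, u)
    state <- update_centroids(state, u)
    state <- sort_classes(state)
    if (est_bias) state <- update_bias(state, u)
    state <- update_levelset(state, u, params)
    e <- level_set_energy(state, u, params)
    trace <- c(trace, e)
    if (abs(e_prev - e) / max(abs(e_prev), .Machine$double.eps) <
        params$energy_tol) break
    e_prev <- e
  }
  state$energy_trace <- trace

  b <- state_bias(state)
  # the bias is identifiable only where there is signal: require strict
  # positivity on the non-darkest (tissue) classes; in pure-air regions the
  # polynomial extrapolates freely and is floored at BIAS_EPS before division
  darkest <- which.min(state$centroids)
  tissue <- state$labels != darkest
  if (any(tissue) && min(b[tissue]) <= 0)
    stop("estimated bias field is not strictly positive on the slice tissue")
  bn <- b / mean(b)
  fat_k <- if (params$fat_class_rule == "brightest") K else c(K - 1L, K)
  seg <- matrix(as.integer(state$labels %in% fat_k), nrow(u), ncol(u))
  bn <- pmax(bn, BIAS_EPS)
  corrected <- slice2d / bn
  structure(list(segmented = seg, corrected = corrected, bias = bn,
                 centroids = state$centroids * scale * mean(b),
                 energy_trace = trace, iterations = iters, state = state,
                 scale = scale),
            class = "slice_result")
}

# warm-start payload for the neighbouring slice: centroids are carried in
# that slice's own normalized units via the scale ratio
warm_from_result <- function(res, next_scale) {
  list(centroids = res$state$centroids * res$scale / next_scale,
       bias_coeffs = res$state$bias_coeffs)
}

# Relabel classes so centroids are ascending (class K = brightest). A pure
# permutation of class identities: leaves the energy unchanged, but keeps
# the two-phase foreground anchored on the brightest class even if
# centroids drift across each other during the alternation.
sort_classes <- function(state) {
  ord <- order(state$centroids)
  if (all(ord == seq_along(ord))) return(state)
  remap <- integer(length(ord))
  remap[ord] <- seq_along(ord)
  state$labels <- matrix(remap[state$labels], nrow(state$labels))
  state$centroids <- state$centroids[ord]
  state$frozen <- state$frozen[ord]
  state
}

# Pointwise reassignment of the non-fat pixels among classes 1..K-1
# (never increases the data term; the fat phase is only changed by the
# level-set step).
reassign_lower_classes <- function(state, u) {
  K <- length(state$centroids)
  if (K == 2) return(state)
  b <- state_bias(state)
  active <- which(!state$frozen[-K])
  if (length(active) <= 1) return(state)
  low <- state$labels < K
  if (!any(low)) return(state)
  cost <- vapply(active, function(k) (u[low] - b[low] * state$centroids[k])^2,
                 numeric(sum(low)))
  cost <- matrix(cost, ncol = length(active))
  state$labels[low] <- active[max.col(-cost, "first")]
  state
}

#' Run the joint segmentation over a slice range of a volume
#'
#' Applies [segment_slice()] to every slice in the range and composes the
#' per-slice results back into 3D volumes. Slices are visited from the
#' middle of the range outward, each warm-started from its already-solved
#' neighbour; this speeds up convergence and anchors the fat class on edge
#' slices that contain almost no bright tissue. Slices outside the range are
#' zero in the segmentation, unchanged in the corrected volume, and one in
#' the bias volume. A slice that fails is zero-filled and reported in the
#' log rather than aborting the run.
#'
#' @param vol an [image_volume()].
#' @param r a [slice_range()].
#' @param params a [level_set_params()].
#' @return list with `seg` ([binary_mask()]), `corrected`, `bias`
#'   ([image_volume()]s), and `log` (data frame: z, iterations, final energy,
#'   error message if any).
#' @export
segment_volume <- function(vol, r, params = level_set_params()) {
  stopifnot(inherits(vol, "image_volume"))
  validate_range(r, vol)
  dims <- dim(vol$data)
  seg <- array(0L, dims)
  corrected <- vol$data
  bias <- array(1, dims)
  zs <- r$z_start:r$z_end
  log <- data.frame(z = zs, iterations = NA_integer_, energy = NA_real_,
                    error = NA_character_)
  z_mid <- zs[ceiling(length(zs) / 2)]
  order_out <- unique(c(z_mid,
                        as.vector(rbind(z_mid + seq_along(zs),
                                        z_mid - seq_along(zs)))))
  order_out <- order_out[order_out %in% zs]
  results <- vector("list", max(zs))
  for (z in order_out) {
    nb <- if (z == z_mid) NULL
          else results[[z + if (z > z_mid) -1L else 1L]]
    warm <- if (!is.null(nb))
      warm_from_result(nb, max(vol$data[z, , ]))
    res <- tryCatch(
      segment_slice(vol$data[z, , ], params, vol$spacing[2:3], warm),
      error = function(e) e)
    i <- match(z, zs)
    if (inherits(res, "error")) {
      log$error[i] <- sprintf("slice %d: %s", z, conditionMessage(res))
      next
    }
    results[[z]] <- res
    seg[z, , ] <- res$segmented
    corrected[z, , ] <- res$corrected
    bias[z, , ] <- res$bias
    log$iterations[i] <- res$iterations
    log$energy[i] <- res$energy_trace[length(res$energy_trace)]
  }
  list(seg = binary_mask(seg, vol$spacing),
       corrected = image_volume(corrected, vol$spacing),
       bias = image_volume(bias, vol$spacing),
       log = log)
}
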