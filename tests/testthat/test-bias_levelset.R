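# direct k-means-style SSE of a converged state (oracle cross-checks)
state_sse <- function(state, u) {
  sum((u - state$centroids[state$labels])^2)
}

test_that("a noise-free two-level slice is segmented exactly with unit bias", {
  sl <- matrix(20, 40, 40)
  sl[10:30, 12:28] <- 200
  res <- segment_slice(sl, level_set_params(n_classes = 2))
  expect_identical(res$segmented == 1, sl == 200)
  expect_lt(max(abs(res$bias - 1)), 0.01)
})

test_that("constant slices are rejected as degenerate", {
  expect_error(segment_slice(matrix(5, 10, 10)), "degenerate")
})

test_that("the energy vanishes iff the model fits exactly", {
  # u = b * c_k exactly in each region, nu = mu = 0
  ny <- 16; nx <- 16
  G <- breastdens:::bias_basis(ny, nx, 1)
  coeffs <- c(1, 0.2, 0.1, 0)
  b <- matrix(G %*% coeffs, ny)
  lab <- matrix(1L, ny, nx); lab[, 9:16] <- 2L
  cents <- c(0.2, 0.8)
  u <- b * cents[lab]; dim(u) <- c(ny, nx)
  st <- breastdens:::new_ls_state(lab, cents, coeffs, G, c(1, 1))
  p0 <- level_set_params(n_classes = 2, length_weight = 0)
  expect_equal(level_set_energy(st, u, p0), 0)
  # perturbing a centroid off its optimum strictly increases the energy
  st2 <- st; st2$centroids[2] <- cents[2] + 0.05
  expect_gt(level_set_energy(st2, u, p0), 0)
})

test_that("centroid update reduces to class means for unit bias", {
  set.seed(2)
  u <- matrix(runif(100), 10, 10)
  lab <- matrix(1L + (u > 0.5), 10, 10)
  G <- matrix(1, 100, 1)
  st <- breastdens:::new_ls_state(lab, c(0.1, 0.9), c(1), G, c(1, 1))
  st <- update_centroids(st, u)
  expect_equal(st$centroids[1], mean(u[lab == 1]))
  expect_equal(st$centroids[2], mean(u[lab == 2]))
})

test_that("an empty class is frozen and flagged, others still update", {
  u <- matrix(runif(64), 8, 8)
  lab <- matrix(1L, 8, 8)  # class 2 empty
  st <- breastdens:::new_ls_state(lab, c(0.4, 0.9), c(1), matrix(1, 64, 1),
                                  c(1, 1))
  st <- update_centroids(st, u)
  expect_true(st$frozen[2])
  expect_equal(st$centroids[1], mean(u))
  expect_equal(st$centroids[2], 0.9)  # untouched
})

test_that("centroid and bias updates never increase the energy (seeded states)", {
  p0 <- level_set_params(n_classes = 2, length_weight = 0,
                         bias_basis_order = 2)
  for (seed in 1:100) {
    set.seed(seed)
    ny <- 12; nx <- 12
    u <- matrix(runif(ny * nx), ny)
    G <- breastdens:::bias_basis(ny, nx, 2)
    coeffs <- c(1, rnorm(ncol(G) - 1, 0, 0.05))
    lab <- matrix(sample(1:2, ny * nx, TRUE), ny)
    st <- breastdens:::new_ls_state(lab, sort(runif(2)), coeffs, G, c(1, 1))
    e0 <- level_set_energy(st, u, p0)
    st1 <- update_centroids(st, u)
    e1 <- level_set_energy(st1, u, p0)
    expect_lte(e1, e0 + 1e-12)
    st2 <- update_bias(st1, u)
    e2 <- level_set_energy(st2, u, p0)
    expect_lte(e2, e1 + 1e-12)
  }
})

test_that("bias in the basis span is recovered exactly for a single class", {
  ny <- 24; nx <- 24
  G <- breastdens:::bias_basis(ny, nx, 3)
  set.seed(4)
  coeffs_true <- c(1, rnorm(ncol(G) - 1, 0, 0.03))
  b_true <- matrix(G %*% coeffs_true, ny)
  cent <- 0.7
  u <- cent * b_true
  st <- breastdens:::new_ls_state(matrix(1L, ny, nx), cent,
                                  c(1, rep(0, ncol(G) - 1)), G, c(1, 1))
  st <- update_bias(st, u)
  b_est <- breastdens:::state_bias(st)
  expect_gt(stats::cor(as.vector(b_est), as.vector(b_true)), 1 - 1e-6)
  expect_equal(as.vector(b_est), as.vector(b_true), tolerance = 1e-8)
})

test_that("an order-0 basis yields the closed-form constant bias", {
  set.seed(5)
  u <- matrix(runif(64, 0.2, 1), 8, 8)
  lab <- matrix(1L + (u > 0.6), 8, 8)
  cents <- c(0.3, 0.8)
  st <- breastdens:::new_ls_state(lab, cents, 1, matrix(1, 64, 1), c(1, 1))
  st <- update_bias(st, u)
  cpx <- cents[lab]
  expect_equal(st$bias_coeffs, sum(u * cpx) / sum(cpx^2))
})

test_that("the level-set step leaves a zero-gradient state unchanged", {
  # exact two-class model, nu = 0: every pixel already in its best phase
  sl <- matrix(0.2, 20, 20); sl[5:15, 5:15] <- 0.9
  lab <- matrix(1L + (sl > 0.5), 20, 20)
  st <- breastdens:::new_ls_state(lab, c(0.2, 0.9), 1, matrix(1, 400, 1),
                                  c(1, 1))
  p0 <- level_set_params(n_classes = 2, length_weight = 0)
  st2 <- update_levelset(st, sl, p0)
  expect_identical(st2$labels, st$labels)
})

test_that("the zero level set converges to a bright disk's boundary", {
  ny <- 48; nx <- 48
  yy <- matrix(seq_len(ny), ny, nx); xx <- matrix(seq_len(nx), ny, nx, TRUE)
  disk <- (yy - 24)^2 + (xx - 24)^2 <= 12^2
  u <- matrix(0.15, ny, nx); u[disk] <- 1
  # start far from the boundary: a small square in a corner
  lab <- matrix(1L, ny, nx); lab[2:6, 2:6] <- 2L
  st <- breastdens:::new_ls_state(lab, c(0.15, 1), 1, matrix(1, ny * nx, 1),
                                  c(1, 1))
  p0 <- level_set_params(n_classes = 2)
  for (i in 1:20) st <- update_levelset(st, u, p0)
  expect_identical(st$labels == 2L, disk)
  phi <- state_phi(st)
  # zero crossing within one voxel of the analytic circle
  ring <- abs(sqrt((yy - 24)^2 + (xx - 24)^2) - 12) < 0.5
  expect_lt(max(abs(phi[ring])), 2)
})

test_that("energy traces are non-increasing on phantom slices", {
  ph <- small_phantom(11)
  for (z in c(6, 12, 18)) {
    res <- segment_slice(ph$volume$data[z, , ], level_set_params(),
                         ph$volume$spacing[2:3])
    tr <- res$energy_trace
    expect_true(all(diff(tr) <= 1e-8 * pmax(abs(tr[-length(tr)]), 1)))
  }
})

test_that("with fixed unit bias the converged partition matches k-means", {
  ph <- small_phantom(3, bias_ap_strength = 0, bias_lr_strength = 0,
                      noise_sd = 2)
  z <- 12
  sl <- ph$volume$data[z, , ]
  p0 <- level_set_params(n_classes = 3, bias_basis_order = NA,
                         length_weight = 0)
  res <- segment_slice(sl, p0, ph$volume$spacing[2:3])
  u <- sl / max(sl)
  km <- stats::kmeans(as.vector(u),
                      centers = quantile(u, c(1, 3, 5) / 6), iter.max = 50)
  expect_equal(state_sse(res$state, u), km$tot.withinss, tolerance = 1e-6)
})

test_that("segment_volume composes slices and zero-fills outside the range", {
  ph <- small_phantom(3, bias_ap_strength = 0, bias_lr_strength = 0,
                      noise_sd = 0)
  r <- slice_range(ph$z_range$z_start + 2, ph$z_range$z_end - 2)
  out <- segment_volume(ph$volume, r)
  outside <- setdiff(seq_len(dim(ph$volume$data)[1]), r$z_start:r$z_end)
  expect_true(all(out$seg$data[outside, , ] == 0))
  expect_true(all(out$bias$data[outside, , ] == 1))
  # on the bias-free noise-free phantom the bright class is exactly the fat
  truth_fat <- ph$breast_mask$data & !ph$parenchyma_mask$data
  zr <- r$z_start:r$z_end
  expect_identical(out$seg$data[zr, , ] == 1, truth_fat[zr, , ])
  expect_error(segment_volume(ph$volume, slice_range(1, 999)), "exceeds")
})

test_that("bias correction deepens the histogram valleys (corrected volume)", {
  sg <- small_segmentation(11)
  ph <- sg$phantom
  zr <- ph$z_range$z_start:ph$z_range$z_end
  centers <- with(ph$spec, c(air_intensity, parenchyma_intensity,
                             fat_intensity))
  raw <- as.vector(ph$volume$data[zr, , ])
  cor_v <- as.vector(sg$seg$corrected$data[zr, , ])
  expect_gt(histogram_valley_depth(cor_v, centers),
            histogram_valley_depth(raw, centers))
})
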