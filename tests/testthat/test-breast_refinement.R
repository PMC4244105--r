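mask_from <- function(arr) binary_mask(arr, c(1, 1, 1))

test_that("largest-component extraction keeps the biggest blob", {
  a <- array(0L, c(3, 12, 12))
  a[1:3, 2:5, 2:5] <- 1L      # 48 voxels
  a[2, 8:11, 8:10] <- 1L      # 12 voxels
  comp <- extract_largest_component(mask_from(a))
  expect_equal(sum(comp$labels == 1L), 48)
  expect_true(all(comp$labels %in% c(-1L, 1L)))
  expect_equal(unname(comp$centroid), c(2, 3.5, 3.5))
  expect_equal(unname(comp$bbox$min), c(1, 2, 2))
  expect_equal(unname(comp$bbox$max), c(3, 5, 5))
  expect_error(extract_largest_component(mask_from(array(0L, c(2, 4, 4)))),
               "empty")
  # deterministic tie-break with a warning
  b <- array(0L, c(1, 8, 8))
  b[1, 1:2, 1:2] <- 1L
  b[1, 6:7, 6:7] <- 1L
  expect_warning(cb <- extract_largest_component(mask_from(b)), "tied")
  expect_equal(sum(cb$labels == 1L), 4)
  expect_true(all(which(cb$labels == 1L, arr.ind = TRUE)[, 2] <= 2))
})

test_that("reference slice search returns the centroid slice for a uniform stack", {
  a <- array(0L, c(7, 16, 16))
  for (z in 1:7) a[z, 4:12, 4:12] <- 1L
  comp <- extract_largest_component(mask_from(a))
  expect_equal(find_reference_slice(comp), 4L)
  # fewer than 3 occupied slices is an error
  b <- array(0L, c(2, 8, 8)); b[, 2:6, 2:6] <- 1L
  expect_error(find_reference_slice(extract_largest_component(mask_from(b))),
               "3 slices")
})

# The 24-slice test phantom samples the breast coarsely, so neighbouring
# slices differ more than in a clinical stack; the triple-similarity
# threshold is opened up to 10% for it.
coarse_params <- function() refinement_params(triple_similarity_frac = 0.1)

test_that("slices carrying a large leakage lobe are not chosen as reference", {
  ph <- small_phantom(11)
  lk <- make_leakage_fixture(ph, 10, 2, z_slices = c(16, 17))
  sg <- segment_volume(lk$volume, lk$z_range)
  comp <- extract_largest_component(sg$seg)
  zr <- find_reference_slice(comp, coarse_params())
  expect_false(zr %in% c(16, 17))
})

test_that("evaluate_components keeps everything when slices agree", {
  sl <- matrix(FALSE, 20, 20); sl[4:16, 4:16] <- TRUE
  kept <- evaluate_components(sl, sl)
  expect_gt(length(kept), 0)
  un <- Reduce(`|`, kept)
  expect_identical(un, sl)
  expect_identical(evaluate_components(sl, matrix(FALSE, 20, 20)), list())
})

test_that("a lobe joined by a thin neck is split off and discarded", {
  si <- matrix(FALSE, 30, 30); si[5:18, 5:25] <- TRUE          # breast
  sj <- si
  sj[22:28, 12:18] <- TRUE                                     # lobe
  sj[19:21, 15] <- TRUE                                        # 1-wide neck
  kept <- evaluate_components(si, sj, refinement_params())
  un <- Reduce(`|`, kept)
  expect_true(all(un[si]))              # breast body kept
  expect_false(any(un[22:28, 12:18]))   # lobe discarded
})

test_that("update_slice restores watershed ridges between kept components", {
  c1 <- matrix(FALSE, 10, 10); c1[2:8, 2:4] <- TRUE
  c2 <- matrix(FALSE, 10, 10); c2[2:8, 6:8] <- TRUE
  out <- update_slice(list(c1, c2), c(10, 10))
  expect_true(all(out[2:8, 5] == 1L))     # ridge column between them
  expect_true(all(out[c1 | c2] == 1L))
  expect_identical(unique(as.vector(update_slice(list(), c(6, 6)))), -1L)
  one <- update_slice(list(c1), c(10, 10))
  expect_identical(one == 1L, c1)
})

test_that("propagation removes lobe voxels but keeps true fat tissue", {
  ph <- small_phantom(11)
  lk <- make_leakage_fixture(ph, 10, 2, z_slices = c(16, 17))
  sg <- segment_volume(lk$volume, lk$z_range)
  comp <- extract_largest_component(sg$seg)
  zr <- find_reference_slice(comp, coarse_params())
  ref <- propagate_boundaries(comp, zr, coarse_params())
  pre <- comp$labels == 1L; post <- ref$labels == 1L
  lob <- attr(lk, "lobe_voxels")
  expect_equal(sum(post[lob]), 0)       # the lobe disk is gone
  truth_fat <- ph$breast_mask$data & !ph$parenchyma_mask$data
  kept_true <- sum(post & pre & truth_fat) / sum(pre & truth_fat)
  expect_gt(kept_true, 0.995)
  dsc <- 2 * sum(post & truth_fat) / (sum(post) + sum(truth_fat))
  expect_gte(dsc, 0.99)
})

test_that("propagation is the identity on a leakage-free phantom", {
  sg <- small_segmentation(11)
  comp <- extract_largest_component(sg$seg$seg)
  zr <- find_reference_slice(comp, coarse_params())
  ref <- propagate_boundaries(comp, zr, coarse_params())
  pre <- comp$labels == 1L; post <- ref$labels == 1L
  # never adds voxels beyond ridge pixels; here: no additions at all
  expect_equal(sum(post & !pre), 0)
  expect_gt(sum(post) / sum(pre), 0.995)
})

test_that("hole filling closes cavities; the posterior image band is excluded", {
  a <- array(0L, c(3, 20, 20))
  a[, 3:12, 4:16] <- 1L
  a[2, 6:8, 8:10] <- 0L          # interior cavity
  band <- floor(0.85 * 20)       # rows beyond this are cut
  a[, 12:20, 9:11] <- 1L         # posterior junk column attached to the blob
  comp <- extract_largest_component(mask_from(a))
  out <- fill_holes_and_exclude_lower(comp, refinement_params())
  fg <- out$labels == 1L
  expect_true(all(fg[2, 6:8, 8:10]))           # cavity filled
  expect_false(any(fg[, (band + 1):20, ]))     # band removed
  removed <- sum(comp$labels == 1L) + length(8:10) * 3 - sum(fg)
  expect_equal(removed, sum(a[, (band + 1):20, ]))  # band occupancy
})

test_that("closing is idempotent on convex masks and radius-limited on notches", {
  a <- array(0L, c(5, 30, 30))
  a[2:4, 8:22, 8:22] <- 1L
  comp <- extract_largest_component(mask_from(a))
  out <- close_concavities(comp, refinement_params())
  expect_identical(out$labels, comp$labels)

  # anterior notch of radius 3 mm in a 1 mm in-plane grid; slices are 15 mm
  # apart so the ball acts within each slice. Filled by the 12 mm ball.
  thick <- function(arr) binary_mask(arr, c(15, 1, 1))
  b <- array(0L, c(3, 30, 30))
  b[, 8:22, 5:25] <- 1L
  yy <- matrix(seq_len(30), 30, 30); xx <- t(yy)
  notch <- (yy - 8)^2 + (xx - 15)^2 <= 3^2
  for (z in 1:3) b[z, , ][notch] <- 0L
  compb <- extract_largest_component(thick(b))
  outb <- close_concavities(compb, refinement_params())
  # interior of the notch is filled (the ball dips < 1 voxel into the
  # mouth row, which may stay open)
  filled <- outb$labels[2, , ][notch & yy > 8]
  expect_true(all(filled == 1L))
  # a notch wider than every ball radius persists
  d <- array(0L, c(3, 60, 60))
  d[, 12:50, 6:54] <- 1L
  notch2 <- (matrix(seq_len(60), 60, 60) - 12)^2 +
    (t(matrix(seq_len(60), 60, 60)) - 30)^2 <= 20^2
  for (z in 1:3) d[z, , ][notch2] <- 0L
  compd <- extract_largest_component(thick(d))
  outd <- close_concavities(compd, refinement_params())
  center_gap <- outd$labels[2, 12:25, 30]
  expect_true(any(center_gap == -1L))
  # closing never removes voxels
  expect_true(all(outd$labels[compd$labels == 1L] == 1L))
})

test_that("the sternum cut row equals the phantom's chest-wall boundary", {
  sg <- small_segmentation(11)
  ph <- sg$phantom
  comp <- extract_largest_component(sg$seg$seg)
  cut <- cut_at_sternum(comp, refinement_params())
  expect_equal(unname(attr(cut, "y_sternum")), ph$y_chest - 1)
  # all-anterior component: unchanged
  a <- array(0L, c(3, 20, 20)); a[, 2:8, 2:18] <- 1L
  ca <- extract_largest_component(mask_from(a))
  cut_a <- cut_at_sternum(ca, refinement_params())
  expect_identical(cut_a$labels, ca$labels)
  # empty midline window (centroid falls between the two occupied columns
  # and the window is narrower than a voxel): warning + identity
  b <- array(0L, c(3, 20, 20)); b[, 2:8, 2:3] <- 1L
  cb <- extract_largest_component(mask_from(b))
  expect_warning(cut_b <- cut_at_sternum(cb, refinement_params()), "midline")
  expect_identical(cut_b$labels, cb$labels)
})

test_that("build_breast_mask recovers the phantom breast with high Dice", {
  sg <- small_segmentation(11)
  ph <- sg$phantom
  bm <- build_breast_mask(sg$seg$seg, coarse_params())
  expect_gte(agreement_stats(bm, ph$breast_mask)$dsc, 0.95)
  # and from a leakage-corrupted segmentation as well
  lk <- make_leakage_fixture(ph, 10, 2, z_slices = c(16, 17))
  sgl <- segment_volume(lk$volume, lk$z_range)
  bml <- build_breast_mask(sgl$seg, coarse_params())
  expect_gte(agreement_stats(bml, ph$breast_mask)$dsc, 0.95)
  # refinement repairs damage monotonically
  raw_dice <- agreement_stats(sgl$seg, ph$breast_mask)$dsc
  expect_gte(agreement_stats(bml, ph$breast_mask)$dsc, raw_dice)
  # single connected component after refinement
  lab <- breastdens:::label_3d(bm$data)
  expect_equal(max(lab), 1)
  expect_error(build_breast_mask(binary_mask(array(0L, c(2, 4, 4)),
                                             c(1, 1, 1))), "empty")
})
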