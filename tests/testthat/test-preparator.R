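make_stack <- function(vox, vs = c(0.1, 0.1, 0.5), bits = 16L) {
  if (length(dim(vox)) == 3L) dim(vox) <- c(dim(vox), 1L)
  image_stack(vox, vs, bits)
}

test_that("rolling-ball background subtraction has the opening semantics", {
  const <- make_stack(array(120, c(40, 40, 2)))
  out <- subtract_background(const, 10)
  expect_true(all(out$voxels == 0))

  # flat background plus a single bright spike: spike preserved within 5%
  img <- array(100, c(60, 60, 1))
  img[30, 30, 1] <- 5000
  out <- subtract_background(make_stack(img), 20)
  expect_gt(out$voxels[30, 30, 1, 1], 0.95 * (5000 - 100))

  # linear ramp + tube: tube-to-background contrast strictly increases
  ramp <- outer(seq(0, 2000, length.out = 60), rep(1, 60))
  img <- array(ramp, c(60, 60, 1))
  img[28:32, 10:50, 1] <- img[28:32, 10:50, 1] + 1500
  stk <- make_stack(round(img))
  out <- subtract_background(stk, 15)
  # contrast-to-background-variation ratio: removing the ramp must improve it
  contrast <- function(s) {
    fg <- s$voxels[28:32, 10:50, 1, 1]
    bg <- s$voxels[c(1:20, 40:60), , 1, 1]
    (mean(fg) - mean(bg)) / (sd(bg) + 1)
  }
  expect_gt(contrast(out), contrast(stk))

  expect_error(subtract_background(const, 0), "radius")
  expect_error(subtract_background(const, 100), "extent")
})

test_that("Gaussian blur is identity at sigma 0 and conserves intensity", {
  set.seed(3)
  stk <- make_stack(array(sample(0:500, 30 * 30 * 2, TRUE), c(30, 30, 2)))
  expect_identical(gaussian_blur(stk, 0)$voxels, stk$voxels)
  expect_error(gaussian_blur(stk, -1), "sigma")

  # delta impulse reproduces the (renormalized) discrete Gaussian kernel
  img <- array(0, c(41, 41, 1))
  img[21, 21, 1] <- 10000
  out <- gaussian_blur(make_stack(img), 2)
  k <- exp(-0.5 * (-7:7)^2 / 4)
  expected <- 10000 * outer(k, k) / sum(outer(k, k))
  expect_equal(out$voxels[14:28, 14:28, 1, 1], expected, tolerance = 1e-6)

  # total intensity conserved away from borders
  inner <- array(0, c(61, 61, 1))
  inner[25:35, 25:35, 1] <- 300
  out <- gaussian_blur(make_stack(inner), 2)
  expect_equal(sum(out$voxels), sum(inner), tolerance = 1e-3)
})

test_that("hysteresis keeps low components anchored above the high threshold", {
  # 1D profile 0,5,9,5,0,5 with low 4 / high 8: positions 2:4 kept, 6 dropped
  img <- array(0, c(1, 6, 1))
  img[1, , 1] <- c(0, 5, 9, 5, 0, 5)
  stk <- make_stack(img, bits = 8L)
  mask <- hysteresis_segment(stk, 4, 8)
  expect_equal(which(mask[1, , 1]), 2:4)

  # two tubes, one dim one bright: only the bright one is retained
  img <- array(0, c(20, 40, 2))
  img[5, 5:35, 1] <- 120    # dim tube, below high
  img[15, 5:35, 1] <- 240   # bright tube
  stk <- make_stack(img, bits = 8L)
  mask <- hysteresis_segment(stk, 100, 200)
  expect_true(all(mask[15, 5:35, 1]))
  expect_false(any(mask[5, , ]))

  expect_error(hysteresis_segment(stk, 200, 100), "low <= high")
})

test_that("hysteresis nesting holds on random stacks", {
  set.seed(11)
  for (i in 1:50) {
    vox <- array(sample(0:255, 10 * 10 * 4, TRUE), c(10, 10, 4))
    stk <- make_stack(vox, bits = 8L)
    lo <- sample(20:120, 1)
    hi <- lo + sample(10:100, 1)
    m <- hysteresis_segment(stk, lo, hi)
    m_lo <- vox > lo
    m_hi <- vox > hi
    expect_true(all(m[m_hi]), label = sprintf("high subset, stack %d", i))
    expect_true(all(m_lo[m]), label = sprintf("low superset, stack %d", i))
  }
})

test_that("raising a manual threshold never increases the mask", {
  set.seed(5)
  vox <- array(sample(0:255, 16^3, TRUE), c(16, 16, 4))
  stk <- make_stack(vox, bits = 8L)
  counts <- vapply(c(10, 60, 120, 200), function(t) {
    seg <- segment_stack(stk, segmentation_settings(method = t,
                                                    style = "binary"))
    sum(seg$voxels > 0)
  }, 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("segment_stack styles and determinism behave as documented", {
  cl <- generate_centerline(2, c(6, 6, 2), c(2, 4))
  truth <- phantom_truth(list(cl), snr = Inf, background_level = 0, seed = 2)
  stk <- rasterize_scene(truth, c(75, 75, 4), antialias = FALSE)
  seg <- segment_stack(stk, segmentation_settings(method = 1))
  # noise-free: mask equals the rasterization ground truth
  expect_equal(seg$voxels[, , , 1] > 0, stk$voxels[, , , 1] > 0)

  seg2 <- segment_stack(stk, segmentation_settings(method = 1))
  expect_identical(seg$voxels, seg2$voxels)

  # keep-intensities: nonzero histogram equals original above the cut
  noisy <- phantom_truth(list(cl), snr = 8, background_level = 60,
                         psf_sigma_um = c(0.08, 0.08, 0.2), seed = 3)
  nstk <- rasterize_scene(noisy, c(75, 75, 4))
  seg3 <- segment_stack(nstk, segmentation_settings(method = "Otsu"))
  t <- attr(seg3, "metadata")$settings$threshold_value
  orig <- nstk$voxels[, , , 1]
  kept <- seg3$voxels[, , , 1]
  expect_equal(sort(kept[kept > 0]), sort(orig[orig > t]))

  # binary style uses the maximum representable intensity
  seg4 <- segment_stack(nstk, segmentation_settings(method = "Otsu",
                                                    style = "binary"))
  expect_true(all(seg4$voxels[, , , 1] %in% c(0, 65535)))

  expect_warning(segment_stack(nstk,
                               segmentation_settings(method = 65534)),
                 "empty mask")
})

test_that("mask edits are exact inverses and validate bounds", {
  mask <- array(FALSE, c(8, 8, 3))
  mask[2:4, 2:4, 1] <- TRUE
  region <- cbind(c(6, 7), c(6, 7), c(2, 2))
  edited <- apply_mask_edit(mask, region, "add")
  expect_true(all(edited[region]))
  back <- apply_mask_edit(edited, region, "remove")
  expect_equal(array(back, dim(mask)), mask)

  empty <- array(FALSE, c(4, 4, 2))
  expect_equal(sum(apply_mask_edit(empty, cbind(1, 1, 1), "remove")), 0)
  expect_error(apply_mask_edit(mask, cbind(9, 1, 1), "add"),
               "out-of-bounds")

  # bridging a 1-voxel gap merges two objects downstream
  gap <- array(FALSE, c(5, 11, 1))
  gap[3, 1:5, 1] <- TRUE
  gap[3, 7:11, 1] <- TRUE
  expect_equal(label_objects(gap)$n_objects, 2L)
  bridged <- apply_mask_edit(gap, cbind(3, 6, 1), "add")
  expect_equal(label_objects(bridged)$n_objects, 1L)
})

test_that("sampling limits follow the Rayleigh criterion", {
  lim <- compute_sampling_limits(668, 1.4)
  expect_equal(unname(lim["resolution_nm"]), 0.61 * 668 / 1.4)
  expect_equal(unname(lim["nyquist_nm"]), 0.61 * 668 / 1.4 / 2)

  # linearity in wavelength
  expect_equal(unname(compute_sampling_limits(1000, 1.2)),
               2 * unname(compute_sampling_limits(500, 1.2)))
  lim2 <- compute_sampling_limits(500, 1.0)
  expect_equal(unname(lim2["resolution_nm"]), 305)
  expect_equal(unname(lim2["nyquist_nm"]), 152.5)
  expect_error(compute_sampling_limits(-1, 1.4), "wavelength")
  expect_error(compute_sampling_limits(500, 2), "aperture")
})
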