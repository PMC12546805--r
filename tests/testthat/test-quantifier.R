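vs_iso <- c(dx = 0.1, dy = 0.1, dz = 0.1)
vs_conf <- c(dx = 0.08, dy = 0.08, dz = 0.5)

test_that("object labeling matches flood-fill and handles gap bridging", {
  # two tubes separated by >= 3 background voxels: 2 labels either way
  m <- array(FALSE, c(9, 20, 3))
  m[3, 2:18, 2] <- TRUE
  m[7, 2:18, 2] <- TRUE
  expect_equal(label_objects(m)$n_objects, 2L)
  expect_equal(label_objects(m, increase_range = TRUE)$n_objects, 2L)

  # tube split by exactly one background voxel: bridged only with the flag
  g <- array(FALSE, c(5, 21, 3))
  g[3, 2:9, 2] <- TRUE
  g[3, 11:20, 2] <- TRUE
  expect_equal(label_objects(g)$n_objects, 2L)
  expect_equal(label_objects(g, increase_range = TRUE)$n_objects, 1L)

  # 3D checkerboard is a single 26-connected object
  cb <- array(FALSE, c(6, 6, 4))
  idx <- which(array(TRUE, dim(cb)), arr.ind = TRUE)
  cb[(idx[, 1] + idx[, 2] + idx[, 3]) %% 2 == 0] <- TRUE
  lab <- label_objects(cb)
  expect_equal(lab$n_objects, 1L)

  set.seed(8)
  for (i in 1:10) {
    r <- array(runif(12 * 12 * 5) < 0.25, c(12, 12, 5))
    ours <- label_objects(r)$labels
    ref <- oracle_label(r)
    # same partition (labels may be permuted)
    expect_equal(max(ours), max(ref))
    expect_true(all(tapply(ref[r], ours[r], function(x)
      length(unique(x))) == 1))
  }
})

test_that("size and border filtering equals the brute-force rule", {
  m <- array(FALSE, c(10, 30, 4))
  m[2:3, 2:3, 2] <- TRUE                 # 4 voxels < min size 10
  m[6:8, 5:20, 2:3] <- TRUE              # large object
  lab <- label_objects(m)
  f <- filter_objects(lab, min_size_voxels = 10)
  expect_equal(f$n_objects, 1L)
  rep <- attr(f, "exclusion_report")
  expect_equal(rep$reason, "too-small")

  # border object removed with the axis flag, kept without
  b <- array(FALSE, c(8, 8, 3))
  b[4:5, 4:5, 1] <- TRUE                 # touches z = 1
  lab_b <- label_objects(b)
  expect_equal(filter_objects(lab_b, 1, c(x = FALSE, y = FALSE,
                                          z = TRUE))$n_objects, 0L)
  expect_equal(filter_objects(lab_b, 1, c(x = FALSE, y = FALSE,
                                          z = FALSE))$n_objects, 1L)
  expect_equal(attr(filter_objects(lab_b, 1, c(FALSE, FALSE, TRUE)),
                    "exclusion_report")$reason, "border")

  # random fields against an exhaustive per-object check
  set.seed(13)
  for (i in 1:8) {
    r <- array(runif(14 * 14 * 6) < 0.2, c(14, 14, 6))
    lab <- label_objects(r)
    keep_min <- sample(2:6, 1)
    f <- filter_objects(lab, keep_min, c(x = TRUE, y = FALSE, z = TRUE))
    survivors <- 0L
    d <- dim(r)
    for (l in seq_len(lab$n_objects)) {
      co <- which(lab$labels == l, arr.ind = TRUE)
      at_border <- any(co[, 2] %in% c(1, d[2])) || any(co[, 3] %in% c(1, d[3]))
      if (nrow(co) >= keep_min && !at_border) survivors <- survivors + 1L
    }
    expect_equal(f$n_objects, survivors, label = sprintf("field %d", i))
  }
})

test_that("minimum size suggestion scales inversely with squared pixel size", {
  expect_equal(suggest_min_size(0.1), 10L)
  expect_equal(suggest_min_size(0.05), 40L)
  expect_equal(suggest_min_size(0.2), 3L)   # 2.5 rounded up
  expect_error(suggest_min_size(0), "pixel_size")
})

test_that("morphology has exact closed forms", {
  # single voxel at (0.1, 0.1, 0.5) um
  m <- measure_morphology(cbind(1, 1, 1), c(dx = 0.1, dy = 0.1, dz = 0.5))
  expect_equal(m$volume_um3, 0.005)
  expect_equal(m$surface_um2, 2 * 0.1 * 0.1 + 4 * 0.1 * 0.5)
  expect_equal(m$max_span_um, 0)

  # 1 x 1 x 10 rod along z spans 9 * dz
  rod <- cbind(1, 1, 1:10)
  m <- measure_morphology(rod, c(dx = 0.1, dy = 0.1, dz = 0.5))
  expect_equal(m$max_span_um, 9 * 0.5)
  expect_equal(m$volume_voxels, 10)
  expect_equal(m$volume_um3, 10 * 0.1 * 0.1 * 0.5)

  # random blob: span equals the brute-force pairwise maximum
  set.seed(21)
  co <- unique(cbind(sample(1:12, 60, TRUE), sample(1:12, 60, TRUE),
                     sample(1:5, 60, TRUE)))
  m <- measure_morphology(co, vs_conf)
  pts <- cbind((co[, 2] - 0.5) * 0.08, (co[, 1] - 0.5) * 0.08,
               (co[, 3] - 0.5) * 0.5)
  best <- 0
  for (i in seq_len(nrow(pts))) for (j in seq_len(nrow(pts)))
    best <- max(best, sqrt(sum((pts[i, ] - pts[j, ])^2)))
  expect_equal(m$max_span_um, best)
})

test_that("skeleton measures recover straight, L and T geometries", {
  # straight 51-voxel line along x, dx = 0.1: length 5.0, one branch
  line <- array(FALSE, c(3, 53, 3))
  line[2, 2:52, 2] <- TRUE
  sk <- skeletonize_and_measure(line, vs_iso)
  expect_equal(sk$cilia_length_um, 5.0, tolerance = 1e-9)
  expect_equal(sk$tree_length_um, 5.0, tolerance = 1e-9)
  expect_equal(sk$n_branches, 1L)
  expect_equal(sk$bending_ratio, 1.0, tolerance = 1e-9)

  # T-shaped skeleton: 3 branches, tree > cilia, cilia = longest route
  tee <- array(FALSE, c(13, 13, 3))
  tee[7, 2:12, 2] <- TRUE
  tee[8:12, 7, 2] <- TRUE
  sk <- skeletonize_and_measure(tee, vs_iso)
  expect_equal(sk$n_branches, 3L)
  expect_gt(sk$tree_length_um, sk$cilia_length_um)
  # longest of the three end-to-end routes on the produced skeleton, equal to
  # the independent Dijkstra oracle (thinning may open the junction into a
  # diagonal jog, so the route can exceed the ideal 1.0 um by one step)
  expect_equal(sk$cilia_length_um,
               oracle_dijkstra_lengths(sk$skeleton,
                                       sk$skeleton_voxel_size_um),
               tolerance = 1e-9)
  expect_gte(sk$cilia_length_um, 1.0 - 1e-9)
  expect_lt(sk$cilia_length_um, 1.1)

  # single voxel: zero length, reported not erred
  dot <- array(FALSE, c(3, 3, 3)); dot[2, 2, 2] <- TRUE
  sk <- skeletonize_and_measure(dot, vs_iso)
  expect_equal(sk$cilia_length_um, 0)
  expect_equal(sk$n_branches, 1L)
})

test_that("path lengths equal an independent Dijkstra on the returned skeleton", {
  set.seed(77)
  for (i in 1:20) {
    skel_in <- random_voxel_path(len = sample(10:25, 1))
    sk <- skeletonize_and_measure(skel_in, vs_iso)
    ref <- oracle_dijkstra_lengths(sk$skeleton, sk$skeleton_voxel_size_um)
    # point-like skeletons (span <= one step) are reported as zero length
    if (ref <= sqrt(sum(sk$skeleton_voxel_size_um^2)) + 1e-12) ref <- 0
    expect_equal(sk$cilia_length_um, ref, tolerance = 1e-9,
                 label = sprintf("constructed skeleton %d", i))
  }
})

test_that("intensity statistics use population moments within the mask", {
  vox <- array(7, c(4, 4, 2, 1))
  stk <- image_stack(vox, c(0.1, 0.1, 0.5))
  r <- measure_intensity(cbind(c(1, 2), c(1, 1), c(1, 1)), stk, 1)
  expect_equal(unname(r["mean"]), 7)
  expect_equal(unname(r["sd"]), 0)

  vox[1, 1, 1, 1] <- 10; vox[2, 1, 1, 1] <- 20
  stk <- image_stack(vox, c(0.1, 0.1, 0.5))
  r <- measure_intensity(cbind(c(1, 2), c(1, 1), c(1, 1)), stk, 1)
  expect_equal(unname(r["mean"]), 15)
  expect_equal(unname(r["sd"]), 5)     # population sd
  expect_error(measure_intensity(cbind(1, 1, 1), stk, 9), "channel")
})

test_that("quantify_stack runs the full per-object pipeline on phantoms", {
  # five tubes in separate lanes so none touch each other
  vs5 <- c(dx = 0.1, dy = 0.1, dz = 0.3)
  cls <- lapply(1:5, function(s) {
    cl <- generate_centerline(300 + s, c(9.5, 1.6, 3), c(2, 6),
                              curvature = 0.04, radius_um = 0.3)
    cp <- cl$control_points
    cp[, 2] <- cp[, 2] + (s - 1) * 2 + 0.2
    centerline_spec(cp, 0.3, 1000)
  })
  truth <- phantom_truth(cls, vs5, snr = Inf, background_level = 0,
                         psf_sigma_um = c(0.08, 0.08, 0.15), seed = 1)
  stk <- rasterize_scene(truth, c(100, 100, 10))
  stk <- segment_stack(stk, segmentation_settings(method = 400))
  tab <- quantify_stack(stk, min_size_voxels = 16,
                        exclude_borders = c(FALSE, FALSE, FALSE),
                        gauss_xy_sigma = 2, range_voxels = 2,
                        rebinarize_level = 0.45)
  expect_equal(nrow(tab$records), 5L)
  # match records to ground truth by lane position
  ord <- order(tab$records$centroid_y_um)
  to <- order(vapply(cls, function(c) mean(c$control_points[, 2]), 0))
  meas <- tab$records$cilia_length_um[ord]
  truthL <- truth$arc_lengths_um[to]
  expect_true(all(abs(meas - truthL) / truthL < 0.10))

  # volume identity: volume_um3 / volume_voxels = dx dy dz exactly
  expect_equal(tab$records$volume_um3 / tab$records$volume_voxels,
               rep(prod(vs5), 5))
  # tree >= cilia for every record
  expect_true(all(tab$records$tree_length_um >=
                  tab$records$cilia_length_um - 1e-9))
})

test_that("border exclusion removes a tube touching z and spheres get zero length", {
  cl0 <- generate_centerline(9, c(8, 8, 1.2), c(2, 5))
  cp <- cl0$control_points
  cp[, 3] <- cp[, 3] + 0.65          # keep the tube clear of the z borders
  cl1 <- centerline_spec(cp, cl0$radius_um, cl0$intensity)
  truth <- phantom_truth(list(cl1), vs_conf, snr = Inf,
                         background_level = 0, seed = 1)
  stk <- rasterize_scene(truth, c(100, 100, 5), antialias = FALSE)
  # plant a slab touching the first z plane, in rows clear of the tube
  occ <- which(apply(stk$voxels[, , , 1] > 0, 1, any))
  rows <- if (max(occ) <= 90) (max(occ) + 4):(max(occ) + 9) else
    (min(occ) - 9):(min(occ) - 4)
  stk$voxels[rows, 10:60, 1, 1] <- 1000
  tab_off <- quantify_stack(stk, min_size_voxels = 16,
                            exclude_borders = c(FALSE, FALSE, FALSE))
  tab_on <- quantify_stack(stk, min_size_voxels = 16,
                           exclude_borders = c(FALSE, FALSE, TRUE))
  expect_equal(nrow(tab_off$records), 2L)
  expect_equal(nrow(tab_on$records), 1L)
  expect_true("border" %in% attr(tab_on, "exclusion_report")$reason)

  # basal-body-like spherical blob: cilia_length 0
  ball <- array(0, c(30, 30, 7, 1))
  cc <- c(15, 15, 4)
  for (z in 1:7) for (x in 1:30) for (y in 1:30) {
    if (sqrt(((x - cc[1]) * 0.08)^2 + ((y - cc[2]) * 0.08)^2 +
             ((z - cc[3]) * 0.5)^2) <= 0.3) ball[y, x, z, 1] <- 800
  }
  bstk <- image_stack(ball, vs_conf)
  btab <- quantify_stack(bstk, min_size_voxels = 5,
                         exclude_borders = c(FALSE, FALSE, FALSE),
                         gauss_xy_sigma = 0)
  expect_equal(nrow(btab$records), 1L)
  expect_equal(btab$records$cilia_length_um, 0)
})
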