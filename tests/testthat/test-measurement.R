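test_that("point-like column and symmetric fields localise exactly", {
  # a 3-frame column (the shortest object the z median filter preserves)
  # centred at 0-based (z=4, y=10, x=10)
  vox <- array(0, c(10, 20, 20))
  vox[4:6, 11, 11] <- 100
  st <- channel_stack(vox, dx = 1, dy = 1, dz = 2, z0 = 0, "473")
  ct <- compute_centroid(st, bead_roi(5, 16, 5, 16))
  expect_equal(ct$z, 8)           # z0 + 4 * dz
  expect_equal(ct$x, 10); expect_equal(ct$y, 10)
  expect_gt(ct$total_weight, 0)

  # field symmetric about voxel (5, 8, 8) (0-based): separable triangle
  tz <- pmax(0, 4 - abs(0:11 - 5)); ty <- pmax(0, 5 - abs(0:16 - 8))
  sym <- 100 * tz %o% ty %o% ty
  st2 <- channel_stack(sym, dx = 0.5, dy = 0.5, dz = 3, z0 = 10, "473")
  ct2 <- suppressMessages(compute_centroid(st2, bead_roi(0, 17, 0, 17)))
  expect_equal(ct2$z, 10 + 5 * 3, tolerance = 1e-12)
  expect_equal(ct2$y, 8 * 0.5, tolerance = 1e-12)
  expect_equal(ct2$x, 8 * 0.5, tolerance = 1e-12)
})

test_that("centroid agrees with the brute-force oracle on random ROIs", {
  set.seed(42)
  for (rep in 1:25) {
    shape <- c(sample(4:9, 1), sample(4:9, 1), sample(4:9, 1))
    vox <- array(stats::rexp(prod(shape), 1 / 50), shape)
    # implant a bright cluster so the threshold keeps something
    cz <- sample(2:(shape[1] - 1), 1)
    cy <- sample(2:(shape[2] - 1), 1)
    cx <- sample(2:(shape[3] - 1), 1)
    vox[(cz - 1):(cz + 1), cy, cx] <- 4000 + runif(3) * 1000
    vox[cz, cy, min(cx + 1, shape[3])] <- 3000
    dx <- runif(1, 0.5, 3); dy <- runif(1, 0.5, 3); dz <- runif(1, 0.5, 4)
    z0 <- runif(1, -10, 10)
    st <- channel_stack(vox, dx, dy, dz, z0, "473")
    roi <- bead_roi(0, shape[3], 0, shape[2], 0, shape[1])
    want <- oracle_centroid(vox, dx, dy, dz, z0, roi)
    got <- suppressMessages(compute_centroid(st, roi))
    expect_equal(got$x, want[["x"]], tolerance = 1e-12)
    expect_equal(got$y, want[["y"]], tolerance = 1e-12)
    expect_equal(got$z, want[["z"]], tolerance = 1e-12)
    expect_equal(got$total_weight, want[["weight"]], tolerance = 1e-12)
  }
})

test_that("centroid is translation-equivariant and scale-invariant", {
  st <- single_bead_stack(center = c(60.7, 23.2, 25.1))
  roi <- bead_roi(3, 21, 3, 21, 10, 50)
  ct <- compute_centroid(st, roi)
  # integer-voxel translation of content and ROI moves centroid exactly
  sh <- c(4L, 2L, -3L)  # (z, y, x) voxels
  vox2 <- array(0, dim(st$voxels))
  vox2[(1 + sh[1]):60, (1 + sh[2]):24, 1:(24 + sh[3])] <-
    st$voxels[1:(60 - sh[1]), 1:(24 - sh[2]), (1 - sh[3]):24]
  st2 <- channel_stack(vox2, st$dx, st$dy, st$dz, st$z0, "473")
  roi2 <- bead_roi(roi$x_min + sh[3], roi$x_max + sh[3],
                   roi$y_min + sh[2], roi$y_max + sh[2],
                   roi$z_min + sh[1], roi$z_max + sh[1])
  ct2 <- compute_centroid(st2, roi2)
  expect_equal(ct2$z - ct$z, sh[1] * st$dz, tolerance = 1e-9)
  expect_equal(ct2$y - ct$y, sh[2] * st$dy, tolerance = 1e-9)
  expect_equal(ct2$x - ct$x, sh[3] * st$dx, tolerance = 1e-9)
  # positive intensity scaling leaves the centroid unchanged
  st3 <- st; st3$voxels <- st$voxels * 7.5
  ct3 <- compute_centroid(st3, roi)
  expect_equal(c(ct3$x, ct3$y, ct3$z), c(ct$x, ct$y, ct$z),
               tolerance = 1e-12)
})

test_that("sub-threshold symmetric noise does not move the centroid", {
  st <- single_bead_stack(center = c(40, 24, 24))
  roi <- bead_roi(6, 18, 6, 18, 8, 32)
  ct_clean <- compute_centroid(st, roi)
  set.seed(9)
  noisy <- st$voxels + sample(c(-1, 1), length(st$voxels), TRUE) *
    runif(length(st$voxels), 0, 20)  # far below mean + 10 SD of the blob
  st_n <- channel_stack(pmax(noisy, 0), st$dx, st$dy, st$dz, st$z0, "473")
  ct_noisy <- compute_centroid(st_n, roi)
  # kept voxel set is identical, weights perturbed by <= 20/10000
  expect_equal(ct_noisy$z, ct_clean$z, tolerance = 0.01)
  expect_equal(ct_noisy$x, ct_clean$x, tolerance = 0.01)
})

test_that("threshold fallback ladder engages for dim objects, then errors", {
  # dim blob (3 x noise SD) on a noisy pedestal: the noise-driven SD puts
  # mean + 10 SD above every voxel, so the ladder must step down
  set.seed(1)
  vox <- array(200 + rnorm(30 * 16 * 16, 0, 20), c(30, 16, 16))
  vox <- chromaxial:::add_blob(vox, c(30, 16, 16), c(6, 2, 2), c(2, 2, 2),
                               0, 60, extent = 20)
  st <- channel_stack(pmax(vox, 0), 2, 2, 2, 0, "473")
  roi <- bead_roi(0, 16, 0, 16, 0, 30)
  expect_message(ct <- compute_centroid(st, roi), "retrying with k")
  expect_true("fallback_threshold" %in% ct$flags)
  flat <- channel_stack(array(100, c(10, 8, 8)), 1, 1, 1, 0, "473")
  expect_error(suppressMessages(
    compute_centroid(flat, bead_roi(0, 8, 0, 8))), "no object")
})

test_that("reference shifts are zero and frame translation gives exact dz", {
  st <- single_bead_stack(center = c(50, 24, 24), shape = c(80L, 24L, 24L))
  # channel 2: identical content translated +3 frames
  vox2 <- array(0, dim(st$voxels))
  vox2[4:80, , ] <- st$voxels[1:77, , ]
  st2 <- channel_stack(vox2, st$dx, st$dy, st$dz, st$z0, "559")
  mc <- multi_channel_stack(list(st, st2), "473")
  roi <- bead_roi(4, 20, 4, 20, 10, 45)
  smp <- measure_sample(mc, roi)
  expect_identical(unname(smp$shifts[["473"]]), c(0, 0, 0))
  expect_equal(smp$shifts[["559"]][["dz"]], 3 * st$dz, tolerance = 1e-9)
  expect_equal(smp$shifts[["559"]][["dx"]], 0, tolerance = 1e-9)
  expect_equal(smp$depth, compute_centroid(st, roi)$z)
})

test_that("batch measurement recovers phantom ground truth within dz/2", {
  spec <- small_bead_spec(seed = 3, n = 15)
  ph <- generate_phantom(spec)
  smp <- suppressMessages(measure_batch(ph$stack, ph$rois))
  expect_equal(nrow(attr(smp, "failures")), 0)
  m <- merge(smp[smp$channel == "559", ], ph$truth, by = "label")
  expect_equal(nrow(m), 15)
  expect_lt(max(abs(m$dz_um.x - m$dz_um.y)), spec$pitch[1] / 2)
  expect_lt(max(abs(m$depth_um.x - m$depth_um.y)), spec$pitch[1] / 2)
  # cardinality: failures are reported, not fatal
  rois_bad <- c(ph$rois[1:3], list(bead_roi(0, 6, 0, 6, 0, 2, "thin")))
  smp2 <- suppressMessages(measure_batch(ph$stack, rois_bad))
  expect_equal(length(unique(smp2$label)), 3)
  expect_equal(attr(smp2, "failures")$label, "thin")
  empty <- measure_batch(ph$stack, list())
  expect_equal(nrow(empty), 0)
})

test_that("guide-star truncation sanity check flags clipped objects", {
  st <- single_bead_stack(center = c(20, 24, 24), shape = c(60L, 24L, 24L))
  roi_full <- bead_roi(4, 20, 4, 20, 0, 30)
  ct_ok <- suppressMessages(compute_centroid(st, roi_full))
  expect_false("possibly_truncated" %in% ct_ok$flags)
  roi_clip <- bead_roi(4, 20, 4, 20, 8, 12)  # cuts through the blob
  ct_bad <- suppressMessages(compute_centroid(st, roi_clip))
  expect_true("possibly_truncated" %in% ct_bad$flags)
})
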