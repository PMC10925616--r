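test_that("NEMA phantom conserves sphere activity within voxelisation error", {
  ph <- build_nema(grid = nm_grid(c(64, 64, 48)))
  total <- sum(ph$activity$data)
  nominal <- mci_to_mbq(0.13 + 0.27 + 0.63)
  expect_lt(abs(total - nominal) / nominal, 0.01)
  # each sphere individually
  for (i in 1:3) {
    sp <- default_nema_spheres()[i, ]
    spec <- nema_phantom_spec(spheres = sp)
    one <- build_nema(spec, grid = nm_grid(c(64, 64, 48)))
    nom <- mci_to_mbq(sp$activity_mCi)
    expect_lt(abs(sum(one$activity$data) - nom) / nom, 0.01)
  }
})

test_that("refining the grid reduces NEMA voxelisation error", {
  sp <- default_nema_spheres()[3, ] # 22 mm, worst case on the coarse grid
  spec <- nema_phantom_spec(spheres = sp)
  nom <- mci_to_mbq(sp$activity_mCi)
  err_coarse <- abs(sum(build_nema(spec, nm_grid(c(64, 64, 48)))$activity$data) - nom)
  fine <- nm_grid(c(96, 96, 64), spacing = rep(2.21, 3))
  err_fine <- abs(sum(build_nema(spec, fine)$activity$data) - nom)
  expect_lt(err_fine, err_coarse)
})

test_that("degenerate phantom inputs behave", {
  zero <- nema_phantom_spec(spheres = sphere_spec(22, c(55, 0, 0), 0))
  ph <- build_nema(zero, grid = nm_grid(c(32, 32, 24)))
  expect_true(all(ph$activity$data == 0))
  expect_gt(sum(ph$mu$data), 0)
  outside <- nema_phantom_spec(spheres = sphere_spec(37, c(108, 0, 0), 0.1))
  expect_error(build_nema(outside, nm_grid(c(32, 32, 24))),
               class = "luquant_geometry_error")
})

test_that("uniform cylinder reconstitutes its total activity", {
  j <- build_jaszczak(18, diameter_mm = 216, height_mm = 164.2,
                      grid = nm_grid(c(64, 64, 48)))
  expect_equal(j$concentration_MBq_per_ml * j$volume_ml, mci_to_mbq(18),
               tolerance = 1e-6)
  expect_equal(18 / 6011.5, 0.003, tolerance = 0.01) # 18 mCi in ~6 L is 0.003 mCi/mL
  nominal <- mci_to_mbq(18)
  expect_lt(abs(sum(j$activity$data) - nominal) / nominal, 0.01)
  # doubling volume at fixed activity halves concentration
  j2 <- build_jaszczak(18, diameter_mm = 216, height_mm = 2 * 164.2,
                       grid = nm_grid(c(64, 64, 96)))
  expect_equal(j2$concentration_MBq_per_ml, j$concentration_MBq_per_ml / 2,
               tolerance = 1e-12)
  expect_true(all(build_jaszczak(0, grid = nm_grid(c(16, 16, 8)))$activity$data == 0))
  expect_error(build_jaszczak(10, diameter_mm = -5), class = "luquant_geometry_error")
})

test_that("point sources land with sub-voxel centroid accuracy", {
  g <- nm_grid(c(16, 16, 8))
  at_center <- build_point_sources(rbind(c(2.21, 2.21, 2.21)), 10, g)
  expect_equal(sum(at_center$data > 0), 1) # a voxel centre: one hot voxel
  expect_equal(centroid_mm(at_center), c(2.21, 2.21, 2.21), tolerance = 1e-9)
  # half-voxel offsets
  pos <- c(2.21, -1.105, 1.3)
  v <- build_point_sources(rbind(pos), 10, g)
  expect_lt(max(abs(centroid_mm(v) - pos)), 0.05)
  # conservation over several sources
  five <- build_point_sources(cbind(runif(5, -20, 20), runif(5, -20, 20),
                                    runif(5, -10, 10)), 3, g)
  expect_equal(sum(five$data), 15, tolerance = 1e-9)
  expect_error(build_point_sources(rbind(c(500, 0, 0)), 1, g),
               class = "luquant_geometry_error")
})

test_that("resampling preserves constants, identity, and totals", {
  g <- nm_grid(c(16, 16, 8))
  v <- volume_image(array(runif(16 * 16 * 8), c(16, 16, 8)), g$spacing,
                    quantity = "arbitrary")
  expect_equal(resample(v, g, method = "trilinear")$data, v$data,
               tolerance = 1e-12)
  const <- volume_image(array(3.5, c(16, 16, 8)), g$spacing)
  fine <- nm_grid(c(24, 24, 12), spacing = rep(2.5, 3))
  res <- resample(const, fine, method = "trilinear")
  interior <- res$data[5:20, 5:20, 3:10]
  expect_equal(max(abs(interior - 3.5)), 0, tolerance = 1e-9)
  # activity conservation when downsampling CT-grid spheres to the NM grid
  sp <- default_nema_spheres()[1, ]
  ctg <- ct_grid(c(160, 160, 24))
  ph_ct <- build_nema(nema_phantom_spec(spheres = sp), ctg)
  down <- resample(ph_ct$activity, nm_grid(c(48, 48, 24)), method = "average")
  expect_lt(abs(sum(down$data) - sum(ph_ct$activity$data)) /
              sum(ph_ct$activity$data), 0.01)
  # disjoint fields of view
  far <- volume_image(array(0, c(8, 8, 4)), c(1, 1, 1),
                      origin = c(1000, 1000, 1000))
  expect_error(resample(v, far), class = "luquant_geometry_error")
})

test_that("CT contours resampled to the NM grid keep their volume", {
  masks <- sphere_masks(default_nema_spheres(), ct_grid(c(160, 160, 24)))
  nm <- nm_grid(c(48, 48, 24))
  nm_voxel_ml <- voxel_volume_ml(nm)
  for (nmk in names(masks)) {
    ct_vol_ml <- sum(masks[[nmk]]$data) * voxel_volume_ml(masks[[nmk]])
    res <- resample(masks[[nmk]], nm, method = "mask")
    nm_vol_ml <- sum(res$data) * nm_voxel_ml
    # binary voxelisation at 4.42 mm carries a surface-voxel volume error of
    # a few percent on 22-37 mm spheres
    expect_lt(abs(nm_vol_ml - ct_vol_ml) / ct_vol_ml, 0.08)
  }
})

test_that("sphere masks have the nominal diameters within one CT voxel", {
  spheres <- default_nema_spheres()
  masks <- sphere_masks(spheres, ct_grid(c(160, 160, 24)))
  for (i in seq_len(nrow(spheres))) {
    m <- masks[[i]]
    idx <- which(m$data != 0, arr.ind = TRUE)
    extent_x <- (max(idx[, 1]) - min(idx[, 1]) + 1) * m$spacing[1]
    expect_lt(abs(extent_x - spheres$diameter_mm[i]), m$spacing[1] + 1e-9)
  }
})

test_that("metric dilation adds the requested margin on every axis", {
  g <- nm_grid(c(24, 24, 16))
  m <- array(0, c(24, 24, 16)); m[12, 12, 8] <- 1
  mask <- volume_image(m, g$spacing, quantity = "mask")
  d10 <- dilate_mask(mask, 10)
  # the dilated set is exactly the voxels whose centres lie within 10 mm
  all_idx <- expand.grid(i = 1:24, j = 1:24, k = 1:16)
  dist <- sqrt(((all_idx$i - 12) * g$spacing[1])^2 +
               ((all_idx$j - 12) * g$spacing[2])^2 +
               ((all_idx$k - 8) * g$spacing[3])^2)
  expected <- array(as.numeric(dist <= 10), c(24, 24, 16))
  expect_identical(d10$data, expected)
  expect_identical(dilate_mask(mask, 0)$data, m * 1)
})

test_that("volumes survive a NIfTI round-trip", {
  g <- nm_grid(c(12, 10, 6))
  v <- volume_image(array(runif(720), c(12, 10, 6)), g$spacing,
                    quantity = "cps")
  path <- tempfile(fileext = ".nii.gz")
  on.exit(unlink(path))
  write_volume(v, path)
  back <- read_volume(path, frame = "NM", quantity = "cps")
  expect_equal(back$data, v$data, tolerance = 1e-6)
  expect_equal(back$spacing, v$spacing, tolerance = 1e-6)
})
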