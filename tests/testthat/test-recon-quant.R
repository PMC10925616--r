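test_that("TEW correction equals the per-pixel trapezoid oracle", {
  tew_oracle <- function(m, l, u) max(m - (l / 17.8 + u / 24) * 41.6 / 2, 0)
  set.seed(3)
  d <- c(8, 4, 6)
  main <- array(rpois(prod(d), 50), d)
  lower <- array(rpois(prod(d), 8), d)
  upper <- array(rpois(prod(d), 10), d)
  cs <- tew_correct(fake_projection_set(main, lower, upper))
  expected <- array(mapply(tew_oracle, main, lower, upper), d)
  expect_equal(cs$counts, expected, tolerance = 1e-12)
  # worked single-pixel case: C_lower = 17.8 and C_upper = 24 give 41.6
  one <- fake_projection_set(array(100, c(1, 1, 1)), array(17.8, c(1, 1, 1)),
                             array(24, c(1, 1, 1)))
  expect_equal(tew_correct(one)$scatter_estimate[1], 41.6, tolerance = 1e-12)
  expect_equal(tew_correct(one)$counts[1], 100 - 41.6, tolerance = 1e-12)
})

test_that("TEW leaves clean data alone and never goes negative", {
  d <- c(6, 3, 4)
  main <- array(runif(prod(d), 0, 20), d)
  zero <- array(0, d)
  cs <- tew_correct(fake_projection_set(main, zero, zero))
  expect_identical(cs$counts, main)
  # overwhelming scatter estimate clamps at zero
  huge <- fake_projection_set(array(1, d), array(1000, d), array(1000, d))
  expect_true(all(tew_correct(huge)$counts == 0))
  broken <- fake_projection_set(main, zero, zero)
  broken$windows$lower <- NULL
  expect_error(tew_correct(broken), class = "luquant_input_error")
})

test_that("MLEM concentrates a single hot voxel and conserves counts", {
  g <- tiny_grid()
  act <- nm_grid(c(16, 16, 8), quantity = "activity_MBq_per_voxel")
  act$data[9, 8, 4] <- 2
  cfg <- acquisition_config(n_angles = 16, duration_s = 10, psf_sigma_mm = 0,
                            scatter_fraction = 0, noise = FALSE)
  ps <- simulate_acquisition(act, uniform_mu(g), cfg)
  rec <- mlem_reconstruct(ps, uniform_mu(g), iterations = 10, subsets = 4)
  hood <- rec$data[8:10, 7:9, 3:5]
  expect_gt(sum(hood) / sum(rec$data), 0.95)
  # forward-projected reconstruction matches the measured data within 1%
  proj <- luquant:::make_projector(uniform_mu(g), cfg$angles_deg, 0)
  refit <- proj$forward(rec$data) * ps$duration_s
  expect_lt(abs(sum(refit) - sum(ps$windows$main)) / sum(ps$windows$main), 0.01)
})

test_that("MLEM maps zero data to a zero image and ignores duration rescaling", {
  g <- tiny_grid()
  zero_sino <- fake_projection_set(array(0, c(16, 8, 8)), array(0, c(16, 8, 8)),
                                   array(0, c(16, 8, 8)))
  zero_sino$vol_dim <- c(16, 16, 8)
  rec0 <- mlem_reconstruct(zero_sino, uniform_mu(g), iterations = 2,
                           subsets = 2, psf_sigma_mm = 0)
  expect_true(all(rec0$data == 0))
  # doubling the acquisition duration leaves the cps image unchanged
  hp <- small_hot_phantom()
  mk <- function(dur) {
    cfg <- acquisition_config(n_angles = 12, duration_s = dur, psf_sigma_mm = 4.25,
                              scatter_fraction = 0.2, noise = FALSE)
    mlem_reconstruct(tew_correct(simulate_acquisition(hp$phantom$activity,
                                                      hp$phantom$mu, cfg)),
                     hp$phantom$mu, iterations = 2, subsets = 4)
  }
  expect_equal(mk(60)$data, mk(30)$data, tolerance = 1e-8)
})

test_that("full-data MLEM has monotone non-increasing Poisson NLL", {
  hp <- small_hot_phantom(nm_grid(c(16, 16, 8)))
  cfg <- acquisition_config(n_angles = 8, duration_s = 30, psf_sigma_mm = 4.25,
                            scatter_fraction = 0, noise = FALSE)
  sino <- tew_correct(simulate_acquisition(hp$phantom$activity, hp$phantom$mu, cfg))
  nll <- vapply(1:4, function(k) {
    rec <- mlem_reconstruct(sino, hp$phantom$mu, iterations = k, subsets = 1)
    luquant:::mlem_nll(rec, sino, hp$phantom$mu)
  }, numeric(1))
  expect_true(all(diff(nll) <= 1e-8 * abs(nll[-length(nll)])))
})

test_that("calibration factor recovers the simulated sensitivity", {
  g <- nm_grid(c(24, 24, 12))
  cfg <- acquisition_config(n_angles = 24, duration_s = 60, psf_sigma_mm = 4.25,
                            scatter_fraction = 0.3, noise = FALSE)
  jas <- build_jaszczak(2, diameter_mm = 70, height_mm = 40, grid = g)
  rec <- mlem_reconstruct(tew_correct(simulate_acquisition(jas$activity, jas$mu, cfg)),
                          jas$mu, iterations = 5, subsets = 4)
  cf <- compute_cf(rec, dilate_mask(jas$mask, 10), mci_to_mbq(2))
  expect_lt(abs(cf$value_cps_per_MBq - cfg$sensitivity_cps_per_MBq) /
              cfg$sensitivity_cps_per_MBq, 0.05)
  # CF is intensive: doubling the phantom activity leaves it unchanged
  jas2 <- build_jaszczak(4, diameter_mm = 70, height_mm = 40, grid = g)
  rec2 <- mlem_reconstruct(tew_correct(simulate_acquisition(jas2$activity, jas2$mu, cfg)),
                           jas2$mu, iterations = 5, subsets = 4)
  cf2 <- compute_cf(rec2, dilate_mask(jas2$mask, 10), mci_to_mbq(4))
  expect_equal(cf2$value_cps_per_MBq, cf$value_cps_per_MBq, tolerance = 1e-6)
  expect_error(compute_cf(rec, jas$mask, 0), class = "luquant_domain_error")
})

test_that("count rates convert to the printed activities", {
  counts <- commissioning_sphere_counts()
  cf <- commissioning_cf()[["post_service"]]
  est <- activity_from_counts(counts$measured_cps, cf)
  expect_equal(round(est, 2), c(1.33, 0.58, 0.27))
  expect_identical(activity_from_counts(0, cf), 0)
  expect_error(activity_from_counts(-1, cf), class = "luquant_domain_error")
  expect_error(activity_from_counts(10, 0), class = "luquant_domain_error")
})

test_that("sphere recovery on a perfect unblurred image is exact to ~2%", {
  g <- nm_grid(c(48, 48, 24))
  spheres <- default_nema_spheres()
  ph <- build_nema(nema_phantom_spec(spheres = spheres), g)
  S <- 5
  perfect <- volume_image(ph$activity$data * S, g$spacing, g$origin,
                          frame = "NM", quantity = "cps")
  contours <- sphere_masks(spheres, ct_grid(c(160, 160, 24)))
  rec <- sphere_recovery(perfect, contours, S, injected = spheres, margin_mm = 0)
  expect_lt(max(abs(rec$pct_diff)), 2)
  # empty contour list gives an empty report
  empty <- sphere_recovery(perfect, list(), S, injected = spheres[0, ])
  expect_identical(nrow(empty), 0L)
})

test_that("overlapping dilated VOIs are rejected by name", {
  g <- nm_grid(c(48, 48, 24))
  spheres <- dplyr::bind_rows(
    sphere_spec(22, c(18, 0, 0), 0.1),
    sphere_spec(22, c(-18, 0, 0), 0.1)
  )
  ph <- build_nema(nema_phantom_spec(spheres = spheres), g)
  perfect <- volume_image(ph$activity$data, g$spacing, g$origin,
                          frame = "NM", quantity = "cps")
  contours <- sphere_masks(spheres, ct_grid(c(120, 120, 24)))
  names(contours) <- c("sphere_A", "sphere_B")
  expect_error(
    sphere_recovery(perfect, contours, 5, injected = spheres, margin_mm = 10),
    regexp = "sphere_A.*sphere_B",
    class = "luquant_geometry_error"
  )
})

test_that("the estimated activities scale linearly with the injected ones", {
  hp <- small_hot_phantom()
  cfg <- acquisition_config(n_angles = 12, duration_s = 30, psf_sigma_mm = 4.25,
                            scatter_fraction = 0.2, noise = FALSE)
  run <- function(scale) {
    spec <- hp$spec
    spec$spheres$activity_mCi <- spec$spheres$activity_mCi * scale
    ph <- build_nema(spec, hp$grid)
    rec <- mlem_reconstruct(tew_correct(simulate_acquisition(ph$activity, ph$mu, cfg)),
                            ph$mu, iterations = 3, subsets = 4)
    contours <- sphere_masks(spec$spheres, ct_grid(c(96, 96, 16)))
    sphere_recovery(rec, contours, 5, injected = spec$spheres, margin_mm = 6)
  }
  r1 <- run(1)
  r2 <- run(2)
  expect_equal(r2$estimated_mCi, 2 * r1$estimated_mCi, tolerance = 0.01)
})
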