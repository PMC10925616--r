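test_that("identical NM and CT point images report zero offset and pass", {
  g <- nm_grid(c(24, 24, 16))
  vols <- lapply(1:3, function(i) build_point_sources(rbind(c(5 * i - 10, 3, 0)), 1, g))
  rep <- estimate_offsets(vols, vols)
  expect_equal(rep$summary$mean_mm, rep(0, 3), tolerance = 1e-12)
  expect_equal(rep$summary$sd_mm, rep(0, 3), tolerance = 1e-12)
  expect_true(rep$overall_pass)
})

test_that("imposed offsets are recovered within 0.3 mm and gated correctly", {
  # pre-service-style misalignment: X beyond the 2.2-mm limit
  pre <- simulate_registration_pair(rigid_offset(3.0, 0.9, 1.2), n_sources = 5,
                                    noise = TRUE, seed = 21)
  rep_pre <- estimate_offsets(pre$nm, pre$ct)
  expect_lt(max(abs(rep_pre$summary$mean_mm - c(3.0, 0.9, 1.2))), 0.3)
  expect_false(rep_pre$summary$pass[rep_pre$summary$axis == "x"])
  expect_true(all(rep_pre$summary$pass[rep_pre$summary$axis != "x"]))
  expect_false(rep_pre$overall_pass)
  # post-service-style alignment: all axes inside the limit
  post <- simulate_registration_pair(rigid_offset(0.8, 0.6, 0.9), n_sources = 5,
                                     noise = TRUE, seed = 22)
  rep_post <- estimate_offsets(post$nm, post$ct)
  expect_true(rep_post$overall_pass)
})

test_that("correction shifts cancel the estimated offsets", {
  # noise off: residuals are interpolation-limited
  clean <- simulate_registration_pair(rigid_offset(2.7, -1.4, 3.9), n_sources = 4,
                                      noise = FALSE, seed = 5)
  rep <- estimate_offsets(clean$nm, clean$ct)
  res <- correct_and_verify(clean$nm, clean$ct, rep)
  expect_lt(max(abs(res$residual_mm)), 0.1)
  # noisy, random shifts up to 5 mm: residuals under 1 mm
  set.seed(31)
  ov <- runif(3, 0, 5)
  noisy <- simulate_registration_pair(rigid_offset(ov[1], ov[2], ov[3]),
                                      n_sources = 5, noise = TRUE, seed = 32)
  rep_n <- estimate_offsets(noisy$nm, noisy$ct)
  res_n <- correct_and_verify(noisy$nm, noisy$ct, rep_n)
  expect_lt(max(abs(res_n$residual_mm)), 1)
  # a zero correction leaves the original means in place
  rep0 <- rep_n
  rep0$correction <- rigid_offset(0, 0, 0)
  res0 <- correct_and_verify(noisy$nm, noisy$ct, rep0)
  expect_equal(res0$residual_mm, rep_n$summary$mean_mm, tolerance = 1e-9)
})

test_that("offset estimation is equivariant under a common NM shift", {
  pairs <- simulate_registration_pair(rigid_offset(1, 0.5, -0.5), n_sources = 3,
                                      noise = FALSE, seed = 8)
  base <- estimate_offsets(pairs$nm, pairs$ct)
  delta <- rigid_offset(1.7, -0.9, 1.1)
  shifted_nm <- lapply(pairs$nm, apply_offset, offset = delta)
  shifted <- estimate_offsets(shifted_nm, pairs$ct)
  expect_lt(max(abs(shifted$summary$mean_mm - base$summary$mean_mm -
                      c(1.7, -0.9, 1.1))), 0.05)
})

test_that("enlarging the tolerance never flips a pass to a fail", {
  pairs <- simulate_registration_pair(rigid_offset(2.0, 1.0, 2.5), n_sources = 4,
                                      noise = TRUE, seed = 13)
  tols <- c(0.5, 1, 2.2, 3, 5)
  passes <- lapply(tols, function(tl) {
    estimate_offsets(pairs$nm, pairs$ct, tolerance_mm = tl)$summary$pass
  })
  for (k in seq_along(tols)[-1]) {
    expect_true(all(passes[[k]] >= passes[[k - 1]]))
  }
})

test_that("mismatched or multi-modal inputs are rejected", {
  g <- nm_grid(c(24, 24, 16))
  a <- build_point_sources(rbind(c(0, 0, 0)), 1, g)
  expect_error(estimate_offsets(list(a), list(a, a)), class = "luquant_input_error")
  two_blobs <- build_point_sources(rbind(c(-40, -40, -20), c(40, 40, 20)), 1,
                                   nm_grid(c(32, 32, 24)))
  expect_error(estimate_offsets(list(two_blobs), list(two_blobs)),
               class = "luquant_input_error")
})

test_that("the COR sinusoid fit recovers known rotation-centre offsets", {
  c0 <- cor_analysis(simulate_cor_sinogram(cor_offset_mm = 0))
  expect_lt(abs(c0$cor_offset_mm), 0.05)
  c15 <- cor_analysis(simulate_cor_sinogram(radius_mm = 40, phase_deg = 30,
                                            cor_offset_mm = 1.5))
  expect_lt(abs(c15$cor_offset_mm - 1.5), 0.1)
  expect_lt(abs(c15$amplitude_mm - 40), 0.1)
  # sub-0.1-mm offsets remain resolvable in the report
  c_tiny <- cor_analysis(simulate_cor_sinogram(cor_offset_mm = 0.05))
  expect_lt(abs(c_tiny$cor_offset_mm - 0.05), 0.02)
  expect_error(cor_analysis(simulate_cor_sinogram(n_angles = 6)),
               class = "luquant_input_error")
})

test_that("the linear sinusoid fit agrees with a grid-search oracle", {
  sg <- simulate_cor_sinogram(radius_mm = 30, phase_deg = 72, cor_offset_mm = 1.2,
                              n_angles = 24)
  fit <- cor_analysis(sg)
  th <- sg$angles_deg * pi / 180
  trace <- fit$trace$centroid_mm
  grid_r <- seq(28, 32, by = 0.25)
  grid_phi <- seq(60, 84, by = 1) * pi / 180
  grid_c <- seq(0, 2.5, by = 0.1)
  best <- c(Inf, NA, NA, NA)
  for (r in grid_r) for (phi in grid_phi) for (cc in grid_c) {
    sse <- sum((trace - (r * cos(th - phi) + cc))^2)
    if (sse < best[1]) best <- c(sse, r, phi, cc)
  }
  expect_lt(abs(fit$amplitude_mm - best[2]), 0.25)
  expect_lt(abs(fit$phase_deg - best[3] * 180 / pi), 1)
  expect_lt(abs(fit$cor_offset_mm - best[4]), 0.1)
})

test_that("an acquired point-source sinogram feeds the COR analysis", {
  g <- nm_grid(c(32, 32, 8))
  act <- build_point_sources(rbind(c(30, 10, 0)), 5, g)
  cfg <- acquisition_config(n_angles = 16, duration_s = 30, psf_sigma_mm = 4.25,
                            scatter_fraction = 0, noise = FALSE)
  ps <- simulate_acquisition(act, uniform_mu(g), cfg)
  fit <- cor_analysis(ps)
  # an aligned system has no constant offset; the orbit radius is recovered
  expect_lt(abs(fit$cor_offset_mm), 0.1)
  expect_equal(fit$amplitude_mm, sqrt(30^2 + 10^2), tolerance = 0.05)
})
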