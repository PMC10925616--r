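# Shared desk-scale fixtures; everything is generated in code.

tiny_grid <- function(dim = c(16, 16, 8)) nm_grid(dim)

uniform_mu <- function(grid, value = 0) {
  volume_image(array(value, dim(grid$data)), grid$spacing, grid$origin,
               frame = grid$frame, quantity = "mu_per_mm")
}

quiet_cfg <- function(...) {
  acquisition_config(n_angles = 8, duration_s = 10, psf_sigma_mm = 0,
                     scatter_fraction = 0, noise = FALSE, ...)
}

# hand-built projection set for exercising TEW independently of the simulator
fake_projection_set <- function(main, lower, upper, duration_s = 10) {
  d <- dim(main)
  structure(
    list(
      windows = list(main = main, lower = lower, upper = upper),
      angles_deg = seq(0, 360, length.out = d[3] + 1)[seq_len(d[3])],
      duration_s = duration_s,
      det_spacing = c(4.42, 4.42, 4.42),
      vol_dim = c(d[1], d[1], d[2]),
      window_table = lu177_windows(),
      config = NULL,
      offset = rigid_offset()
    ),
    class = "projection_set"
  )
}

# single small hot sphere in a compact water body, for recon closed loops
small_hot_phantom <- function(grid = nm_grid(c(24, 24, 12))) {
  spec <- nema_phantom_spec(
    body = list(a_mm = 45, b_mm = 40, height_mm = 50, center_mm = c(0, 0, 0)),
    spheres = sphere_spec(20, c(10, 5, 0), 0.05)
  )
  list(spec = spec, phantom = build_nema(spec, grid = grid), grid = grid)
}

# reduced-size end-to-end configuration (two small spheres, short scan)
small_e2e_config <- function(seed = 1L) {
  spheres <- dplyr::bind_rows(
    sphere_spec(20, c(15, 0, 0), 0.10),
    sphere_spec(16, c(-15, 0, 0), 0.05)
  )
  e2e_config(
    seed = seed,
    nm_dim = c(24, 24, 16),
    phantom = nema_phantom_spec(
      body = list(a_mm = 42, b_mm = 38, height_mm = 55, center_mm = c(0, 0, 0)),
      spheres = spheres
    ),
    jaszczak_mCi = 2,
    jaszczak_dims = list(diameter_mm = 70, height_mm = 50),
    acquisition = list(n_angles = 12, duration_s = 30),
    recon = list(iterations = 3, subsets = 4),
    margin_mm = 4,
    registration = list(n_sources = 3, max_shift_mm = 5, offset = NULL,
                        noise = TRUE, counts = 2e4)
  )
}
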