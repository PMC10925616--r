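#' Sphere and phantom specifications
#'
#' `sphere_spec()` describes one fillable sphere; `default_nema_spheres()`
#' returns the three spheres used for the quantification end-to-end test
#' (22/28/37 mm diameter filled with 0.13/0.27/0.63 mCi). Sphere centres are
#' not a measured quantity; the defaults place the three spheres 120 degrees
#' apart on a 55-mm radius circle in the central transaxial plane, following
#' the usual NEMA arrangement, and are configurable.
#'
#' @param diameter_mm Sphere diameter in mm (> 0).
#' @param center_mm Length-3 world position of the sphere centre (mm).
#' @param activity_mCi Filled activity in mCi (>= 0).
#' @return `sphere_spec()`: a one-row tibble; `default_nema_spheres()`: a
#'   three-row tibble with columns `diameter_mm`, `cx`, `cy`, `cz`,
#'   `activity_mCi`.
#' @export
#' @examples
#' default_nema_spheres()
sphere_spec <- function(diameter_mm, center_mm, activity_mCi) {
  if (diameter_mm <= 0) abort("Sphere diameter must be positive.", class = "luquant_geometry_error")
  if (activity_mCi < 0) abort("Sphere activity must be nonnegative.", class = "luquant_domain_error")
  tibble::tibble(
    diameter_mm = diameter_mm,
    cx = center_mm[1], cy = center_mm[2], cz = center_mm[3],
    activity_mCi = activity_mCi
  )
}

#' @rdname sphere_spec
#' @export
default_nema_spheres <- function() {
  r <- 55
  ang <- c(0, 120, 240) * pi / 180
  dplyr::bind_rows(
    sphere_spec(37, c(r * cos(ang[1]), r * sin(ang[1]), 0), 0.63),
    sphere_spec(28, c(r * cos(ang[2]), r * sin(ang[2]), 0), 0.27),
    sphere_spec(22, c(r * cos(ang[3]), r * sin(ang[3]), 0), 0.13)
  )
}

#' @rdname sphere_spec
#' @param body List describing the water-filled body: an elliptical cylinder
#'   with transaxial semi-axes `a_mm`, `b_mm`, height `height_mm`, centred at
#'   `center_mm`. (The exact IEC body contour is not modelled; nothing
#'   downstream uses its precise shape quantitatively.)
#' @param background_MBq_per_ml Background activity concentration (the
#'   commissioning phantom body was filled without radioactivity, so 0).
#' @param mu_water_per_mm Linear attenuation coefficient of water at the
#'   208-keV photopeak, in 1/mm. Default 0.0137/mm from standard attenuation
#'   tables; configurable.
#' @param spheres Tibble of spheres as from [default_nema_spheres()].
#' @export
nema_phantom_spec <- function(body = list(a_mm = 110, b_mm = 85,
                                          height_mm = 180,
                                          center_mm = c(0, 0, 0)),
                              background_MBq_per_ml = 0,
                              mu_water_per_mm = 0.0137,
                              spheres = default_nema_spheres()) {
  if (background_MBq_per_ml < 0) {
    abort("Background concentration must be nonnegative.", class = "luquant_domain_error")
  }
  structure(
    list(body = body, background_MBq_per_ml = background_MBq_per_ml,
         mu_water_per_mm = mu_water_per_mm, spheres = tibble::as_tibble(spheres)),
    class = "phantom_spec"
  )
}

# voxel coordinate arrays for a grid (full 3-D, memory ~3 x grid size)
grid_coords <- function(grid) {
  d <- dim(grid$data)
  list(
    x = array(rep(axis_coords(grid, 1), times = d[2] * d[3]), d),
    y = array(rep(rep(axis_coords(grid, 2), each = d[1]), times = d[3]), d),
    z = array(rep(axis_coords(grid, 3), each = d[1] * d[2]), d),
    d = d
  )
}

# per-voxel volume fraction covered by a sphere, with n^3 subsampling of
# boundary voxels only
sphere_fractions <- function(grid, center, radius, nsub = 3) {
  co <- grid_coords(grid)
  half_diag <- sqrt(sum((grid$spacing / 2)^2))
  dist <- sqrt((co$x - center[1])^2 + (co$y - center[2])^2 + (co$z - center[3])^2)
  frac <- array(0, co$d)
  frac[dist <= radius - half_diag] <- 1
  boundary <- which(dist > radius - half_diag & dist < radius + half_diag)
  if (length(boundary)) {
    offs <- expand.grid(
      dx = (seq_len(nsub) - (nsub + 1) / 2) / nsub * grid$spacing[1],
      dy = (seq_len(nsub) - (nsub + 1) / 2) / nsub * grid$spacing[2],
      dz = (seq_len(nsub) - (nsub + 1) / 2) / nsub * grid$spacing[3]
    )
    acc <- numeric(length(boundary))
    bx <- co$x[boundary]; by <- co$y[boundary]; bz <- co$z[boundary]
    for (o in seq_len(nrow(offs))) {
      acc <- acc + ((bx + offs$dx[o] - center[1])^2 +
                    (by + offs$dy[o] - center[2])^2 +
                    (bz + offs$dz[o] - center[3])^2 <= radius^2)
    }
    frac[boundary] <- acc / nrow(offs)
  }
  frac
}

# elliptical-cylinder membership (voxel-centre test) for the phantom body
body_mask <- function(grid, body) {
  co <- grid_coords(grid)
  inside <- ((co$x - body$center_mm[1]) / body$a_mm)^2 +
    ((co$y - body$center_mm[2]) / body$b_mm)^2 <= 1
  inside & abs(co$z - body$center_mm[3]) <= body$height_mm / 2
}

check_sphere_in_body <- function(sp, body) {
  r <- sp$diameter_mm / 2
  a <- body$a_mm - r; b <- body$b_mm - r
  dx <- sp$cx - body$center_mm[1]; dy <- sp$cy - body$center_mm[2]
  inside_xy <- a > 0 && b > 0 && (dx / a)^2 + (dy / b)^2 <= 1
  inside_z <- abs(sp$cz - body$center_mm[3]) + r <= body$height_mm / 2
  if (!(inside_xy && inside_z)) {
    abort(sprintf("Sphere (%.0f mm at %.1f, %.1f, %.1f) lies outside the phantom body.",
                  sp$diameter_mm, sp$cx, sp$cy, sp$cz),
          class = "luquant_geometry_error")
  }
  invisible(TRUE)
}

#' Voxelise a NEMA-style hot-sphere phantom
#'
#' Builds the activity map (MBq per voxel) and the water attenuation map
#' (1/mm) of a body phantom with hot spheres on a given grid. Sphere
#' boundaries are handled by partial-voxel weighting (boundary voxels
#' subsampled `nsub^3`), so each sphere's voxel sum matches its nominal
#' activity to within voxelisation error.
#'
#' @param spec A [nema_phantom_spec()].
#' @param grid A [volume_image()] template (e.g. [nm_grid()] or [ct_grid()]).
#' @param nsub Boundary-subsampling factor per axis.
#' @return A list with `activity` and `mu` [volume_image()]s plus the `spec`.
#' @export
#' @examples
#' ph <- build_nema(grid = nm_grid(c(48, 48, 32)))
#' sum(ph$activity$data) / mci_to_mbq(1.03) # close to 1
build_nema <- function(spec = nema_phantom_spec(), grid = nm_grid(), nsub = 3) {
  stopifnot(inherits(spec, "phantom_spec"))
  act <- array(0, dim(grid$data))
  voxvol_mm3 <- prod(grid$spacing)
  for (i in seq_len(nrow(spec$spheres))) {
    sp <- spec$spheres[i, ]
    check_sphere_in_body(sp, spec$body)
    if (sp$activity_mCi == 0) next
    r <- sp$diameter_mm / 2
    conc <- mci_to_mbq(sp$activity_mCi) / (4 / 3 * pi * r^3) # MBq per mm^3
    frac <- sphere_fractions(grid, c(sp$cx, sp$cy, sp$cz), r, nsub = nsub)
    act <- act + conc * voxvol_mm3 * frac
  }
  body <- body_mask(grid, spec$body)
  if (spec$background_MBq_per_ml > 0) {
    act <- act + body * spec$background_MBq_per_ml * voxvol_mm3 / 1000
  }
  mu <- array(0, dim(grid$data))
  mu[body] <- spec$mu_water_per_mm
  list(
    activity = volume_image(act, grid$spacing, grid$origin, frame = grid$frame,
                            quantity = "activity_MBq_per_voxel"),
    mu = volume_image(mu, grid$spacing, grid$origin, frame = grid$frame,
                      quantity = "mu_per_mm"),
    spec = spec
  )
}

#' Voxelise a uniform-cylinder (Jaszczak-style) calibration phantom
#'
#' A water-filled circular cylinder holding a uniformly mixed activity, used
#' to calibrate the system volume sensitivity. The default fill of 18 mCi sits
#' in the 15--20 mCi range used for Lu-177 calibration scans.
#'
#' @param total_activity_mCi Total activity in the cylinder.
#' @param diameter_mm,height_mm Interior dimensions (default 216 x 186 mm,
#'   standard Jaszczak interior).
#' @param center_mm Cylinder centre in world mm.
#' @param mu_water_per_mm Water attenuation at the photopeak, 1/mm.
#' @param grid Grid template.
#' @param nsub Boundary-subsampling factor.
#' @return A list with `activity` and `mu` [volume_image()]s,
#'   `concentration_MBq_per_ml`, `volume_ml`, and the cylinder mask.
#' @export
#' @examples
#' j <- build_jaszczak(18, grid = nm_grid(c(48, 48, 32)))
#' j$concentration_MBq_per_ml * j$volume_ml / mci_to_mbq(18) # exactly 1
build_jaszczak <- function(total_activity_mCi = 18, diameter_mm = 216,
                           height_mm = 186, center_mm = c(0, 0, 0),
                           mu_water_per_mm = 0.0137,
                           grid = nm_grid(), nsub = 3) {
  if (diameter_mm <= 0 || height_mm <= 0) {
    abort("Cylinder dimensions must be positive.", class = "luquant_geometry_error")
  }
  if (total_activity_mCi < 0) {
    abort("Total activity must be nonnegative.", class = "luquant_domain_error")
  }
  r <- diameter_mm / 2
  volume_ml <- pi * r^2 * height_mm / 1000
  conc <- mci_to_mbq(total_activity_mCi) / volume_ml # MBq/mL
  co <- grid_coords(grid)
  half_diag_xy <- sqrt(sum((grid$spacing[1:2] / 2)^2))
  rad <- sqrt((co$x - center_mm[1])^2 + (co$y - center_mm[2])^2)
  # analytic partial-volume weight of each slice against the slab ends
  dz <- grid$spacing[3]
  zrel <- co$z - center_mm[3]
  frac_z <- pmin(zrel + dz / 2, height_mm / 2) - pmax(zrel - dz / 2, -height_mm / 2)
  frac_z <- pmin(pmax(frac_z / dz, 0), 1)
  frac <- array(0, co$d)
  frac[rad <= r - half_diag_xy] <- 1
  boundary <- which(rad > r - half_diag_xy & rad < r + half_diag_xy & frac_z > 0)
  if (length(boundary)) {
    offs <- expand.grid(
      dx = (seq_len(nsub) - (nsub + 1) / 2) / nsub * grid$spacing[1],
      dy = (seq_len(nsub) - (nsub + 1) / 2) / nsub * grid$spacing[2]
    )
    acc <- numeric(length(boundary))
    bx <- co$x[boundary]; by <- co$y[boundary]
    for (o in seq_len(nrow(offs))) {
      acc <- acc + ((bx + offs$dx[o] - center_mm[1])^2 +
                    (by + offs$dy[o] - center_mm[2])^2 <= r^2)
    }
    frac[boundary] <- acc / nrow(offs)
  }
  frac <- frac * frac_z
  voxvol_ml <- prod(grid$spacing) / 1000
  act <- conc * voxvol_ml * frac
  mu <- mu_water_per_mm * (frac > 0.5)
  list(
    activity = volume_image(act, grid$spacing, grid$origin, frame = grid$frame,
                            quantity = "activity_MBq_per_voxel"),
    mu = volume_image(mu * 1, grid$spacing, grid$origin, frame = grid$frame,
                      quantity = "mu_per_mm"),
    mask = volume_image((frac > 0.5) * 1, grid$spacing, grid$origin,
                        frame = grid$frame, quantity = "mask"),
    concentration_MBq_per_ml = conc,
    volume_ml = volume_ml,
    total_activity_mCi = total_activity_mCi
  )
}

#' Deposit point sources with sub-voxel accuracy
#'
#' Each source is spread over its 8 neighbouring voxels with trilinear
#' weights, so the intensity-weighted centroid of an isolated source equals
#' the requested position to well under 0.05 mm. Used for alignment-QA jigs.
#'
#' @param positions Matrix (n x 3) or list of length-3 world positions (mm).
#' @param strength_MBq Activity per source.
#' @param grid Grid template.
#' @return A [volume_image()] activity map.
#' @export
#' @examples
#' v <- build_point_sources(rbind(c(0, 0, 0)), 10, nm_grid(c(16, 16, 8)))
#' centroid_mm(v)
build_point_sources <- function(positions, strength_MBq = 1, grid = nm_grid()) {
  if (is.list(positions) && !is.matrix(positions)) {
    positions <- do.call(rbind, positions)
  }
  positions <- matrix(positions, ncol = 3)
  if (nrow(positions) < 1) abort("At least one position is required.", class = "luquant_input_error")
  d <- dim(grid$data)
  idx <- world_to_index(grid, positions)
  if (any(idx < 1) || any(sweep(idx, 2, d, ">"))) {
    abort("Point-source position outside the grid.", class = "luquant_geometry_error")
  }
  out <- array(0, d)
  for (s in seq_len(nrow(positions))) {
    i0 <- pmin(pmax(floor(idx[s, ]), 1), d - 1)
    f <- idx[s, ] - i0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- (if (dx) f[1] else 1 - f[1]) * (if (dy) f[2] else 1 - f[2]) *
        (if (dz) f[3] else 1 - f[3])
      out[i0[1] + dx, i0[2] + dy, i0[3] + dz] <-
        out[i0[1] + dx, i0[2] + dy, i0[3] + dz] + strength_MBq * w
    }
  }
  volume_image(out, grid$spacing, grid$origin, frame = grid$frame,
               quantity = "activity_MBq_per_voxel")
}

#' Sphere contour masks on a grid
#'
#' Voxelised sphere contours (voxel-centre membership), the digital analogue
#' of outlining the visible spheres on the CT series.
#'
#' @param spheres Tibble as from [default_nema_spheres()].
#' @param grid Grid template (typically [ct_grid()]).
#' @return A named list of mask [volume_image()]s, names `"sphere_<d>mm"`.
#' @export
sphere_masks <- function(spheres = default_nema_spheres(), grid = ct_grid()) {
  co <- grid_coords(grid)
  out <- list()
  for (i in seq_len(nrow(spheres))) {
    sp <- spheres[i, ]
    m <- (co$x - sp$cx)^2 + (co$y - sp$cy)^2 + (co$z - sp$cz)^2 <=
      (sp$diameter_mm / 2)^2
    out[[i]] <- volume_image(m * 1, grid$spacing, grid$origin,
                             frame = grid$frame, quantity = "mask")
  }
  names(out) <- make.unique(sprintf("sphere_%.0fmm", spheres$diameter_mm))
  out
}
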