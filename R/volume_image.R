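#' Volumetric scalar images
#'
#' The package's 3-D container: a numeric array with voxel spacing (mm),
#' world origin (mm, position of the centre of voxel `[1,1,1]`), the frame it
#' lives in (`"NM"` for the 4.42-mm isotropic emission grid, `"CT"` for the
#' fine anatomical grid), and the physical quantity each voxel holds.
#'
#' By default the origin centres the grid on the world origin, so NM and CT
#' grids covering the same field of view are spatially aligned.
#'
#' @param data Numeric (or logical, for masks) 3-D array.
#' @param spacing Length-3 positive voxel spacing in mm.
#' @param origin Length-3 world position (mm) of the first voxel centre;
#'   default centres the grid.
#' @param frame `"NM"` or `"CT"`.
#' @param quantity One of `"activity_MBq_per_voxel"`, `"mu_per_mm"`,
#'   `"counts"`, `"cps"`, `"dose_Gy"`, `"MBq_s_per_voxel"`, `"mask"`,
#'   `"arbitrary"`.
#' @return A `volume_image` object.
#' @export
#' @examples
#' v <- volume_image(array(0, c(8, 8, 4)), spacing = c(4.42, 4.42, 4.42))
#' voxel_volume_ml(v)
volume_image <- function(data, spacing,
                         origin = -(dim(data) - 1) / 2 * spacing,
                         frame = c("NM", "CT"),
                         quantity = "arbitrary") {
  frame <- match.arg(frame)
  quantity <- match.arg(quantity, c(
    "activity_MBq_per_voxel", "mu_per_mm", "counts", "cps", "dose_Gy",
    "MBq_s_per_voxel", "mask", "arbitrary"
  ))
  if (length(dim(data)) != 3) abort("`data` must be a 3-D array.", class = "luquant_input_error")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(spacing <= 0)) {
    abort("`spacing` must be 3 positive numbers (mm).", class = "luquant_domain_error")
  }
  if (quantity %in% c("activity_MBq_per_voxel", "counts", "cps", "dose_Gy",
                      "MBq_s_per_voxel") && any(data < 0)) {
    abort(paste0(quantity, " values must be nonnegative."), class = "luquant_domain_error")
  }
  structure(
    list(data = data, spacing = spacing, origin = as.numeric(origin),
         frame = frame, quantity = quantity),
    class = "volume_image"
  )
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<volume_image> %dx%dx%d %s [%s], spacing %.2fx%.2fx%.2f mm, sum %.4g\n",
    d[1], d[2], d[3], x$quantity, x$frame,
    x$spacing[1], x$spacing[2], x$spacing[3], sum(x$data)
  ))
  invisible(x)
}

#' @rdname volume_image
#' @export
voxel_volume_ml <- function(data) {
  stopifnot(inherits(data, "volume_image"))
  prod(data$spacing) / 1000
}

#' Standard NM and CT grid templates
#'
#' Zero-filled [volume_image()] templates on the two acquisition grids: the
#' emission grid at 4.42 mm isotropic and the anatomical grid at
#' 0.98 x 0.98 x 3.75 mm, both centred on the world origin so they cover the
#' same field of view.
#'
#' @param dim Integer grid dimensions.
#' @param spacing Voxel spacing in mm.
#' @param quantity Passed to [volume_image()].
#' @return A zero [volume_image()].
#' @export
#' @examples
#' nm_grid(c(32, 32, 16))
nm_grid <- function(dim = c(64, 64, 48), spacing = c(4.42, 4.42, 4.42),
                    quantity = "arbitrary") {
  volume_image(array(0, dim), spacing, frame = "NM", quantity = quantity)
}

#' @rdname nm_grid
#' @export
ct_grid <- function(dim = c(288, 288, 56), spacing = c(0.98, 0.98, 3.75),
                    quantity = "arbitrary") {
  volume_image(array(0, dim), spacing, frame = "CT", quantity = quantity)
}

# world coordinates of voxel centres along one axis
axis_coords <- function(vol, axis) {
  (seq_len(dim(vol$data)[axis]) - 1) * vol$spacing[axis] + vol$origin[axis]
}

#' Intensity-weighted centroid in world coordinates
#'
#' @param vol A [volume_image()] with nonnegative intensities and positive sum.
#' @return Length-3 numeric, mm.
#' @export
centroid_mm <- function(vol) {
  stopifnot(inherits(vol, "volume_image"))
  tot <- sum(vol$data)
  if (tot <= 0) abort("Centroid of an all-zero image is undefined.", class = "luquant_domain_error")
  m_x <- apply(vol$data, 1, sum)
  m_y <- apply(vol$data, 2, sum)
  m_z <- apply(vol$data, 3, sum)
  c(sum(m_x * axis_coords(vol, 1)),
    sum(m_y * axis_coords(vol, 2)),
    sum(m_z * axis_coords(vol, 3))) / tot
}

# fractional 1-based voxel indices of world points in `vol`
world_to_index <- function(vol, pts) {
  sweep(sweep(pts, 2, vol$origin, "-"), 2, vol$spacing, "/") + 1
}

# trilinear interpolation of a 3-D array at fractional 1-based indices,
# zero outside the grid
interp_trilinear <- function(arr, ix, iy, iz) {
  d <- dim(arr)
  x0 <- floor(ix); y0 <- floor(iy); z0 <- floor(iz)
  fx <- ix - x0; fy <- iy - y0; fz <- iz - z0
  out <- numeric(length(ix))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) * (if (dz) fz else 1 - fz)
    xs <- x0 + dx; ys <- y0 + dy; zs <- z0 + dz
    ok <- which(w > 0 & xs >= 1 & xs <= d[1] & ys >= 1 & ys <= d[2] & zs >= 1 & zs <= d[3])
    if (length(ok)) {
      lin <- xs[ok] + (ys[ok] - 1) * d[1] + (zs[ok] - 1) * d[1] * d[2]
      out[ok] <- out[ok] + w[ok] * arr[lin]
    }
  }
  out
}

# nearest-neighbour lookup, zero outside
interp_nearest <- function(arr, ix, iy, iz) {
  d <- dim(arr)
  xs <- round(ix); ys <- round(iy); zs <- round(iz)
  out <- numeric(length(ix))
  ok <- which(xs >= 1 & xs <= d[1] & ys >= 1 & ys <= d[2] & zs >= 1 & zs <= d[3])
  if (length(ok)) {
    lin <- xs[ok] + (ys[ok] - 1) * d[1] + (zs[ok] - 1) * d[1] * d[2]
    out[ok] <- arr[lin]
  }
  out
}

#' Resample a volume onto another grid
#'
#' Continuous quantities use trilinear interpolation. Per-voxel amounts
#' (activity, counts) use volume-weighted averaging of the corresponding
#' density, which preserves totals when downsampling. Masks are resampled by
#' supersampled volume-fraction thresholding at 0.5 (a metric analogue of
#' nearest-neighbour that is unbiased for volumes).
#'
#' @param vol Source [volume_image()].
#' @param target Target grid ([volume_image()] template; its data are ignored).
#' @param method `"auto"` (from `vol$quantity`), `"trilinear"`, `"nearest"`,
#'   `"average"` (density-preserving, for per-voxel amounts), or `"mask"`.
#' @param mask_threshold Volume fraction above which a target voxel joins a
#'   resampled mask. 0.5 (default) is volume-unbiased; a small value yields a
#'   covering mask that includes every voxel the contour touches.
#' @return A [volume_image()] on the target grid with `vol`'s quantity and
#'   the target's spacing/frame.
#' @export
resample <- function(vol, target, method = c("auto", "trilinear", "nearest",
                                             "average", "mask"),
                     mask_threshold = 0.5) {
  stopifnot(inherits(vol, "volume_image"), inherits(target, "volume_image"))
  method <- match.arg(method)
  if (method == "auto") {
    method <- switch(vol$quantity,
      activity_MBq_per_voxel = , counts = , cps = , MBq_s_per_voxel = "average",
      mask = "mask",
      "trilinear"
    )
  }
  # overlap check on world extents
  for (a in 1:3) {
    s_lo <- vol$origin[a] - vol$spacing[a] / 2
    s_hi <- s_lo + dim(vol$data)[a] * vol$spacing[a]
    t_lo <- target$origin[a] - target$spacing[a] / 2
    t_hi <- t_lo + dim(target$data)[a] * target$spacing[a]
    if (t_hi <= s_lo || t_lo >= s_hi) {
      abort("Source and target fields of view do not overlap.",
            class = "luquant_geometry_error")
    }
  }
  td <- dim(target$data)
  cx <- axis_coords(target, 1); cy <- axis_coords(target, 2); cz <- axis_coords(target, 3)
  out <- array(0, td)

  if (method %in% c("trilinear", "nearest")) {
    pts <- cbind(
      rep(cx, times = td[2] * td[3]),
      rep(rep(cy, each = td[1]), times = td[3]),
      rep(cz, each = td[1] * td[2])
    )
    idx <- world_to_index(vol, pts)
    vals <- if (method == "trilinear") {
      interp_trilinear(vol$data, idx[, 1], idx[, 2], idx[, 3])
    } else {
      interp_nearest(vol$data, idx[, 1], idx[, 2], idx[, 3])
    }
    out[] <- vals
  } else {
    # supersample each target voxel; per-axis subdivisions follow the spacing ratio
    k <- pmax(1L, ceiling(target$spacing / vol$spacing))
    offs <- expand.grid(
      x = (seq_len(k[1]) - (k[1] + 1) / 2) / k[1] * target$spacing[1],
      y = (seq_len(k[2]) - (k[2] + 1) / 2) / k[2] * target$spacing[2],
      z = (seq_len(k[3]) - (k[3] + 1) / 2) / k[3] * target$spacing[3]
    )
    src <- if (method == "mask") {
      (vol$data != 0) * 1
    } else {
      vol$data / prod(vol$spacing) # density per mm^3
    }
    slab <- matrix(0, td[1] * td[2], td[3])
    base_xy <- cbind(rep(cx, times = td[2]), rep(cy, each = td[1]))
    for (zi in seq_len(td[3])) {
      acc <- numeric(td[1] * td[2])
      for (o in seq_len(nrow(offs))) {
        pts <- cbind(base_xy[, 1] + offs$x[o], base_xy[, 2] + offs$y[o],
                     cz[zi] + offs$z[o])
        idx <- world_to_index(vol, pts)
        acc <- acc + if (method == "mask") {
          interp_nearest(src, idx[, 1], idx[, 2], idx[, 3])
        } else {
          interp_trilinear(src, idx[, 1], idx[, 2], idx[, 3])
        }
      }
      slab[, zi] <- acc / nrow(offs)
    }
    out[] <- slab
    if (method == "mask") {
      out <- (out >= mask_threshold) * 1
    } else {
      out <- out * prod(target$spacing) # density -> per-voxel amount
    }
  }
  volume_image(out, target$spacing, target$origin, frame = target$frame,
               quantity = vol$quantity)
}

#' Metric morphological dilation of a voxel mask
#'
#' Dilates by a Euclidean ball of radius `margin_mm` measured in world
#' millimetres (equivalent to thresholding the Euclidean distance transform
#' at the margin), so the result is identical in meaning across grids with
#' different voxel sizes.
#'
#' @param mask A [volume_image()] holding a logical/0-1 mask.
#' @param margin_mm Nonnegative dilation radius in mm.
#' @return A [volume_image()] mask on the same grid.
#' @export
dilate_mask <- function(mask, margin_mm) {
  stopifnot(inherits(mask, "volume_image"))
  if (margin_mm < 0) abort("`margin_mm` must be nonnegative.", class = "luquant_domain_error")
  m <- mask$data != 0
  if (margin_mm == 0) return(volume_image(m * 1, mask$spacing, mask$origin,
                                          frame = mask$frame, quantity = "mask"))
  r <- floor(margin_mm / mask$spacing)
  out <- m
  d <- dim(m)
  for (dx in -r[1]:r[1]) for (dy in -r[2]:r[2]) for (dz in -r[3]:r[3]) {
    if (dx == 0 && dy == 0 && dz == 0) next
    if (sum((c(dx, dy, dz) * mask$spacing)^2) > margin_mm^2) next
    sx <- intersect(seq_len(d[1]), seq_len(d[1]) - dx)
    sy <- intersect(seq_len(d[2]), seq_len(d[2]) - dy)
    sz <- intersect(seq_len(d[3]), seq_len(d[3]) - dz)
    out[sx + dx, sy + dy, sz + dz] <- out[sx + dx, sy + dy, sz + dz] | m[sx, sy, sz]
  }
  volume_image(out * 1, mask$spacing, mask$origin, frame = mask$frame,
               quantity = "mask")
}

#' Read and write volumes as NIfTI
#'
#' Voxel spacing is carried in the NIfTI pixdim; frame and quantity are the
#' caller's to supply on read (NIfTI has no slot for them).
#'
#' @param vol A [volume_image()].
#' @param path File path (`.nii` or `.nii.gz`).
#' @param frame,quantity Metadata to attach on read.
#' @return `read_volume()` returns a [volume_image()].
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume_image"))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path, frame = "NM", quantity = "arbitrary") {
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)[1:3]
  volume_image(array(as.numeric(img), dim(img)), spacing,
               frame = frame, quantity = quantity)
}

#' Plot an axial slice of a volume
#'
#' @param vol A [volume_image()].
#' @param z Slice index (default: middle slice).
#' @return A ggplot object.
#' @export
plot_slice <- function(vol, z = ceiling(dim(vol$data)[3] / 2)) {
  stopifnot(inherits(vol, "volume_image"))
  df <- expand.grid(x = axis_coords(vol, 1), y = axis_coords(vol, 2))
  df$value <- as.vector(vol$data[, , z])
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = vol$quantity) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)",
                  title = sprintf("%s slice z = %d", vol$frame, z))
}
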