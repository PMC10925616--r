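# Parallel-beam system model shared by the simulator and the reconstruction.
#
# A view at gantry angle theta is modelled by rotating the volume by -theta
# about the axial (z) axis with a sparse bilinear-interpolation operator,
# weighting every voxel by its attenuation survival along +y toward the
# detector, and summing along y. The adjoint is the exact transpose
# (replicate along y, weight, apply the transposed rotation), so MLEM uses a
# matched forward/back pair. Resolution is modelled as a separable,
# distance-independent Gaussian in image space (sigma in mm), applied before
# projection; its matrix is symmetric, hence self-adjoint.

# sparse bilinear rotation operator for an nx x ny in-plane grid
rotation_op <- function(nx, ny, theta_deg) {
  th <- theta_deg * pi / 180
  cxc <- (nx + 1) / 2; cyc <- (ny + 1) / 2
  gx <- rep(seq_len(nx), times = ny); gy <- rep(seq_len(ny), each = nx)
  # source coordinates: rotate output grid back by +theta
  xs <- cos(th) * (gx - cxc) - sin(th) * (gy - cyc) + cxc
  ys <- sin(th) * (gx - cxc) + cos(th) * (gy - cyc) + cyc
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  out_idx <- seq_len(nx * ny)
  for (dx in 0:1) for (dy in 0:1) {
    w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy)
    xi <- x0 + dx; yi <- y0 + dy
    ok <- which(w > 0 & xi >= 1 & xi <= nx & yi >= 1 & yi <= ny)
    rows <- c(rows, out_idx[ok])
    cols <- c(cols, xi[ok] + (yi[ok] - 1) * nx)
    vals <- c(vals, w[ok])
  }
  Matrix::sparseMatrix(i = rows, j = cols, x = vals, dims = c(nx * ny, nx * ny))
}

# symmetric truncated-Gaussian convolution matrix along one axis
gauss_mat <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  half <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-((-half:half)^2) / (2 * sigma_vox^2))
  k <- k / sum(k)
  G <- matrix(0, n, n)
  for (j in seq_len(n)) {
    i <- j + (-half:half)
    ok <- i >= 1 & i <= n
    G[i[ok], j] <- G[i[ok], j] + k[ok]
  }
  (G + t(G)) / 2
}

# separable 3-D Gaussian blur of an (nx, ny, nz) array
blur3 <- function(v, Gx, Gy, Gz) {
  d <- dim(v)
  if (!is.null(Gx)) {
    v <- array(Gx %*% matrix(v, d[1], d[2] * d[3]), d)
  }
  if (!is.null(Gy)) {
    vp <- aperm(v, c(2, 1, 3))
    vp <- array(Gy %*% matrix(vp, d[2], d[1] * d[3]), c(d[2], d[1], d[3]))
    v <- aperm(vp, c(2, 1, 3))
  }
  if (!is.null(Gz)) {
    v <- array(matrix(v, d[1] * d[2], d[3]) %*% Gz, d)
  }
  v
}

# Precompute per-angle operators for a given attenuation map and geometry.
# Returns closures forward(vol_array, subset) -> [nx, nz, n_angles(subset)]
# and adjoint(sino_subset, subset) -> vol_array, both including the PSF blur
# and attenuation survival, excluding sensitivity and duration.
make_projector <- function(mu, angles_deg, psf_sigma_mm = 0) {
  stopifnot(inherits(mu, "volume_image"))
  sp <- mu$spacing
  if (abs(sp[1] - sp[2]) > 1e-9) {
    abort("The projector requires square in-plane voxels.", class = "luquant_geometry_error")
  }
  d <- dim(mu$data)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  n_ang <- length(angles_deg)
  # forward rotation is the splat (transpose-of-gather) operator: every input
  # voxel distributes its full weight, so projection totals are conserved
  # exactly; the adjoint is the corresponding gather, an exact transpose pair
  Rt <- lapply(angles_deg, function(a) rotation_op(nx, ny, -a))
  R <- lapply(Rt, Matrix::t)
  sig <- psf_sigma_mm / sp
  Gx <- if (sig[1] > 0) gauss_mat(nx, sig[1]) else NULL
  Gy <- if (sig[2] > 0) gauss_mat(ny, sig[2]) else NULL
  Gz <- if (sig[3] > 0) gauss_mat(nz, sig[3]) else NULL

  # attenuation survival in each rotated frame: photons travel toward +y
  W <- vector("list", n_ang)
  mu_mat <- matrix(mu$data, nx * ny, nz)
  for (a in seq_len(n_ang)) {
    mr <- array(as.numeric(R[[a]] %*% mu_mat), d)
    # path integral from each voxel (half-weighted) through all voxels above it
    csum <- apply(mr[, ny:1, , drop = FALSE], c(1, 3), cumsum) # [y_rev, x, z]
    csum <- aperm(csum, c(2, 1, 3))[, ny:1, , drop = FALSE]
    W[[a]] <- exp(-sp[2] * (csum - mr / 2))
  }

  forward <- function(v, subset = seq_len(n_ang)) {
    vb <- blur3(v, Gx, Gy, Gz)
    vm <- matrix(vb, nx * ny, nz)
    out <- array(0, c(nx, nz, length(subset)))
    for (k in seq_along(subset)) {
      a <- subset[k]
      vr <- array(as.numeric(R[[a]] %*% vm), d) * W[[a]]
      out[, , k] <- rowSums(aperm(vr, c(1, 3, 2)), dims = 2)
    }
    out
  }

  adjoint <- function(sino, subset = seq_len(n_ang)) {
    acc <- matrix(0, nx * ny, nz)
    for (k in seq_along(subset)) {
      a <- subset[k]
      rep_y <- aperm(array(sino[, , k], c(nx, nz, ny)), c(1, 3, 2)) * W[[a]]
      acc <- acc + as.matrix(Rt[[a]] %*% matrix(rep_y, nx * ny, nz))
    }
    blur3(array(acc, d), Gx, Gy, Gz)
  }

  list(forward = forward, adjoint = adjoint, n_angles = n_ang,
       angles_deg = angles_deg, dim = d, spacing = sp)
}
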