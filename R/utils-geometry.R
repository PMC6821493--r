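# Internal geometry helpers: physical-coordinate voxel grids and trilinear
# interpolation. All coordinates are micrometres; arrays are indexed [x, y, z].

# Voxel-centre coordinate axes for a grid covering [-ext, ext] laterally and
# [zmin, zmax] axially. Lateral axes are symmetric about 0 so that x = 0 is a
# voxel centre.
voxel_axes <- function(ext_xy, zlim, spacing) {
  nx <- floor(ext_xy / spacing[1])
  ny <- floor(ext_xy / spacing[2])
  xs <- seq(-nx, nx) * spacing[1]
  ys <- seq(-ny, ny) * spacing[2]
  zs <- seq(zlim[1] + spacing[3] / 2, zlim[2], by = spacing[3])
  list(x = xs, y = ys, z = zs)
}

# Long-format coordinates of every voxel centre (n x 3 matrix), matching
# as.vector() order of an [x, y, z] array.
axes_coords <- function(axes) {
  nx <- length(axes$x); ny <- length(axes$y); nz <- length(axes$z)
  cbind(
    x = rep(axes$x, times = ny * nz),
    y = rep(rep(axes$y, each = nx), times = nz),
    z = rep(axes$z, each = nx * ny)
  )
}

# Trilinear interpolation of a 3D array at arbitrary points (n x 3 matrix of
# micrometre coordinates). Points outside the grid evaluate to `fill`.
interp_trilinear <- function(vol, axes, pts, fill = 0) {
  dm <- dim(vol)
  fx <- (pts[, 1] - axes$x[1]) / (axes$x[2] - axes$x[1])
  fy <- (pts[, 2] - axes$y[1]) / (axes$y[2] - axes$y[1])
  fz <- if (length(axes$z) > 1) (pts[, 3] - axes$z[1]) / (axes$z[2] - axes$z[1]) else rep(0, nrow(pts))
  i0 <- floor(fx); j0 <- floor(fy); k0 <- floor(fz)
  wx <- fx - i0; wy <- fy - j0; wz <- fz - k0
  out <- numeric(nrow(pts))
  ok <- i0 >= 0 & i0 <= dm[1] - 1 & j0 >= 0 & j0 <= dm[2] - 1 &
    k0 >= 0 & k0 <= dm[3] - 1
  # clamp the +1 neighbour at the upper faces so border points interpolate
  i1 <- pmin(i0 + 1, dm[1] - 1); j1 <- pmin(j0 + 1, dm[2] - 1)
  k1 <- pmin(k0 + 1, dm[3] - 1)
  if (any(ok)) {
    idx <- function(i, j, k) 1 + i + dm[1] * (j + dm[2] * k)
    i0k <- i0[ok]; j0k <- j0[ok]; k0k <- k0[ok]
    i1k <- i1[ok]; j1k <- j1[ok]; k1k <- k1[ok]
    wxk <- wx[ok]; wyk <- wy[ok]; wzk <- wz[ok]
    v <- vol
    out[ok] <-
      v[idx(i0k, j0k, k0k)] * (1 - wxk) * (1 - wyk) * (1 - wzk) +
      v[idx(i1k, j0k, k0k)] * wxk * (1 - wyk) * (1 - wzk) +
      v[idx(i0k, j1k, k0k)] * (1 - wxk) * wyk * (1 - wzk) +
      v[idx(i1k, j1k, k0k)] * wxk * wyk * (1 - wzk) +
      v[idx(i0k, j0k, k1k)] * (1 - wxk) * (1 - wyk) * wzk +
      v[idx(i1k, j0k, k1k)] * wxk * (1 - wyk) * wzk +
      v[idx(i0k, j1k, k1k)] * (1 - wxk) * wyk * wzk +
      v[idx(i1k, j1k, k1k)] * wxk * wyk * wzk
  }
  out[!ok] <- fill
  out
}

# Rotation matrix mapping unit vector `from` onto unit vector `to`
# (Rodrigues). Degenerate anti-parallel case handled via an arbitrary
# perpendicular axis.
rotation_between <- function(from, to) {
  from <- from / sqrt(sum(from^2))
  to <- to / sqrt(sum(to^2))
  v <- c(
    from[2] * to[3] - from[3] * to[2],
    from[3] * to[1] - from[1] * to[3],
    from[1] * to[2] - from[2] * to[1]
  )
  c_ <- sum(from * to)
  s <- sqrt(sum(v^2))
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    # 180 degrees: rotate about any axis perpendicular to `from`
    p <- if (abs(from[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- p - sum(p * from) * from
    axis <- axis / sqrt(sum(axis^2))
    K <- rbind(
      c(0, -axis[3], axis[2]),
      c(axis[3], 0, -axis[1]),
      c(-axis[2], axis[1], 0)
    )
    return(diag(3) + 2 * K %*% K)
  }
  K <- rbind(
    c(0, -v[3], v[2]),
    c(v[3], 0, -v[1]),
    c(-v[2], v[1], 0)
  )
  diag(3) + K + K %*% K * ((1 - c_) / s^2)
}
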