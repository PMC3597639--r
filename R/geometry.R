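# Voxel geometry helpers. Arrays are indexed (z, y, x), column-major, so the
# linear index of voxel (z, y, x) is z + (y-1)*Z + (x-1)*Z*Y. All physical
# coordinates are micrometres at voxel centers: coord = (index - 0.5) * pitch.

vox_index <- function(z, y, x, dim) {
  as.integer(z + (y - 1L) * dim[1] + (x - 1L) * dim[1] * dim[2])
}

vox_coords <- function(idx, dim) {
  idx0 <- idx - 1L
  z <- idx0 %% dim[1]
  r <- idx0 %/% dim[1]
  y <- r %% dim[2]
  x <- r %/% dim[2]
  cbind(z = z + 1L, y = y + 1L, x = x + 1L)
}

voxel_centers_um <- function(dim, voxel_size) {
  list(z = (seq_len(dim[1]) - 0.5) * voxel_size[1],
       y = (seq_len(dim[2]) - 0.5) * voxel_size[2],
       x = (seq_len(dim[3]) - 0.5) * voxel_size[3])
}

# Minimum distance from points P (n x 3, um, columns z,y,x) to a segment a-b.
point_segment_distance <- function(P, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) {
    return(sqrt(rowSums(sweep(P, 2, a)^2)))
  }
  t <- pmin(pmax((sweep(P, 2, a) %*% ab) / len2, 0), 1)
  proj <- matrix(a, nrow(P), 3, byrow = TRUE) + outer(as.vector(t), ab)
  sqrt(rowSums((P - proj)^2))
}

# Rasterize cylindrical tube segments into a logical (z, y, x) mask.
# segments: data.frame with z0,y0,x0,z1,y1,x1,radius in um.
tube_mask <- function(dim, voxel_size, segments) {
  mask <- array(FALSE, dim = dim)
  if (is.null(segments) || nrow(segments) == 0) return(mask)
  cc <- voxel_centers_um(dim, voxel_size)
  P <- cbind(rep(cc$z, times = dim[2] * dim[3]),
             rep(rep(cc$y, each = dim[1]), times = dim[3]),
             rep(cc$x, each = dim[1] * dim[2]))
  for (i in seq_len(nrow(segments))) {
    s <- segments[i, ]
    d <- point_segment_distance(P, c(s$z0, s$y0, s$x0), c(s$z1, s$y1, s$x1))
    mask <- mask | array(d <= s$radius, dim = dim)
  }
  mask
}

# Binary dilation by a physical distance (um) under anisotropic voxels:
# a voxel is set if any voxel of `mask` lies within `dist` of it. When the
# distance does not reach the neighbouring z-slice (the usual case at
# 8.2 um optical sections) the dilation is in-plane and is delegated
# per-slice to EBImage's morphological dilate with an exact
# physical-distance brush.
dilate_mask <- function(mask, voxel_size, dist) {
  if (dist <= 0) return(mask)
  d <- dim(mask)
  nz <- floor(dist / voxel_size[1])
  ny <- floor(dist / voxel_size[2])
  nx <- floor(dist / voxel_size[3])
  if (nz == 0 && ny > 0 && nx > 0) {
    brush <- outer((-ny:ny) * voxel_size[2], (-nx:nx) * voxel_size[3],
                   function(a, b) as.numeric(a^2 + b^2 <= dist^2))
    out <- array(FALSE, dim = d)
    for (z in seq_len(d[1])) {
      sl <- matrix(as.numeric(mask[z, , ]), d[2], d[3])
      out[z, , ] <- EBImage::imageData(
        EBImage::dilate(EBImage::Image(sl), brush)) > 0.5
    }
    return(out)
  }
  out <- array(FALSE, dim = d)
  for (dz in -nz:nz) for (dy in -ny:ny) for (dx in -nx:nx) {
    if ((dz * voxel_size[1])^2 + (dy * voxel_size[2])^2 +
        (dx * voxel_size[3])^2 > dist^2) next
    if (abs(dz) >= d[1] || abs(dy) >= d[2] || abs(dx) >= d[3]) next
    zs <- max(1, 1 + dz):min(d[1], d[1] + dz)
    ys <- max(1, 1 + dy):min(d[2], d[2] + dy)
    xs <- max(1, 1 + dx):min(d[3], d[3] + dx)
    out[zs, ys, xs] <- out[zs, ys, xs] |
      mask[zs - dz, ys - dy, xs - dx]
  }
  out
}

# Voxels of a filled in-plane ellipse at slice `z`, center (cy, cx) in pixels,
# semi-axes (a, b) in pixels, rotated by theta. Returns linear indices, or
# NULL if the ellipse leaves the field.
ellipse_voxels <- function(z, cy, cx, a, b, theta, dim) {
  r <- ceiling(max(a, b)) + 1L
  ys <- floor(cy - r):ceiling(cy + r)
  xs <- floor(cx - r):ceiling(cx + r)
  if (min(ys) < 1 || max(ys) > dim[2] || min(xs) < 1 || max(xs) > dim[3] ||
      z < 1 || z > dim[1]) {
    return(NULL)
  }
  g <- expand.grid(y = ys, x = xs)
  dy <- g$y - cy
  dx <- g$x - cx
  u <- cos(theta) * dy + sin(theta) * dx
  v <- -sin(theta) * dy + cos(theta) * dx
  keep <- (u / a)^2 + (v / b)^2 <= 1
  if (!any(keep)) {
    # degenerate tiny ellipse: keep the center voxel
    g <- data.frame(y = round(cy), x = round(cx))
    keep <- TRUE
  }
  vox_index(z, g$y[keep], g$x[keep], dim)
}

# A voxel set expanded by its full 26-neighbourhood, clipped to the field.
expand_neighborhood <- function(idx, d) {
  co <- vox_coords(idx, d)
  out <- integer(0)
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    z <- co[, 1] + dz; y <- co[, 2] + dy; x <- co[, 3] + dx
    ok <- z >= 1 & z <= d[1] & y >= 1 & y <= d[2] & x >= 1 & x <= d[3]
    out <- c(out, vox_index(z[ok], y[ok], x[ok], d))
  }
  unique(out)
}

# Mark voxels along a 3D segment (um coordinates) with an in-plane brush of
# `thickness` um radius; used for astrocyte processes.
paint_segment <- function(mask, voxel_size, a, b, thickness = 0.4) {
  d <- dim(mask)
  len <- sqrt(sum((b - a)^2))
  n <- max(2L, ceiling(len / (0.5 * min(voxel_size[2:3]))))
  t <- seq(0, 1, length.out = n)
  pts <- cbind(a[1] + t * (b[1] - a[1]),
               a[2] + t * (b[2] - a[2]),
               a[3] + t * (b[3] - a[3]))
  iz <- pmin(pmax(ceiling(pts[, 1] / voxel_size[1]), 1L), d[1])
  iy <- pmin(pmax(ceiling(pts[, 2] / voxel_size[2]), 1L), d[2])
  ix <- pmin(pmax(ceiling(pts[, 3] / voxel_size[3]), 1L), d[3])
  rpx <- max(0L, round(thickness / voxel_size[2]))
  for (dy in -rpx:rpx) for (dx in -rpx:rpx) {
    yy <- pmin(pmax(iy + dy, 1L), d[2])
    xx <- pmin(pmax(ix + dx, 1L), d[3])
    mask[vox_index(iz, yy, xx, d)] <- TRUE
  }
  mask
}

# Surface area (um^2) of a binary mask via the coarea formula: the mask is
# smoothed with a small separable Gaussian and the integral of |grad| over
# the volume converges to the interface area. Gradients use central
# differences with clamped borders, so faces lying on the volume boundary
# (e.g. a tube cut by the field edge) are not counted.
mask_surface_area <- function(mask, voxel_size, sigma_um = NULL) {
  d <- dim(mask)
  u <- array(as.numeric(mask), dim = d)
  if (is.null(sigma_um)) sigma_um <- 1.2 * min(voxel_size[voxel_size > 0])
  for (ax in 1:3) {
    sig_px <- sigma_um / voxel_size[ax]
    if (sig_px < 0.3 || d[ax] < 3) next
    u <- gauss_smooth_axis(u, ax, sig_px)
  }
  gz <- axis_gradient(u, 1) / voxel_size[1]
  gy <- axis_gradient(u, 2) / voxel_size[2]
  gx <- axis_gradient(u, 3) / voxel_size[3]
  sum(sqrt(gz^2 + gy^2 + gx^2)) * prod(voxel_size)
}

gauss_smooth_axis <- function(u, axis, sigma_px) {
  r <- max(1L, ceiling(3 * sigma_px))
  k <- exp(-0.5 * ((-r:r) / sigma_px)^2)
  k <- k / sum(k)
  d <- dim(u)
  perm <- c(axis, setdiff(1:3, axis))
  up <- aperm(u, perm)
  m <- matrix(up, nrow = d[axis])
  # replicate-pad convolution along columns
  padded <- rbind(m[rep(1L, r), , drop = FALSE], m,
                  m[rep(nrow(m), r), , drop = FALSE])
  out <- matrix(0, nrow(m), ncol(m))
  for (j in seq_along(k)) {
    out <- out + k[j] * padded[j:(j + nrow(m) - 1L), , drop = FALSE]
  }
  aperm(array(out, dim = d[perm]), order(perm))
}

axis_gradient <- function(u, axis) {
  d <- dim(u)
  n <- d[axis]
  if (n < 2) return(array(0, dim = d))
  idx_hi <- pmin(seq_len(n) + 1L, n)
  idx_lo <- pmax(seq_len(n) - 1L, 1L)
  step <- idx_hi - idx_lo          # 1 at borders, 2 inside
  perm <- c(axis, setdiff(1:3, axis))
  up <- aperm(u, perm)
  m <- matrix(up, nrow = n)
  g <- (m[idx_hi, , drop = FALSE] - m[idx_lo, , drop = FALSE]) / step
  aperm(array(g, dim = d[perm]), order(perm))
}
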