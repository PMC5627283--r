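# Trilinear / nearest-neighbour interpolation on 3-D (or multi-component
# 4-D) arrays at continuous 1-based voxel coordinates.  Points outside the
# grid yield NA (trilinear) so callers can mask them explicitly.

interp_trilinear <- function(arr, vox, clamp = FALSE) {
  d <- dim(arr)
  nc <- if (length(d) == 4L) d[4] else 1L
  shape <- d[1:3]
  vox <- rbind_pts(vox)
  n <- nrow(vox)

  if (clamp) {
    for (a in 1:3) vox[, a] <- pmin(pmax(vox[, a], 1), shape[a])
  }
  inside <- vox[, 1] >= 1 & vox[, 1] <= shape[1] &
            vox[, 2] >= 1 & vox[, 2] <= shape[2] &
            vox[, 3] >= 1 & vox[, 3] <= shape[3]
  out <- matrix(NA_real_, n, nc)
  if (!any(inside)) return(if (nc == 1L) out[, 1] else out)
  v <- vox[inside, , drop = FALSE]

  x0 <- pmin(pmax(floor(v[, 1]), 1), shape[1] - 1)
  y0 <- pmin(pmax(floor(v[, 2]), 1), shape[2] - 1)
  z0 <- pmin(pmax(floor(v[, 3]), 1), shape[3] - 1)
  if (shape[1] == 1L) x0 <- rep(1, nrow(v))
  if (shape[2] == 1L) y0 <- rep(1, nrow(v))
  if (shape[3] == 1L) z0 <- rep(1, nrow(v))
  fx <- v[, 1] - x0; fy <- v[, 2] - y0; fz <- v[, 3] - z0
  x1 <- pmin(x0 + 1, shape[1]); y1 <- pmin(y0 + 1, shape[2])
  z1 <- pmin(z0 + 1, shape[3])

  nxy <- shape[1] * shape[2]
  base <- function(ix, iy, iz) (iz - 1) * nxy + (iy - 1) * shape[1] + ix
  i000 <- base(x0, y0, z0); i100 <- base(x1, y0, z0)
  i010 <- base(x0, y1, z0); i110 <- base(x1, y1, z0)
  i001 <- base(x0, y0, z1); i101 <- base(x1, y0, z1)
  i011 <- base(x0, y1, z1); i111 <- base(x1, y1, z1)
  w000 <- (1 - fx) * (1 - fy) * (1 - fz); w100 <- fx * (1 - fy) * (1 - fz)
  w010 <- (1 - fx) * fy * (1 - fz);       w110 <- fx * fy * (1 - fz)
  w001 <- (1 - fx) * (1 - fy) * fz;       w101 <- fx * (1 - fy) * fz
  w011 <- (1 - fx) * fy * fz;             w111 <- fx * fy * fz

  nvox <- prod(shape)
  res <- matrix(0, nrow(v), nc)
  for (c in seq_len(nc)) {
    off <- (c - 1L) * nvox
    a <- arr
    res[, c] <- w000 * a[i000 + off] + w100 * a[i100 + off] +
                w010 * a[i010 + off] + w110 * a[i110 + off] +
                w001 * a[i001 + off] + w101 * a[i101 + off] +
                w011 * a[i011 + off] + w111 * a[i111 + off]
  }
  out[inside, ] <- res
  if (nc == 1L) out[, 1] else out
}

interp_nearest <- function(arr, vox) {
  shape <- dim(arr)[1:3]
  vox <- rbind_pts(vox)
  ix <- round(vox[, 1]); iy <- round(vox[, 2]); iz <- round(vox[, 3])
  inside <- ix >= 1 & ix <= shape[1] & iy >= 1 & iy <= shape[2] &
            iz >= 1 & iz <= shape[3]
  out <- rep(NA, nrow(vox))
  idx <- (pmin(pmax(iz, 1), shape[3]) - 1) * shape[1] * shape[2] +
         (pmin(pmax(iy, 1), shape[2]) - 1) * shape[1] +
          pmin(pmax(ix, 1), shape[1])
  out[inside] <- arr[idx[inside]]
  out
}

# Sample a scalar_volume at world-space points (mm).
sample_world <- function(vol, points, mode = c("trilinear", "nearest")) {
  mode <- match.arg(mode)
  vox <- world_to_voxel(points, vol$affine)
  if (mode == "trilinear") interp_trilinear(vol$values, vox)
  else interp_nearest(vol$values, vox)
}

# Central-difference spatial gradient of a 3-D array in world (mm) units.
# Assumes (as all grids in this package) an affine whose rotational part is
# axis-aligned up to scaling; for general affines the voxel-space gradient
# is mapped through the inverse linear part.
gradient_mm <- function(values, affine) {
  d <- dim(values)
  g <- array(0, c(d, 3L))
  cd <- function(a, axis) {
    n <- dim(a)[axis]
    ip <- pmin(seq_len(n) + 1L, n)
    im <- pmax(seq_len(n) - 1L, 1L)
    den <- ip - im
    idx <- function(v) switch(axis, a[v, , , drop = FALSE],
                              a[, v, , drop = FALSE], a[, , v, drop = FALSE])
    sweep(idx(ip) - idx(im), axis, den, "/")
  }
  gv <- list(cd(values, 1L), cd(values, 2L), cd(values, 3L))
  Ainv <- solve(affine[1:3, 1:3])
  for (a in 1:3) {
    acc <- array(0, d)
    for (b in 1:3) acc <- acc + gv[[b]] * Ainv[b, a]
    g[, , , a] <- acc
  }
  g
}

clamp_vox <- function(vox, shape) {
  for (a in 1:3) vox[, a] <- pmin(pmax(vox[, a], 1), shape[a])
  vox
}
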