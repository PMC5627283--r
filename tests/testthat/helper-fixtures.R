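# Shared fixtures: random tensors, tiny grids, analytic images.

random_spd_tensor6 <- function(scale = 1e-3) {
  A <- matrix(rnorm(9), 3, 3)
  S <- crossprod(A) * scale / 3
  mat_to_tensor6(S)
}

random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

rotate_tensor6 <- function(v, R) {
  mat_to_tensor6(R %*% tensor6_to_mat(v) %*% t(R))
}

# Constant-tensor volume on a small grid.
const_tensor_volume <- function(v6, shape = c(8L, 8L, 8L), voxel = 2) {
  tensor_volume(array(rep(v6, each = prod(shape)), c(shape, 6L)),
                diag(c(rep(voxel, 3), 1)))
}

# Tensor volume with iid random SPD tensors.
random_tensor_volume <- function(shape = c(6L, 6L, 6L), voxel = 2,
                                 scale = 1e-3) {
  n <- prod(shape)
  m <- t(replicate(n, random_spd_tensor6(scale)))
  tensor_volume(array(m, c(shape, 6L)), diag(c(rep(voxel, 3), 1)))
}

# Smooth analytic blob image evaluated exactly on a grid (optionally under
# an affine map of the coordinates), useful for registration parameter
# recovery without resampling artifacts.
blob_volume <- function(shape = c(24L, 24L, 24L), voxel = 2,
                        centers = NULL, sigma = 8, M = diag(4)) {
  aff <- diag(c(rep(voxel, 3), 1))
  if (is.null(centers)) {
    ext <- (shape - 1) * voxel
    centers <- rbind(0.4 * ext, c(0.65, 0.35, 0.55) * ext,
                     c(0.35, 0.65, 0.6) * ext)
  }
  X <- tractatlas:::grid_world(shape, aff)
  Y <- sweep(X %*% t(M[1:3, 1:3]), 2, M[1:3, 4], "+")
  v <- 0
  for (i in seq_len(nrow(centers)))
    v <- v + exp(-rowSums(sweep(Y, 2, centers[i, ])^2) / (2 * sigma^2))
  scalar_volume(array(v, shape), aff)
}

# Small phantom for fast tests.
small_phantom <- function(shape = c(32L, 32L, 32L)) {
  build_phantom(phantom_spec(shape = shape))
}

# Independent brute-force 1-D TFCE oracle: per point, walk thresholds and
# find the containing run directly.
tfce_oracle <- function(stats, E = 0.5, H = 2, dh = 0.1) {
  one <- function(x) {
    K <- length(x)
    out <- numeric(K)
    for (k in seq_len(K)) {
      if (x[k] < dh) next
      hs <- seq(dh, x[k], by = dh)
      for (h in hs) {
        l <- k
        while (l > 1 && x[l - 1] >= h) l <- l - 1
        r <- k
        while (r < K && x[r + 1] >= h) r <- r + 1
        out[k] <- out[k] + (r - l + 1)^E * h^H * dh
      }
    }
    out
  }
  one(stats) - one(-stats)
}

# Brute-force AUC by pair counting (ties count 1/2).
auc_oracle <- function(x, labels) {
  labels <- as.factor(labels)
  xp <- x[labels == levels(labels)[2]]
  xn <- x[labels == levels(labels)[1]]
  tot <- 0
  for (p in xp) for (n in xn)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(xp) * length(xn))
}
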