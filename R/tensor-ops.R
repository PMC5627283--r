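# Core tensor operations: eigen-decomposition, FA, averaging, tensor fit.

#' Pack / unpack symmetric 3x3 matrices
#'
#' `tensor6_to_mat` expands a length-6 component vector (Dxx, Dxy, Dyy,
#' Dxz, Dyz, Dzz) into a symmetric 3x3 matrix; `mat_to_tensor6` is its
#' inverse.
#' @param v length-6 numeric vector.
#' @return 3x3 matrix / length-6 vector.
#' @export
tensor6_to_mat <- function(v) {
  matrix(c(v[1], v[2], v[4],
           v[2], v[3], v[5],
           v[4], v[5], v[6]), 3, 3)
}

#' @rdname tensor6_to_mat
#' @param m symmetric 3x3 matrix.
#' @export
mat_to_tensor6 <- function(m) {
  c(m[1, 1], m[1, 2], m[2, 2], m[1, 3], m[2, 3], m[3, 3])
}

tensors_as_matrix <- function(t) matrix(t$tensors, ncol = 6L)

#' Eigen-decompose a tensor volume
#'
#' Per-voxel symmetric eigen-decomposition with eigenvalues sorted
#' descending and eigenvector signs canonicalized (first component of
#' magnitude above tolerance made positive).  Voxels with non-finite
#' tensor entries are excluded from the returned mask with a warning.
#'
#' @param t a [tensor_volume()].
#' @return object of class `eigen_system`: list with `lambdas`
#'   (`nx,ny,nz,3` array, descending), `vectors` (`nx,ny,nz,3,3`; last index
#'   selects the eigenvector, second-to-last its component), `mask`, `shape`,
#'   `affine`.
#' @export
eigendecompose <- function(t) {
  stopifnot(inherits(t, "tensor_volume"))
  comp <- tensors_as_matrix(t)
  res <- .eig_sym3_batch(comp)
  lam <- res$lambdas
  bad <- !is.finite(lam[, 1]) & t$mask
  mask <- t$mask
  if (any(bad)) {
    warning(sprintf("%d voxels with non-finite eigen-systems masked out",
                    sum(bad)))
    mask <- mask & !bad
  }
  structure(list(
    lambdas = array(lam, c(t$shape, 3L)),
    vectors = array(res$vectors, c(t$shape, 3L, 3L)),
    mask = mask, shape = t$shape, affine = t$affine
  ), class = "eigen_system")
}

# Eigen-system at a single voxel / single tensor matrix (test convenience).
eig_tensor6 <- function(v) {
  res <- .eig_sym3_batch(matrix(v, nrow = 1))
  list(lambdas = drop(res$lambdas),
       vectors = matrix(res$vectors, 3, 3))
}

#' Fractional anisotropy from eigenvalues
#'
#' FA = sqrt(1/2) * sqrt((l1-l2)^2 + (l2-l3)^2 + (l3-l1)^2) /
#' sqrt(l1^2 + l2^2 + l3^2), clipped to \[0, 1\].  All-zero tensors give 0.
#' Negative eigenvalues (noisy fits) are clamped to zero first; the clamp
#' count is reported as an attribute.
#'
#' @param es an `eigen_system` from [eigendecompose()], or a numeric matrix
#'   of eigenvalue triples (columns l1..l3).
#' @return For an `eigen_system`, a [scalar_volume()] whose mask excludes
#'   all-zero tensors; for a matrix, a numeric vector.
#' @export
fractional_anisotropy <- function(es) {
  if (inherits(es, "eigen_system")) {
    lam <- matrix(es$lambdas, ncol = 3L)
    fa <- fa_from_lambdas(lam)
    vol <- scalar_volume(array(fa, es$shape), es$affine,
                         mask = es$mask & array(attr(fa, "nonzero"), es$shape))
    attr(vol, "n_clamped") <- attr(fa, "n_clamped")
    return(vol)
  }
  fa_from_lambdas(rbind_pts(es)[, 1:3, drop = FALSE])
}

fa_from_lambdas <- function(lam) {
  n_clamped <- sum(lam < 0, na.rm = TRUE)
  lam[lam < 0] <- 0
  ss <- rowSums(lam^2)
  num <- (lam[, 1] - lam[, 2])^2 + (lam[, 2] - lam[, 3])^2 +
         (lam[, 3] - lam[, 1])^2
  fa <- sqrt(0.5) * sqrt(num) / sqrt(ss)
  nonzero <- is.finite(ss) & ss > 0
  fa[!nonzero] <- 0
  fa <- pmin(pmax(fa, 0), 1)
  attr(fa, "nonzero") <- nonzero
  attr(fa, "n_clamped") <- n_clamped
  fa
}

#' FA map of a tensor volume
#'
#' Convenience wrapper computing FA directly from tensor invariants
#' (equivalent to eigen-decomposition, but cheaper): FA^2 =
#' 3/2 * ||dev D||_F^2 / ||D||_F^2.
#'
#' @param t a [tensor_volume()].
#' @return a [scalar_volume()] of FA in \[0, 1\].
#' @export
fa_map <- function(t) {
  m <- tensors_as_matrix(t)
  tr <- m[, 1] + m[, 3] + m[, 6]
  frob2 <- m[, 1]^2 + m[, 3]^2 + m[, 6]^2 +
           2 * (m[, 2]^2 + m[, 4]^2 + m[, 5]^2)
  dev2 <- frob2 - tr^2 / 3
  fa <- sqrt(pmax(1.5 * dev2 / frob2, 0))
  zero <- !is.finite(frob2) | frob2 <= 0
  fa[zero] <- 0
  fa <- pmin(fa, 1)
  scalar_volume(array(fa, t$shape), t$affine, mask = t$mask & !array(zero, t$shape))
}

#' Average tensor volumes
#'
#' Voxel-wise mean over a list of tensor volumes sharing one grid.  The
#' `euclidean` mode averages components; `log_euclidean` averages matrix
#' logarithms (preserving positive-definiteness) and exponentiates back.
#' The output mask is the intersection of input masks.
#'
#' @param ts nonempty list of [tensor_volume()] on a common grid.
#' @param mode `"euclidean"` (default) or `"log_euclidean"`.
#' @return a [tensor_volume()].
#' @export
mean_tensor_volume <- function(ts, mode = c("euclidean", "log_euclidean")) {
  mode <- match.arg(mode)
  stopifnot(is.list(ts), length(ts) >= 1L)
  ref <- ts[[1]]
  for (t in ts) {
    stopifnot(inherits(t, "tensor_volume"))
    stop_if_grid_mismatch(ref, t, "tensor volumes")
  }
  mask <- Reduce(`&`, lapply(ts, `[[`, "mask"))
  if (mode == "euclidean") {
    acc <- Reduce(`+`, lapply(ts, `[[`, "tensors")) / length(ts)
  } else {
    acc <- Reduce(`+`, lapply(ts, function(t)
      array(log_tensor6(tensors_as_matrix(t)), dim(t$tensors)))) / length(ts)
    acc <- array(exp_tensor6(matrix(acc, ncol = 6L)), dim(acc))
  }
  tensor_volume(acc, ref$affine, mask = mask)
}

# Matrix log / exp of packed symmetric tensors (rows of an n x 6 matrix).
# Eigenvalues are floored at a small positive epsilon before log.
log_tensor6 <- function(comp, eps = 1e-12) {
  res <- .eig_sym3_batch(comp)
  lam <- pmax(res$lambdas, eps)
  recompose6(log(lam), res$vectors)
}

exp_tensor6 <- function(comp) {
  res <- .eig_sym3_batch(comp)
  recompose6(exp(res$lambdas), res$vectors)
}

# Rebuild packed tensors from eigenvalues (n x 3) and eigenvectors (n x 9).
recompose6 <- function(lam, vec) {
  out <- matrix(0, nrow(lam), 6L)
  for (j in 1:3) {
    v1 <- vec[, 3 * j - 2]; v2 <- vec[, 3 * j - 1]; v3 <- vec[, 3 * j]
    l <- lam[, j]
    out[, 1] <- out[, 1] + l * v1 * v1
    out[, 2] <- out[, 2] + l * v1 * v2
    out[, 3] <- out[, 3] + l * v2 * v2
    out[, 4] <- out[, 4] + l * v1 * v3
    out[, 5] <- out[, 5] + l * v2 * v3
    out[, 6] <- out[, 6] + l * v3 * v3
  }
  out
}

#' Fit diffusion tensors from diffusion-weighted volumes
#'
#' Log-linear least squares fit of the single-tensor model
#' `S = S0 * exp(-b g' D g)` per voxel.  Noise-free signals are recovered
#' exactly (up to numerical precision).
#'
#' @param dwis list of [scalar_volume()], one per gradient table row
#'   (including the b=0 volumes), all on one grid.
#' @param bvals numeric vector of b-values (s/mm^2), length equal to
#'   `length(dwis)`.
#' @param bvecs matrix `length(dwis) x 3` of unit gradient directions
#'   (rows for b=0 volumes are ignored).
#' @param min_signal nonpositive signals are clamped to this fraction of
#'   the voxel's S0 estimate before taking logs; the clamp count is
#'   reported as attribute `n_clamped`.
#' @return a [tensor_volume()] with attribute `s0` (a [scalar_volume()]).
#' @export
fit_tensors <- function(dwis, bvals, bvecs, min_signal = 1e-6) {
  stopifnot(is.list(dwis), length(dwis) == length(bvals),
            nrow(bvecs) == length(bvals))
  ref <- dwis[[1]]
  for (d in dwis) stop_if_grid_mismatch(ref, d, "DWI volumes")
  if (sum(bvals <= 0) < 1L) stop("at least one b=0 volume is required")
  if (sum(bvals > 0) < 6L)
    stop("at least 6 diffusion-weighted volumes are required")
  # design: log S = log S0 - b * (g' D g), unknowns (log S0, D components)
  g <- bvecs
  X <- cbind(1,
             -bvals * g[, 1]^2,
             -2 * bvals * g[, 1] * g[, 2],
             -bvals * g[, 2]^2,
             -2 * bvals * g[, 1] * g[, 3],
             -2 * bvals * g[, 2] * g[, 3],
             -bvals * g[, 3]^2)
  qrX <- qr(X)
  if (qrX$rank < 7L)
    stop("rank-deficient gradient design: need >= 6 unique non-collinear ",
         "directions plus a b=0 volume")
  S <- sapply(dwis, function(d) as.vector(d$values))
  s0 <- rowMeans(S[, bvals <= 0, drop = FALSE])
  floorv <- pmax(s0 * min_signal, .Machine$double.xmin)
  n_clamped <- sum(S <= 0)
  S <- pmax(S, floorv)
  beta <- qr.coef(qrX, t(log(S)))
  comp <- t(beta[2:7, , drop = FALSE])
  tens <- tensor_volume(array(comp, c(ref$shape, 6L)), ref$affine,
                        mask = Reduce(`&`, lapply(dwis, `[[`, "mask")))
  attr(tens, "s0") <- scalar_volume(array(exp(beta[1, ]), ref$shape),
                                    ref$affine)
  attr(tens, "n_clamped") <- n_clamped
  tens
}
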