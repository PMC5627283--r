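# Scalar feature images that drive registration: FA, hFA (largest
# eigenvalue of the Hessian of the FA map), and a T1-like structural
# channel.

# Shift an array along one axis by s voxels with reflective padding
# (mirror about the edge voxel: index 0 -> 2, index n+1 -> n-1).
shift_reflect <- function(arr, axis, s) {
  n <- dim(arr)[axis]
  idx <- seq_len(n) + s
  idx <- ifelse(idx < 1L, 2L - idx, idx)
  idx <- ifelse(idx > n, 2L * n - idx, idx)
  idx <- pmin(pmax(idx, 1L), n)
  switch(axis, arr[idx, , , drop = FALSE], arr[, idx, , drop = FALSE],
         arr[, , idx, drop = FALSE])
}

# Separable Gaussian smoothing with per-axis sigma given in voxels.
gaussian_smooth_vox <- function(arr, sigma_vox) {
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    w <- exp(-0.5 * ((-r):r / s)^2)
    w <- w / sum(w)
    acc <- array(0, dim(arr))
    for (t in (-r):r) acc <- acc + w[t + r + 1L] * shift_reflect(arr, axis, t)
    arr <- acc
  }
  arr
}

#' Gaussian-smooth a scalar volume
#'
#' @param vol a [scalar_volume()].
#' @param sigma smoothing sigma in mm (scalar, applied per axis after
#'   conversion to voxels via the affine).
#' @return a [scalar_volume()].
#' @export
smooth_volume <- function(vol, sigma) {
  stopifnot(inherits(vol, "scalar_volume"), sigma >= 0)
  vs <- voxel_size(vol$affine)
  scalar_volume(gaussian_smooth_vox(vol$values, sigma / vs), vol$affine,
                mask = vol$mask)
}

#' Hessian-of-FA feature image (hFA)
#'
#' Gaussian-smooths the FA map at `sigma` mm, forms the 3x3 Hessian per
#' voxel by central second differences in world (mm) units with reflective
#' boundary padding, and returns the largest Hessian eigenvalue.
#' Derivatives in mm make the result resolution-independent; anisotropic
#' voxel sizes are honored per axis.
#'
#' @param fa a [scalar_volume()] (an FA map).
#' @param sigma smoothing sigma in mm, >= 0; must not exceed half the
#'   field of view.
#' @return a [scalar_volume()] of the largest Hessian eigenvalue (1/mm^2
#'   times the FA scale).
#' @export
compute_hfa <- function(fa, sigma = 2) {
  stopifnot(inherits(fa, "scalar_volume"), sigma >= 0)
  vs <- voxel_size(fa$affine)
  fov <- fa$shape * vs
  if (sigma > min(fov) / 2)
    stop("smoothing sigma exceeds half the field of view")
  f <- gaussian_smooth_vox(fa$values, sigma / vs)

  d2 <- function(a, b) {
    if (a == b) {
      (shift_reflect(f, a, 1L) - 2 * f + shift_reflect(f, a, -1L)) / vs[a]^2
    } else {
      (shift_reflect(shift_reflect(f, a, 1L), b, 1L) -
       shift_reflect(shift_reflect(f, a, 1L), b, -1L) -
       shift_reflect(shift_reflect(f, a, -1L), b, 1L) +
       shift_reflect(shift_reflect(f, a, -1L), b, -1L)) / (4 * vs[a] * vs[b])
    }
  }
  comp <- cbind(as.vector(d2(1L, 1L)), as.vector(d2(1L, 2L)),
                as.vector(d2(2L, 2L)), as.vector(d2(1L, 3L)),
                as.vector(d2(2L, 3L)), as.vector(d2(3L, 3L)))
  lam <- .eig_sym3_batch(comp)$lambdas[, 1]
  scalar_volume(array(lam, fa$shape), fa$affine, mask = fa$mask)
}

#' Build a registration feature image for a subject
#'
#' Dispatches over the three feature kinds: `"FA"` (from the subject's
#' tensor volume), `"hFA"` ([compute_hfa()] of the FA map), `"T1"` (the
#' subject's structural channel, unchanged).
#'
#' @param subject list with fields `tensor` (a [tensor_volume()], needed
#'   for FA/hFA) and/or `structural` (a [scalar_volume()], needed for T1).
#' @param kind `"FA"`, `"hFA"` or `"T1"`.
#' @param sigma hFA smoothing sigma in mm (default 2).
#' @return object of class `feature_image`: list with `kind`, `image`
#'   (a [scalar_volume()]) and `smoothing_sigma` (hFA only, else `NA`).
#' @export
make_feature <- function(subject, kind = c("FA", "hFA", "T1"), sigma = 2) {
  kind <- match.arg(kind)
  if (kind %in% c("FA", "hFA")) {
    if (is.null(subject$tensor))
      stop("subject record has no 'tensor' channel (needed for ", kind, ")")
    fa <- fa_map(subject$tensor)
    img <- if (kind == "FA") fa else compute_hfa(fa, sigma)
  } else {
    if (is.null(subject$structural))
      stop("subject record has no 'structural' channel (needed for T1)")
    img <- subject$structural
  }
  structure(list(kind = kind, image = img,
                 smoothing_sigma = if (kind == "hFA") sigma else NA_real_),
            class = "feature_image")
}
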