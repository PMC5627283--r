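# Ground-truth sinusoidal deformation simulation and tensor warping with
# reorientation.

#' Sinusoidal deformation specification
#'
#' Displacement component c at world point x is
#' `amplitude[c] * sin(2*pi*frequency[c] * (x . direction) + phase[c])`:
#' each component oscillates along the spatial axis `direction` with its
#' own amplitude (mm), frequency (cycles/mm) and phase.  The constructor
#' enforces the invertibility bound: the spectral norm of the displacement
#' gradient, `sqrt(sum((2*pi*amplitude*frequency)^2))`, must stay below
#' `max_grad` (default 0.9 < 1).
#'
#' @param amplitude length-3 amplitudes, mm.
#' @param frequency length-3 frequencies, cycles/mm.
#' @param phase length-3 phases, radians.
#' @param direction 3-vector (normalized internally).
#' @param max_grad invertibility bound on `|grad u|`.
#' @return object of class `sinusoid_spec`.
#' @export
sinusoid_spec <- function(amplitude, frequency, phase = c(0, 0, 0),
                          direction = c(1, 0, 0), max_grad = 0.9) {
  stopifnot(length(amplitude) == 3L, length(frequency) == 3L,
            length(phase) == 3L, length(direction) == 3L,
            all(amplitude >= 0), all(frequency >= 0))
  nd <- sqrt(sum(direction^2))
  if (nd == 0) stop("direction must be nonzero")
  g <- sqrt(sum((2 * pi * amplitude * frequency)^2))
  if (g >= max_grad)
    stop(sprintf(paste0("amplitude/frequency violate the invertibility ",
                        "bound: |grad u| = %.3f >= %.3f"), g, max_grad))
  structure(list(amplitude = amplitude, frequency = frequency,
                 phase = phase, direction = direction / nd,
                 max_grad_norm = g),
            class = "sinusoid_spec")
}

# Render a sinusoid_spec as a dense displacement array on a grid.
render_sinusoid <- function(spec, shape, affine) {
  X <- grid_world(shape, affine)
  proj <- as.vector(X %*% spec$direction)
  disp <- array(0, c(shape, 3L))
  for (c in 1:3) {
    disp[, , , c] <- array(spec$amplitude[c] *
                             sin(2 * pi * spec$frequency[c] * proj +
                                 spec$phase[c]), shape)
  }
  disp
}

#' Generate a balanced family of sinusoidal deformation fields
#'
#' Draws `n_pairs` random [sinusoid_spec()]s, renders each as a dense
#' field, and appends its exact negation, so the per-voxel vector sum over
#' all `2*n_pairs` fields is exactly zero.  The negation is the first-order
#' inverse of the field; the true-inverse composition residual
#' `max |d(x + (-d)(x)) + (-d)(x)|` is computed per pair (in voxels) and
#' attached as attribute `inversion_residual`.
#'
#' @param n_pairs number of (field, negated field) pairs, >= 1.
#' @param shape grid dimensions (3 integers).
#' @param affine 4x4 voxel-to-world matrix.
#' @param seed integer RNG seed.
#' @param amplitude_range,frequency_range ranges (mm, cycles/mm) the
#'   per-axis amplitudes and frequencies are drawn from uniformly.
#'   Defaults keep every draw within the invertibility bound.
#' @return list of `2*n_pairs` [deformation_field()]s, ordered
#'   `d1, -d1, d2, -d2, ...`, with attributes `specs` (the drawn
#'   [sinusoid_spec()]s) and `inversion_residual` (voxels, one per pair).
#' @export
generate_sinusoid_family <- function(n_pairs, shape, affine = diag(4),
                                     seed = 1L,
                                     amplitude_range = c(0.5, 2),
                                     frequency_range = c(0.005, 0.025)) {
  stopifnot(n_pairs >= 1L, length(shape) == 3L)
  set.seed(seed)
  specs <- vector("list", n_pairs)
  fields <- vector("list", 2L * n_pairs)
  residual <- numeric(n_pairs)
  vs <- voxel_size(affine)
  for (p in seq_len(n_pairs)) {
    dirv <- rnorm(3)
    specs[[p]] <- sinusoid_spec(
      amplitude = runif(3, amplitude_range[1], amplitude_range[2]),
      frequency = runif(3, frequency_range[1], frequency_range[2]),
      phase = runif(3, 0, 2 * pi),
      direction = dirv / sqrt(sum(dirv^2)))
    disp <- render_sinusoid(specs[[p]], shape, affine)
    d <- deformation_field(disp, affine, source_space = "native",
                           target_space = "native")
    dneg <- deformation_field(-disp, affine, source_space = "native",
                              target_space = "native")
    fields[[2L * p - 1L]] <- d
    fields[[2L * p]] <- dneg
    residual[p] <- composition_residual(d, dneg) / min(vs)
  }
  attr(fields, "specs") <- specs
  attr(fields, "inversion_residual") <- residual
  fields
}

# Max norm (mm) of x + u2(x) + u1(x + u2(x)) - x over the grid: how far the
# composition of d1 after d2 is from the identity.
composition_residual <- function(d1, d2) {
  X <- grid_world(d2$shape, d2$affine)
  y <- X + matrix(d2$disp, ncol = 3L)
  u1 <- interp_field(d1, y)
  max(sqrt(rowSums((y + u1 - X)^2)))
}

# Displacement of a field at world points, border-clamped trilinear.
interp_field <- function(d, points) {
  vox <- world_to_voxel(points, d$affine)
  for (a in 1:3) vox[, a] <- pmin(pmax(vox[, a], 1), d$shape[a])
  interp_trilinear(d$disp, vox)
}

# Local Jacobian F = I + du/dx (world units) of a field's pull-back map,
# as an n x 9 matrix of column-major 3x3 blocks.
field_jacobian <- function(d) {
  n <- prod(d$shape)
  J <- matrix(0, n, 9L)
  for (c in 1:3) {
    g <- gradient_mm(array(d$disp[, , , c], d$shape), d$affine)
    for (a in 1:3) {
      col <- (a - 1L) * 3L + c          # column-major: entry (c, a)
      J[, col] <- as.vector(g[, , , a]) + as.numeric(a == c)
    }
  }
  J
}

#' Warp a tensor volume with reorientation
#'
#' Resamples tensors at the pulled-back positions `x + u(x)` and reorients
#' each sampled tensor by the rotational part of the local Jacobian of the
#' map (finite strain: polar-decomposition rotation; `ppd`: preservation
#' of principal directions).  Interpolation is trilinear, componentwise,
#' on log-tensors by default (positive-definiteness preserved); the
#' eigenvalue multiset is preserved under pure-rotation fields to
#' interpolation tolerance.
#'
#' @param t a [tensor_volume()].
#' @param d a [deformation_field()] whose grid defines the output.
#' @param reorient `"finite_strain"` (default) or `"ppd"`.
#' @param interp_domain `"log_euclidean"` (default) or `"euclidean"`.
#' @return a [tensor_volume()] on `d`'s grid; voxels mapped outside `t`
#'   are masked out and their fraction reported as attribute
#'   `outside_fraction`.
#' @export
warp_tensor_volume <- function(t, d, reorient = c("finite_strain", "ppd"),
                               interp_domain = c("log_euclidean",
                                                 "euclidean")) {
  reorient <- match.arg(reorient)
  interp_domain <- match.arg(interp_domain)
  stopifnot(inherits(t, "tensor_volume"), inherits(d, "deformation_field"))
  X <- grid_world(d$shape, d$affine)
  pts <- X + matrix(d$disp, ncol = 3L)
  vox <- world_to_voxel(pts, t$affine)

  inside <- vox[, 1] >= 1 & vox[, 1] <= t$shape[1] &
            vox[, 2] >= 1 & vox[, 2] <= t$shape[2] &
            vox[, 3] >= 1 & vox[, 3] <= t$shape[3]
  src <- t$tensors
  if (interp_domain == "log_euclidean")
    src <- array(log_tensor6(tensors_as_matrix(t)), dim(t$tensors))
  # border-replicated sampling: out-of-volume voxels get boundary tensors
  # but are excluded from the mask
  samp <- interp_trilinear(src, vox, clamp = TRUE)
  if (interp_domain == "log_euclidean") samp <- exp_tensor6(samp)
  mask_src <- interp_nearest(t$mask, clamp_vox(vox, t$shape))
  mask <- array(inside & !is.na(mask_src) & mask_src, d$shape)

  J <- field_jacobian(d)
  out <- .reorient_batch(samp, J, as.integer(reorient == "ppd"))
  mask <- mask & array(is.finite(out[, 1]), d$shape)
  out[!is.finite(out)] <- 0
  res <- tensor_volume(array(out, c(d$shape, 6L)), d$affine, mask = mask)
  attr(res, "outside_fraction") <- mean(!inside)
  res
}

#' Warp a scalar volume
#'
#' Resamples a scalar volume at the pulled-back positions of a deformation
#' field's grid (trilinear; nearest-neighbour for the mask).
#'
#' @param vol a [scalar_volume()].
#' @param d a [deformation_field()] defining the output grid.
#' @return a [scalar_volume()] on `d`'s grid.
#' @export
warp_scalar_volume <- function(vol, d) {
  X <- grid_world(d$shape, d$affine)
  pts <- X + matrix(d$disp, ncol = 3L)
  vox <- world_to_voxel(pts, vol$affine)
  inside <- vox[, 1] >= 1 & vox[, 1] <= vol$shape[1] &
            vox[, 2] >= 1 & vox[, 2] <= vol$shape[2] &
            vox[, 3] >= 1 & vox[, 3] <= vol$shape[3]
  vals <- interp_trilinear(vol$values, vox, clamp = TRUE)
  m <- interp_nearest(vol$mask, clamp_vox(vox, vol$shape))
  mask <- array(inside & !is.na(m) & m, d$shape)
  scalar_volume(array(vals, d$shape), d$affine, mask = mask)
}

#' Deform a ground-truth tensor volume by a family of fields
#'
#' Applies [warp_tensor_volume()] once per field, emulating a simulated
#' data set of subjects deformed from one ground-truth image.
#'
#' @param gt a [tensor_volume()].
#' @param fields list of [deformation_field()]s on `gt`'s grid.
#' @param ... passed to [warp_tensor_volume()].
#' @return list of [tensor_volume()]s, one per field.
#' @export
simulate_dataset <- function(gt, fields, ...) {
  stopifnot(is.list(fields))
  lapply(fields, function(d) warp_tensor_volume(gt, d, ...))
}
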