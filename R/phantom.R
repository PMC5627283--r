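# Synthetic tensor phantom with curved bundles, a T1-like structural
# channel, per-subject anatomical variability, and a configurable
# localized group effect.

#' Phantom specification
#'
#' Defaults describe a 48^3 grid of 2 mm voxels with three bundles: a
#' straight corticospinal-like tract, an arc (callosal-like) and an
#' S-curve (cingulum-like), with eigenvalues (1.7, 0.4, 0.2)e-3 mm^2/s in
#' an isotropic 0.7e-3 background.  The radial eigenvalues are distinct so
#' the full eigenframe is well-defined (as in real white matter), which
#' keeps orientation metrics such as OVL stable; the secondary eigenvector
#' follows a consistent reference frame along each tube.
#'
#' @param shape grid dimensions.
#' @param voxel_mm isotropic voxel size, mm.
#' @param bundles list of bundle specs: `list(name, centerline (m x 3
#'   world mm), radius (mm), evals (axial, radial1, radial2) mm^2/s)`.
#' @param background_evals isotropic background eigenvalue, mm^2/s.
#' @param structural_intensities list with `wm` and `gm` channel
#'   intensities.
#' @param seed RNG seed for the structural background texture.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(48L, 48L, 48L), voxel_mm = 2,
                         bundles = NULL,
                         background_evals = 0.7e-3,
                         structural_intensities = list(wm = 1, gm = 0.55),
                         seed = 42L) {
  ext <- (shape - 1) * voxel_mm
  if (is.null(bundles)) {
    zline <- seq(0.1, 0.9, length.out = 40L)
    theta <- seq(20, 160, length.out = 60L) * pi / 180
    xs <- seq(0.1, 0.9, length.out = 50L)
    bundles <- list(
      list(name = "cst",
           centerline = cbind(0.25 * ext[1], 0.67 * ext[2], zline * ext[3]),
           radius = 4, evals = c(1.7e-3, 0.4e-3, 0.2e-3)),
      list(name = "cc",
           centerline = cbind(0.5 * ext[1] + 0.25 * ext[1] * cos(theta),
                              0.3 * ext[2] + 0.25 * ext[2] * sin(theta),
                              rep(0.3 * ext[3], length(theta))),
           radius = 4, evals = c(1.7e-3, 0.4e-3, 0.2e-3)),
      list(name = "cg",
           centerline = cbind(xs * ext[1],
                              0.75 * ext[2] +
                                0.07 * ext[2] * sin(2 * pi * (xs - 0.1)),
                              rep(0.62 * ext[3], length(xs))),
           radius = 3.5, evals = c(1.7e-3, 0.4e-3, 0.2e-3))
    )
  }
  structure(list(shape = as.integer(shape), voxel_mm = voxel_mm,
                 bundles = bundles, background_evals = background_evals,
                 structural_intensities = structural_intensities,
                 seed = seed),
            class = "phantom_spec")
}

# Densely resample a centerline (chord-length parameterized spline) and
# return samples, unit tangents and arc fractions.
densify_centerline <- function(ctrl, step_mm = 1) {
  seg <- sqrt(rowSums(diff(ctrl)^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  s <- seq(0, total, by = step_mm)
  if (s[length(s)] < total) s <- c(s, total)
  P <- sapply(1:3, function(c)
    stats::spline(cum, ctrl[, c], xout = s, method = "natural")$y)
  tang <- rbind(P[2, ] - P[1, ],
                (P[-(1:2), , drop = FALSE] -
                 P[seq_len(nrow(P) - 2L), , drop = FALSE]) / 2,
                P[nrow(P), ] - P[nrow(P) - 1L, ])
  tang <- tang / sqrt(rowSums(tang^2))
  list(points = P, tangents = tang, arc_fraction = s / total)
}

#' Build the ground-truth tensor phantom
#'
#' Tensors inside each bundle's tube have their principal axis along the
#' centerline tangent at the nearest centerline sample (secondary axis
#' from a consistent reference frame); the background is isotropic.  Overlapping bundles are resolved
#' by the nearest centerline (overlap fraction reported).  The structural
#' channel is homogeneous inside white matter and carries a smooth,
#' seeded texture outside.  The atlas holds one tube mask per bundle plus
#' a mid-tract waypoint slab per bundle (`<name>_mid`).
#'
#' @param spec a [phantom_spec()].
#' @return object of class `phantom`: list with `tensor`
#'   ([tensor_volume()]), `structural` ([scalar_volume()]), `atlas`
#'   ([roi_atlas()]), `arc` (per-bundle arc-fraction arrays, NA outside
#'   the tube), `tangent` (per-bundle `(nx,ny,nz,3)` arrays), `spec`, and
#'   attribute `overlap_fraction`.
#' @export
build_phantom <- function(spec = phantom_spec()) {
  shape <- spec$shape
  affine <- diag(c(rep(spec$voxel_mm, 3), 1))
  nvox <- prod(shape)
  tensors <- matrix(0, nvox, 6L)
  bg <- spec$background_evals
  tensors[, c(1, 3, 6)] <- bg
  bestdist <- array(Inf, shape)
  owner <- array(0L, shape)
  arc <- list(); tangent <- list()
  masks <- list()

  for (bi in seq_along(spec$bundles)) {
    b <- spec$bundles[[bi]]
    cl <- densify_centerline(b$centerline)
    arc_arr <- array(NA_real_, shape)
    tan_arr <- array(0, c(shape, 3L))
    lo <- pmax(floor(world_to_voxel(apply(cl$points, 2, min), affine) -
                     b$radius / spec$voxel_mm - 1), 1)
    hi <- pmin(ceiling(world_to_voxel(apply(cl$points, 2, max), affine) +
                       b$radius / spec$voxel_mm + 1), shape)
    ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
    sub <- as.matrix(expand.grid(i = ii, j = jj, k = kk))
    W <- voxel_to_world(sub, affine)
    # nearest centerline sample per voxel (chunked distance computation)
    nseg <- nrow(cl$points)
    nn <- integer(nrow(W)); nd <- numeric(nrow(W))
    chunk <- max(1L, floor(2e6 / nseg))
    for (s0 in seq(1, nrow(W), by = chunk)) {
      s1 <- min(s0 + chunk - 1L, nrow(W))
      D2 <- outer(rowSums(W[s0:s1, , drop = FALSE]^2), rep(1, nseg)) +
            outer(rep(1, s1 - s0 + 1L), rowSums(cl$points^2)) -
            2 * W[s0:s1, , drop = FALSE] %*% t(cl$points)
      nn[s0:s1] <- max.col(-D2, ties.method = "first")
      nd[s0:s1] <- sqrt(pmax(D2[cbind(seq_len(s1 - s0 + 1L), nn[s0:s1])], 0))
    }
    intube <- nd <= b$radius
    lin <- (sub[, 3] - 1) * shape[1] * shape[2] +
           (sub[, 2] - 1) * shape[1] + sub[, 1]
    lin_in <- lin[intube]
    closer <- nd[intube] < bestdist[lin_in]
    take <- lin_in[closer]
    bestdist[take] <- nd[intube][closer]
    owner[take] <- bi

    arc_arr[lin_in] <- cl$arc_fraction[nn[intube]]
    for (c in 1:3)
      tan_arr[lin_in + (c - 1L) * nvox] <- cl$tangents[nn[intube], c]
    arc[[b$name]] <- arc_arr
    tangent[[b$name]] <- tan_arr
    mask <- array(FALSE, shape); mask[lin_in] <- TRUE
    masks[[b$name]] <- mask
  }

  # assign bundle tensors by owner (dominant bundle where tubes overlap)
  n_overlap <- 0L
  for (bi in seq_along(spec$bundles)) {
    b <- spec$bundles[[bi]]
    sel <- which(owner == bi)
    n_overlap <- n_overlap + sum(masks[[b$name]]) - length(sel)
    tg <- cbind(tangent[[b$name]][sel],
                tangent[[b$name]][sel + nvox],
                tangent[[b$name]][sel + 2L * nvox])
    tensors[sel, ] <- frame_tensor6(tg, bundle_evals(b))
  }

  wm <- owner > 0L
  set.seed(spec$seed)
  texture <- gaussian_smooth_vox(array(rnorm(nvox), shape),
                                 rep(6 / spec$voxel_mm, 3))
  texture <- texture / max(abs(texture))
  struct <- array(spec$structural_intensities$gm + 0.08 * texture, shape)
  struct[wm] <- spec$structural_intensities$wm

  for (b in spec$bundles) {
    mid <- array(FALSE, shape)
    a <- arc[[b$name]]
    mid[!is.na(a) & abs(a - 0.5) <= 0.07] <- TRUE
    masks[[paste0(b$name, "_mid")]] <- mid
  }
  masks[["background"]] <- !wm

  ph <- structure(list(
    tensor = tensor_volume(array(tensors, c(shape, 6L)), affine),
    structural = scalar_volume(struct, affine),
    atlas = roi_atlas(masks, affine),
    arc = arc, tangent = tangent, spec = spec
  ), class = "phantom")
  attr(ph, "overlap_fraction") <- n_overlap / max(sum(wm), 1L)
  ph
}

bundle_evals <- function(b) {
  ev <- b$evals
  if (length(ev) == 2L) ev <- c(ev[1], ev[2], ev[2])
  ev
}

# Packed tensors l1 t t' + l2 e2 e2' + l3 e3 e3' for unit tangents `tg`
# (n x 3).  The secondary axis e2 follows a consistent reference
# direction (z-hat, or y-hat where the tangent is nearly axial) so the
# eigenframe varies smoothly along a tube.
frame_tensor6 <- function(tg, evals) {
  n <- nrow(tg)
  ref <- matrix(rep(c(0, 0, 1), each = n), n, 3L)
  axial <- abs(tg[, 3]) > 0.9
  ref[axial, ] <- matrix(rep(c(0, 1, 0), each = sum(axial)), ncol = 3L)
  e2 <- ref - rowSums(ref * tg) * tg
  e2 <- e2 / sqrt(rowSums(e2^2))
  e3 <- cbind(tg[, 2] * e2[, 3] - tg[, 3] * e2[, 2],
              tg[, 3] * e2[, 1] - tg[, 1] * e2[, 3],
              tg[, 1] * e2[, 2] - tg[, 2] * e2[, 1])
  out <- matrix(0, n, 6L)
  for (j in 1:3) {
    v <- switch(j, tg, e2, e3)
    l <- evals[j]
    out[, 1] <- out[, 1] + l * v[, 1]^2
    out[, 2] <- out[, 2] + l * v[, 1] * v[, 2]
    out[, 3] <- out[, 3] + l * v[, 2]^2
    out[, 4] <- out[, 4] + l * v[, 1] * v[, 3]
    out[, 5] <- out[, 5] + l * v[, 2] * v[, 3]
    out[, 6] <- out[, 6] + l * v[, 3]^2
  }
  out
}

# Radial scale s achieving FA(l1, s l2, s l3) = fa_target (FA decreases
# as the radial eigenvalues grow toward l1).
radial_scale_for_fa <- function(evals, fa_target) {
  stopifnot(fa_target >= 0)
  f <- function(s) fa_from_lambdas(matrix(c(evals[1], s * evals[2],
                                            s * evals[3]), 1))[1] - fa_target
  upper <- evals[1] / max(evals[2:3])
  if (f(upper) > 0) return(upper)
  stats::uniroot(f, c(1, upper), tol = 1e-12)$root
}

# Apply an FA reduction of `delta` inside one bundle's arc interval by a
# common rescaling of the radial eigenvalues (axial kept fixed):
# D' = s D + (1 - s) l1 t t'.
apply_fa_effect <- function(phantom, bundle, interval, delta) {
  stopifnot(delta >= 0)
  a <- phantom$arc[[bundle]]
  if (is.null(a)) stop("unknown bundle: ", bundle)
  sel <- which(!is.na(a) & a >= interval[1] & a <= interval[2])
  t <- phantom$tensor
  if (!length(sel) || delta == 0) return(t)
  nvox <- prod(t$shape)
  b <- Filter(function(x) x$name == bundle, phantom$spec$bundles)[[1]]
  ev <- bundle_evals(b)
  fa0 <- fa_from_lambdas(matrix(ev, 1))[1]
  s <- radial_scale_for_fa(ev, max(fa0 - delta, 0))
  tg <- phantom$tangent[[bundle]]
  t1 <- tg[sel]; t2 <- tg[sel + nvox]; t3 <- tg[sel + 2L * nvox]
  tens <- t$tensors
  l1 <- ev[1]
  outer6 <- list(t1 * t1, t1 * t2, t2 * t2, t1 * t3, t2 * t3, t3 * t3)
  for (c in 1:6) {
    idx <- sel + (c - 1L) * nvox
    tens[idx] <- s * tens[idx] + (1 - s) * l1 * outer6[[c]]
  }
  tensor_volume(tens, t$affine, mask = t$mask)
}

#' Cohort specification
#'
#' @param n_per_group subjects per group.
#' @param warp_amplitude_range,warp_frequency_range per-axis ranges (mm,
#'   cycles/mm) for the random subject warps; defaults satisfy the
#'   invertibility bound.
#' @param effect list `(bundle, interval, delta)`: FA reduction `delta`
#'   applied to group B inside the bundle's arc-fraction interval (in
#'   anatomical space, before warping).
#' @param noise list `(kind = "none"|"tensor_jitter"|"rician", sigma, snr)`.
#' @param seed RNG seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 10L,
                        warp_amplitude_range = c(0.5, 1.5),
                        warp_frequency_range = c(0.005, 0.02),
                        effect = list(bundle = "cc",
                                      interval = c(0.4, 0.6),
                                      delta = 0.1),
                        noise = list(kind = "none"),
                        seed = 1L) {
  stopifnot(n_per_group >= 1L,
            effect$interval[1] >= 0, effect$interval[2] <= 1,
            effect$interval[1] < effect$interval[2])
  structure(list(n_per_group = as.integer(n_per_group),
                 warp_amplitude_range = warp_amplitude_range,
                 warp_frequency_range = warp_frequency_range,
                 effect = effect, noise = noise, seed = seed),
            class = "cohort_spec")
}

#' Generate a two-group cohort from a phantom
#'
#' Each subject is the ground-truth phantom (group B: with the FA effect
#' applied first, in anatomical space) warped by a random sinusoidal
#' field, with optional noise.  The true warp is stored per subject so
#' registration accuracy can be evaluated against ground truth.
#'
#' @param phantom a [build_phantom()] result.
#' @param spec a [cohort_spec()].
#' @return list of subject records: `id`, `group` ("A"/"B"), `tensor`
#'   (native-space [tensor_volume()]), `structural`, `true_warp` (the
#'   [deformation_field()] used to create the subject; it maps
#'   subject-grid points into anatomical space, so registering the
#'   subject back to the phantom should recover its inverse).
#' @export
make_cohort <- function(phantom, spec = cohort_spec()) {
  set.seed(spec$seed)
  affected <- NULL
  n <- spec$n_per_group
  records <- vector("list", 2L * n)
  aff <- phantom$tensor$affine
  shape <- phantom$tensor$shape
  for (s in seq_len(2L * n)) {
    group <- if (s <= n) "A" else "B"
    base <- phantom$tensor
    if (group == "B" && spec$effect$delta > 0) {
      if (is.null(affected))
        affected <- apply_fa_effect(phantom, spec$effect$bundle,
                                    spec$effect$interval, spec$effect$delta)
      base <- affected
    }
    sp <- NULL
    attempts <- 0L
    repeat {
      attempts <- attempts + 1L
      dirv <- rnorm(3)
      sp <- tryCatch(sinusoid_spec(
        amplitude = runif(3, spec$warp_amplitude_range[1],
                          spec$warp_amplitude_range[2]),
        frequency = runif(3, spec$warp_frequency_range[1],
                          spec$warp_frequency_range[2]),
        phase = runif(3, 0, 2 * pi),
        direction = dirv), error = function(e) NULL)
      if (!is.null(sp)) break
      if (attempts > 20L) stop("could not draw an invertible subject warp")
    }
    d <- deformation_field(render_sinusoid(sp, shape, aff), aff,
                           source_space = "anatomical",
                           target_space = paste0("subject", s))
    tens <- warp_tensor_volume(base, d)
    struct <- warp_scalar_volume(phantom$structural, d)
    if (identical(spec$noise$kind, "tensor_jitter")) {
      jit <- array(rnorm(length(tens$tensors), sd = spec$noise$sigma),
                   dim(tens$tensors))
      tens <- tensor_volume(tens$tensors + jit, aff, mask = tens$mask)
    } else if (identical(spec$noise$kind, "rician")) {
      sch <- gradient_scheme()
      dwis <- simulate_dwis(tens, sch$bvals, sch$bvecs,
                            snr = spec$noise$snr)
      tens <- fit_tensors(dwis, sch$bvals, sch$bvecs)
    }
    records[[s]] <- list(id = sprintf("sub%02d", s), group = group,
                         tensor = tens, structural = struct,
                         true_warp = d, warp_spec = sp,
                         warp_attempts = attempts)
  }
  records
}

#' Deterministic diffusion gradient scheme
#'
#' `n_b0` unweighted volumes followed by `n_dir` directions spread on the
#' sphere by the golden-angle (Fibonacci) construction.
#'
#' @param n_dir number of diffusion-weighted directions (default 30).
#' @param n_b0 number of b=0 volumes (default 5).
#' @param bval diffusion weighting, s/mm^2 (default 1000).
#' @return list with `bvals` and `bvecs`.
#' @export
gradient_scheme <- function(n_dir = 30L, n_b0 = 5L, bval = 1000) {
  i <- seq_len(n_dir) - 0.5
  z <- 1 - 2 * i / n_dir
  r <- sqrt(pmax(1 - z^2, 0))
  phi <- pi * (1 + sqrt(5)) * i
  g <- cbind(r * cos(phi), r * sin(phi), z)
  list(bvals = c(rep(0, n_b0), rep(bval, n_dir)),
       bvecs = rbind(matrix(0, n_b0, 3L), g))
}

#' Simulate diffusion-weighted volumes from a tensor volume
#'
#' `S = S0 exp(-b g' D g)` per direction, with optional Rician noise at
#' the given SNR (relative to S0).  Projections `g' D g` that come out
#' negative (non-positive-semidefinite tensors) are floored at zero and
#' counted (attribute `n_floored` on the first volume).
#'
#' @param t a [tensor_volume()].
#' @param bvals,bvecs gradient table as in [gradient_scheme()].
#' @param snr Rician signal-to-noise ratio on S0, or `NULL` for
#'   noise-free.
#' @param s0 unweighted signal level.
#' @return list of [scalar_volume()]s, one per gradient row.
#' @export
simulate_dwis <- function(t, bvals, bvecs, snr = NULL, s0 = 100) {
  stopifnot(inherits(t, "tensor_volume"), length(bvals) == nrow(bvecs))
  if (!is.null(snr)) stopifnot(snr > 0)
  m <- tensors_as_matrix(t)
  n_floored <- 0L
  out <- vector("list", length(bvals))
  for (i in seq_along(bvals)) {
    g <- bvecs[i, ]
    q <- bvals[i] * (g[1]^2 * m[, 1] + 2 * g[1] * g[2] * m[, 2] +
                     g[2]^2 * m[, 3] + 2 * g[1] * g[3] * m[, 4] +
                     2 * g[2] * g[3] * m[, 5] + g[3]^2 * m[, 6])
    n_floored <- n_floored + sum(q < 0)
    S <- s0 * exp(-pmax(q, 0))
    if (!is.null(snr)) {
      sigma <- s0 / snr
      S <- sqrt((S + rnorm(length(S), sd = sigma))^2 +
                rnorm(length(S), sd = sigma)^2)
    }
    out[[i]] <- scalar_volume(array(S, t$shape), t$affine, mask = t$mask)
  }
  attr(out[[1]], "n_floored") <- n_floored
  out
}
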