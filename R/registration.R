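# Scalar-image registration: multiresolution affine (SSD), B-spline
# free-form deformation with bending-energy regularization, groupwise
# mean-deformation normalization, transform composition, field inversion.

# ---- image pyramid -------------------------------------------------------

# Downsample by 2 along each axis (Gaussian presmoothing, 1 voxel sigma).
downsample_volume <- function(vol) {
  sm <- gaussian_smooth_vox(vol$values, c(1, 1, 1))
  ix <- seq(1, vol$shape[1], by = 2)
  iy <- seq(1, vol$shape[2], by = 2)
  iz <- seq(1, vol$shape[3], by = 2)
  aff <- vol$affine
  aff[1:3, 1:3] <- aff[1:3, 1:3] * 2
  scalar_volume(sm[ix, iy, iz, drop = FALSE], aff,
                mask = vol$mask[ix, iy, iz, drop = FALSE])
}

build_pyramid <- function(vol, levels, min_axis = 12L) {
  pyr <- list(vol)
  for (l in seq_len(levels - 1L)) {
    if (min(pyr[[1]]$shape) < 2L * min_axis) break
    pyr <- c(list(downsample_volume(pyr[[1]])), pyr)
  }
  pyr  # coarse first
}

# In-level Gaussian smoothing (voxels) applied to both images before the
# SSD is evaluated; sharp binary-like features make the interpolated
# image gradient inconsistent with the true interpolant slope, so a
# little smoothing is essential for descent (FNIRT does the same).
smooth_level <- function(vol, sigma_vox) {
  if (sigma_vox <= 0) return(vol)
  scalar_volume(gaussian_smooth_vox(vol$values, rep(sigma_vox, 3)),
                vol$affine, mask = vol$mask)
}

# Moving image packed with its mm-space gradient: (nx,ny,nz,4).
pack_moving <- function(vol) {
  g <- gradient_mm(vol$values, vol$affine)
  arr <- array(0, c(vol$shape, 4L))
  arr[, , , 1] <- vol$values
  arr[, , , 2:4] <- g
  arr
}

# ---- affine registration -------------------------------------------------

#' Affine registration of two scalar volumes
#'
#' 12-parameter (linear map + translation) registration minimizing the
#' mean squared intensity difference under a multiresolution schedule,
#' using analytic gradients and BFGS.  Parameters act about the center of
#' the fixed field of view.
#'
#' @param moving,fixed [scalar_volume()]s with overlapping fields of view.
#' @param levels multiresolution levels (default 3).
#' @param maxit simplex iterations per level.
#' @param smooth_vox in-level Gaussian smoothing (voxels) applied to both
#'   images; set 0 for already-smooth images.
#' @return an [affine_transform()] mapping fixed-space world points to
#'   moving-space world points (pull-back; resample `moving` through it),
#'   with attribute `ssd` = c(before, after) at full resolution.
#' @export
register_affine <- function(moving, fixed, levels = 3L,
                            maxit = 1500L, smooth_vox = 1) {
  stopifnot(inherits(moving, "scalar_volume"), inherits(fixed, "scalar_volume"))
  if (sd(fixed$values[fixed$mask]) == 0 || sd(moving$values[moving$mask]) == 0)
    stop("degenerate (constant) image: affine registration has no signal")
  # simplex optimization tolerates badly aliased coarse levels poorly, so
  # the affine pyramid never drops below 16 voxels per axis
  pyrM <- build_pyramid(moving, levels, min_axis = 16L)
  pyrF <- build_pyramid(fixed, levels, min_axis = 16L)
  nlev <- min(length(pyrM), length(pyrF))
  pyrM <- pyrM[seq(length(pyrM) - nlev + 1L, length(pyrM))]
  pyrF <- pyrF[seq(length(pyrF) - nlev + 1L, length(pyrF))]
  maxit <- rep_len(maxit, nlev)

  ctr <- voxel_to_world((fixed$shape + 1) / 2, fixed$affine)[1, ]
  p <- numeric(12)
  for (l in seq_len(nlev)) {
    fx <- smooth_level(pyrF[[l]], smooth_vox)
    mv <- smooth_level(pyrM[[l]], smooth_vox)
    X <- grid_world(fx$shape, fx$affine)
    keep <- as.vector(fx$mask)
    X <- X[keep, , drop = FALSE]
    fvals <- fx$values[keep]
    Xc <- sweep(X, 2, ctr)
    packed <- pack_moving(mv)
    n <- nrow(X)

    cache <- new.env(parent = emptyenv())
    evalp <- function(p) {
      key <- paste(p, collapse = ",")
      if (identical(cache$key, key)) return(cache$val)
      B <- diag(3) + matrix(p[1:9], 3, 3)
      pts <- Xc %*% t(B) + rep(ctr + p[10:12], each = n)
      samp <- interp_trilinear(packed, world_to_voxel(pts, mv$affine),
                               clamp = TRUE)
      r <- samp[, 1] - fvals
      grad_pts <- samp[, 2:4, drop = FALSE]
      f <- sum(r^2) / n
      w <- 2 * r / n
      gB <- crossprod(w * grad_pts, Xc)      # d/dB[i,j]
      gt <- colSums(w * grad_pts)
      val <- list(f = f, g = c(as.vector(gB), gt))
      cache$key <- key; cache$val <- val
      val
    }
    # Nelder-Mead rather than quasi-Newton: the analytic gradient of a
    # trilinearly interpolated objective is only approximately consistent
    # with the objective and stalls BFGS in voxel-scale wiggles.  Each
    # level restarts the simplex both from the carried-over parameters
    # and from a BFGS warm start, keeping whichever converges lower.
    # parscale makes a unit step in any scaled coordinate move edge
    # voxels by about 1 mm.
    L <- mean((fixed$shape - 1) * voxel_size(fixed$affine)) / 2
    pscale <- c(rep(1 / L, 9), rep(1, 3))
    warm <- stats::optim(p, fn = function(p) evalp(p)$f,
                         gr = function(p) evalp(p)$g,
                         method = "BFGS",
                         control = list(maxit = 60L, reltol = 1e-10,
                                        parscale = pscale))$par
    best <- NULL
    for (start in list(p, warm)) {
      q <- start
      for (round in seq_len(if (l == nlev) 2L else 1L)) {
        opt <- stats::optim(q, fn = function(p) evalp(p)$f,
                            method = "Nelder-Mead",
                            control = list(maxit = maxit[l],
                                           reltol = 1e-13,
                                           parscale = pscale))
        q <- opt$par
      }
      if (is.null(best) || opt$value < best$value)
        best <- list(par = q, value = opt$value)
    }
    p <- best$par
  }

  B <- diag(3) + matrix(p[1:9], 3, 3)
  if (det(B) <= 0) stop("affine registration collapsed (non-positive det)")
  M <- diag(4)
  M[1:3, 1:3] <- B
  M[1:3, 4] <- ctr + p[10:12] - B %*% ctr
  tr <- affine_transform(M, source_space = "moving", target_space = "fixed")
  attr(tr, "ssd") <- c(before = affine_ssd(moving, fixed, diag(4)),
                       after = affine_ssd(moving, fixed, M))
  tr
}

affine_ssd <- function(moving, fixed, M) {
  X <- grid_world(fixed$shape, fixed$affine)[as.vector(fixed$mask), ,
                                             drop = FALSE]
  pts <- sweep(X %*% t(M[1:3, 1:3]), 2, M[1:3, 4], "+")
  s <- interp_trilinear(moving$values, world_to_voxel(pts, moving$affine),
                        clamp = TRUE)
  mean((s - fixed$values[fixed$mask])^2)
}

# ---- B-spline lattice ----------------------------------------------------

# Cubic B-spline basis matrix for world coordinates x (1-D), knots spaced
# `s` starting at xmin.  Returns n x (m+3) dense matrix.
bspline_basis_1d <- function(x, xmin, s, m) {
  t <- (x - xmin) / s
  i0 <- pmin(pmax(floor(t), 0), m - 1)
  u <- t - i0
  u2 <- u * u; u3 <- u2 * u
  w <- cbind((1 - u)^3 / 6,
             (3 * u3 - 6 * u2 + 4) / 6,
             (-3 * u3 + 3 * u2 + 3 * u + 1) / 6,
             u3 / 6)
  B <- matrix(0, length(x), m + 3L)
  for (k in 0:3) B[cbind(seq_along(x), i0 + k + 1L)] <- w[, k + 1L]
  B
}

# arr (a x b x c) -> Mx arr x1 My x2 Mz x3 (mode products along each axis).
tensor3_prod <- function(arr, Mx, My, Mz) {
  d <- dim(arr)
  a1 <- Mx %*% matrix(arr, d[1])
  arr <- array(a1, c(nrow(Mx), d[2], d[3]))
  arr <- aperm(arr, c(2, 1, 3))
  a2 <- My %*% matrix(arr, d[2])
  arr <- array(a2, c(nrow(My), nrow(Mx), d[3]))
  arr <- aperm(arr, c(3, 2, 1))
  a3 <- Mz %*% matrix(arr, d[3])
  arr <- array(a3, c(nrow(Mz), nrow(Mx), nrow(My)))
  aperm(arr, c(2, 3, 1))
}

# Second-difference bending penalty on a control-coefficient array.
bend_penalty <- function(C) {
  val <- 0
  G <- array(0, dim(C))
  for (axis in 1:3) {
    n <- dim(C)[axis]
    if (n < 3L) next
    sl <- function(idx) switch(axis, C[idx, , , drop = FALSE],
                               C[, idx, , drop = FALSE],
                               C[, , idx, drop = FALSE])
    i <- 2:(n - 1L)
    E <- sl(i + 1L) - 2 * sl(i) + sl(i - 1L)
    val <- val + sum(E^2)
    add <- function(idx, v) {
      if (axis == 1L) G[idx, , ] <<- G[idx, , ] + v
      else if (axis == 2L) G[, idx, ] <<- G[, idx, ] + v
      else G[, , idx] <<- G[, , idx] + v
    }
    add(i + 1L, 2 * E); add(i - 1L, 2 * E); add(i, -4 * E)
  }
  list(value = val, grad = G)
}

default_nonlinear_cfg <- function() {
  list(control_spacing = 4,     # voxels of the fixed grid
       levels = 3L,
       iterations = c(60L, 40L, 25L),
       bending_weight = 1e-4,
       smooth_vox = 1,
       verbose = FALSE)
}

#' Nonlinear B-spline registration of two scalar volumes
#'
#' Free-form deformation parameterized by a cubic B-spline control lattice
#' over the fixed image's field of view, minimizing mean squared intensity
#' difference plus a bending-energy penalty on the control coefficients,
#' by gradient descent with backtracking line search under a
#' multiresolution schedule.  The lattice lives in world space, so
#' coefficients transfer unchanged between pyramid levels.
#'
#' @param moving,fixed [scalar_volume()]s, already affinely aligned.
#' @param cfg list overriding any of: `control_spacing` (voxels of the
#'   fixed grid, default 4), `levels` (3), `iterations` (per level, coarse
#'   to fine, default 60/40/25), `bending_weight` (1e-4, on the
#'   per-coefficient mean squared second difference), `smooth_vox`
#'   (in-level Gaussian smoothing, voxels, default 1).
#' @return a [deformation_field()] on the fixed grid (resample `moving`
#'   through it), with attribute `ssd` = c(before, after) at full
#'   resolution.  A level that fails to reduce its energy triggers a
#'   warning and returns the best coefficients found.
#' @export
register_nonlinear <- function(moving, fixed, cfg = list()) {
  stopifnot(inherits(moving, "scalar_volume"), inherits(fixed, "scalar_volume"))
  cfg <- utils::modifyList(default_nonlinear_cfg(), cfg)
  A3 <- fixed$affine[1:3, 1:3]
  if (max(abs(A3 - diag(diag(A3)))) > 1e-8)
    stop("nonlinear registration requires an axis-aligned affine")
  vs <- voxel_size(fixed$affine)
  s_mm <- cfg$control_spacing * vs
  x0 <- fixed$affine[1:3, 4]
  fov <- (fixed$shape - 1) * vs
  m <- pmax(ceiling(fov / s_mm), 1)
  nc <- m + 3L
  C <- list(array(0, nc), array(0, nc), array(0, nc))  # mm, per component

  pyrM <- build_pyramid(moving, cfg$levels)
  pyrF <- build_pyramid(fixed, cfg$levels)
  nlev <- min(length(pyrM), length(pyrF))
  pyrM <- pyrM[seq(length(pyrM) - nlev + 1L, length(pyrM))]
  pyrF <- pyrF[seq(length(pyrF) - nlev + 1L, length(pyrF))]
  iters <- rep_len(cfg$iterations, nlev)

  for (l in seq_len(nlev)) {
    fx <- smooth_level(pyrF[[l]], cfg$smooth_vox)
    mv <- smooth_level(pyrM[[l]], cfg$smooth_vox)
    vsl <- voxel_size(fx$affine)
    ax <- lapply(1:3, function(a) fx$affine[a, 4] +
                                  (seq_len(fx$shape[a]) - 1) * vsl[a])
    B <- lapply(1:3, function(a)
      bspline_basis_1d(ax[[a]], x0[a], s_mm[a], m[a]))
    Bt <- lapply(B, t)
    packed <- pack_moving(mv)
    fmask <- fx$mask
    fvals <- fx$values
    X <- grid_world(fx$shape, fx$affine)
    nvox <- prod(fx$shape)

    dense_u <- function(C) {
      vapply(1:3, function(c)
        as.vector(tensor3_prod(C[[c]], B[[1]], B[[2]], B[[3]])),
        numeric(nvox))
    }
    energy <- function(C, want_grad = FALSE) {
      U <- dense_u(C)
      samp <- interp_trilinear(packed, world_to_voxel(X + U, mv$affine),
                               clamp = TRUE)
      r <- samp[, 1] - fvals
      ok <- as.vector(fmask)
      r[!ok] <- 0
      nok <- max(sum(ok), 1L)
      e <- sum(r^2) / nok
      ncoef <- 3 * prod(nc)
      pen <- lapply(C, bend_penalty)
      e <- e + cfg$bending_weight *
        sum(vapply(pen, `[[`, 0, "value")) / ncoef
      if (!want_grad) return(list(e = e))
      G <- vector("list", 3L)
      w <- 2 * r / nok
      for (c in 1:3) {
        rc <- samp[, 1 + c]
        rc[!ok] <- 0
        Rarr <- array(w * rc, fx$shape)
        G[[c]] <- tensor3_prod(Rarr, Bt[[1]], Bt[[2]], Bt[[3]]) +
          cfg$bending_weight * pen[[c]]$grad / ncoef
      }
      list(e = e, G = G)
    }

    cur <- energy(C, want_grad = TRUE)
    alpha <- 0.4 * min(vsl)            # trial step in mm (max control move)
    for (it in seq_len(iters[l])) {
      gmax <- max(vapply(cur$G, function(g) max(abs(g)), 0))
      if (gmax < 1e-14) break
      improved <- FALSE
      while (alpha > 1e-6) {
        Cn <- lapply(1:3, function(c) C[[c]] - (alpha / gmax) * cur$G[[c]])
        en <- energy(Cn, want_grad = TRUE)
        if (en$e < cur$e) {
          C <- Cn; cur <- en
          alpha <- min(alpha * 1.4, 2 * min(s_mm))
          improved <- TRUE
          break
        }
        alpha <- alpha / 2
      }
      if (!improved) break
      if (isTRUE(cfg$verbose))
        message(sprintf("level %d iter %d energy %.6g (step %.3g mm)",
                        l, it, cur$e, alpha))
    }
  }

  # dense field at full resolution
  vsf <- voxel_size(fixed$affine)
  axf <- lapply(1:3, function(a) fixed$affine[a, 4] +
                                 (seq_len(fixed$shape[a]) - 1) * vsf[a])
  Bf <- lapply(1:3, function(a)
    bspline_basis_1d(axf[[a]], x0[a], s_mm[a], m[a]))
  disp <- array(0, c(fixed$shape, 3L))
  for (c in 1:3)
    disp[, , , c] <- tensor3_prod(C[[c]], Bf[[1]], Bf[[2]], Bf[[3]])
  d <- deformation_field(disp, fixed$affine,
                         source_space = "moving", target_space = "fixed")
  ssd0 <- field_ssd(moving, fixed, NULL)
  ssd1 <- field_ssd(moving, fixed, d)
  if (ssd1 > ssd0)
    warning(sprintf("nonlinear registration did not reduce SSD (%.4g -> %.4g)",
                    ssd0, ssd1))
  attr(d, "ssd") <- c(before = ssd0, after = ssd1)
  d
}

field_ssd <- function(moving, fixed, d) {
  X <- grid_world(fixed$shape, fixed$affine)
  if (!is.null(d)) X <- X + matrix(d$disp, ncol = 3L)
  s <- interp_trilinear(moving$values, world_to_voxel(X, moving$affine),
                        clamp = TRUE)
  r <- s - as.vector(fixed$values)
  mean(r[as.vector(fixed$mask)]^2)
}

# ---- groupwise normalization --------------------------------------------

#' Groupwise mean-deformation normalization
#'
#' Implements the iterative pairwise strategy: every subject's feature
#' image is nonlinearly registered to every other subject's, and the
#' arithmetic mean of subject i's pairwise displacement fields becomes its
#' normalization field.  Optionally iterated (`group_iters`), composing
#' each round's correction onto the running field.
#'
#' @param features list (length >= 2) of [feature_image()] objects of one
#'   kind, all on a common grid.
#' @param cfg as [register_nonlinear()] plus `group_iters` (default 1).
#' @return list of [deformation_field()]s, one per subject, with
#'   attributes `mean_pairwise_ssd` = c(before, after) and `n_failed`
#'   (count of excluded pairwise registrations).
#' @export
groupwise_mean_deformation <- function(features, cfg = list()) {
  if (!is.list(features) || length(features) < 2L)
    stop("groupwise normalization needs at least 2 subjects")
  kinds <- vapply(features, `[[`, "", "kind")
  if (length(unique(kinds)) != 1L)
    stop("all features must be of the same kind")
  imgs <- lapply(features, `[[`, "image")
  ref <- imgs[[1]]
  for (im in imgs) stop_if_grid_mismatch(ref, im, "feature images")
  group_iters <- if (is.null(cfg$group_iters)) 1L else cfg$group_iters
  cfg$group_iters <- NULL
  n <- length(imgs)

  fields <- NULL
  cur <- imgs
  n_failed <- 0L
  for (iter in seq_len(group_iters)) {
    round_fields <- vector("list", n)
    for (i in seq_len(n)) {
      acc <- array(0, c(ref$shape, 3L))
      cnt <- 0L
      for (j in seq_len(n)[-i]) {
        d <- tryCatch(register_nonlinear(cur[[i]], cur[[j]], cfg),
                      error = function(e) NULL)
        if (is.null(d)) { n_failed <- n_failed + 1L; next }
        acc <- acc + d$disp
        cnt <- cnt + 1L
      }
      if (cnt < (n - 1L) / 2)
        stop("more than half of the pairwise registrations failed")
      round_fields[[i]] <- deformation_field(acc / cnt, ref$affine,
                                             source_space = "native",
                                             target_space = "group")
    }
    if (is.null(fields)) {
      fields <- round_fields
    } else {
      fields <- lapply(seq_len(n), function(i) {
        fi <- fields[[i]]; ri <- round_fields[[i]]
        fi$source_space <- "native"; fi$target_space <- "group"
        ri$source_space <- "group"; ri$target_space <- "group"
        compose(transform_chain(list(fi, ri)))
      })
    }
    cur <- lapply(seq_len(n), function(i) warp_scalar_volume(imgs[[i]],
                                                             fields[[i]]))
  }
  ssd0 <- mean_pairwise_ssd(imgs)
  warped <- lapply(seq_len(n), function(i) warp_scalar_volume(imgs[[i]],
                                                              fields[[i]]))
  ssd1 <- mean_pairwise_ssd(warped)
  attr(fields, "mean_pairwise_ssd") <- c(before = ssd0, after = ssd1)
  attr(fields, "n_failed") <- n_failed
  fields
}

mean_pairwise_ssd <- function(imgs) {
  n <- length(imgs)
  tot <- 0; cnt <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    m <- imgs[[i]]$mask & imgs[[j]]$mask
    tot <- tot + mean((imgs[[i]]$values[m] - imgs[[j]]$values[m])^2)
    cnt <- cnt + 1L
  }
  tot / cnt
}

# ---- composition and inversion ------------------------------------------

#' Transform chain
#'
#' An ordered list of [affine_transform()] / [deformation_field()] stages
#' in the order they are applied to an image (first resampling first).
#' Adjacent space tags must match: stage i+1's source space is stage i's
#' target space.
#'
#' @param stages list of transform stages.
#' @return object of class `transform_chain`.
#' @export
transform_chain <- function(stages) {
  stopifnot(is.list(stages), length(stages) >= 1L)
  for (s in stages)
    stopifnot(inherits(s, "affine_transform") ||
              inherits(s, "deformation_field"))
  if (length(stages) > 1L) {
    for (i in seq_len(length(stages) - 1L)) {
      if (!identical(stages[[i + 1L]]$source_space, stages[[i]]$target_space))
        stop(sprintf("space-tag mismatch at junction %d: '%s' vs '%s'",
                     i, stages[[i]]$target_space,
                     stages[[i + 1L]]$source_space))
    }
  }
  structure(list(stages = stages), class = "transform_chain")
}

apply_transform_points <- function(t, pts) {
  if (inherits(t, "affine_transform")) {
    sweep(pts %*% t(t$matrix[1:3, 1:3]), 2, t$matrix[1:3, 4], "+")
  } else {
    pts + interp_field(t, pts)
  }
}

#' Compose a transform chain into one dense deformation field
#'
#' Evaluates the stages in sequence at every voxel of the output grid and
#' returns a single field equivalent (to interpolation tolerance) to
#' applying the stages one after another.
#'
#' @param chain a [transform_chain()] (or plain list of stages).
#' @param shape,affine output grid; defaults to the grid of the last
#'   deformation-field stage.
#' @return a [deformation_field()].
#' @export
compose <- function(chain, shape = NULL, affine = NULL) {
  if (!inherits(chain, "transform_chain")) chain <- transform_chain(chain)
  stages <- chain$stages
  if (is.null(shape)) {
    for (s in rev(stages)) if (inherits(s, "deformation_field")) {
      shape <- s$shape; affine <- s$affine; break
    }
    if (is.null(shape))
      stop("output grid must be given for an all-affine chain")
  }
  X <- grid_world(shape, affine)
  pts <- X
  for (s in rev(stages)) pts <- apply_transform_points(s, pts)
  deformation_field(array(pts - X, c(shape, 3L)), affine,
                    source_space = stages[[1L]]$source_space,
                    target_space = stages[[length(stages)]]$target_space)
}

#' Invert a deformation field by fixed-point iteration
#'
#' Solves `u_inv(x) = -u(x + u_inv(x))` on the field's own grid.  Requires
#' the field's pull-back map to be invertible (positive Jacobian
#' determinant); errors if the composition residual does not fall below
#' tolerance.
#'
#' @param d a [deformation_field()].
#' @param tol convergence tolerance on the composition residual, in voxels
#'   (default 0.01).
#' @param max_iter maximum fixed-point iterations (default 50).
#' @return a [deformation_field()] with swapped space tags and attribute
#'   `residual` (voxels).
#' @export
invert_field <- function(d, tol = 0.01, max_iter = 50L) {
  X <- grid_world(d$shape, d$affine)
  vmin <- min(voxel_size(d$affine))
  V <- matrix(0, nrow(X), 3L)
  for (it in seq_len(max_iter)) {
    Vn <- -interp_field(d, X + V)
    delta <- max(abs(Vn - V)) / vmin
    V <- Vn
    if (delta < tol / 2) break
  }
  resid <- max(sqrt(rowSums((V + interp_field(d, X + V))^2))) / vmin
  if (resid > tol)
    stop(sprintf("field inversion did not converge: residual %.4g voxels",
                 resid))
  out <- deformation_field(array(V, c(d$shape, 3L)), d$affine,
                           source_space = d$target_space,
                           target_space = d$source_space)
  attr(out, "residual") <- resid
  out
}
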