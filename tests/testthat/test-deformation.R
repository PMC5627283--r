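# Sinusoidal deformation families and tensor warping with reorientation.

test_that("sinusoid families sum to zero exactly and respect the bound", {
  shape <- c(16L, 16L, 16L)
  aff <- diag(c(2, 2, 2, 1))
  fam <- generate_sinusoid_family(3, shape, aff, seed = 21)
  expect_length(fam, 6L)
  s <- Reduce(`+`, lapply(fam, `[[`, "disp"))
  expect_true(all(s == 0))                       # bitwise, negation is exact
  expect_equal(fam[[2]]$disp, -fam[[1]]$disp)
  for (sp in attr(fam, "specs"))
    expect_lt(sp$max_grad_norm, 0.9)
  # out-of-bound spec rejected before rendering
  expect_error(sinusoid_spec(c(5, 5, 5), c(0.05, 0.05, 0.05)),
               "invertibility")
  # determinism
  fam2 <- generate_sinusoid_family(3, shape, aff, seed = 21)
  expect_identical(fam[[1]]$disp, fam2[[1]]$disp)
})

test_that("small-amplitude negation is a near-inverse", {
  shape <- c(16L, 16L, 16L)
  aff <- diag(c(2, 2, 2, 1))
  fam <- generate_sinusoid_family(2, shape, aff, seed = 3,
                                  amplitude_range = c(0.3, 0.5),
                                  frequency_range = c(0.005, 0.01))
  expect_true(all(attr(fam, "inversion_residual") < 0.1))
})

test_that("warping: identity field, translation, eigenvalue preservation", {
  ph <- small_phantom(c(24L, 24L, 24L))
  zero <- deformation_field(array(0, c(ph$tensor$shape, 3L)),
                            ph$tensor$affine)
  w0 <- warp_tensor_volume(ph$tensor, zero)
  expect_equal(w0$tensors, ph$tensor$tensors, tolerance = 1e-12)

  # integer-voxel translation shifts the lattice exactly
  tr <- deformation_field(array(rep(c(2, 0, 0),
                                    each = prod(ph$tensor$shape)),
                                c(ph$tensor$shape, 3L)), ph$tensor$affine)
  wt <- warp_tensor_volume(ph$tensor, tr)
  expect_equal(wt$tensors[1:23, , , ], ph$tensor$tensors[2:24, , , ],
               tolerance = 1e-12)
})

test_that("global rotation reorients tensors by the closed form", {
  shape <- c(15L, 15L, 15L)
  aff <- diag(c(2, 2, 2, 1))
  tv <- const_tensor_volume(c(2, 0, 1, 0, 0, 1) * 1e-3, shape)
  ctr <- tractatlas:::voxel_to_world((shape + 1) / 2, aff)[1, ]
  th <- pi / 2
  Q <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
              3, 3, byrow = TRUE)
  X <- tractatlas:::grid_world(shape, aff)
  pts <- sweep(sweep(X, 2, ctr) %*% t(Q), 2, ctr, "+")
  d <- deformation_field(array(pts - X, c(shape, 3L)), aff)
  mid <- (shape + 1) / 2
  for (mode in c("finite_strain", "ppd")) {
    w <- warp_tensor_volume(tv, d, reorient = mode)
    es <- tractatlas:::eig_tensor6(w$tensors[mid[1], mid[2], mid[3], ])
    expect_equal(abs(es$vectors[, 1]), c(0, 1, 0), tolerance = 1e-6)
    expect_equal(es$lambdas, c(2, 1, 1) * 1e-3, tolerance = 1e-9)
  }
  # FA preserved under the constant-rotation field; both modes agree on e1
  ph <- small_phantom(c(24L, 24L, 24L))
  # use interior comparison: rotate the phantom about its center
  X2 <- tractatlas:::grid_world(ph$tensor$shape, ph$tensor$affine)
  c2 <- tractatlas:::voxel_to_world((ph$tensor$shape + 1) / 2,
                                    ph$tensor$affine)[1, ]
  p2 <- sweep(sweep(X2, 2, c2) %*% t(Q), 2, c2, "+")
  d2 <- deformation_field(array(p2 - X2, c(ph$tensor$shape, 3L)),
                          ph$tensor$affine)
  wf <- warp_tensor_volume(ph$tensor, d2, reorient = "finite_strain")
  wp <- warp_tensor_volume(ph$tensor, d2, reorient = "ppd")
  sel <- wf$mask & fa_map(wf)$values > 0.5
  e1f <- eigendecompose(wf)$vectors[, , , , 1]
  e1p <- eigendecompose(wp)$vectors[, , , , 1]
  dots <- abs(rowSums(matrix(e1f, ncol = 3)[sel, ] *
                      matrix(e1p, ncol = 3)[sel, ]))
  expect_true(all(acos(pmin(dots, 1)) < 1e-6))
})

test_that("warp round trip through the numeric inverse preserves OVL", {
  ph <- small_phantom(c(24L, 24L, 24L))
  set.seed(13)
  sp <- sinusoid_spec(runif(3, 0.8, 1.5), runif(3, 0.008, 0.02),
                      runif(3, 0, 2 * pi), rnorm(3))
  d <- deformation_field(
    tractatlas:::render_sinusoid(sp, ph$tensor$shape, ph$tensor$affine),
    ph$tensor$affine)
  w <- warp_tensor_volume(ph$tensor, d)
  wb <- warp_tensor_volume(w, invert_field(d))
  o <- ovl(wb, ph$tensor)
  fa <- fa_map(ph$tensor)
  wm <- o$mask & fa$mask & fa$values >= 0.2
  expect_gt(mean(o$values[wm]), 0.99)
})

test_that("simulate_dataset warps once per field; determinism; symmetry", {
  ph <- small_phantom(c(20L, 20L, 20L))
  fam <- generate_sinusoid_family(2, ph$tensor$shape, ph$tensor$affine,
                                  seed = 5)
  sims <- simulate_dataset(ph$tensor, fam)
  expect_length(sims, 4L)
  zero <- deformation_field(array(0, c(ph$tensor$shape, 3L)),
                            ph$tensor$affine)
  expect_equal(simulate_dataset(ph$tensor, list(zero))[[1]]$tensors,
               ph$tensor$tensors, tolerance = 1e-12)
  # a small-amplitude field and its negation deform FA symmetrically
  # (first-order regime; white-matter mean over each image's own support)
  ph32 <- small_phantom(c(32L, 32L, 32L))
  fam32 <- generate_sinusoid_family(1, ph32$tensor$shape,
                                    ph32$tensor$affine, seed = 5,
                                    amplitude_range = c(0.5, 1))
  s32 <- simulate_dataset(ph32$tensor, fam32)
  fa1 <- fa_map(s32[[1]]); fa2 <- fa_map(s32[[2]])
  m1 <- mean(fa1$values[fa1$mask & fa1$values >= 0.2])
  m2 <- mean(fa2$values[fa2$mask & fa2$values >= 0.2])
  expect_lt(abs(m1 - m2) / m1, 0.01)
  # determinism of warping
  again <- warp_tensor_volume(ph$tensor, fam[[1]])
  expect_identical(again$tensors, sims[[1]]$tensors)
})
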