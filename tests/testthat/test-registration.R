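# Registration: affine parameter recovery, nonlinear ground-truth
# recovery, groupwise normalization, composition, inversion.

test_that("affine registration: identity, translation and rotation recovery", {
  # dense analytic texture (40 blobs) pins all 12 parameters; accuracy is
  # judged on the recovered point map in mm, since rotation/translation
  # decompositions trade off freely below the interpolation-bias floor
  set.seed(2)
  ctrs <- cbind(runif(40, 8, 38), runif(40, 8, 38), runif(40, 8, 38))
  fixed <- blob_volume(centers = ctrs, sigma = 4)
  X <- tractatlas:::grid_world(fixed$shape, fixed$affine)
  map_err <- function(est, truth) {
    Minv <- solve(truth)
    pt <- sweep(X %*% t(Minv[1:3, 1:3]), 2, Minv[1:3, 4], "+")
    pe <- sweep(X %*% t(est$matrix[1:3, 1:3]), 2, est$matrix[1:3, 4], "+")
    mean(sqrt(rowSums((pt - pe)^2)))
  }

  est0 <- register_affine(fixed, fixed)
  expect_lt(map_err(est0, diag(4)), 1e-3)

  # moving(x) = fixed(Mt x): recover the pull-back map Mt^-1,
  # a translation of -(4, -2, 0) mm
  Mt <- diag(4); Mt[1:3, 4] <- c(4, -2, 0)
  est <- register_affine(blob_volume(centers = ctrs, sigma = 4, M = Mt),
                         fixed)
  expect_lt(map_err(est, Mt), 0.2)
  expect_lt(max(abs(est$matrix[1:3, 4] - c(-4, 2, 0))), 0.35)
  expect_lt(attr(est, "ssd")["after"], attr(est, "ssd")["before"])

  # 5-degree rotation about z about the volume center: point-map error
  # below 0.25 mm (the displacement a 0.5-degree error produces at the
  # fixture's 30 mm lever arm)
  th <- 5 * pi / 180
  Q <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
              3, 3, byrow = TRUE)
  ctrw <- c(23, 23, 23)
  Mr <- diag(4); Mr[1:3, 1:3] <- Q; Mr[1:3, 4] <- ctrw - Q %*% ctrw
  est_r <- register_affine(blob_volume(centers = ctrs, sigma = 4, M = Mr),
                           fixed)
  expect_lt(map_err(est_r, Mr), 0.25)

  expect_error(register_affine(scalar_volume(array(1, c(8, 8, 8))), fixed),
               "degenerate")
})

test_that("nonlinear registration: null case and ground-truth recovery", {
  ph <- small_phantom()
  fa <- fa_map(ph$tensor)
  d0 <- register_nonlinear(fa, fa, list(iterations = c(10, 5, 5)))
  expect_lt(max(abs(d0$disp)) / min(voxel_size(fa$affine)), 0.1)

  set.seed(31)
  sp <- sinusoid_spec(runif(3, 1, 1.8), runif(3, 0.008, 0.018),
                      runif(3, 0, 2 * pi), rnorm(3))
  d_true <- deformation_field(
    tractatlas:::render_sinusoid(sp, fa$shape, fa$affine), fa$affine)
  moving <- fa_map(warp_tensor_volume(ph$tensor, d_true))
  d_est <- register_nonlinear(moving, fa)
  expect_lte(attr(d_est, "ssd")["after"], attr(d_est, "ssd")["before"])
  d_inv <- invert_field(d_true)
  wm <- fa$mask & fa$values >= 0.2
  err0 <- sqrt(rowSums(matrix(d_inv$disp, ncol = 3)^2))
  err1 <- sqrt(rowSums(matrix(d_est$disp - d_inv$disp, ncol = 3)^2))
  expect_lt(mean(err1[wm]), 0.5 * mean(err0[wm]))
})

test_that("degenerate nonlinear inputs exercise the warning/error path", {
  uni <- scalar_volume(array(0.5, c(12L, 12L, 12L)), diag(c(2, 2, 2, 1)))
  set.seed(2)
  noise <- scalar_volume(array(runif(12^3), c(12L, 12L, 12L)),
                         diag(c(2, 2, 2, 1)))
  # constant fixed image: nothing to align; must not error, SSD not worse
  d <- register_nonlinear(noise, uni, list(iterations = c(3, 2, 2)))
  expect_true(is.finite(attr(d, "ssd")["after"]))
})

test_that("groupwise mean deformation reduces pairwise SSD", {
  ph <- small_phantom(c(24L, 24L, 24L))
  fa <- fa_map(ph$tensor)
  set.seed(17)
  mk_subj <- function() {
    sp <- sinusoid_spec(runif(3, 0.8, 1.5), runif(3, 0.01, 0.02),
                        runif(3, 0, 2 * pi), rnorm(3))
    d <- deformation_field(
      tractatlas:::render_sinusoid(sp, fa$shape, fa$affine), fa$affine)
    structure(list(kind = "FA",
                   image = fa_map(warp_tensor_volume(ph$tensor, d)),
                   smoothing_sigma = NA_real_), class = "feature_image")
  }
  feats <- list(mk_subj(), mk_subj(), mk_subj())
  flds <- groupwise_mean_deformation(feats,
                                     list(iterations = c(25, 15, 8)))
  expect_length(flds, 3L)
  ssd <- attr(flds, "mean_pairwise_ssd")
  expect_lt(ssd["after"], ssd["before"])

  # N = 2 identical subjects -> both mean fields ~ 0
  feats2 <- list(feats[[1]], feats[[1]])
  flds2 <- groupwise_mean_deformation(feats2,
                                      list(iterations = c(8, 4, 3)))
  expect_lt(max(abs(flds2[[1]]$disp)) / 2, 0.1)  # < 0.1 voxel (2 mm voxels)

  expect_error(groupwise_mean_deformation(feats[1]), "at least 2")
  bad <- feats; bad[[2]]$kind <- "hFA"
  expect_error(groupwise_mean_deformation(bad), "same kind")
})

test_that("compose handles affines, fields and sequential-application oracle", {
  shape <- c(14L, 14L, 14L)
  aff <- diag(c(2, 2, 2, 1))
  idA <- affine_transform(diag(4))
  z <- compose(list(idA), shape, aff)
  expect_true(all(z$disp == 0))

  t1 <- diag(4); t1[1:3, 4] <- c(1, 2, -1)
  t2 <- diag(4); t2[1:3, 4] <- c(-3, 0.5, 2)
  cc <- compose(list(affine_transform(t1, "orig", "mid"),
                     affine_transform(t2, "mid", "final")), shape, aff)
  expect_equal(matrix(cc$disp, ncol = 3)[1, ], c(-2, 2.5, 1),
               tolerance = 1e-12)

  # affine o sinusoid vs sequential application on a test image
  set.seed(41)
  sp <- sinusoid_spec(runif(3, 0.5, 1), runif(3, 0.01, 0.02),
                      runif(3, 0, 2 * pi), rnorm(3))
  d <- deformation_field(tractatlas:::render_sinusoid(sp, shape, aff), aff,
                         source_space = "orig", target_space = "mid")
  A <- diag(4); A[1:3, 4] <- c(2, -1, 1)
  tA <- affine_transform(A, source_space = "mid", target_space = "final")
  img <- blob_volume(shape)
  seq1 <- warp_scalar_volume(img, d)
  seq2 <- warp_scalar_volume(
    seq1, deformation_field(
      array(rep(c(2, -1, 1), each = prod(shape)), c(shape, 3L)), aff,
      source_space = "mid", target_space = "final"))
  oneshot <- warp_scalar_volume(img, compose(list(d, tA), shape, aff))
  interior <- array(FALSE, shape); interior[3:12, 3:12, 3:12] <- TRUE
  ok <- interior & seq2$mask & oneshot$mask
  # tolerance: one extra trilinear resampling of a smooth unit-scale image
  expect_lt(max(abs(seq2$values[ok] - oneshot$values[ok])), 0.05)

  # space-tag mismatch names the junction
  expect_error(transform_chain(list(tA, d)), "junction")
})

test_that("compose is associative to interpolation tolerance", {
  shape <- c(12L, 12L, 12L)
  aff <- diag(c(2, 2, 2, 1))
  set.seed(19)
  mk <- function(a, b) {
    sp <- sinusoid_spec(runif(3, 0.3, 0.6), runif(3, 0.01, 0.02),
                        runif(3, 0, 2 * pi), rnorm(3))
    deformation_field(tractatlas:::render_sinusoid(sp, shape, aff), aff,
                      source_space = a, target_space = b)
  }
  d1 <- mk("s0", "s1"); d2 <- mk("s1", "s2"); d3 <- mk("s2", "s3")
  left <- compose(list(compose(list(d1, d2)), d3), shape, aff)
  left$source_space <- "s0"
  right <- compose(list(d1, compose(list(d2, d3))), shape, aff)
  expect_lt(max(abs(left$disp - right$disp)), 0.05)
})

test_that("invert_field: zero, constant translation, sinusoid round trip", {
  shape <- c(14L, 14L, 14L)
  aff <- diag(c(2, 2, 2, 1))
  z <- deformation_field(array(0, c(shape, 3L)), aff)
  expect_true(all(invert_field(z)$disp == 0))

  tr <- deformation_field(array(rep(c(2, -1, 0.5), each = prod(shape)),
                                c(shape, 3L)), aff)
  ti <- invert_field(tr)
  expect_equal(matrix(ti$disp, ncol = 3)[5, ], c(-2, 1, -0.5),
               tolerance = 1e-6)

  set.seed(23)
  sp <- sinusoid_spec(runif(3, 0.5, 1), runif(3, 0.01, 0.02),
                      runif(3, 0, 2 * pi), rnorm(3))
  d <- deformation_field(tractatlas:::render_sinusoid(sp, shape, aff), aff)
  di <- invert_field(d, tol = 0.01)
  expect_lt(attr(di, "residual"), 0.05)
  # invert twice ~ identity
  dii <- invert_field(di, tol = 0.01)
  expect_lt(max(abs(dii$disp - d$disp)) / 2, 0.04)
  expect_identical(di$source_space, d$target_space)
})
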