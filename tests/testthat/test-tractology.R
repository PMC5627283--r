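# Tractography, bundle selection, parameterization, native sampling,
# streamline file formats.

# Slab phantom: uniform e1 = x-hat, FA ~ 0.8 inside an x-parallel slab.
slab_template <- function(shape = c(30L, 12L, 12L), voxel = 2) {
  tens <- array(0, c(shape, 6L))
  tens[, , , c(1, 3, 6)] <- 0.7e-3       # isotropic background
  slab <- function(j, k) j >= 4 & j <= 9 & k >= 4 & k <= 9
  for (j in 1:shape[2]) for (k in 1:shape[3]) {
    if (slab(j, k)) {
      tens[, j, k, 1] <- 1.7e-3
      tens[, j, k, 3] <- 0.4e-3
      tens[, j, k, 6] <- 0.2e-3
    }
  }
  tensor_volume(tens, diag(c(rep(voxel, 3), 1)))
}

test_that("tracking a uniform slab yields straight x-parallel streamlines", {
  tm <- slab_template()
  lines <- track(tm, step_mm = 1)
  expect_gt(length(lines), 10)
  for (line in lines[seq(1, length(lines), length.out = 10)]) {
    expect_lt(max(abs(line[, 2] - line[1, 2])), 0.51)
    expect_lt(max(abs(line[, 3] - line[1, 3])), 0.51)
    # spans the slab in x within one step of the faces
    expect_lt(abs(min(line[, 1]) - 0), 1 + 1e-6)
    expect_lt(abs(max(line[, 1]) - 58), 1 + 1e-6)
    # step-size invariant
    expect_true(all(sqrt(rowSums(diff(line)^2)) <= 1 + 1e-6))
  }
  # seed below threshold -> nothing
  expect_warning(out <- track(tm, seeds = matrix(c(58, 2, 2), 1)),
                 "threshold")
  expect_length(out, 0L)
})

test_that("tracking terminates on FA and angle criteria; deterministic", {
  ph <- small_phantom()
  seeds <- tractatlas:::voxel_to_world(which(ph$atlas$masks$cc,
                                             arr.ind = TRUE),
                                       ph$tensor$affine)
  l1 <- track(ph$tensor, seeds = seeds)
  l2 <- track(ph$tensor, seeds = seeds)
  expect_identical(l1, l2)
  fa <- fa_map(ph$tensor)
  for (line in l1[seq(1, length(l1), length.out = 8)]) {
    v <- tractatlas:::interp_trilinear(
      fa$values, tractatlas:::world_to_voxel(line, fa$affine))
    expect_true(all(v >= 0.2 - 1e-9))
    steps <- diff(line)
    steps <- steps / sqrt(rowSums(steps^2))
    if (nrow(steps) > 1) {
      cosang <- rowSums(steps[-1, , drop = FALSE] *
                        steps[-nrow(steps), , drop = FALSE])
      expect_true(all(cosang >= cos(30 * pi / 180) - 1e-9))
    }
  }
})

test_that("a quarter-circle bundle is tracked to the analytic arc length", {
  theta <- seq(0, pi / 2, length.out = 80)
  cl <- cbind(4 + 28 * cos(theta), 4 + 28 * sin(theta), 20)
  spec <- phantom_spec(shape = c(40L, 40L, 40L), voxel_mm = 1,
                       bundles = list(list(name = "arc", centerline = cl,
                                           radius = 4,
                                           evals = c(1.7e-3, 0.4e-3,
                                                     0.2e-3))))
  ph <- build_phantom(spec)
  midpt <- cl[40, , drop = FALSE]
  lines <- track(ph$tensor, seeds = midpt, step_mm = 0.5)
  expect_length(lines, 1L)
  len <- tractatlas:::streamline_length(lines[[1]])
  # the tube's rounded end caps carry the end tangent, so tracking runs
  # one radius past each end of the quarter circle
  arclen <- 28 * pi / 2 + 2 * 4
  expect_lt(abs(len - arclen) / arclen, 0.05)
})

test_that("select_bundle applies AND/OR/NOT logic with a selection log", {
  ph <- small_phantom()
  seeds <- rbind(
    tractatlas:::voxel_to_world(which(ph$atlas$masks$cc, arr.ind = TRUE),
                                ph$tensor$affine),
    tractatlas:::voxel_to_world(which(ph$atlas$masks$cst, arr.ind = TRUE),
                                ph$tensor$affine))
  lines <- track(ph$tensor, seeds = seeds)
  all_mask <- array(TRUE, ph$tensor$shape)
  atlas2 <- roi_atlas(c(ph$atlas$masks, list(everything = all_mask)),
                      ph$atlas$affine)
  keep_all <- select_bundle(lines, atlas2,
                            list(list(op = "AND", roi = "everything")))
  expect_length(keep_all$streamlines, length(lines))
  none <- select_bundle(lines, atlas2,
                        list(list(op = "NOT", roi = "everything")))
  expect_true(none$empty)
  # crossing-bundle separation by waypoint
  only_cc <- select_bundle(lines, ph$atlas,
                           list(list(op = "AND", roi = "cc_mid")))
  expect_gt(length(only_cc$streamlines), 0)
  hits_cst <- vapply(only_cc$streamlines, function(l) {
    v <- tractatlas:::interp_nearest(
      ph$atlas$masks$cst_mid,
      tractatlas:::world_to_voxel(l, ph$tensor$affine))
    any(!is.na(v) & v)
  }, logical(1))
  expect_true(!any(hits_cst))
  expect_equal(nrow(only_cc$selection_log), 1L)
  expect_error(select_bundle(lines, ph$atlas,
                             list(list(op = "AND", roi = "nope"))),
               "unknown ROI")
})

test_that("parameterize resamples at equal arc fractions and unifies flips", {
  line <- cbind(seq(0, 40, by = 2), 0, 0)  # straight, 40 mm
  p <- parameterize(list(line), K = 5)
  expect_equal(p$points[1, , 1], c(0, 10, 20, 30, 40))
  expect_equal(p$arc_fractions, c(0, 0.25, 0.5, 0.75, 1))

  # identical streamlines -> representative equals the member
  p2 <- parameterize(list(line, line, line), K = 9)
  expect_equal(p2$representative, p2$points[1, , ])

  # anti-parallel copy triggers the flip
  curve <- cbind(seq(0, 30, length.out = 40),
                 5 * sin(seq(0, pi, length.out = 40)), 0)
  p3 <- parameterize(list(curve, curve[rev(seq_len(nrow(curve))), ]), K = 20)
  expect_equal(sum(p3$flipped), 1L)
  expect_lt(max(abs(p3$points[1, , ] - p3$points[2, , ])), 1e-9)

  # arc length preserved within 1% for K >= 20
  plen <- sum(sqrt(rowSums(diff(p3$points[1, , ])^2)))
  clen <- tractatlas:::streamline_length(curve)
  expect_lt(abs(plen - clen) / clen, 0.01)

  expect_error(parameterize(list(), 5), "empty")
})

test_that("native-space mapping samples measures through inverse fields", {
  shape <- c(16L, 16L, 16L)
  aff <- diag(c(2, 2, 2, 1))
  X <- tractatlas:::grid_world(shape, aff)
  ramp <- scalar_volume(array(0.01 * X[, 1], shape), aff)
  pts <- cbind(seq(6, 24, length.out = 10), 15, 15)

  zero <- deformation_field(array(0, c(shape, 3L)), aff)
  s0 <- map_to_native_and_sample(pts, list(a = zero), list(a = ramp))
  expect_equal(as.vector(s0["a", ]), 0.01 * pts[, 1], tolerance = 1e-10)

  tr <- deformation_field(array(rep(c(4, 0, 0), each = prod(shape)),
                                c(shape, 3L)), aff)
  s1 <- map_to_native_and_sample(pts, list(a = tr), list(a = ramp))
  expect_equal(as.vector(s1["a", ]), 0.01 * (pts[, 1] + 4),
               tolerance = 1e-10)

  # out-of-volume points yield counted missing values
  far <- deformation_field(array(rep(c(300, 0, 0), each = prod(shape)),
                                 c(shape, 3L)), aff)
  s2 <- map_to_native_and_sample(pts, list(a = far), list(a = ramp))
  expect_equal(unname(attr(s2, "n_missing")["a"]), 10L)
  expect_error(map_to_native_and_sample(pts, list(a = zero),
                                        list(b = ramp)), "subject")
})

test_that("TCK and TRK files round-trip streamlines", {
  set.seed(33)
  lines <- lapply(1:5, function(i)
    cbind(cumsum(runif(10 + i)), rnorm(10 + i), rnorm(10 + i)))
  tck <- tempfile(fileext = ".tck")
  write_tck(lines, tck)
  back <- read_tck(tck)
  expect_length(back, 5L)
  for (i in 1:5) expect_equal(back[[i]], lines[[i]], tolerance = 1e-6)

  trk <- tempfile(fileext = ".trk")
  aff <- diag(c(2, 2, 2, 1)); aff[1:3, 4] <- c(-10, 4, 0)
  write_trk(lines, trk, affine = aff, dim = c(32L, 32L, 32L))
  back2 <- read_trk(trk)
  expect_length(back2, 5L)
  for (i in 1:5) expect_equal(back2[[i]], lines[[i]], tolerance = 1e-5)
})
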