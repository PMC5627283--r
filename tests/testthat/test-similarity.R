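# Similarity metrics: Eqs for FA accuracy/precision, OVL, DTED/DVED/AI/COH,
# corrFA, summaries.

test_that("FA accuracy/precision match hand evaluation", {
  shape <- c(3L, 3L, 3L)
  gt <- scalar_volume(array(0.6, shape))
  a <- scalar_volume(array(0.5, shape))
  b <- scalar_volume(array(0.7, shape))
  r <- fa_accuracy_precision(list(a, b), gt)
  expect_equal(unique(as.vector(r$accuracy$values)), 0)
  expect_equal(unique(as.vector(r$precision$values)), 0.01, tolerance = 1e-12)

  # N = 1, FA = GT + 0.1
  r1 <- fa_accuracy_precision(list(scalar_volume(array(0.7, shape))), gt)
  expect_equal(unique(as.vector(r1$accuracy$values)), 0.1, tolerance = 1e-12)
  expect_equal(unique(as.vector(r1$precision$values)), 0.01, tolerance = 1e-12)

  # identical inputs -> both zero
  r0 <- fa_accuracy_precision(list(gt, gt), gt)
  expect_true(all(r0$accuracy$values == 0) && all(r0$precision$values == 0))
  expect_error(fa_accuracy_precision(list(scalar_volume(array(0, c(2, 2, 2)))),
                                     gt), "grid")
})

test_that("OVL: identity, 90-degree rotation oracle, isotropic pairs", {
  set.seed(5)
  tv <- random_tensor_volume(c(5L, 5L, 5L))
  o <- ovl(tv, tv)
  expect_true(all(abs(o$values[o$mask] - 1) < 1e-12))

  a <- const_tensor_volume(c(2, 0, 1, 0, 0, 1), c(3L, 3L, 3L))
  b <- const_tensor_volume(c(1, 0, 2, 0, 0, 1), c(3L, 3L, 3L))  # 90 deg about z
  o2 <- ovl(a, b)
  expect_equal(unique(as.vector(o2$values)), 1 / 6, tolerance = 1e-9)

  iso1 <- const_tensor_volume(c(1, 0, 1, 0, 0, 1), c(3L, 3L, 3L))
  iso2 <- const_tensor_volume(c(3, 0, 3, 0, 0, 3), c(3L, 3L, 3L))
  o3 <- ovl(iso1, iso2)
  expect_true(all(abs(o3$values - 1) < 1e-12))

  # both zero -> masked out
  z <- const_tensor_volume(rep(0, 6), c(3L, 3L, 3L))
  oz <- ovl(z, z)
  expect_false(any(oz$mask))
})

test_that("OVL is symmetric and bounded", {
  set.seed(6)
  a <- random_tensor_volume(c(4L, 4L, 4L))
  b <- random_tensor_volume(c(4L, 4L, 4L))
  expect_equal(ovl(a, b)$values, ovl(b, a)$values, tolerance = 1e-12)
  v <- ovl(a, b)$values
  expect_true(all(v >= -1e-12 & v <= 1 + 1e-12))
})

test_that("OVL accuracy/precision combine correctly", {
  gt <- const_tensor_volume(c(2, 0, 1, 0, 0, 1), c(3L, 3L, 3L))
  rot <- const_tensor_volume(c(1, 0, 2, 0, 0, 1), c(3L, 3L, 3L))
  r <- ovl_accuracy_precision(list(gt, rot), gt)
  expect_equal(unique(as.vector(r$precision$values)), (1 + 1 / 6) / 2,
               tolerance = 1e-12)
  # all equal to gt -> both 1
  r1 <- ovl_accuracy_precision(list(gt, gt), gt)
  expect_true(all(abs(r1$accuracy$values - 1) < 1e-12))
  expect_true(all(abs(r1$precision$values - 1) < 1e-12))
  # N = 1: accuracy == precision
  r2 <- ovl_accuracy_precision(list(rot), gt)
  expect_equal(r2$accuracy$values, r2$precision$values, tolerance = 1e-12)
})

test_that("pairwise tensor metrics match hand Frobenius norms", {
  a <- const_tensor_volume(c(1, 0, 1, 0, 0, 1) * 1e-3, c(3L, 3L, 3L))
  b <- const_tensor_volume(c(2, 0, 1, 0, 0, 1) * 1e-3, c(3L, 3L, 3L))
  m <- pairwise_tensor_metrics(a, b)
  expect_equal(unique(as.vector(m$DTED$values)), 1e-3, tolerance = 1e-12)
  expect_equal(unique(as.vector(m$DVED$values)), sqrt(6) / 3 * 1e-3,
               tolerance = 1e-12)
  expect_equal(round(unique(as.vector(m$DVED$values)) * 1e3, 4), 0.8165)

  # identical tensors
  m0 <- pairwise_tensor_metrics(b, b)
  expect_true(all(m0$DTED$values == 0) && all(m0$DVED$values == 0))
  expect_true(all(abs(m0$AI$values[m0$AI$mask]) < 1e-5))
  expect_true(all(abs(m0$COH$values[m0$COH$mask] - 1) < 1e-12))

  # antipodal principal eigenvectors: AI 0, COH 1 (via rotated copy)
  flip <- const_tensor_volume(
    rotate_tensor6(c(2, 0, 1, 0, 0, 1) * 1e-3, diag(c(-1, -1, 1))),
    c(3L, 3L, 3L))
  mf <- pairwise_tensor_metrics(b, flip)
  expect_true(all(abs(mf$AI$values[mf$AI$mask]) < 1e-5))
  expect_true(all(abs(mf$COH$values[mf$COH$mask] - 1) < 1e-12))

  # isotropic voxels excluded from AI/COH but kept for distances
  expect_false(any(pairwise_tensor_metrics(a, b)$AI$mask))
  expect_true(all(pairwise_tensor_metrics(a, b)$DTED$mask))
})

test_that("metric symmetry, Pythagorean split, rigid-motion equivariance", {
  set.seed(8)
  a <- random_tensor_volume(c(4L, 4L, 4L))
  b <- random_tensor_volume(c(4L, 4L, 4L))
  ma <- pairwise_tensor_metrics(a, b)
  mb <- pairwise_tensor_metrics(b, a)
  expect_identical(ma$DTED$values, mb$DTED$values)
  expect_identical(ma$DVED$values, mb$DVED$values)
  expect_equal(ma$AI$values[ma$AI$mask], mb$AI$values[mb$AI$mask],
               tolerance = 1e-12)
  expect_true(all(ma$COH$values[ma$COH$mask] >= 0 &
                  ma$COH$values[ma$COH$mask] <= 1))
  expect_true(all(ma$AI$values[ma$AI$mask] >= 0 &
                  ma$AI$values[ma$AI$mask] <= 90))

  # DTED^2 = DVED^2 + 3 (dtr/3)^2
  dtr <- (a$tensors[, , , 1] + a$tensors[, , , 3] + a$tensors[, , , 6]) -
         (b$tensors[, , , 1] + b$tensors[, , , 3] + b$tensors[, , , 6])
  expect_equal(as.vector(ma$DTED$values^2),
               as.vector(ma$DVED$values^2 + 3 * (dtr / 3)^2),
               tolerance = 1e-12)

  # one global rotation applied to both leaves all metrics unchanged
  R <- random_rotation()
  rot_vol <- function(t) {
    m <- t(apply(tractatlas:::tensors_as_matrix(t), 1, rotate_tensor6, R = R))
    tensor_volume(array(m, dim(t$tensors)), t$affine)
  }
  mr <- pairwise_tensor_metrics(rot_vol(a), rot_vol(b))
  expect_equal(mr$DTED$values, ma$DTED$values, tolerance = 1e-9)
  expect_equal(mr$DVED$values, ma$DVED$values, tolerance = 1e-9)
  expect_equal(mr$AI$values[ma$AI$mask], ma$AI$values[ma$AI$mask],
               tolerance = 1e-6)
  ovl_ab <- ovl(a, b)$values
  ovl_r <- ovl(rot_vol(a), rot_vol(b))$values
  expect_equal(ovl_r, ovl_ab, tolerance = 1e-9)
})

test_that("corrFA matches direct Pearson computation", {
  shape <- c(5L, 1L, 1L)
  region <- array(TRUE, shape)
  x <- c(0.1, 0.4, 0.2, 0.8, 0.5)
  imgs <- list(scalar_volume(array(x, shape)),
               scalar_volume(array(2 * x + 0.1, shape)),
               scalar_volume(array(c(0.3, 0.1, 0.9, 0.2, 0.4), shape)))
  r <- corr_fa(imgs, region)
  expect_equal(r$matrix[1, 2], 1, tolerance = 1e-12)
  expect_equal(r$matrix[1, 3],
               cor(x, c(0.3, 0.1, 0.9, 0.2, 0.4)), tolerance = 1e-12)
  expect_equal(r$matrix, t(r$matrix))
  expect_equal(r$mean, mean(r$matrix[upper.tri(r$matrix)]))
  # zero-variance image -> undefined pair, counted
  imgs2 <- list(imgs[[1]], scalar_volume(array(0.5, shape)))
  r2 <- corr_fa(imgs2, region)
  expect_true(is.na(r2$matrix[1, 2]))
  expect_equal(r2$n_undefined, 1L)
  expect_error(corr_fa(imgs, array(c(TRUE, TRUE, FALSE, FALSE, FALSE),
                                   shape)), "3 voxels")
})

test_that("summarize_metric builds ROI tables and normalized histograms", {
  ph <- small_phantom(c(20L, 20L, 20L))
  const <- scalar_volume(array(0.42, ph$tensor$shape), ph$tensor$affine)
  rep1 <- summarize_metric(const, ph$atlas, bins = 10, range = c(0, 1))
  expect_true(all(abs(rep1$roi_table$mean - 0.42) < 1e-12))
  expect_true(all(rep1$roi_table$sd == 0))
  expect_equal(sum(rep1$histogram$fraction), 1)

  set.seed(9)
  noisy <- scalar_volume(array(runif(prod(ph$tensor$shape)),
                               ph$tensor$shape), ph$tensor$affine)
  rep2 <- summarize_metric(list(noisy, const), ph$atlas, bins = 25)
  expect_equal(sum(rep2$histogram$fraction), 1)
  expect_equal(nrow(rep2$roi_table), length(ph$atlas$masks))

  empty_atlas <- roi_atlas(c(ph$atlas$masks,
                             list(empty = array(FALSE, ph$tensor$shape))),
                           ph$atlas$affine)
  expect_warning(rep3 <- summarize_metric(const, empty_atlas), "empty ROI")
  expect_true(is.na(rep3$roi_table$mean[rep3$roi_table$roi == "empty"]))
})

test_that("condition comparison: identical distributions give F ~ 0", {
  set.seed(10)
  x <- rnorm(200)
  r <- compare_conditions(list(a = x, b = x, c = x))
  expect_lt(r$anova$F, 1e-20)
  expect_gt(r$anova$p, 0.999)
  expect_true(all(r$pairwise$p_bonferroni == 1))
  # shifted condition detected
  r2 <- compare_conditions(list(a = x, b = x + 2))
  expect_lt(r2$anova$p, 1e-10)
  # Wilcoxon utility
  w <- wilcoxon_matched(x[1:50], x[1:50] + 0.5)
  expect_lt(w$p, 0.01)
})
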