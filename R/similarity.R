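# Tensor-similarity metrics for evaluating spatial normalization:
# FA accuracy/precision, overlap of eigenvalue-eigenvector pairs (OVL)
# with its accuracy/precision, Euclidean tensor distances (DTED/DVED),
# primary-eigenvector angle (AI) and coherence (COH), FA cross-correlation
# (corrFA), plus ROI/histogram summaries and group tests.

#' FA accuracy and precision maps
#'
#' Per voxel, accuracy is `|mean_i(FA_i) - FA_GT|` and precision is
#' `|mean_i((FA_i - FA_GT)^2)|` over the N normalized images.
#'
#' @param normalized list of FA [scalar_volume()]s on the ground-truth grid.
#' @param gt ground-truth FA [scalar_volume()].
#' @return list with `accuracy` and `precision` [scalar_volume()]s (mask =
#'   gt mask intersected with all input masks).
#' @export
fa_accuracy_precision <- function(normalized, gt) {
  stopifnot(is.list(normalized), length(normalized) >= 1L)
  for (v in normalized) stop_if_grid_mismatch(gt, v, "FA volumes")
  n <- length(normalized)
  msum <- Reduce(`+`, lapply(normalized, `[[`, "values")) / n
  m2sum <- Reduce(`+`, lapply(normalized, function(v)
    (v$values - gt$values)^2)) / n
  mask <- Reduce(`&`, lapply(normalized, `[[`, "mask"), gt$mask)
  list(accuracy = scalar_volume(abs(msum - gt$values), gt$affine, mask),
       precision = scalar_volume(abs(m2sum), gt$affine, mask))
}

eigen_pair_arrays <- function(t) {
  es <- if (inherits(t, "eigen_system")) t else eigendecompose(t)
  list(lam = matrix(es$lambdas, ncol = 3L),
       vec = matrix(es$vectors, ncol = 9L),
       mask = es$mask, shape = es$shape, affine = es$affine)
}

#' Overlap of eigenvalue-eigenvector pairs (OVL)
#'
#' Per voxel, `OVL = sum_j lambda_j lambda*_j (e_j . e*_j)^2 /
#' sum_j lambda_j lambda*_j` with eigen-pairs matched by descending
#' eigenvalue order.  Symmetric in its arguments; equals 1 for identical
#' tensors and lies in \[0, 1\] for nonnegative eigenvalues.  Voxels where
#' the denominator vanishes (both tensors zero) are masked out.
#'
#' @param a,b [tensor_volume()]s (or precomputed `eigen_system`s) on one
#'   grid.
#' @return a [scalar_volume()].
#' @export
ovl <- function(a, b) {
  ea <- eigen_pair_arrays(a)
  eb <- eigen_pair_arrays(b)
  stopifnot(identical(ea$shape, eb$shape))
  num <- den <- numeric(nrow(ea$lam))
  for (j in 1:3) {
    ll <- ea$lam[, j] * eb$lam[, j]
    dotj <- rowSums(ea$vec[, (3 * j - 2):(3 * j), drop = FALSE] *
                    eb$vec[, (3 * j - 2):(3 * j), drop = FALSE])
    num <- num + ll * dotj^2
    den <- den + ll
  }
  ok <- is.finite(den) & abs(den) > .Machine$double.xmin
  vals <- ifelse(ok, num / den, 0)
  scalar_volume(array(vals, ea$shape), ea$affine,
                mask = ea$mask & eb$mask & array(ok, ea$shape))
}

#' OVL accuracy and precision maps
#'
#' Accuracy is `OVL(mean(normalized), gt)` (the mean over normalized
#' tensor volumes, then OVL against ground truth); precision is the mean
#' over subjects of `OVL(normalized_i, gt)`.
#'
#' @param normalized list of [tensor_volume()]s.
#' @param gt ground-truth [tensor_volume()].
#' @param mean_mode averaging mode for the accuracy template, see
#'   [mean_tensor_volume()].
#' @return list with `accuracy` and `precision` [scalar_volume()]s.
#' @export
ovl_accuracy_precision <- function(normalized, gt, mean_mode = "euclidean") {
  stopifnot(is.list(normalized), length(normalized) >= 1L)
  eg <- eigendecompose(gt)
  acc <- ovl(mean_tensor_volume(normalized, mean_mode), eg)
  n <- length(normalized)
  psum <- NULL
  pmask <- NULL
  for (t in normalized) {
    o <- ovl(t, eg)
    psum <- if (is.null(psum)) o$values else psum + o$values
    pmask <- if (is.null(pmask)) o$mask else pmask & o$mask
  }
  list(accuracy = acc,
       precision = scalar_volume(psum / n, gt$affine, pmask))
}

#' Pairwise tensor distance and orientation metrics
#'
#' DTED is the Frobenius norm of the tensor difference; DVED the Frobenius
#' norm of the difference of deviatoric parts `dev(D) = D - tr(D)/3 I`;
#' AI the angle `acos(|e1_a . e1_b|)` between primary eigenvectors; COH
#' the coherence `|e1_a . e1_b|`.  All symmetric in (a, b).  Voxels that
#' are orientationally degenerate (`lambda1 ~ lambda2`) in either input
#' are excluded from the AI/COH masks but kept for DTED/DVED.
#'
#' @param a,b [tensor_volume()]s on one grid.
#' @param angle_unit `"degrees"` (default) or `"radians"` for AI.
#' @param iso_rtol relative eigenvalue gap below which a voxel counts as
#'   orientationally degenerate.
#' @return named list of [scalar_volume()]s: `DTED`, `DVED`, `AI`, `COH`.
#' @export
pairwise_tensor_metrics <- function(a, b, angle_unit = c("degrees", "radians"),
                                    iso_rtol = 1e-6) {
  angle_unit <- match.arg(angle_unit)
  stop_if_grid_mismatch(a, b, "tensor volumes")
  ma <- tensors_as_matrix(a); mb <- tensors_as_matrix(b)
  dd <- ma - mb
  frob2 <- function(m) m[, 1]^2 + m[, 3]^2 + m[, 6]^2 +
                       2 * (m[, 2]^2 + m[, 4]^2 + m[, 5]^2)
  dted <- sqrt(frob2(dd))
  dtr <- (dd[, 1] + dd[, 3] + dd[, 6]) / 3
  dev <- dd
  dev[, 1] <- dev[, 1] - dtr; dev[, 3] <- dev[, 3] - dtr
  dev[, 6] <- dev[, 6] - dtr
  dved <- sqrt(frob2(dev))

  ea <- eigen_pair_arrays(a); eb <- eigen_pair_arrays(b)
  dot1 <- abs(rowSums(ea$vec[, 1:3, drop = FALSE] *
                      eb$vec[, 1:3, drop = FALSE]))
  coh <- pmin(dot1, 1)
  ai <- acos(coh)
  if (angle_unit == "degrees") ai <- ai * 180 / pi
  degen <- function(e) (e$lam[, 1] - e$lam[, 2]) <=
    iso_rtol * pmax(abs(e$lam[, 1]), abs(e$lam[, 2]), .Machine$double.xmin)
  orient_ok <- array(!degen(ea) & !degen(eb), a$shape)

  base_mask <- a$mask & b$mask
  list(DTED = scalar_volume(array(dted, a$shape), a$affine, base_mask),
       DVED = scalar_volume(array(dved, a$shape), a$affine, base_mask),
       AI = scalar_volume(array(ai, a$shape), a$affine,
                          base_mask & orient_ok),
       COH = scalar_volume(array(coh, a$shape), a$affine,
                           base_mask & orient_ok))
}

#' Cross-correlation of FA over a region (corrFA)
#'
#' Pearson correlation of FA values over the region's voxels for every
#' unordered pair of images.
#'
#' @param images list (>= 2) of FA [scalar_volume()]s on one grid.
#' @param region logical array (or [scalar_volume()] mask) with >= 3
#'   voxels.
#' @return list with `matrix` (pairwise correlations, unit diagonal; NA
#'   for zero-variance pairs), `mean` (off-diagonal mean over defined
#'   pairs) and `n_undefined`.
#' @export
corr_fa <- function(images, region) {
  stopifnot(is.list(images), length(images) >= 2L)
  if (inherits(region, "scalar_volume")) region <- region$mask
  ref <- images[[1]]
  for (im in images) stop_if_grid_mismatch(ref, im, "FA volumes")
  idx <- which(region)
  if (length(idx) < 3L) stop("region must contain at least 3 voxels")
  vals <- sapply(images, function(im) im$values[idx])
  n <- length(images)
  cm <- diag(1, n)
  undef <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (sd(vals[, i]) == 0 || sd(vals[, j]) == 0) {
      cm[i, j] <- cm[j, i] <- NA_real_
      undef <- undef + 1L
    } else {
      cm[i, j] <- cm[j, i] <- stats::cor(vals[, i], vals[, j])
    }
  }
  off <- cm[upper.tri(cm)]
  list(matrix = cm, mean = mean(off, na.rm = TRUE), n_undefined = undef)
}

#' ROI atlas
#'
#' Named boolean masks on a common grid.
#'
#' @param masks named list of logical 3-D arrays (unique names).
#' @param affine 4x4 voxel-to-world matrix of the atlas grid.
#' @return object of class `roi_atlas`.
#' @export
roi_atlas <- function(masks, affine = diag(4)) {
  stopifnot(is.list(masks), length(masks) >= 1L,
            !is.null(names(masks)), !anyDuplicated(names(masks)))
  shape <- dim(masks[[1]])
  for (m in masks) stopifnot(is.logical(m), identical(dim(m), shape))
  structure(list(masks = masks, shape = shape,
                 affine = validate_affine(affine)),
            class = "roi_atlas")
}

#' Summarize metric maps over an ROI atlas
#'
#' Builds the per-ROI mean/SD table (pooling voxels over all supplied
#' maps, e.g. all image pairs) and a whole-mask relative-frequency
#' histogram.  Empty ROIs yield NA rows with a warning.
#'
#' @param maps a [scalar_volume()] or list of them (one per image pair),
#'   on the atlas grid.
#' @param atlas a [roi_atlas()].
#' @param bins number of equal-width histogram bins (default 100).
#' @param range histogram range (default the metric's observed range).
#' @return object of class `metric_report`: list with `roi_table`
#'   (data.frame: roi, mean, sd, n_voxels), `histogram` (data.frame:
#'   bin_left, bin_right, fraction summing to 1).
#' @export
summarize_metric <- function(maps, atlas, bins = 100L, range = NULL) {
  if (inherits(maps, "scalar_volume")) maps <- list(maps)
  stopifnot(inherits(atlas, "roi_atlas"))
  for (m in maps) stopifnot(identical(m$shape, atlas$shape))
  rows <- lapply(names(atlas$masks), function(nm) {
    sel <- atlas$masks[[nm]]
    vals <- unlist(lapply(maps, function(m) m$values[sel & m$mask]))
    if (length(vals) == 0L) {
      warning("empty ROI: ", nm)
      data.frame(roi = nm, mean = NA_real_, sd = NA_real_, n_voxels = 0L)
    } else {
      data.frame(roi = nm, mean = mean(vals), sd = sd(vals),
                 n_voxels = length(vals))
    }
  })
  allvals <- unlist(lapply(maps, function(m) m$values[m$mask]))
  if (is.null(range)) range <- base::range(allvals)
  if (diff(range) == 0) range <- range + c(-0.5, 0.5)
  edges <- seq(range[1], range[2], length.out = bins + 1L)
  cl <- pmin(pmax(allvals, range[1]), range[2])
  counts <- tabulate(pmin(findInterval(cl, edges,
                                       rightmost.closed = TRUE), bins),
                     nbins = bins)
  hist <- data.frame(bin_left = edges[-length(edges)], bin_right = edges[-1],
                     fraction = counts / sum(counts))
  structure(list(roi_table = do.call(rbind, rows), histogram = hist),
            class = "metric_report")
}

#' Compare metric distributions across feature-image conditions
#'
#' One-way ANOVA across conditions plus Bonferroni-corrected pairwise
#' two-sample t-tests.
#'
#' @param values_by_condition named list of numeric vectors (one per
#'   condition, e.g. per feature image).
#' @return list with `anova` (data.frame F, df1, df2, p) and `pairwise`
#'   (data.frame: condition_a, condition_b, p_bonferroni).
#' @export
compare_conditions <- function(values_by_condition) {
  stopifnot(is.list(values_by_condition), length(values_by_condition) >= 2L,
            !is.null(names(values_by_condition)))
  g <- factor(rep(names(values_by_condition),
                  vapply(values_by_condition, length, 1L)),
              levels = names(values_by_condition))
  y <- unlist(values_by_condition, use.names = FALSE)
  fit <- stats::oneway.test(y ~ g, var.equal = TRUE)
  nms <- names(values_by_condition)
  pairs <- utils::combn(nms, 2L)
  m <- ncol(pairs)
  pw <- data.frame(condition_a = pairs[1, ], condition_b = pairs[2, ],
                   p_bonferroni = NA_real_)
  for (k in seq_len(m)) {
    tt <- stats::t.test(values_by_condition[[pairs[1, k]]],
                        values_by_condition[[pairs[2, k]]],
                        var.equal = TRUE)
    pw$p_bonferroni[k] <- min(1, tt$p.value * m)
  }
  list(anova = data.frame(F = unname(fit$statistic),
                          df1 = unname(fit$parameter[1]),
                          df2 = unname(fit$parameter[2]),
                          p = fit$p.value),
       pairwise = pw)
}

#' Wilcoxon matched-pairs signed-rank test (reporting utility)
#'
#' Thin wrapper over [stats::wilcox.test()] with `paired = TRUE`.
#'
#' @param x,y paired numeric vectors.
#' @return list with `statistic` (V) and `p`.
#' @export
wilcoxon_matched <- function(x, y) {
  wt <- stats::wilcox.test(x, y, paired = TRUE, exact = FALSE)
  list(statistic = unname(wt$statistic), p = wt$p.value)
}
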