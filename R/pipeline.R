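# End-to-end TABS helpers: feature-driven normalization of a cohort to a
# standard space, similarity evaluation, and the along-tract analysis.

#' Normalize a cohort to a reference (standard) space
#'
#' Builds the chosen feature image per subject and for the reference,
#' nonlinearly registers each subject's feature to the reference feature,
#' and applies each estimated field to the subject's tensors with
#' reorientation.
#'
#' @param cohort list of subject records (see [make_cohort()]).
#' @param reference list with `tensor` and/or `structural` (e.g. a
#'   [build_phantom()] result).
#' @param kind feature kind, see [make_feature()].
#' @param cfg [register_nonlinear()] configuration.
#' @param sigma hFA smoothing (mm).
#' @return list with `fields` (estimated [deformation_field()]s, one per
#'   subject; they map reference-grid points into each subject's native
#'   space) and `normalized` (list of [tensor_volume()]s on the reference
#'   grid).
#' @export
normalize_cohort <- function(cohort, reference, kind = "FA", cfg = list(),
                             sigma = 2) {
  ref_feat <- make_feature(reference, kind, sigma)
  fields <- vector("list", length(cohort))
  normalized <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    sub_feat <- make_feature(cohort[[i]], kind, sigma)
    d <- register_nonlinear(sub_feat$image, ref_feat$image, cfg)
    fields[[i]] <- d
    normalized[[i]] <- warp_tensor_volume(cohort[[i]]$tensor, d)
  }
  names(fields) <- names(normalized) <-
    vapply(cohort, `[[`, "", "id")
  list(fields = fields, normalized = normalized)
}

#' Evaluate normalization quality against a ground truth
#'
#' Mean OVL (precision sense: per-subject OVL against ground truth,
#' averaged over subjects and in-mask voxels) and mean pairwise corrFA of
#' the normalized FA maps over the evaluation mask.
#'
#' @param normalized list of [tensor_volume()]s on the ground-truth grid.
#' @param gt ground-truth [tensor_volume()].
#' @param mask evaluation mask (logical array); default: ground-truth
#'   white matter is approximated by FA(gt) >= 0.2.
#' @return list with `mean_ovl`, `mean_corr_fa`, `fa_accuracy_mean`,
#'   `fa_precision_mean`.
#' @export
evaluate_normalization <- function(normalized, gt, mask = NULL) {
  gt_fa <- fa_map(gt)
  if (is.null(mask)) mask <- gt_fa$mask & (gt_fa$values >= 0.2)
  eg <- eigendecompose(gt)
  ovl_means <- vapply(normalized, function(t) {
    o <- ovl(t, eg)
    mean(o$values[o$mask & mask])
  }, numeric(1))
  fas <- lapply(normalized, fa_map)
  cf <- corr_fa(fas, mask)
  fap <- fa_accuracy_precision(fas, gt_fa)
  list(mean_ovl = mean(ovl_means),
       mean_corr_fa = cf$mean,
       fa_accuracy_mean = mean(fap$accuracy$values[mask]),
       fa_precision_mean = mean(fap$precision$values[mask]))
}

#' Along-tract group analysis on a normalized cohort
#'
#' The TABS statistical step at desk scale: average the normalized
#' tensors into a template, track on the template seeded inside the
#' target bundle, select the bundle with its waypoint ROI, parameterize
#' to K corresponding points, map the representative curve into every
#' subject's native space through the estimated fields, sample each
#' subject's native FA, and run the pointwise permutation-FWE test plus
#' the tract-averaged test and ROC/AUC.
#'
#' @param cohort subject records ([make_cohort()]).
#' @param norm result of [normalize_cohort()] on this cohort.
#' @param phantom the [build_phantom()] result (supplies the atlas).
#' @param bundle bundle name (default "cc").
#' @param K points per tract (default 50).
#' @param n_perm,seed,alpha see [permutation_fwe()].
#' @return list with `profiles` (subjects x K), `labels`, `template`,
#'   `tract` (the [parameterize()]d set), `result`
#'   ([permutation_fwe()] output), `tract_test`
#'   ([tract_average_test()] output), `roc` ([roc_auc()] output, feature
#'   reduced over the significant points when any, else over all points),
#'   `truth_index` (points of the representative curve lying in the
#'   effect interval, from the phantom's arc map).
#' @export
tabs_along_tract <- function(cohort, norm, phantom, bundle = "cc", K = 50L,
                             n_perm = 1000L, seed = 1L, alpha = 0.05) {
  template <- mean_tensor_volume(norm$normalized)
  seed_mask <- phantom$atlas$masks[[bundle]]
  seeds <- voxel_to_world(which(seed_mask, arr.ind = TRUE),
                          phantom$tensor$affine)
  lines <- track(template, seeds = seeds)
  sel <- select_bundle(lines, phantom$atlas,
                       list(list(op = "AND", roi = paste0(bundle, "_mid")),
                            list(op = "AND", roi = bundle)))
  if (sel$empty) stop("bundle selection returned no streamlines")
  tract <- parameterize(sel, K)
  measures <- lapply(cohort, function(s) fa_map(s$tensor))
  names(measures) <- vapply(cohort, `[[`, "", "id")
  profiles <- map_to_native_and_sample(tract, norm$fields, measures)
  labels <- vapply(cohort, `[[`, "", "group")
  A <- profiles[labels == "A", , drop = FALSE]
  B <- profiles[labels == "B", , drop = FALSE]
  res <- permutation_fwe(A, B, n_perm = n_perm, seed = seed, alpha = alpha)
  ttest <- tract_average_test(A, B)
  red <- if (length(res$significant)) res$significant else seq_len(K)
  roc <- roc_auc(profiles, labels, reduce_index = red)
  arcvals <- interp_nearest(
    ifelse(is.na(phantom$arc[[bundle]]), -1, phantom$arc[[bundle]]),
    world_to_voxel(tract$representative, phantom$tensor$affine))
  list(profiles = profiles, labels = labels, template = template,
       tract = tract, result = res, tract_test = ttest, roc = roc,
       rep_arc = arcvals)
}
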