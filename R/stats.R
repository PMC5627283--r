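# Group statistics along parameterized tracts: pointwise two-sample
# t-tests, 1-D threshold-free cluster enhancement, permutation-based
# family-wise error control, tract-averaged testing, ROC/AUC.

#' Pointwise two-sample t-statistics along a tract
#'
#' Student t with pooled variance per tract point (Welch optional), sign
#' convention A - B, pairwise-complete over missing values.  Points with
#' fewer than 2 complete values in either group, or zero pooled variance,
#' yield NA (degenerate-variance cases are additionally counted in
#' attribute `n_degenerate`).
#'
#' @param groupA,groupB subjects x K numeric matrices.
#' @param welch use Welch's unequal-variance t instead of pooled.
#' @return list with `t` (length K), `df` (length K), `n_degenerate`.
#' @export
pointwise_ttest <- function(groupA, groupB, welch = FALSE) {
  groupA <- as.matrix(groupA); groupB <- as.matrix(groupB)
  stopifnot(ncol(groupA) == ncol(groupB),
            nrow(groupA) >= 2L, nrow(groupB) >= 2L)
  K <- ncol(groupA)
  nA <- colSums(is.finite(groupA)); nB <- colSums(is.finite(groupB))
  mA <- colMeans(groupA, na.rm = TRUE); mB <- colMeans(groupB, na.rm = TRUE)
  vA <- apply(groupA, 2, var, na.rm = TRUE)
  vB <- apply(groupB, 2, var, na.rm = TRUE)
  tt <- rep(NA_real_, K); df <- rep(NA_real_, K)
  enough <- nA >= 2L & nB >= 2L
  if (welch) {
    se2 <- vA / nA + vB / nB
    tt[enough] <- ((mA - mB) / sqrt(se2))[enough]
    df[enough] <- (se2^2 / ((vA / nA)^2 / (nA - 1) +
                            (vB / nB)^2 / (nB - 1)))[enough]
  } else {
    sp2 <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
    tt[enough] <- ((mA - mB) / sqrt(sp2 * (1 / nA + 1 / nB)))[enough]
    df[enough] <- (nA + nB - 2)[enough]
  }
  degen <- enough & !is.finite(tt)
  tt[degen] <- NA_real_
  list(t = tt, df = df, n_degenerate = sum(degen))
}

#' 1-D threshold-free cluster enhancement
#'
#' For each tract point k, `TFCE(k) = sum over thresholds h = dh, 2dh, ...
#' up to stat_k of extent(k, h)^E * h^H * dh`, where extent(k, h) is the
#' length in points of the contiguous suprathreshold run containing k.
#' Positive and negative tails are enhanced separately and recombined
#' with sign, so the output is signed like the input.
#'
#' @param stats length-K statistic profile (finite; NA not allowed).
#' @param E extent exponent (default 0.5).
#' @param H height exponent (default 2).
#' @param dh threshold step (default 0.1).
#' @return length-K enhanced values.
#' @export
tfce_1d <- function(stats, E = 0.5, H = 2, dh = 0.1) {
  stopifnot(E > 0, H > 0, dh > 0)
  if (any(!is.finite(stats)))
    stop("non-finite statistics at indices: ",
         paste(which(!is.finite(stats)), collapse = ", "))
  one_tail <- function(x) {
    out <- numeric(length(x))
    mx <- max(x)
    if (mx < dh) return(out)
    hs <- seq(dh, mx, by = dh)
    for (h in hs) {
      above <- x >= h
      if (!any(above)) next
      r <- rle(above)
      ext <- rep(r$lengths, r$lengths)
      out[above] <- out[above] + ext[above]^E * h^H * dh
    }
    out
  }
  one_tail(stats) - one_tail(-stats)
}

#' Permutation-based FWE-corrected along-tract inference
#'
#' Permutes group labels, builds the null distribution of the maximum
#' absolute TFCE value over tract points, and reports corrected p-values
#' `p_k = (1 + #(null_max >= |tfce_k|)) / (n_perm + 1)`.  When the number
#' of distinct label assignments is at most `n_perm`, the complete
#' enumeration is used instead (noted in the result) and the p-value is
#' `#(null_max >= |tfce_k|) / n_distinct` since the observed labeling is
#' part of the enumeration.
#'
#' @param groupA,groupB subjects x K matrices.
#' @param n_perm number of permutations (>= 100 recommended; default
#'   1000).
#' @param seed mandatory RNG seed.
#' @param tfce_params list with E, H, dh (defaults 0.5, 2, 0.1).
#' @param alpha significance level (default 0.05).
#' @param welch see [pointwise_ttest()].
#' @param max_missing_frac subjects missing more than this fraction of
#'   points are excluded (default 0.5).
#' @return object of class `tract_stat_result`: list with `t`, `tfce`,
#'   `p_fwe`, `significant` (indices with p < alpha), `n_perm`, `seed`,
#'   `exact` (TRUE if enumeration), `alpha`.
#' @export
permutation_fwe <- function(groupA, groupB, n_perm = 1000L, seed,
                            tfce_params = list(E = 0.5, H = 2, dh = 0.1),
                            alpha = 0.05, welch = FALSE,
                            max_missing_frac = 0.5) {
  if (missing(seed)) stop("a seed is required for reproducibility")
  groupA <- as.matrix(groupA); groupB <- as.matrix(groupB)
  drop_bad <- function(m) m[rowMeans(!is.finite(m)) <= max_missing_frac, ,
                            drop = FALSE]
  groupA <- drop_bad(groupA); groupB <- drop_bad(groupB)
  nA <- nrow(groupA); nB <- nrow(groupB)
  stopifnot(nA >= 2L, nB >= 2L)
  K <- ncol(groupA)
  tp <- utils::modifyList(list(E = 0.5, H = 2, dh = 0.1), tfce_params)

  tfce_of <- function(A, B) {
    tt <- pointwise_ttest(A, B, welch = welch)$t
    tt[!is.finite(tt)] <- 0
    tfce_1d(tt, tp$E, tp$H, tp$dh)
  }
  obs_t <- pointwise_ttest(groupA, groupB, welch = welch)
  obs <- tfce_of(groupA, groupB)

  pool <- rbind(groupA, groupB)
  n <- nA + nB
  n_distinct <- choose(n, nA)
  exact <- n_distinct <= n_perm
  if (exact) {
    sel <- utils::combn(n, nA)
    n_used <- ncol(sel)
    draws <- lapply(seq_len(n_used), function(i) sel[, i])
  } else {
    set.seed(seed)
    n_used <- n_perm
    draws <- lapply(seq_len(n_used), function(i) sample(n, nA))
  }
  null_max <- vapply(draws, function(ia) {
    max(abs(tfce_of(pool[ia, , drop = FALSE],
                    pool[-ia, , drop = FALSE])))
  }, numeric(1))
  # Monte-Carlo p adds the observed labeling to the null; under exact
  # enumeration it is already included, so no +1 correction applies
  p <- if (exact) {
    vapply(abs(obs), function(v) sum(null_max >= v) / n_used, numeric(1))
  } else {
    vapply(abs(obs), function(v) (1 + sum(null_max >= v)) / (n_used + 1),
           numeric(1))
  }
  structure(list(t = obs_t$t, tfce = obs, p_fwe = p,
                 significant = which(p < alpha), n_perm = n_used,
                 seed = seed, exact = exact, alpha = alpha),
            class = "tract_stat_result")
}

#' Tract-averaged group test
#'
#' Reduces each subject's profile to its mean over tract points
#' (missing-aware; subjects with no finite points are excluded and
#' counted) and runs one pooled two-sample t-test.
#'
#' @param groupA,groupB subjects x K matrices.
#' @param welch see [pointwise_ttest()].
#' @return list with `meansA`, `meansB`, `t`, `df`, `p`, `n_excluded`.
#' @export
tract_average_test <- function(groupA, groupB, welch = FALSE) {
  mA <- rowMeans(as.matrix(groupA), na.rm = TRUE)
  mB <- rowMeans(as.matrix(groupB), na.rm = TRUE)
  exA <- !is.finite(mA); exB <- !is.finite(mB)
  mA <- mA[!exA]; mB <- mB[!exB]
  stopifnot(length(mA) >= 2L, length(mB) >= 2L)
  tt <- stats::t.test(mA, mB, var.equal = !welch)
  list(meansA = mA, meansB = mB, t = unname(tt$statistic),
       df = unname(tt$parameter), p = tt$p.value,
       n_excluded = sum(exA) + sum(exB))
}

#' ROC curve and AUC
#'
#' AUC via the rank (Mann-Whitney) formulation with tie correction; the
#' curve enumerates all distinct thresholds.  If the raw AUC is below
#' 0.5 the feature orientation is flipped and reported via `direction`.
#' Vector-valued features are reduced to a scalar by the mean over
#' `reduce_index` (e.g. the significant-point set).
#'
#' @param feature per-subject scalar, or subjects x K matrix.
#' @param labels two-class factor/vector, one per subject.
#' @param reduce_index columns used to reduce a matrix feature (default
#'   all).
#' @return object of class `roc_result`: list with `thresholds`, `tpr`,
#'   `fpr`, `auc`, `direction` (+1 if larger feature values indicate the
#'   positive class).
#' @export
roc_auc <- function(feature, labels, reduce_index = NULL) {
  if (is.matrix(feature)) {
    if (is.null(reduce_index)) reduce_index <- seq_len(ncol(feature))
    if (length(reduce_index) == 0L)
      stop("empty reduction index for a matrix feature")
    feature <- rowMeans(feature[, reduce_index, drop = FALSE], na.rm = TRUE)
  }
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L) stop("exactly two classes are required")
  pos <- labels == levels(labels)[2L]
  x <- feature
  stopifnot(all(is.finite(x)))
  auc_of <- function(x) {
    r <- rank(x)                        # midranks handle ties
    (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) / (sum(pos) * sum(!pos))
  }
  a <- auc_of(x)
  direction <- 1
  if (a < 0.5) { x <- -x; a <- auc_of(x); direction <- -1 }
  th <- c(Inf, sort(unique(x), decreasing = TRUE))
  tpr <- vapply(th, function(t) mean(x[pos] >= t), numeric(1))
  fpr <- vapply(th, function(t) mean(x[!pos] >= t), numeric(1))
  structure(list(thresholds = th, tpr = tpr, fpr = fpr, auc = a,
                 direction = direction),
            class = "roc_result")
}
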