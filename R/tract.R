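# Deterministic streamline tractography on a tensor template, ROI-logic
# bundle selection, arc-length parameterization with cross-subject point
# correspondence, and inverse mapping to native space.

# Interpolate a principal-direction field at voxel coords `vox` with local
# sign alignment: each of the 8 corner vectors is flipped to agree with
# the reference direction before trilinear weighting.
interp_direction <- function(e1, shape, vox, refdir) {
  n <- nrow(vox)
  x0 <- pmin(pmax(floor(vox[, 1]), 1), shape[1] - 1)
  y0 <- pmin(pmax(floor(vox[, 2]), 1), shape[2] - 1)
  z0 <- pmin(pmax(floor(vox[, 3]), 1), shape[3] - 1)
  fx <- vox[, 1] - x0; fy <- vox[, 2] - y0; fz <- vox[, 3] - z0
  nxy <- shape[1] * shape[2]
  nvox <- prod(shape)
  acc <- matrix(0, n, 3L)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) *
         (if (dz) fz else 1 - fz)
    idx <- (z0 + dz - 1) * nxy + (y0 + dy - 1) * shape[1] + (x0 + dx)
    v <- cbind(e1[idx], e1[idx + nvox], e1[idx + 2 * nvox])
    s <- sign(rowSums(v * refdir))
    s[s == 0] <- 1
    acc <- acc + (w * s) * v
  }
  nrm <- sqrt(rowSums(acc^2))
  list(dir = acc / pmax(nrm, .Machine$double.xmin), norm = nrm)
}

# March a batch of streamlines from seed points along a direction field.
march <- function(seeds, dirs, e1, fa_arr, shape, affine, fa_thresh,
                  cos_thresh, step_mm, max_steps) {
  n <- nrow(seeds)
  traj <- array(NA_real_, c(n, max_steps + 1L, 3L))
  traj[, 1L, ] <- seeds
  pts <- seeds
  cur <- dirs
  alive <- rep(TRUE, n)
  steps <- integer(n)
  for (s in seq_len(max_steps)) {
    if (!any(alive)) break
    ia <- which(alive)
    vox <- world_to_voxel(pts[ia, , drop = FALSE], affine)
    di <- interp_direction(e1, shape, vox, cur[ia, , drop = FALSE])
    ok <- di$norm > 1e-8
    cosang <- rowSums(di$dir * cur[ia, , drop = FALSE])
    ok <- ok & cosang >= cos_thresh
    newpts <- pts[ia, , drop = FALSE] + step_mm * di$dir
    nv <- world_to_voxel(newpts, affine)
    inside <- nv[, 1] >= 1 & nv[, 1] <= shape[1] &
              nv[, 2] >= 1 & nv[, 2] <= shape[2] &
              nv[, 3] >= 1 & nv[, 3] <= shape[3]
    ok <- ok & inside
    fa_new <- rep(0, length(ia))
    if (any(ok)) fa_new[ok] <- interp_trilinear(fa_arr,
                                                nv[ok, , drop = FALSE])
    ok <- ok & is.finite(fa_new) & fa_new >= fa_thresh
    keep <- ia[ok]
    alive[ia[!ok]] <- FALSE
    if (length(keep)) {
      pts[keep, ] <- newpts[ok, , drop = FALSE]
      cur[keep, ] <- di$dir[ok, , drop = FALSE]
      traj[keep, s + 1L, ] <- newpts[ok, , drop = FALSE]
      steps[keep] <- s
    }
  }
  lapply(seq_len(n), function(i) {
    k <- steps[i] + 1L
    matrix(traj[i, seq_len(k), ], ncol = 3L)
  })
}

#' Deterministic streamline tractography
#'
#' Euler integration along the principal eigenvector field (trilinearly
#' interpolated with local sign alignment), bidirectionally from every
#' seed, terminating when FA drops below `fa_thresh`, the per-step turning
#' angle exceeds `angle_thresh_deg`, or the streamline leaves the volume.
#' Streamlines shorter than `min_length_mm` are discarded.
#'
#' @param template a [tensor_volume()].
#' @param fa_thresh FA termination threshold in (0, 1), default 0.2.
#' @param angle_thresh_deg per-step turning-angle threshold, default 30.
#' @param step_mm integration step; default half the smallest voxel size.
#' @param seeds n x 3 matrix of world-space seed points; default one seed
#'   at the center of every in-mask voxel with FA >= `fa_thresh`.
#' @param min_length_mm minimum streamline length, default 10.
#' @param max_steps per-direction step budget.
#' @return list of streamlines (matrices of world points, >= 2 rows each),
#'   each with attribute `seed` (row index into the seed set).  Empty
#'   with a warning if no seed passes the threshold.
#' @export
track <- function(template, fa_thresh = 0.2, angle_thresh_deg = 30,
                  step_mm = NULL, seeds = NULL, min_length_mm = 10,
                  max_steps = 2000L) {
  stopifnot(inherits(template, "tensor_volume"),
            fa_thresh > 0, fa_thresh < 1,
            angle_thresh_deg > 0, angle_thresh_deg <= 90)
  if (is.null(step_mm)) step_mm <- 0.5 * min(voxel_size(template$affine))
  stopifnot(step_mm > 0)
  es <- eigendecompose(template)
  fa <- fractional_anisotropy(es)
  e1 <- array(es$vectors[, , , , 1L], c(template$shape, 3L))
  if (is.null(seeds)) {
    sel <- which(fa$mask & fa$values >= fa_thresh, arr.ind = TRUE)
    if (nrow(sel) == 0L) {
      warning("no seeds above the FA threshold")
      return(list())
    }
    seeds <- voxel_to_world(sel, template$affine)
  } else {
    seeds <- rbind_pts(seeds)
    svox <- world_to_voxel(seeds, template$affine)
    sfa <- interp_trilinear(fa$values, svox)
    keep <- is.finite(sfa) & sfa >= fa_thresh
    if (!any(keep)) {
      warning("no seeds above the FA threshold")
      return(list())
    }
    seeds <- seeds[keep, , drop = FALSE]
  }
  svox <- world_to_voxel(seeds, template$affine)
  d0 <- interp_direction(e1, template$shape, svox,
                         matrix(1, nrow(seeds), 3L))$dir
  cos_thresh <- cos(angle_thresh_deg * pi / 180)
  fwd <- march(seeds, d0, e1, fa$values, template$shape, template$affine,
               fa_thresh, cos_thresh, step_mm, max_steps)
  bwd <- march(seeds, -d0, e1, fa$values, template$shape, template$affine,
               fa_thresh, cos_thresh, step_mm, max_steps)
  out <- list()
  for (i in seq_along(fwd)) {
    b <- bwd[[i]]
    line <- rbind(b[rev(seq_len(nrow(b))[-1L]), , drop = FALSE], fwd[[i]])
    if (nrow(line) < 2L) next
    len <- sum(sqrt(rowSums(diff(line)^2)))
    if (len < min_length_mm) next
    attr(line, "seed") <- i
    out[[length(out) + 1L]] <- line
  }
  out
}

streamline_length <- function(line) sum(sqrt(rowSums(diff(line)^2)))

#' Select a fiber bundle by ROI logic
#'
#' Keeps streamlines that pass through every `AND` mask, through at least
#' one `OR` mask (when any OR terms are given), and through no `NOT` mask.
#' A streamline passes through a mask if any of its points falls in a
#' mask voxel (nearest-neighbour lookup).
#'
#' @param streamlines list of point matrices (world mm).
#' @param rois a [roi_atlas()] (or named list of logical arrays plus
#'   `affine`).
#' @param logic list of terms `list(op = "AND"|"OR"|"NOT", roi = name)`,
#'   applied in order for the selection log.
#' @param affine used when `rois` is a bare list.
#' @return object of class `fiber_bundle`: list with `streamlines`,
#'   `space`, `selection_log` (data.frame: op, roi, n_remaining) and flag
#'   `empty`.
#' @export
select_bundle <- function(streamlines, rois, logic, affine = NULL) {
  if (inherits(rois, "roi_atlas")) {
    masks <- rois$masks; affine <- rois$affine; shape <- rois$shape
  } else {
    masks <- rois; shape <- dim(masks[[1]])
    if (is.null(affine)) affine <- diag(4)
  }
  hits <- function(roi_name) {
    if (!roi_name %in% names(masks))
      stop("unknown ROI name: ", roi_name)
    m <- masks[[roi_name]]
    vapply(streamlines, function(line) {
      v <- interp_nearest(m, world_to_voxel(line, affine))
      any(!is.na(v) & v)
    }, logical(1))
  }
  keep <- rep(TRUE, length(streamlines))
  or_any <- NULL
  log_rows <- list()
  for (term in logic) {
    h <- hits(term$roi)
    if (term$op == "AND") keep <- keep & h
    else if (term$op == "NOT") keep <- keep & !h
    else if (term$op == "OR") {
      or_any <- if (is.null(or_any)) h else or_any | h
    } else stop("unknown ROI logic op: ", term$op)
    cur <- keep & (if (is.null(or_any)) TRUE else or_any)
    log_rows[[length(log_rows) + 1L]] <-
      data.frame(op = term$op, roi = term$roi, n_remaining = sum(cur))
  }
  if (!is.null(or_any)) keep <- keep & or_any
  sel <- streamlines[keep]
  structure(list(streamlines = sel, space = "template",
                 selection_log = if (length(log_rows))
                   do.call(rbind, log_rows) else
                   data.frame(op = character(), roi = character(),
                              n_remaining = integer()),
                 empty = length(sel) == 0L),
            class = "fiber_bundle")
}

# Resample a polyline at given arc-length fractions (linear interpolation).
resample_polyline <- function(line, fractions) {
  seg <- sqrt(rowSums(diff(line)^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  if (total <= 0) return(NULL)
  s <- fractions * total
  out <- matrix(0, length(s), 3L)
  for (c in 1:3) out[, c] <- stats::approx(cum, line[, c], xout = s,
                                           rule = 2)$y
  out
}

#' Arc-length parameterization of a fiber bundle
#'
#' Resamples every streamline to `K` points at equal arc-length fractions,
#' unifies orientations against the bundle medoid (the streamline with
#' the smallest summed endpoint distance to all others, allowing flips),
#' and aggregates a representative curve.  The point correspondence is
#' the orientation flip plus equal-fraction sampling that minimizes the
#' summed endpoint distance to the medoid.
#'
#' @param bundle a [fiber_bundle()] (or plain list of streamlines).
#' @param K points per streamline, >= 2.
#' @param aggregate `"mean"` (default) or `"median"` for the
#'   representative curve.
#' @return object of class `parameterized_tract_set`: list with `K`,
#'   `arc_fractions` (strictly increasing, 0 to 1), `points`
#'   (n x K x 3 resampled streamlines), `representative` (K x 3),
#'   `flipped` (logical per streamline), `n_dropped` (zero-length).
#' @export
parameterize <- function(bundle, K, aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  lines <- if (inherits(bundle, "fiber_bundle")) bundle$streamlines
           else bundle
  stopifnot(K >= 2L)
  if (length(lines) == 0L) stop("cannot parameterize an empty bundle")
  fr <- seq(0, 1, length.out = K)
  res <- lapply(lines, resample_polyline, fractions = fr)
  dropped <- vapply(res, is.null, logical(1))
  res <- res[!dropped]
  if (length(res) == 0L) stop("all streamlines have zero length")
  n <- length(res)
  starts <- t(vapply(res, function(m) m[1L, ], numeric(3)))
  ends <- t(vapply(res, function(m) m[K, ], numeric(3)))
  pd2 <- function(A, B) outer(rowSums(A^2), rep(1, nrow(B))) +
    outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * A %*% t(B)
  d_same <- sqrt(pmax(pd2(starts, starts), 0)) +
            sqrt(pmax(pd2(ends, ends), 0))
  d_flip <- sqrt(pmax(pd2(starts, ends), 0)) +
            sqrt(pmax(pd2(ends, starts), 0))
  best <- pmin(d_same, d_flip)
  medoid <- which.min(rowSums(best))
  flip <- d_flip[, medoid] < d_same[, medoid]
  pts <- array(0, c(n, K, 3L))
  for (i in seq_len(n)) {
    m <- res[[i]]
    if (flip[i]) m <- m[rev(seq_len(K)), , drop = FALSE]
    pts[i, , ] <- m
  }
  rep_curve <- apply(pts, c(2, 3), if (aggregate == "mean") mean
                                   else stats::median)
  structure(list(K = K, arc_fractions = fr, points = pts,
                 representative = rep_curve, flipped = flip,
                 n_dropped = sum(dropped)),
            class = "parameterized_tract_set")
}

#' Map parameterized tract points to native space and sample a measure
#'
#' Each representative point is pushed through a subject's inverse
#' deformation field and the subject's native-space scalar measure is
#' sampled there by trilinear interpolation.  Points mapping outside the
#' measure volume yield NA.
#'
#' @param pts a [parameterize()]d tract set or a K x 3 matrix of
#'   population-space points.
#' @param inverse_fields named list of per-subject [deformation_field()]s
#'   (population -> native).
#' @param native_measures named list of per-subject [scalar_volume()]s;
#'   names must match `inverse_fields`.
#' @return subjects x K numeric matrix with attribute `n_missing`
#'   (per-subject NA counts).
#' @export
map_to_native_and_sample <- function(pts, inverse_fields, native_measures) {
  P <- if (inherits(pts, "parameterized_tract_set")) pts$representative
       else rbind_pts(pts)
  subj <- names(inverse_fields)
  if (is.null(subj) || is.null(names(native_measures)))
    stop("inverse_fields and native_measures must be named per subject")
  missing_m <- setdiff(subj, names(native_measures))
  if (length(missing_m))
    stop("missing native measure for subject: ", missing_m[1])
  out <- matrix(NA_real_, length(subj), nrow(P),
                dimnames = list(subj, NULL))
  nmiss <- stats::setNames(integer(length(subj)), subj)
  for (s in subj) {
    d <- inverse_fields[[s]]
    native <- P + interp_field(d, P)
    v <- interp_trilinear(native_measures[[s]]$values,
                          world_to_voxel(native, native_measures[[s]]$affine))
    out[s, ] <- v
    nmiss[s] <- sum(!is.finite(v))
  }
  attr(out, "n_missing") <- nmiss
  out
}

# ---- streamline file formats --------------------------------------------

#' Write / read streamlines in TCK format
#'
#' MRtrix TCK: text header, Float32LE triplets, streamlines separated by
#' NaN triplets, file terminated by an Inf triplet.  Coordinates are
#' world-space mm.
#'
#' @param streamlines list of point matrices.
#' @param path file path.
#' @return `read_tck`: list of point matrices.
#' @export
write_tck <- function(streamlines, path) {
  hdr_fixed <- c("mrtrix tracks",
                 "datatype: Float32LE",
                 sprintf("count: %d", length(streamlines)))
  # compute offset: header lines + "file: . OFFSET" + "END" newline-joined
  offset <- 0L
  repeat {
    lines <- c(hdr_fixed, sprintf("file: . %d", offset), "END")
    need <- sum(nchar(lines, type = "bytes")) + length(lines)
    if (need <= offset) break
    offset <- need
  }
  con <- file(path, "wb")
  on.exit(close(con))
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  writeChar(txt, con, eos = NULL)
  pad <- offset - nchar(txt, type = "bytes")
  if (pad > 0) writeBin(raw(pad), con)
  for (line in streamlines) {
    writeBin(as.vector(t(line)), con, size = 4L, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4L, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4L, endian = "little")
  invisible(path)
}

#' @rdname write_tck
#' @export
read_tck <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  lines <- character()
  repeat {
    ln <- readBin(con, "raw", n = 1L)
    buf <- raw()
    while (length(ln) && ln != as.raw(10L)) {
      buf <- c(buf, ln)
      ln <- readBin(con, "raw", n = 1L)
    }
    lines <- c(lines, rawToChar(buf))
    if (identical(lines[length(lines)], "END")) break
    if (length(lines) > 1000L) stop("malformed TCK header")
  }
  if (!identical(lines[1], "mrtrix tracks")) stop("not a TCK file")
  filefield <- grep("^file: ", lines, value = TRUE)
  offset <- as.integer(sub("^file: \\. ", "", filefield))
  dt <- grep("^datatype: ", lines, value = TRUE)
  if (!identical(sub("^datatype: ", "", dt), "Float32LE"))
    stop("only Float32LE TCK files are supported")
  seek(con, offset)
  vals <- readBin(con, "double", n = file.size(path), size = 4L,
                  endian = "little")
  m <- matrix(vals, ncol = 3L, byrow = TRUE)
  out <- list()
  cur <- integer()
  for (i in seq_len(nrow(m))) {
    if (any(is.infinite(m[i, ]))) break
    if (any(is.nan(m[i, ]))) {
      if (length(cur)) out[[length(out) + 1L]] <- m[cur, , drop = FALSE]
      cur <- integer()
    } else cur <- c(cur, i)
  }
  if (length(cur)) out[[length(out) + 1L]] <- m[cur, , drop = FALSE]
  out
}

#' Write / read streamlines in TrackVis TRK format
#'
#' Minimal TRK v2 support: no per-point scalars or per-track properties,
#' `vox_to_ras` stored and honored on read (nibabel's voxmm convention
#' with the half-voxel shift).  The writer exists mainly to round-trip
#' the reader; TCK is the primary interchange format.
#'
#' @param streamlines list of point matrices (world mm).
#' @param path file path.
#' @param affine voxel-to-world matrix stored as `vox_to_ras`.
#' @param voxel_sizes length-3 voxel size (mm); default from `affine`.
#' @param dim grid dimensions.
#' @return `read_trk`: list of point matrices in world mm.
#' @export
write_trk <- function(streamlines, path, affine = diag(4),
                      voxel_sizes = NULL, dim = c(1L, 1L, 1L)) {
  if (is.null(voxel_sizes)) voxel_sizes <- voxel_size(affine)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- raw(1000)
  put <- function(off, val, size) {
    b <- writeBin(val, raw(), size = size, endian = "little")
    hdr[(off + 1):(off + length(b))] <<- b
  }
  hdr[1:6] <- c(charToRaw("TRACK"), as.raw(0L))
  put(6L, as.integer(dim), 2L)
  put(12L, as.double(voxel_sizes), 4L)
  put(24L, c(0, 0, 0), 4L)              # origin
  put(36L, 0L, 2L)                      # n_scalars
  put(238L, 0L, 2L)                     # n_properties
  put(440L, as.double(t(affine)), 4L)   # vox_to_ras, row-major
  hdr[949:952] <- c(charToRaw("RAS"), as.raw(0L))  # voxel_order
  put(988L, length(streamlines), 4L)    # n_count
  put(992L, 2L, 4L)                     # version
  put(996L, 1000L, 4L)                  # hdr_size
  writeBin(hdr, con)
  inv <- solve(affine)
  for (line in streamlines) {
    vox <- sweep(line %*% t(inv[1:3, 1:3]), 2, inv[1:3, 4], "+")
    voxmm <- sweep(vox + 0.5, 2, voxel_sizes, "*")
    writeBin(nrow(line), con, size = 4L, endian = "little")
    writeBin(as.vector(t(voxmm)), con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' @rdname write_trk
#' @export
read_trk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 1000L)
  if (!identical(rawToChar(hdr[1:5]), "TRACK")) stop("not a TRK file")
  rd <- function(off, n, size, what = "integer")
    readBin(hdr[(off + 1):(off + n * size)], what, n = n, size = size,
            endian = "little")
  voxel_size <- rd(12L, 3L, 4L, "double")
  n_scalars <- rd(36L, 1L, 2L)
  n_properties <- rd(238L, 1L, 2L)
  M <- matrix(rd(440L, 16L, 4L, "double"), 4, 4, byrow = TRUE)
  if (all(M == 0)) M <- diag(4)          # legacy files without vox_to_ras
  n_count <- rd(988L, 1L, 4L)
  hdr_size <- rd(996L, 1L, 4L)
  if (hdr_size != 1000L) stop("unsupported TRK header size: ", hdr_size)
  out <- list()
  repeat {
    np <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
    if (length(np) == 0L) break
    vals <- readBin(con, "double", n = np * (3L + n_scalars), size = 4L,
                    endian = "little")
    m <- matrix(vals, ncol = 3L + n_scalars, byrow = TRUE)[, 1:3,
                                                           drop = FALSE]
    if (n_properties > 0L)
      readBin(con, "double", n = n_properties, size = 4L, endian = "little")
    vox <- sweep(m, 2, voxel_size, "/") - 0.5
    world <- sweep(vox %*% t(M[1:3, 1:3]), 2, M[1:3, 4], "+")
    out[[length(out) + 1L]] <- world
    if (n_count > 0L && length(out) >= n_count) break
  }
  out
}
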