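# Minimal NIfTI-1 reader/writer (single-file .nii / .nii.gz, sform affine,
# little-endian on write, either endianness on read).  Implemented in base
# R because no NIfTI package is available in the supported dependency set;
# covers exactly what this package stores: 3-D scalar images and 4-D
# component images (6 tensor components or 3 displacement components).

NIFTI_DT <- list(`2`  = list(what = "integer", size = 1L, signed = FALSE),
                 `4`  = list(what = "integer", size = 2L, signed = TRUE),
                 `8`  = list(what = "integer", size = 4L, signed = TRUE),
                 `16` = list(what = "double",  size = 4L, signed = TRUE),
                 `64` = list(what = "double",  size = 8L, signed = TRUE))

nifti_con <- function(path, open) {
  gzfile(path, open)  # reads plain files transparently; gz-compresses *.gz
}

#' Read a NIfTI-1 image
#'
#' Supports single-file `.nii` / `.nii.gz`, 3-D or 4-D, datatypes uint8,
#' int16, int32, float32, float64, with `scl_slope`/`scl_inter` applied.
#' The sform affine is used when present, otherwise a diagonal affine from
#' `pixdim`.
#'
#' @param path file path.
#' @return list with `data` (numeric array) and `affine` (4x4).
#' @export
read_nifti <- function(path) {
  con <- nifti_con(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348L)
  endian <- "little"
  sz <- readBin(hdr[1:4], "integer", size = 4L, endian = endian)
  if (sz != 348L) {
    endian <- "big"
    sz <- readBin(hdr[1:4], "integer", size = 4L, endian = endian)
    if (sz != 348L) stop("not a NIfTI-1 file: ", path)
  }
  rd_i16 <- function(off, n) readBin(hdr[(off + 1):(off + 2 * n)], "integer",
                                     n = n, size = 2L, endian = endian)
  rd_f32 <- function(off, n) readBin(hdr[(off + 1):(off + 4 * n)], "double",
                                     n = n, size = 4L, endian = endian)
  dim8 <- rd_i16(40L, 8L)
  ndim <- dim8[1]
  if (ndim < 3L || ndim > 4L) stop("only 3-D/4-D NIfTI images are supported")
  shape <- dim8[2:(1 + ndim)]
  datatype <- rd_i16(70L, 1L)
  spec <- NIFTI_DT[[as.character(datatype)]]
  if (is.null(spec)) stop("unsupported NIfTI datatype code: ", datatype)
  pixdim <- rd_f32(76L, 8L)
  vox_offset <- rd_f32(108L, 1L)
  scl_slope <- rd_f32(112L, 1L)
  scl_inter <- rd_f32(116L, 1L)
  sform_code <- rd_i16(254L, 1L)
  n <- prod(shape)
  if (vox_offset > 348) readBin(con, "raw", n = as.integer(vox_offset) - 348L)
  data <- readBin(con, spec$what, n = n, size = spec$size,
                  signed = spec$signed, endian = endian)
  data <- as.double(data)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    data <- data * scl_slope + scl_inter
  affine <- if (sform_code > 0L) {
    rbind(rd_f32(280L, 4L), rd_f32(296L, 4L), rd_f32(312L, 4L), c(0, 0, 0, 1))
  } else {
    diag(c(pixdim[2:4], 1))
  }
  list(data = array(data, shape), affine = affine)
}

#' Write a NIfTI-1 image
#'
#' Writes float32 (default) or float64 data with the affine stored in the
#' sform (and mirrored in pixdim), little-endian, single-file.
#'
#' @param x a [scalar_volume()] (3-D), [tensor_volume()] (4-D, 6
#'   components), [deformation_field()] (4-D, 3 components), or a bare
#'   numeric array with an `affine` argument.
#' @param path output path; `.nii.gz` is gz-compressed.
#' @param affine used only when `x` is a bare array.
#' @param datatype `"float32"` or `"float64"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path, affine = diag(4),
                        datatype = c("float32", "float64")) {
  datatype <- match.arg(datatype)
  if (inherits(x, "scalar_volume")) { arr <- x$values; affine <- x$affine }
  else if (inherits(x, "tensor_volume")) { arr <- x$tensors; affine <- x$affine }
  else if (inherits(x, "deformation_field")) { arr <- x$disp; affine <- x$affine }
  else arr <- x
  stopifnot(is.array(arr), length(dim(arr)) %in% c(3L, 4L))
  d <- dim(arr)
  ndim <- length(d)
  dim8 <- integer(8); dim8[1] <- ndim; dim8[2:(1 + ndim)] <- d
  if (any(dim8[-1] == 0L)) dim8[dim8 == 0L] <- 1L
  dtcode <- if (datatype == "float32") 16L else 64L
  bitpix <- if (datatype == "float32") 32L else 64L
  vs <- voxel_size(affine)
  pixdim <- c(1, vs, rep(1, 4))

  hdr <- raw(348)
  put <- function(off, val, size, what) {
    b <- writeBin(val, raw(), size = size, endian = "little")
    if (what == "char") b <- b[seq_along(val)]
    hdr[(off + 1):(off + length(b))] <<- b
  }
  put(0L, 348L, 4L, "int")
  put(40L, as.integer(dim8), 2L, "int")
  put(70L, dtcode, 2L, "int")
  put(72L, bitpix, 2L, "int")
  put(76L, pixdim, 4L, "double")
  put(108L, 352, 4L, "double")          # vox_offset
  put(112L, 1, 4L, "double")            # scl_slope
  put(116L, 0, 4L, "double")            # scl_inter
  put(252L, 0L, 2L, "int")              # qform_code
  put(254L, 2L, 2L, "int")              # sform_code = aligned
  put(280L, affine[1, ], 4L, "double")
  put(296L, affine[2, ], 4L, "double")
  put(312L, affine[3, ], 4L, "double")
  hdr[345:348] <- c(charToRaw("n+1"), as.raw(0L))

  con <- nifti_con(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  writeBin(raw(4), con)                  # extension flag
  writeBin(as.vector(arr), con, size = if (datatype == "float32") 4L else 8L,
           endian = "little")
  invisible(path)
}

#' Read volumes in package containers
#'
#' `read_scalar_nifti`, `read_tensor_nifti` and `read_deformation_nifti`
#' wrap [read_nifti()] and return the corresponding package container.
#' Tensor images must carry 6 components (Dxx, Dxy, Dyy, Dxz, Dyz, Dzz)
#' and deformation images 3 (mm displacements) on the 4th axis.
#'
#' @param path file path.
#' @return a [scalar_volume()], [tensor_volume()] or [deformation_field()].
#' @export
read_scalar_nifti <- function(path) {
  x <- read_nifti(path)
  if (length(dim(x$data)) != 3L) stop("expected a 3-D scalar image")
  scalar_volume(x$data, x$affine)
}

#' @rdname read_scalar_nifti
#' @export
read_tensor_nifti <- function(path) {
  x <- read_nifti(path)
  if (length(dim(x$data)) != 4L || dim(x$data)[4] != 6L)
    stop("expected a 4-D image with 6 tensor components")
  tensor_volume(x$data, x$affine)
}

#' @rdname read_scalar_nifti
#' @param source_space,target_space space tags for the returned field.
#' @export
read_deformation_nifti <- function(path, source_space = "source",
                                   target_space = "target") {
  x <- read_nifti(path)
  if (length(dim(x$data)) != 4L || dim(x$data)[4] != 3L)
    stop("expected a 4-D image with 3 displacement components")
  deformation_field(x$data, x$affine, source_space, target_space)
}

#' Read / write a 4x4 affine as whitespace-delimited text
#' @param path file path.
#' @return `read_affine_text`: 4x4 matrix.
#' @export
read_affine_text <- function(path) {
  m <- as.matrix(utils::read.table(path))
  dimnames(m) <- NULL
  stopifnot(all(dim(m) == c(4L, 4L)))
  m
}

#' @rdname read_affine_text
#' @param matrix 4x4 matrix (or an [affine_transform()]).
#' @export
write_affine_text <- function(matrix, path) {
  if (inherits(matrix, "affine_transform")) matrix <- matrix$matrix
  utils::write.table(format(matrix, digits = 17), path,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
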