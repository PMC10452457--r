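# Minimal NIfTI-1 reader/writer.
#
# The package only needs single-frame 3D volumes with an affine, so this
# implements the NIfTI-1 single-file (.nii / .nii.gz) format directly:
# 348-byte header, sform/qform orientation, the common scalar dtypes, and
# scl_slope/scl_inter intensity scaling on read. Written files carry the
# affine in both srow_* (sform_code 2) and pixdim, little-endian.

NIFTI_DTYPES <- list(
  `2`   = list(what = "integer", size = 1, signed = FALSE),  # uint8
  `4`   = list(what = "integer", size = 2, signed = TRUE),   # int16
  `8`   = list(what = "integer", size = 4, signed = TRUE),   # int32
  `16`  = list(what = "double",  size = 4, signed = TRUE),   # float32
  `64`  = list(what = "double",  size = 8, signed = TRUE),   # float64
  `256` = list(what = "integer", size = 1, signed = TRUE),   # int8
  `512` = list(what = "integer", size = 2, signed = FALSE)   # uint16
)

read_file_raw <- function(path) {
  con <- gzfile(path, "rb")   # reads plain files transparently too
  on.exit(close(con))
  chunks <- list()
  repeat {
    b <- readBin(con, what = "raw", n = 2^22)
    if (length(b) == 0) break
    chunks[[length(chunks) + 1L]] <- b
  }
  do.call(c, chunks)
}

#' Read a NIfTI-1 volume
#'
#' Reads a single-file NIfTI-1 volume (`.nii` or `.nii.gz`) into a
#' [volume_grid]. The affine is taken from the sform when `sform_code > 0`,
#' else from the qform, else from `pixdim`. Only 3D volumes are supported.
#'
#' @param path file path.
#' @return a [volume_grid].
#' @export
read_nifti <- function(path) {
  raw <- read_file_raw(path)
  if (length(raw) < 352) stop("not a NIfTI-1 file (too short): ", path)
  rd <- function(off, what, n, size, signed = TRUE, endian = "little") {
    readBin(raw[(off + 1):(off + n * size)], what = what, n = n, size = size,
            signed = signed, endian = endian)
  }
  endian <- "little"
  if (rd(0, "integer", 1, 4) != 348L) {
    if (readBin(raw[1:4], "integer", 1, 4, endian = "big") == 348L)
      endian <- "big"
    else stop("not a NIfTI-1 file (bad sizeof_hdr): ", path)
  }
  rd2 <- function(off, what, n, size, signed = TRUE)
    rd(off, what, n, size, signed, endian)
  magic <- rawToChar(raw[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop("unsupported NIfTI magic '", magic, "' in ", path)
  dim0     <- rd2(40, "integer", 8, 2)
  datatype <- rd2(70, "integer", 1, 2)
  pixdim   <- rd2(76, "double", 8, 4)
  vox_off  <- rd2(108, "double", 1, 4)
  scl_slope <- rd2(112, "double", 1, 4)
  scl_inter <- rd2(116, "double", 1, 4)
  qform_code <- rd2(252, "integer", 1, 2)
  sform_code <- rd2(254, "integer", 1, 2)

  nd <- dim0[1]
  if (nd < 3 || any(dim0[5:8][seq_len(max(0, nd - 3))] > 1))
    stop("only 3D NIfTI volumes are supported (dim = ",
         paste(dim0, collapse = ","), ")")
  dm <- dim0[2:4]

  dt <- NIFTI_DTYPES[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code ", datatype)
  n <- prod(dm)
  start <- as.integer(round(vox_off))
  vals <- readBin(raw[(start + 1):(start + n * dt$size)], what = dt$what,
                  n = n, size = dt$size, signed = dt$signed, endian = endian)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter

  affine <- NULL
  if (sform_code > 0) {
    affine <- rbind(rd2(280, "double", 4, 4),
                    rd2(296, "double", 4, 4),
                    rd2(312, "double", 4, 4),
                    c(0, 0, 0, 1))
  } else if (qform_code > 0) {
    q <- rd2(256, "double", 3, 4)       # quatern_b, c, d
    qoff <- rd2(268, "double", 3, 4)
    b <- q[1]; cc <- q[2]; d <- q[3]
    a2 <- 1 - b * b - cc * cc - d * d
    a <- sqrt(max(a2, 0))
    R <- matrix(c(
      a * a + b * b - cc * cc - d * d, 2 * (b * cc + a * d), 2 * (b * d - a * cc),
      2 * (b * cc - a * d), a * a + cc * cc - b * b - d * d, 2 * (cc * d + a * b),
      2 * (b * d + a * cc), 2 * (cc * d - a * b), a * a + d * d - b * b - cc * cc
    ), nrow = 3)
    qfac <- if (pixdim[1] < 0) -1 else 1
    sc <- c(pixdim[2:3], qfac * pixdim[4])
    affine <- rbind(cbind(sweep(R, 2, sc, `*`), qoff), c(0, 0, 0, 1))
  } else {
    affine <- diag(c(pixdim[2:4], 1))
  }
  volume_grid(array(vals, dim = dm), affine = affine)
}

#' Write a NIfTI-1 volume
#'
#' Writes a [volume_grid] as a little-endian single-file NIfTI-1 volume; the
#' affine is stored as the sform (code 2, "aligned"). Paths ending in `.gz`
#' are gzip-compressed.
#'
#' @param grid a [volume_grid].
#' @param path output path (`.nii` or `.nii.gz`).
#' @param datatype one of `"auto"`, `"uint8"`, `"int16"`, `"int32"`,
#'   `"float32"`, `"float64"`. `"auto"` picks the narrowest integer type that
#'   holds the data exactly, falling back to `float64`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(grid, path, datatype = "auto") {
  stopifnot(inherits(grid, "volume_grid"))
  v <- as.vector(grid$data)
  if (is.logical(v)) v <- as.integer(v)
  if (datatype == "auto") {
    if (all(v == round(v))) {
      rng <- range(v)
      datatype <- if (rng[1] >= 0 && rng[2] <= 255) "uint8"
                  else if (rng[1] >= -32768 && rng[2] <= 32767) "int16"
                  else "int32"
    } else datatype <- "float64"
  }
  code <- switch(datatype, uint8 = 2L, int16 = 4L, int32 = 8L,
                 float32 = 16L, float64 = 64L,
                 stop("unsupported datatype: ", datatype))
  size <- switch(datatype, uint8 = 1L, int16 = 2L, int32 = 4L,
                 float32 = 4L, float64 = 8L)
  what <- if (code %in% c(16L, 64L)) "double" else "integer"
  if (what == "integer") v <- as.integer(round(v))

  dm <- dim(grid$data)
  A <- grid$affine
  pix <- grid_spacing(grid)

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x, size = 4) writeBin(as.double(x), con, size = size,
                                       endian = "little")
  wi(348L, 4)                                   # sizeof_hdr
  writeBin(raw(36), con)                        # data_type..dim_info (unused)
  wi(c(3L, dm, 1L, 1L, 1L, 1L), 2)              # dim[8]
  wf(c(0, 0, 0))                                # intent_p1..p3
  wi(0L, 2)                                     # intent_code
  wi(code, 2)                                   # datatype
  wi(8L * size, 2)                              # bitpix
  wi(0L, 2)                                     # slice_start
  wf(c(1, pix, 0, 0, 0, 0))                     # pixdim[8] (qfac = 1)
  wf(352)                                       # vox_offset
  wf(c(1, 0))                                   # scl_slope, scl_inter
  wi(0L, 2); writeBin(raw(2), con)              # slice_end, slice_code+xyzt
  wf(c(0, 0, 0, 0))                             # cal_max..toffset
  wi(c(0L, 0L), 4)                              # glmax, glmin
  writeBin(raw(104), con)                       # descrip[80] + aux_file[24]
  wi(c(0L, 2L), 2)                              # qform_code, sform_code
  wf(c(0, 0, 0, 0, 0, 0))                       # quatern, qoffset
  wf(A[1, ]); wf(A[2, ]); wf(A[3, ])            # srow_x, srow_y, srow_z
  writeBin(raw(16), con)                        # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con) # magic
  writeBin(raw(4), con)                         # extension flag
  if (what == "integer" && size == 1) {
    writeBin(as.raw(v), con)
  } else {
    writeBin(if (what == "integer") as.integer(v) else as.double(v),
             con, size = size, endian = "little")
  }
  invisible(path)
}

#' Read a binary mask volume
#'
#' [read_nifti] plus validation that voxel values are exactly 0/1.
#'
#' @param path NIfTI file path.
#' @return a [volume_grid] with logical-equivalent 0/1 data.
#' @export
read_mask <- function(path) {
  g <- read_nifti(path)
  g$data <- array(as.integer(as_binary_array(g, what = paste0("mask ", path))),
                  dim = dim(g$data))
  g
}

#' Write a 0-17 label map
#'
#' Validates that voxel values are integers in 0..17 and writes a uint8
#' NIfTI volume with the input affine unchanged.
#'
#' @param grid a [volume_grid] of labels.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(grid, path) {
  v <- as.vector(grid$data)
  if (any(v != round(v)) || min(v) < 0 || max(v) > 17)
    stop("label map must contain integers in 0..17")
  write_nifti(grid, path, datatype = "uint8")
}
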