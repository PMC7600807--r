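# Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
#
# Only what the pipeline needs: 3D volumes, datatypes uint8 / int16 / int32 /
# float32 / float64, scl_slope/scl_inter scaling, sform (preferred) or qform
# affine.  Files are written little-endian with an sform affine and magic
# "n+1"; reads auto-detect endianness from sizeof_hdr.

NIFTI_DATATYPES <- list(
  uint8   = list(code = 2L,  bitpix = 8L,  what = "integer", size = 1L, signed = FALSE),
  int16   = list(code = 4L,  bitpix = 16L, what = "integer", size = 2L, signed = TRUE),
  int32   = list(code = 8L,  bitpix = 32L, what = "integer", size = 4L, signed = TRUE),
  float32 = list(code = 16L, bitpix = 32L, what = "double",  size = 4L, signed = TRUE),
  float64 = list(code = 64L, bitpix = 64L, what = "double",  size = 8L, signed = TRUE)
)

#' Read a NIfTI-1 volume
#'
#' Reads a single-file NIfTI-1 image (`.nii`, or `.nii.gz` transparently).
#' Intensity scaling (`scl_slope`, `scl_inter`) is applied; the affine is
#' taken from the sform when `sform_code > 0`, else from the qform, else
#' from `pixdim` alone.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A list of class `nifti_image` with elements `data` (numeric
#'   array), `affine` (4x4 voxel-to-world matrix) and `pixdim` (voxel sizes).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) {
    stop("NIfTI file not found: ", path)
  }
  con <- gzfile(path, "rb")
  on.exit(close(con), add = TRUE)

  hdr_raw <- readBin(con, "raw", n = 348L)
  if (length(hdr_raw) < 348L) {
    stop("File too short to hold a NIfTI-1 header: ", path)
  }
  endian <- "little"
  sizeof_hdr <- readBin(hdr_raw[1:4], "integer", size = 4L, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    sizeof_hdr <- readBin(hdr_raw[1:4], "integer", size = 4L, endian = endian)
    if (sizeof_hdr != 348L) {
      stop("Not a NIfTI-1 file (sizeof_hdr != 348): ", path)
    }
  }
  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1")) {
    stop("Unsupported NIfTI magic '", magic, "' in ", path)
  }
  if (magic == "ni1") {
    stop("Two-file NIfTI (.hdr/.img) is not supported: ", path)
  }

  rd_i16 <- function(off, n) readBin(hdr_raw[(off + 1):(off + 2L * n)],
                                     "integer", n = n, size = 2L, endian = endian)
  rd_f32 <- function(off, n) readBin(hdr_raw[(off + 1):(off + 4L * n)],
                                     "double", n = n, size = 4L, endian = endian)

  dim_field <- rd_i16(40L, 8L)
  ndim <- dim_field[1]
  if (ndim < 1L || ndim > 7L) stop("Corrupt dim[0] = ", ndim, " in ", path)
  shape <- dim_field[2:(1 + ndim)]
  datatype <- rd_i16(70L, 1L)
  pixdim <- rd_f32(76L, 8L)
  vox_offset <- rd_f32(108L, 1L)
  scl_slope <- rd_f32(112L, 1L)
  scl_inter <- rd_f32(116L, 1L)
  qform_code <- rd_i16(252L, 1L)
  sform_code <- rd_i16(254L, 1L)
  quatern <- rd_f32(256L, 6L)
  srow <- matrix(rd_f32(280L, 12L), nrow = 3, byrow = TRUE)

  dt <- NULL
  for (nm in names(NIFTI_DATATYPES)) {
    if (NIFTI_DATATYPES[[nm]]$code == datatype) dt <- NIFTI_DATATYPES[[nm]]
  }
  if (is.null(dt)) stop("Unsupported NIfTI datatype code ", datatype, " in ", path)

  # skip extension flag + any header extensions up to vox_offset
  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0L) invisible(readBin(con, "raw", n = skip))

  n_vox <- prod(shape)
  data <- readBin(con, dt$what, n = n_vox, size = dt$size,
                  signed = dt$signed, endian = endian)
  if (length(data) != n_vox) {
    stop("Truncated NIfTI data in ", path, ": expected ", n_vox,
         " voxels, got ", length(data))
  }
  data <- as.numeric(data)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0)) {
    data <- data * scl_slope + scl_inter
  }
  dim(data) <- shape

  affine <- if (sform_code > 0L) {
    rbind(srow, c(0, 0, 0, 1))
  } else if (qform_code > 0L) {
    qform_affine(quatern, pixdim)
  } else {
    diag(c(abs(pixdim[2:4]), 1))
  }

  structure(list(data = data, affine = affine, pixdim = pixdim[2:(1 + min(ndim, 3))]),
            class = "nifti_image")
}

# NIfTI quaternion (method 2) voxel-to-world transform
qform_affine <- function(quatern, pixdim) {
  b <- quatern[1]; c_ <- quatern[2]; d <- quatern[3]
  a2 <- 1 - b^2 - c_^2 - d^2
  a <- if (a2 < 1e-7) 0 else sqrt(a2)
  R <- matrix(c(
    a^2 + b^2 - c_^2 - d^2, 2 * (b * c_ - a * d),   2 * (b * d + a * c_),
    2 * (b * c_ + a * d),   a^2 + c_^2 - b^2 - d^2, 2 * (c_ * d - a * b),
    2 * (b * d - a * c_),   2 * (c_ * d + a * b),   a^2 + d^2 - b^2 - c_^2
  ), nrow = 3, byrow = TRUE)
  qfac <- if (pixdim[1] < 0) -1 else 1
  S <- R %*% diag(c(pixdim[2], pixdim[3], qfac * pixdim[4]))
  rbind(cbind(S, quatern[4:6]), c(0, 0, 0, 1))
}

#' Write a 3D array as a NIfTI-1 volume
#'
#' Writes a single-file little-endian NIfTI-1 image with an sform affine.
#' Gzip compression is chosen by the `.gz` extension.
#'
#' @param data Numeric or logical 3D array.
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @param affine 4x4 voxel-to-world matrix (default identity, 1 mm voxels).
#' @param datatype `"float32"` (default), `"uint8"` (for masks), `"int16"`,
#'   `"int32"` or `"float64"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, affine = diag(4), datatype = "float32") {
  if (is.logical(data)) data <- array(as.integer(data), dim = dim(data))
  if (length(dim(data)) != 3L) stop("write_nifti() expects a 3D array")
  if (!identical(dim(affine), c(4L, 4L))) stop("affine must be a 4x4 matrix")
  dt <- NIFTI_DATATYPES[[datatype]]
  if (is.null(dt)) stop("Unsupported datatype: ", datatype)

  shape <- dim(data)
  pixdim <- c(1, sqrt(colSums(affine[1:3, 1:3]^2)), 0, 0, 0, 0)

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con), add = TRUE)
  en <- "little"
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = en)
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = en)
  w_f32 <- function(x) writeBin(as.double(x), con, size = 4L, endian = en)
  w_raw <- function(n) writeBin(raw(n), con)

  w_i32(348L)                          # sizeof_hdr
  w_raw(36L)                           # data_type..dim_info (unused)
  w_i16(c(3L, shape, 1L, 1L, 1L, 1L))  # dim[8]
  w_raw(14L)                           # intent_p1..intent_code
  w_i16(dt$code)                       # datatype
  w_i16(dt$bitpix)                     # bitpix
  w_i16(0L)                            # slice_start
  w_f32(pixdim)                        # pixdim[8]
  w_f32(352)                           # vox_offset
  w_f32(c(1, 0))                       # scl_slope, scl_inter
  w_i16(0L); w_raw(2L)                 # slice_end, slice_code, xyzt_units
  w_f32(c(0, 0, 0))                    # cal_max, cal_min, slice_duration
  w_f32(0)                             # toffset
  w_i32(c(0L, 0L))                     # glmax, glmin
  w_raw(104L)                          # descrip[80] + aux_file[24]
  w_i16(c(0L, 2L))                     # qform_code = 0, sform_code = 2 (template)
  w_f32(rep(0, 6))                     # quaternions + offsets
  w_f32(t(affine[1:3, , drop = FALSE]))  # srow_x, srow_y, srow_z
  w_raw(16L)                           # intent_name[16]
  writeBin(c(charToRaw("n+1"), raw(1)), con)  # magic
  w_raw(4L)                            # extension flag

  if (dt$what == "integer") {
    writeBin(as.integer(round(data)), con, size = dt$size, endian = en)
  } else {
    writeBin(as.double(data), con, size = dt$size, endian = en)
  }
  invisible(path)
}

#' @export
print.nifti_image <- function(x, ...) {
  cat("<nifti_image> ", paste(dim(x$data), collapse = " x "),
      " voxels, pixdim ", paste(signif(x$pixdim, 4), collapse = " x "), "\n", sep = "")
  invisible(x)
}
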