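# Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
#
# Only what the field-map pipeline needs: little-endian, 2D/3D volumes,
# datatypes uint8 / int16 / int32 / float32 / float64, scl_slope / scl_inter
# honoured on read.  No R NIfTI package ships with this toolchain, so the
# 348-byte fixed header is written by hand.

NIFTI_HDR_SIZE <- 348L
NIFTI_VOX_OFFSET <- 352

nifti_dtypes <- data.frame(
  code   = c(2L, 4L, 8L, 16L, 64L),
  what   = c("integer", "integer", "integer", "double", "double"),
  size   = c(1L, 2L, 4L, 4L, 8L),
  signed = c(FALSE, TRUE, TRUE, TRUE, TRUE)
)

nifti_connection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Write a numeric array to a NIfTI-1 file
#'
#' Writes a 2D or 3D array as a single-file little-endian NIfTI-1 volume
#' (float32 data). Gzip compression is chosen from the file extension
#' (`.nii.gz`).
#'
#' @param values numeric 2D/3D array.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param spacing per-axis voxel size in mm (recycled to the array rank).
#' @param description free-text tag stored in the header (max 79 chars).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(values, path, spacing = rep(1, length(dim(values))),
                        description = "coilsafe") {
  dm <- dim(values)
  if (is.null(dm) || !(length(dm) %in% c(2L, 3L)))
    stop("write_nifti(): `values` must be a 2D or 3D array")
  spacing <- rep_len(as.numeric(spacing), length(dm))
  con <- nifti_connection(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wc <- function(s, n) {
    raw <- charToRaw(substr(s, 1L, n))
    writeBin(c(raw, raw(n - length(raw))), con)
  }
  wi(NIFTI_HDR_SIZE, 4L)                         # sizeof_hdr
  wc("", 10L); wc("", 18L)                       # data_type, db_name (unused)
  wi(0L, 4L); wi(0L, 2L); wc("r", 1L); wc("", 1L)  # extents..dim_info
  dims <- c(length(dm), dm, rep(1L, 7L - length(dm)))
  wi(dims, 2L)                                   # dim[8]
  wf(c(0, 0, 0)); wi(0L, 2L)                     # intent_p1..intent_code
  wi(16L, 2L); wi(32L, 2L); wi(0L, 2L)           # datatype, bitpix, slice_start
  wf(c(1, spacing, rep(1, 7 - length(spacing)))) # pixdim[8]
  wf(NIFTI_VOX_OFFSET)                           # vox_offset
  wf(1); wf(0)                                   # scl_slope, scl_inter
  wi(0L, 2L); wc("", 1L); wc("", 1L)             # slice_end, slice_code, xyzt_units
  wf(c(0, 0, 0, 0))                              # cal_max..toffset
  wi(c(0L, 0L), 4L)                              # glmax, glmin
  wc(description, 80L); wc("", 24L)              # descrip, aux_file
  wi(c(0L, 0L), 2L)                              # qform_code, sform_code
  wf(rep(0, 6))                                  # quatern_b..qoffset_z
  wf(c(spacing[1], 0, 0, 0))                     # srow_x
  wf(c(0, spacing[2], 0, 0))                     # srow_y
  wf(c(0, 0, if (length(spacing) > 2) spacing[3] else 1, 0))  # srow_z
  wc("", 16L)                                    # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con) # magic
  writeBin(raw(4L), con)                         # extension indicator
  writeBin(as.numeric(values), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 file into a numeric array
#'
#' Minimal little-endian NIfTI-1 reader. Returns the data array with a
#' `spacing` attribute (mm per voxel). Trailing singleton dimensions are
#' dropped so a single-slice volume comes back as a matrix.
#'
#' @param path `.nii` or `.nii.gz` file.
#' @return numeric array with attribute `spacing`.
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("read_nifti(): no such file: ", path)
  con <- nifti_connection(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = NIFTI_HDR_SIZE)
  if (length(hdr) < NIFTI_HDR_SIZE) stop("read_nifti(): truncated header in ", path)
  ri <- function(off, size, n = 1L)
    readBin(hdr[(off + 1L):(off + size * n)], "integer", n = n, size = size,
            endian = "little")
  rf <- function(off, n = 1L)
    readBin(hdr[(off + 1L):(off + 4L * n)], "double", n = n, size = 4L,
            endian = "little")
  if (ri(0L, 4L) != NIFTI_HDR_SIZE)
    stop("read_nifti(): not a little-endian NIfTI-1 file: ", path)
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop("read_nifti(): bad magic string in ", path)
  dims <- ri(40L, 2L, 8L)
  ndim <- dims[1L]
  if (ndim < 1L || ndim > 7L) stop("read_nifti(): corrupt dim field")
  dm <- dims[2:(1L + ndim)]
  dtype <- ri(70L, 2L)
  spec <- nifti_dtypes[nifti_dtypes$code == dtype, ]
  if (nrow(spec) == 0L)
    stop("read_nifti(): unsupported NIfTI datatype code ", dtype)
  pixdim <- rf(76L, 8L)
  vox_offset <- rf(108L)
  scl_slope <- rf(112L)
  scl_inter <- rf(116L)
  # skip from end of header to the data
  skip <- vox_offset - NIFTI_HDR_SIZE
  if (skip > 0) readBin(con, "raw", n = skip)
  n <- prod(dm)
  vals <- readBin(con, spec$what, n = n, size = spec$size,
                  signed = spec$signed, endian = "little")
  if (length(vals) < n) stop("read_nifti(): truncated data in ", path)
  vals <- as.numeric(vals)
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  keep <- max(which(dm > 1L), 2L)      # drop trailing singleton dims, keep >= 2D
  dm <- dm[seq_len(keep)]
  out <- array(vals[seq_len(prod(dm))], dim = dm)
  attr(out, "spacing") <- pixdim[2:(1L + length(dm))]
  out
}
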