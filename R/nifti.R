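# Minimal NIfTI-1 I/O (single 3D volume, float64 on write; common integer
# and float datatypes on read). No NIfTI package ships with the supported
# environment, and the format's fixed 348-byte header is simple enough to
# write directly. Files ending in .gz are transparently (de)compressed.

nifti_con <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

pad_raw <- function(s, n) {
  r <- charToRaw(s)
  c(r[seq_len(min(length(r), n))], raw(max(0L, n - length(r))))
}

#' Write a 3D volume as NIfTI-1
#'
#' @param vol 3D numeric array.
#' @param path output path; `.nii` or `.nii.gz`.
#' @param pixdim voxel spacing (mm), length 3.
#' @export
write_nifti <- function(vol, path, pixdim = c(1, 1, 1)) {
  d <- dim(vol)
  if (length(d) != 3L) stop("expected a 3D array")
  con <- nifti_con(path, "wb")
  on.exit(close(con))
  w <- function(x, size, type = "integer") {
    writeBin(x, con, size = size, endian = "little")
  }
  writeBin(348L, con, size = 4L, endian = "little")        # sizeof_hdr
  writeBin(raw(36L), con)                                  # unused + dim_info
  writeBin(as.integer(c(3L, d, 1L, 1L, 1L, 1L)), con, size = 2L,
           endian = "little")                              # dim[8]
  writeBin(numeric(3L), con, size = 4L, endian = "little") # intent_p1..3
  writeBin(c(0L, 64L, 64L, 0L), con, size = 2L, endian = "little")
  # intent_code, datatype = FLOAT64, bitpix, slice_start
  writeBin(as.numeric(c(1, pixdim, 1, 1, 1, 1)), con, size = 4L,
           endian = "little")                              # pixdim[8]
  writeBin(as.numeric(c(352, 1, 0)), con, size = 4L, endian = "little")
  # vox_offset, scl_slope, scl_inter
  writeBin(0L, con, size = 2L, endian = "little")          # slice_end
  writeBin(as.raw(c(0L, 10L)), con)                        # slice_code, xyzt=mm|s
  writeBin(numeric(4L), con, size = 4L, endian = "little")
  # cal_max, cal_min, slice_duration, toffset
  writeBin(c(0L, 0L), con, size = 4L, endian = "little")   # glmax, glmin
  writeBin(pad_raw("mtglioma phantom volume", 80L), con)   # descrip
  writeBin(raw(24L), con)                                  # aux_file
  writeBin(c(0L, 1L), con, size = 2L, endian = "little")   # qform, sform
  writeBin(numeric(6L), con, size = 4L, endian = "little") # quatern + qoffset
  writeBin(as.numeric(c(pixdim[1], 0, 0, 0,
                        0, pixdim[2], 0, 0,
                        0, 0, pixdim[3], 0)), con, size = 4L,
           endian = "little")                              # srow_x/y/z
  writeBin(raw(16L), con)                                  # intent_name
  writeBin(c(pad_raw("n+1", 3L), as.raw(0L)), con)         # magic
  writeBin(raw(4L), con)                                   # extension flag
  writeBin(as.vector(vol), con, size = 8L, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 volume written by [write_nifti()] (or any single-frame
#' scalar NIfTI-1 file with a supported datatype)
#'
#' @param path `.nii` or `.nii.gz` file.
#' @return 3D numeric array.
#' @export
read_nifti <- function(path) {
  con <- nifti_con(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 352L)
  rd <- function(off, what, n, size) {
    readBin(hdr[(off + 1L):(off + n * size)], what, n = n, size = size,
            endian = "little")
  }
  if (rd(0L, "integer", 1L, 4L) != 348L) stop("not a NIfTI-1 file: ", path)
  dims <- rd(40L, "integer", 8L, 2L)
  nd <- dims[1L]
  d <- dims[2:(1L + max(nd, 3L))]
  d <- d[d > 0]
  datatype <- rd(70L, "integer", 1L, 2L)
  vox_offset <- rd(108L, "numeric", 1L, 4L)
  scl_slope <- rd(112L, "numeric", 1L, 4L)
  scl_inter <- rd(116L, "numeric", 1L, 4L)
  n_vox <- prod(d)
  skip <- vox_offset - 352L
  if (skip > 0L) readBin(con, "raw", n = skip)
  data <- switch(as.character(datatype),
    "2" = as.numeric(readBin(con, "integer", n_vox, size = 1L,
                             signed = FALSE)),
    "4" = as.numeric(readBin(con, "integer", n_vox, size = 2L,
                             endian = "little")),
    "8" = as.numeric(readBin(con, "integer", n_vox, size = 4L,
                             endian = "little")),
    "16" = readBin(con, "numeric", n_vox, size = 4L, endian = "little"),
    "64" = readBin(con, "numeric", n_vox, size = 8L, endian = "little"),
    stop("unsupported NIfTI datatype code ", datatype))
  if (!is.na(scl_slope) && scl_slope != 0 && scl_slope != 1) {
    data <- data * scl_slope + scl_inter
  }
  array(data, dim = if (length(d) >= 3L) d[1:3] else c(d, rep(1L, 3L - length(d))))
}
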