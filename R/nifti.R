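# Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
#
# Supports 3D/4D volumes, datatypes uint8/int16/int32/float32/float64,
# both endiannesses on read (little-endian on write), scl_slope/inter on
# read. This is deliberately narrow: enough to exchange perfusion series,
# parameter maps and masks with standard neuroimaging tools.

NIFTI_DATATYPES <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE, r = "uint8"),
  `4`  = list(what = "integer", size = 2L, signed = TRUE,  r = "int16"),
  `8`  = list(what = "integer", size = 4L, signed = TRUE,  r = "int32"),
  `16` = list(what = "double",  size = 4L, signed = TRUE,  r = "float32"),
  `64` = list(what = "double",  size = 8L, signed = TRUE,  r = "float64")
)

nifti_code_for <- function(datatype) {
  switch(datatype,
         uint8 = 2L, int16 = 4L, int32 = 8L,
         float32 = 16L, float64 = 64L,
         stop_parameter(sprintf("unsupported NIfTI datatype '%s'", datatype)))
}

open_nii_con <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Write a 3D or 4D volume as NIfTI-1
#'
#' @param data numeric or logical array, 3 or 4 dimensions (x, y, z\[, t\]).
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @param voxel_size numeric length-3 voxel spacing in mm.
#' @param dt frame interval in seconds (stored in `pixdim[4]`); only
#'   meaningful for 4D data.
#' @param datatype one of `"float32"`, `"float64"`, `"uint8"`, `"int16"`,
#'   `"int32"`. Logical input defaults to `"uint8"`, numeric to `"float32"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, voxel_size, dt = 0,
                        datatype = if (is.logical(data)) "uint8" else "float32") {
  nd <- length(dim(data))
  if (!nd %in% c(3L, 4L))
    stop_dimension(sprintf("write_nifti expects a 3D or 4D array, got %dD", nd))
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop_parameter("voxel_size must be 3 positive spacings (mm)")
  code <- nifti_code_for(datatype)
  info <- NIFTI_DATATYPES[[as.character(code)]]
  dm <- dim(data)

  con <- open_nii_con(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.double(x), con, size = 4L, endian = "little")
  wc <- function(s, len) {
    raw <- charToRaw(s)
    writeBin(c(raw, raw(len - length(raw))), con)
  }
  wi(348L, 4)                       # sizeof_hdr
  writeBin(raw(35), con)            # data_type[10] db_name[18] extents[4]
                                    # session_error[2] regular[1]
  writeBin(as.raw(0L), con)         # dim_info
  dimv <- c(nd, dm, rep(1L, 7 - nd))
  wi(dimv, 2)                       # dim[8]
  wf(c(0, 0, 0))                    # intent_p1..p3
  wi(0L, 2)                         # intent_code
  wi(code, 2)                       # datatype
  wi(info$size * 8L, 2)             # bitpix
  wi(0L, 2)                         # slice_start
  pixdim <- c(1, voxel_size, dt, 0, 0, 0)
  wf(pixdim)                        # pixdim[8]
  wf(352)                           # vox_offset
  wf(1); wf(0)                      # scl_slope, scl_inter
  wi(0L, 2); writeBin(raw(1), con); writeBin(as.raw(10L), con) # slice_end, slice_code, xyzt_units = mm|sec
  wf(c(0, 0, 0, 0))                 # cal_max cal_min slice_duration toffset
  wi(c(0L, 0L), 4)                  # glmax glmin
  wc("perfstroke", 80)              # descrip
  wc("", 24)                        # aux_file
  wi(0L, 2); wi(1L, 2)              # qform_code = 0, sform_code = 1
  wf(rep(0, 6))                     # quatern b,c,d + qoffset x,y,z
  wf(c(voxel_size[1], 0, 0, 0))     # srow_x
  wf(c(0, voxel_size[2], 0, 0))     # srow_y
  wf(c(0, 0, voxel_size[3], 0))     # srow_z
  wc("", 16)                        # intent_name
  wc("n+1", 4)                      # magic
  writeBin(raw(4), con)             # extender
  vals <- as.vector(data)
  if (info$what == "integer") {
    writeBin(as.integer(round(vals)), con, size = info$size, endian = "little")
  } else {
    writeBin(as.double(vals), con, size = info$size, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path `.nii` or `.nii.gz` file.
#' @return list with `data` (array), `voxel_size` (mm), `dt` (s,
#'   `pixdim[4]`), `datatype`.
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  con <- open_nii_con(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L) stop_format("truncated NIfTI header")
  sz_le <- readBin(hdr[1:4], "integer", size = 4L, endian = "little")
  endian <- if (sz_le == 348L) "little" else "big"
  rd_i <- function(off, size, n = 1L) readBin(hdr[(off + 1L):(off + size * n)],
    "integer", n = n, size = size, endian = endian)
  rd_f <- function(off, n = 1L) readBin(hdr[(off + 1L):(off + 4L * n)],
    "double", n = n, size = 4L, endian = endian)
  if (rd_i(0L, 4L) != 348L) stop_format("not a NIfTI-1 file (bad sizeof_hdr)")
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop_format("not a NIfTI-1 file (bad magic)")
  dimv <- rd_i(40L, 2L, 8L)
  nd <- dimv[1]
  if (!nd %in% c(3L, 4L)) stop_format(sprintf("unsupported NIfTI rank %d", nd))
  dm <- dimv[2:(1 + nd)]
  code <- rd_i(70L, 2L)
  info <- NIFTI_DATATYPES[[as.character(code)]]
  if (is.null(info)) stop_format(sprintf("unsupported NIfTI datatype code %d", code))
  pixdim <- rd_f(76L, 8L)
  vox_offset <- rd_f(108L)
  scl_slope <- rd_f(112L); scl_inter <- rd_f(116L)
  nvox <- prod(dm)
  # skip to vox_offset (gzfile connections cannot seek)
  skip <- vox_offset - 348L
  if (skip > 0) readBin(con, "raw", n = as.integer(skip))
  if (info$what == "integer") {
    vals <- readBin(con, "integer", n = nvox, size = info$size,
                    endian = endian, signed = info$signed)
    vals <- as.double(vals)
  } else {
    vals <- readBin(con, "double", n = nvox, size = info$size, endian = endian)
  }
  if (length(vals) < nvox) stop_format("truncated NIfTI data section")
  if (!is.na(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  list(data = array(vals, dm),
       voxel_size = pixdim[2:4],
       dt = if (nd == 4L) pixdim[5] else 0,
       datatype = info$r)
}
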