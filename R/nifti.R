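#' Minimal NIfTI-1 volume I/O
#'
#' Self-contained single-file NIfTI-1 (.nii / .nii.gz) reader and writer for
#' the 3D/4D volumes this package produces (label volumes, signal stacks,
#' relaxation maps, validity masks). Little-endian, no extensions; data types
#' uint8 (2), int32 (8), float32 (16) and float64 (64). Voxel sizes are
#' recorded in mm (micrometers x 1e-3); map units (ms) go in the `descrip`
#' field. This deliberately covers only the subset of the format the
#' pipeline emits — it is plumbing, not a general NIfTI library.
#'
#' @param vol Numeric or logical array, 3D or 4D. 4D stacks use the package
#'   convention (acquisition, slice, row, col) and are stored with the
#'   acquisition axis as NIfTI dim 4 (x = col, y = row, z = slice, t =
#'   acquisition).
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @param voxel_size_um Spatial voxel size in micrometers, length 3
#'   `(slice, row, col)`.
#' @param description Free text (<= 79 bytes) stored in `descrip`, e.g.
#'   `"T1 map [ms]"`.
#' @param datatype One of `"float32"`, `"float64"`, `"uint8"`, `"int32"`.
#' @return `write_nifti()` returns `path` invisibly. `read_nifti()` returns
#'   a list with `data` (array in package axis order), `voxel_size_um`,
#'   `description`.
#' @export
write_nifti <- function(vol, path, voxel_size_um = c(120, 120, 120),
                        description = "", datatype = "float32") {
  stopifnot(is.array(vol) || is.vector(vol))
  nd <- length(dim(vol))
  if (!nd %in% c(3L, 4L)) stop("vol must be 3D or 4D", call. = FALSE)
  dt <- switch(datatype,
               uint8 = list(code = 2L, bitpix = 8L, what = "integer", size = 1L),
               int32 = list(code = 8L, bitpix = 32L, what = "integer", size = 4L),
               float32 = list(code = 16L, bitpix = 32L, what = "double", size = 4L),
               float64 = list(code = 64L, bitpix = 64L, what = "double", size = 8L),
               stop("unsupported datatype ", datatype, call. = FALSE))
  # package order (acq, slice, row, col) -> nifti (col, row, slice, acq)
  arr <- if (nd == 3L) aperm(vol, c(3, 2, 1)) else aperm(vol, c(4, 3, 2, 1))
  dims <- dim(arr)
  dim8 <- integer(8)
  dim8[1] <- length(dims)
  dim8[seq_along(dims) + 1L] <- dims
  dim8[dim8 == 0L] <- 1L
  pixdim <- numeric(8)
  pixdim[2:4] <- rev(voxel_size_um) * 1e-3   # (col,row,slice) in mm
  pixdim[5] <- 1
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeBin(348L, con, size = 4, endian = "little")            # sizeof_hdr
  writeBin(raw(36), con)                                      # unused
  writeBin(as.integer(dim8), con, size = 2, endian = "little")
  writeBin(numeric(3), con, size = 4, endian = "little")      # intent p1-p3
  writeBin(0L, con, size = 2, endian = "little")              # intent_code
  writeBin(dt$code, con, size = 2, endian = "little")
  writeBin(dt$bitpix, con, size = 2, endian = "little")
  writeBin(0L, con, size = 2, endian = "little")              # slice_start
  writeBin(pixdim, con, size = 4, endian = "little")
  writeBin(352, con, size = 4, endian = "little")             # vox_offset
  writeBin(c(1, 0), con, size = 4, endian = "little")         # scl slope/inter
  writeBin(0L, con, size = 2, endian = "little")              # slice_end
  writeBin(as.raw(c(0, 2)), con)                              # slice_code, xyzt=mm
  writeBin(numeric(3), con, size = 4, endian = "little")      # cal_max/min, slice_dur
  writeBin(0, con, size = 4, endian = "little")               # toffset
  writeBin(c(0L, 0L), con, size = 4, endian = "little")       # glmax/glmin
  desc <- charToRaw(substr(description, 1, 79))
  writeBin(c(desc, raw(80 - length(desc))), con)
  writeBin(raw(24), con)                                      # aux_file
  writeBin(c(0L, 0L), con, size = 2, endian = "little")       # qform, sform
  writeBin(numeric(18), con, size = 4, endian = "little")     # quatern + srows
  writeBin(raw(16), con)                                      # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)                  # magic
  writeBin(raw(4), con)                                       # header padding
  storage <- if (dt$what == "integer") as.integer(arr) else as.double(arr)
  writeBin(storage, con, size = dt$size, endian = "little")
  invisible(path)
}

#' @rdname write_nifti
#' @export
read_nifti <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 352)
  if (length(hdr) < 352) stop("truncated NIfTI header in ", path, call. = FALSE)
  int_at <- function(off, size, n = 1L)
    readBin(hdr[(off + 1):(off + size * n)], "integer", n = n, size = size,
            endian = "little")
  dbl_at <- function(off, n = 1L)
    readBin(hdr[(off + 1):(off + 4 * n)], "double", n = n, size = 4,
            endian = "little")
  if (int_at(0, 4) != 348L)
    stop(path, " is not a little-endian NIfTI-1 file", call. = FALSE)
  dim8 <- int_at(40, 2, 8)
  nd <- dim8[1]
  dims <- dim8[2:(nd + 1)]
  datatype <- int_at(70, 2)
  pixdim <- dbl_at(76, 8)
  vox_offset <- dbl_at(108)
  descrip <- hdr[149:228]
  descrip <- rawToChar(descrip[seq_len(max(0, which(descrip != 0)))])
  n <- prod(dims)
  extra <- as.integer(vox_offset) - 352L
  if (extra > 0) readBin(con, "raw", extra)
  data <- switch(as.character(datatype),
    "2" = as.numeric(readBin(con, "integer", n, size = 1, signed = FALSE)),
    "8" = as.numeric(readBin(con, "integer", n, size = 4, endian = "little")),
    "16" = readBin(con, "double", n, size = 4, endian = "little"),
    "64" = readBin(con, "double", n, size = 8, endian = "little"),
    stop("unsupported NIfTI datatype code ", datatype, call. = FALSE))
  arr <- array(data, dim = dims)
  # nifti (col,row,slice[,acq]) -> package order
  arr <- if (nd == 3L) aperm(arr, c(3, 2, 1)) else aperm(arr, c(4, 3, 2, 1))
  list(data = arr,
       voxel_size_um = rev(pixdim[2:4]) * 1e3,
       description = descrip)
}
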