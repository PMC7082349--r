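#' Minimal NIfTI-1 input/output
#'
#' The pipeline stores phantom volumes and tumor masks as single-file
#' NIfTI-1 (`.nii` or `.nii.gz`), RAS+ orientation, with voxel spacing in
#' `pixdim` and origin/spacing in the sform rows. Only the subset of the
#' format the pipeline produces is supported on read: single-file magic
#' `n+1`, datatypes uint8 (2), int16 (4), int32 (8), float32 (16) and
#' float64 (64), no extensions.
#'
#' @name nifti-io
NULL

NIFTI_DTYPES <- list(
  `2`  = list(what = "integer", size = 1, signed = FALSE),
  `4`  = list(what = "integer", size = 2, signed = TRUE),
  `8`  = list(what = "integer", size = 4, signed = TRUE),
  `16` = list(what = "double",  size = 4, signed = TRUE),
  `64` = list(what = "double",  size = 8, signed = TRUE)
)

#' Create an image volume
#'
#' Bundles a 3D intensity array with its voxel spacing (mm) and origin (mm).
#' Physical coordinates follow `origin + index * spacing` with 0-based
#' voxel indices, axes in RAS+ order.
#'
#' @param data 3D numeric array.
#' @param spacing numeric length-3, mm per voxel along each axis; all > 0.
#' @param origin numeric length-3, mm coordinate of voxel (0,0,0).
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("image_volume: data must be a 3D array")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("image_volume: spacing must be 3 positive finite values")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("image_volume: origin must be 3 finite values")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s voxels, spacing %s mm, origin %s mm\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              paste(format(x$origin), collapse = ", ")))
  invisible(x)
}

#' Write a volume as NIfTI-1
#'
#' @param vol an [image_volume()], or a 3D array (unit spacing assumed).
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @param datatype `"float32"` (default) or `"uint8"` (for masks).
#' @return `path`, invisibly.
#' @export
nifti_write <- function(vol, path, datatype = c("float32", "uint8")) {
  datatype <- match.arg(datatype)
  if (is.array(vol)) vol <- image_volume(vol)
  stopifnot(inherits(vol, "image_volume"))
  dm <- dim(vol$data)
  code <- if (datatype == "float32") 16L else 2L
  bitpix <- if (datatype == "float32") 32L else 8L

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con), add = TRUE)

  wb <- function(x, size) writeBin(x, con, size = size, endian = "little")
  wb(348L, 4)                                   # sizeof_hdr
  writeBin(raw(36), con)                        # data_type..dim_info
  wb(as.integer(c(3L, dm, 1L, 1L, 1L, 1L)), 2)  # dim[8]
  wb(integer(7), 2)                             # intent_p1..intent_code (14 bytes)
  wb(code, 2)                                   # datatype
  wb(bitpix, 2)                                 # bitpix
  wb(0L, 2)                                     # slice_start
  wb(c(1, vol$spacing, 1, 1, 1, 1), 4)          # pixdim[8] (qfac = 1)
  wb(352, 4)                                    # vox_offset
  wb(c(1, 0), 4)                                # scl_slope, scl_inter
  wb(0L, 2); writeBin(raw(2), con)              # slice_end, slice_code, xyzt_units
  wb(c(0, 0, 0, 0), 4)                          # cal_max..toffset
  wb(c(0L, 0L), 4)                              # glmax, glmin
  writeBin(raw(104), con)                       # descrip[80] + aux_file[24]
  wb(c(0L, 1L), 2)                              # qform_code = 0, sform_code = 1
  wb(numeric(6), 4)                             # quatern b,c,d + offset x,y,z
  srow <- rbind(c(vol$spacing[1], 0, 0, vol$origin[1]),
                c(0, vol$spacing[2], 0, vol$origin[2]),
                c(0, 0, vol$spacing[3], vol$origin[3]))
  wb(as.numeric(t(srow)), 4)                    # srow_x/y/z
  writeBin(raw(16), con)                        # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con) # magic
  writeBin(raw(4), con)                         # extension flag

  if (datatype == "uint8") {
    writeBin(as.integer(vol$data != 0), con, size = 1)
  } else {
    writeBin(as.numeric(vol$data), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 volume written by this package
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return An [image_volume()].
#' @export
nifti_read <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- readBin(con, "raw", 348)
  if (length(hdr) < 348) stop("nifti_read: truncated header in ", path)
  rd <- function(off, what, n, size) {
    readBin(hdr[(off + 1):length(hdr)], what, n = n, size = size,
            endian = "little", signed = TRUE)
  }
  if (rd(0, "integer", 1, 4) != 348L)
    stop("nifti_read: not a NIfTI-1 file: ", path)
  magic <- rawToChar(hdr[345:347])
  if (magic != "n+1") stop("nifti_read: unsupported magic '", magic, "'")
  dims <- rd(40, "integer", 8, 2)
  if (dims[1] < 3L) stop("nifti_read: expected a 3D image")
  dm <- dims[2:4]
  dtype <- rd(70, "integer", 1, 2)
  spec <- NIFTI_DTYPES[[as.character(dtype)]]
  if (is.null(spec)) stop("nifti_read: unsupported datatype code ", dtype)
  pixdim <- rd(76, "double", 8, 4)
  vox_offset <- rd(108, "double", 1, 4)
  scl <- rd(112, "double", 2, 4)
  sform_code <- rd(254, "integer", 1, 2)
  srow <- matrix(rd(280, "double", 12, 4), nrow = 3, byrow = TRUE)
  origin <- if (sform_code > 0L) srow[, 4] else c(0, 0, 0)
  spacing <- if (sform_code > 0L) {
    sqrt(colSums(srow[, 1:3]^2))
  } else {
    abs(pixdim[2:4])
  }
  if (any(spacing <= 0)) spacing[spacing <= 0] <- 1

  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", skip)
  n <- prod(dm)
  vals <- readBin(con, spec$what, n = n, size = spec$size,
                  endian = "little",
                  signed = if (spec$what == "integer") spec$signed else TRUE)
  if (length(vals) != n) stop("nifti_read: truncated data in ", path)
  if (scl[1] != 0 && !(scl[1] == 1 && scl[2] == 0))
    vals <- vals * scl[1] + scl[2]
  image_volume(array(as.numeric(vals), dim = dm), spacing, origin)
}
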