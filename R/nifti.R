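#' @title Image volumes and minimal NIfTI-1 input/output
#' @description An `image_volume` is a 3D numeric array with voxel spacing (mm
#'   per axis) and an origin, the in-memory form of one scan. A label map is an
#'   `image_volume` whose values are small non-negative integers. NIfTI-1
#'   reading/writing supports the subset of the format this package emits:
#'   single-file `.nii` / `.nii.gz`, 3D, float32 or int16, RAS+ affine built
#'   from the spacing with origin at 0.
#' @name nifti-io
NULL

#' Construct an image volume
#'
#' @param data 3D numeric array of voxel intensities.
#' @param spacing numeric length-3, mm per axis; default 1 mm isotropic.
#' @param origin numeric length-3 physical position of voxel (1,1,1), mm.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L) stop("image_volume requires a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) stop("spacing must be 3 positive numbers")
  structure(list(data = data, spacing = spacing, origin = as.numeric(origin)),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume %s, spacing %s mm, range [%.4g, %.4g]>\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$data)

# NIfTI-1 datatype codes we read; we always write float32 (16) for intensity
# volumes and int16 (4) for label maps.
.nifti_dtypes <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE),
  `4`  = list(what = "integer", size = 2L, signed = TRUE),
  `8`  = list(what = "integer", size = 4L, signed = TRUE),
  `16` = list(what = "double",  size = 4L, signed = TRUE),
  `64` = list(what = "double",  size = 8L, signed = TRUE)
)

.open_maybe_gz <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Write a volume as NIfTI-1
#'
#' @param vol an `image_volume`.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param datatype `"float32"` (default) or `"int16"` (for label maps).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(vol, path, datatype = c("float32", "int16")) {
  stopifnot(inherits(vol, "image_volume"))
  datatype <- match.arg(datatype)
  dt_code <- if (datatype == "float32") 16L else 4L
  bitpix <- if (datatype == "float32") 32L else 16L
  dims <- dim(vol$data)
  con <- .open_maybe_gz(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wi(348L, 4)                                   # sizeof_hdr
  writeBin(raw(35), con)                        # data_type[10] db_name[18] extents[4] session_error[2] regular[1]
  writeBin(as.raw(0L), con)                     # dim_info
  wi(c(3L, dims, 1L, 1L, 1L, 1L), 2)            # dim[8]
  wf(c(0, 0, 0))                                # intent_p1..p3
  wi(0L, 2)                                     # intent_code
  wi(dt_code, 2); wi(bitpix, 2); wi(0L, 2)      # datatype, bitpix, slice_start
  wf(c(1, vol$spacing, 1, 1, 1, 1))             # pixdim[8], qfac=1
  wf(352)                                       # vox_offset
  wf(c(1, 0))                                   # scl_slope, scl_inter
  wi(0L, 2); writeBin(raw(2), con)              # slice_end, slice_code+xyzt_units
  wf(c(0, 0, 0, 0))                             # cal_max cal_min slice_duration toffset
  wi(c(0L, 0L), 4)                              # glmax glmin
  writeBin(raw(104), con)                       # descrip[80] aux_file[24]
  wi(c(0L, 1L), 2)                              # qform_code=0, sform_code=1
  wf(c(0, 0, 0, 0, 0, 0))                       # quatern b c d, qoffset x y z
  wf(c(vol$spacing[1], 0, 0, vol$origin[1]))    # srow_x
  wf(c(0, vol$spacing[2], 0, vol$origin[2]))    # srow_y
  wf(c(0, 0, vol$spacing[3], vol$origin[3]))    # srow_z
  writeBin(raw(16), con)                        # intent_name[16]
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)  # magic
  writeBin(raw(4), con)                         # extender
  if (datatype == "float32") {
    writeBin(as.numeric(vol$data), con, size = 4L, endian = "little")
  } else {
    writeBin(as.integer(round(vol$data)), con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path a `.nii` or `.nii.gz` file.
#' @return An `image_volume`; integer-typed files come back as numeric arrays
#'   holding integral values.
#' @export
read_nifti <- function(path) {
  con <- .open_maybe_gz(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348L)
  ri <- function(off, size, n = 1L) readBin(hdr[(off + 1L):(off + size * n)],
                                            "integer", n = n, size = size, endian = "little")
  rf <- function(off, n = 1L) readBin(hdr[(off + 1L):(off + 4L * n)],
                                      "double", n = n, size = 4L, endian = "little")
  if (ri(0L, 4L) != 348L) stop("not a NIfTI-1 file (bad sizeof_hdr): ", path)
  dim8 <- ri(40L, 2L, 8L)
  ndim <- dim8[1]
  if (ndim < 3L) stop("expected a 3D volume: ", path)
  dims <- dim8[2:4]
  if (ndim > 3L && any(dim8[5:(ndim + 1L)] > 1L)) stop("4D+ volumes unsupported: ", path)
  dtype <- ri(70L, 2L)
  spec <- .nifti_dtypes[[as.character(dtype)]]
  if (is.null(spec)) stop("unsupported NIfTI datatype code ", dtype)
  pixdim <- rf(76L, 8L)
  vox_offset <- rf(108L)
  slope <- rf(112L); inter <- rf(116L)
  sform <- ri(254L, 2L)
  origin <- if (sform > 0L) c(rf(280L, 4L)[4], rf(296L, 4L)[4], rf(312L, 4L)[4]) else c(0, 0, 0)
  n <- prod(dims)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = skip)
  vals <- readBin(con, spec$what, n = n, size = spec$size, endian = "little",
                  signed = spec$signed)
  if (length(vals) != n) stop("truncated NIfTI data: ", path)
  vals <- as.numeric(vals)
  if (slope != 0 && (slope != 1 || inter != 0)) vals <- vals * slope + inter
  image_volume(array(vals, dim = dims), spacing = pixdim[2:4], origin = origin)
}
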