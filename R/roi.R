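#' @title Label-based ROI voxel extraction
#' @description Pulls the voxel set of one labeled structure out of an
#'   intensity volume using an integer label map sharing the same lattice,
#'   preserving spacing. Coordinates are 0-based voxel indices in native array
#'   order; physical positions follow from spacing and origin.
#' @name roi-extraction
NULL

#' List the distinct nonzero labels of a label map
#'
#' @param labelmap an `image_volume` with integer values.
#' @return sorted integer vector of distinct nonzero labels (possibly empty).
#' @export
list_labels <- function(labelmap) {
  v <- labelmap$data
  if (any(v != round(v))) stop("label map is not integer-valued")
  sort(unique(as.integer(v[v != 0])))
}

#' Extract the voxels of one labeled structure
#'
#' @param volume an `image_volume` of intensities.
#' @param labelmap an `image_volume` of integer labels on the same grid (same
#'   shape and spacing; checked).
#' @param label integer label to extract.
#' @return An object of class `roi_voxels`: list with `label`, `intensities`
#'   (numeric, length Np), `coords` (Np x 3 integer matrix, 0-based),
#'   `spacing`, `dim` (grid shape) and `bbox` (2 x 3 matrix of 1-based
#'   inclusive bounds).
#' @export
extract_roi_voxels <- function(volume, labelmap, label) {
  if (!identical(dim(volume$data), dim(labelmap$data)))
    stop("geometry error: volume and label map grids differ")
  if (max(abs(volume$spacing - labelmap$spacing)) > 1e-6)
    stop("geometry error: volume and label map spacing differ")
  sel <- labelmap$data == label
  np <- sum(sel)
  if (np == 0L) stop("missing-label error: label ", label, " absent from label map")
  idx <- which(sel, arr.ind = TRUE)
  structure(list(label = as.integer(label),
                 intensities = as.numeric(volume$data[sel]),
                 coords = idx - 1L,
                 spacing = volume$spacing,
                 dim = dim(volume$data),
                 bbox = rbind(lo = apply(idx, 2, min), hi = apply(idx, 2, max))),
            class = "roi_voxels")
}

#' @export
print.roi_voxels <- function(x, ...) {
  cat(sprintf("<roi_voxels label %d, Np=%d, spacing %s mm>\n", x$label,
              length(x$intensities), paste(format(x$spacing), collapse = "x")))
  invisible(x)
}

#' Paint an ROI back into an empty grid
#'
#' Inverse of [extract_roi_voxels()]: returns a volume that is `background`
#' everywhere except the ROI voxels, which carry their intensities. Useful for
#' masked-volume export and round-trip checks.
#'
#' @param roi a `roi_voxels`.
#' @param background fill value outside the ROI (default 0).
#' @return an `image_volume`.
#' @export
roi_to_volume <- function(roi, background = 0) {
  a <- array(background, roi$dim)
  a[roi$coords + 1L] <- roi$intensities
  image_volume(a, roi$spacing)
}

# Dense bounding-box view of an ROI: 3D array of intensities with NA outside
# the mask. The working representation for texture-matrix construction.
.roi_dense <- function(roi) {
  lo <- roi$bbox["lo", ]; hi <- roi$bbox["hi", ]
  a <- array(NA_real_, hi - lo + 1L)
  a[roi$coords + 1L - rep(lo - 1L, each = nrow(roi$coords))] <- roi$intensities
  a
}
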