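#' @title Per-scan feature aggregation
#' @description Each of the 107 features is computed per structure (16 ROIs)
#'   and collapsed to one value per scan. Physically extensive quantities
#'   (volumes, surfaces, energies) are summed across the bilateral structures;
#'   everything else is averaged. A mode aggregator (after rounding to 6
#'   significant digits, ties to the smallest value) is available but not
#'   assigned by default.
#' @name aggregation
NULL

#' Default aggregator map
#'
#' @return named character vector over the 107-feature manifest with values
#'   in `c("mean", "mode", "sum")`.
#' @export
default_aggregator_map <- function() {
  mf <- feature_manifest()
  agg <- stats::setNames(rep("mean", nrow(mf)), mf$feature)
  extensive <- c("firstorder_Energy", "firstorder_TotalEnergy",
                 "shape3D_MeshVolume", "shape3D_VoxelVolume",
                 "shape3D_SurfaceArea", "shape2D_MeshSurface",
                 "shape2D_PixelSurface", "shape2D_Perimeter")
  agg[extensive] <- "sum"
  agg
}

# mode of continuous values: round to 6 significant digits, most frequent,
# ties broken toward the smallest value
.mode_agg <- function(x) {
  r <- signif(x, 6)
  u <- sort(unique(r))
  u[which.max(tabulate(match(r, u)))]    # first max = smallest value on ties
}

#' Aggregate 16 per-ROI feature records into one per-scan vector
#'
#' @param records list of 16 `feature_record`s with distinct labels 1..16.
#' @param map aggregator map as from [default_aggregator_map()].
#' @return named numeric vector of 107 aggregated values.
#' @export
aggregate_features <- function(records, map = default_aggregator_map()) {
  labs <- vapply(records, function(r) r$roi_label, integer(1))
  if (!identical(sort(labs), 1:16))
    stop("incomplete-scan error: need exactly 16 records with labels 1..16")
  mf <- feature_manifest()
  m <- vapply(records, function(r) r$values[mf$feature], numeric(nrow(mf)))
  out <- numeric(nrow(mf))
  for (fi in seq_len(nrow(mf))) {
    out[fi] <- switch(map[[mf$feature[fi]]],
                      mean = mean(m[fi, ]),
                      sum = sum(m[fi, ]),
                      mode = .mode_agg(m[fi, ]),
                      stop("unknown aggregator for ", mf$feature[fi]))
  }
  stats::setNames(out, mf$feature)
}

#' Build the cohort feature table
#'
#' Reads every scan of a manifest (volume + label map), extracts the 16 ROIs,
#' runs the feature engine and aggregates to one row per scan. Scans whose
#' files cannot be read or that miss a label are dropped with a warning.
#'
#' @param manifest data.frame with columns scan_id, volume_path,
#'   labelmap_path, class (as written by [generate_cohort()]).
#' @param config an `engine_config`.
#' @param map aggregator map.
#' @param out_csv optional path; if given the table is also written as CSV.
#' @return data.frame: scan_id, class, then the 107 aggregated features.
#' @export
build_feature_table <- function(manifest, config = engine_config(),
                                map = default_aggregator_map(), out_csv = NULL) {
  rows <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    sid <- manifest$scan_id[i]
    res <- tryCatch({
      vol <- read_nifti(manifest$volume_path[i])
      lab <- read_nifti(manifest$labelmap_path[i])
      recs <- lapply(1:16, function(L)
        extract_all(extract_roi_voxels(vol, lab, L), config))
      aggregate_features(recs, map)
    }, error = function(e) {
      warning("dropping scan ", sid, ": ", conditionMessage(e), call. = FALSE)
      NULL
    })
    if (!is.null(res))
      rows[[i]] <- cbind(data.frame(scan_id = sid, class = manifest$class[i],
                                    stringsAsFactors = FALSE),
                         as.data.frame(as.list(res), check.names = FALSE))
  }
  tab <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(tab) <- NULL
  if (!is.null(out_csv)) utils::write.csv(tab, out_csv, row.names = FALSE)
  tab
}
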