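#' Per-sample metadata and soil chemistry
#'
#' A `sample_frame` is a data frame with one row per soil sample carrying the
#' predictors: plant `species`, plant `genus`, planar coordinates `x`, `y`
#' (metres) and the ten soil-chemistry variables measured per sample.
#'
#' @format Chemistry columns, in fixed order:
#' `no3_ppm`, `p_olsen_ppm`, `k_ppm`, `k_meq`, `na_ppm`, `ca_meq`, `mg_meq`,
#' `cec`, `om_pct`, `ph` (NO3 ppm, Olsen P ppm, K ppm, K meq/100 g, Na ppm,
#' Ca meq/100 g, Mg meq/100 g, cation-exchange capacity, organic matter %,
#' pH).
#' @name sample_frame
NULL

#' @rdname sample_frame
#' @export
chemistry_vars <- function() {
  c("no3_ppm", "p_olsen_ppm", "k_ppm", "k_meq", "na_ppm",
    "ca_meq", "mg_meq", "cec", "om_pct", "ph")
}

.earth_radius_m <- 6371000

#' Project GPS coordinates to planar metres
#'
#' Equirectangular projection about the mean latitude: over a study extent of
#' a few kilometres the distortion is negligible and pairwise planar distances
#' approximate great-circle distances.
#'
#' @param lat,lon decimal degrees.
#' @param lat0 reference latitude for the cosine scaling; defaults to
#'   `mean(lat)`.
#' @return data frame with columns `x`, `y` in metres (centred on the mean).
#' @export
latlon_to_xy <- function(lat, lon, lat0 = mean(lat)) {
  rad <- pi / 180
  data.frame(
    x = .earth_radius_m * cos(lat0 * rad) * (lon - mean(lon)) * rad,
    y = .earth_radius_m * (lat - mean(lat)) * rad)
}

## Inverse, used when emitting synthetic designs in the external file format.
xy_to_latlon <- function(x, y, lat0 = 38.318, lon0 = -123.07) {
  rad <- pi / 180
  data.frame(lat = lat0 + y / (.earth_radius_m * rad),
             lon = lon0 + x / (.earth_radius_m * cos(lat0 * rad) * rad))
}

validate_sample_frame <- function(frame, require_chemistry = TRUE) {
  need <- c("sample_id", "species", "genus", "x", "y")
  miss <- setdiff(need, names(frame))
  if (length(miss))
    stop("sample frame missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(frame$sample_id))
    stop("duplicate sample_id in sample frame")
  if (require_chemistry) {
    miss <- setdiff(chemistry_vars(), names(frame))
    if (length(miss))
      stop("chemistry missing columns: ", paste(miss, collapse = ", "))
    chem <- as.matrix(frame[, chemistry_vars()])
    if (anyNA(chem) || any(!is.finite(chem)))
      stop("chemistry values must be finite and present for every sample")
    if (any(frame$ph <= 0 | frame$ph >= 14))
      stop("pH out of range (0, 14) for samples: ",
           paste(frame$sample_id[frame$ph <= 0 | frame$ph >= 14],
                 collapse = ", "))
  }
  invisible(frame)
}

#' Read sample metadata and chemistry into a sample frame
#'
#' Joins a metadata table (`sample_id`, `species`, `genus`, `lat`, `lon`) with
#' a chemistry table keyed by `sample_id`, and converts GPS coordinates to
#' planar metres with [latlon_to_xy()].  Samples present in one file but not
#' the other are an error.
#'
#' @param metadata_path,chemistry_path tab-separated files with header.
#' @return a validated [sample_frame] data frame.
#' @export
read_sample_frame <- function(metadata_path, chemistry_path) {
  meta <- utils::read.delim(metadata_path, check.names = FALSE,
                            na.strings = NULL)
  need <- c("sample_id", "species", "genus", "lat", "lon")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("metadata missing columns: ", paste(miss, collapse = ", "))
  chem <- utils::read.delim(chemistry_path, check.names = FALSE,
                            na.strings = NULL)
  miss <- setdiff(c("sample_id", chemistry_vars()), names(chem))
  if (length(miss))
    stop("chemistry table missing columns: ", paste(miss, collapse = ", "))
  only_meta <- setdiff(meta$sample_id, chem$sample_id)
  only_chem <- setdiff(chem$sample_id, meta$sample_id)
  if (length(only_meta) || length(only_chem))
    stop("samples not shared between metadata and chemistry: ",
         paste(c(only_meta, only_chem), collapse = ", "))
  frame <- merge(meta, chem[, c("sample_id", chemistry_vars())],
                 by = "sample_id", sort = FALSE)
  frame <- frame[match(meta$sample_id, frame$sample_id), ]
  xy <- latlon_to_xy(frame$lat, frame$lon)
  frame$x <- xy$x
  frame$y <- xy$y
  rownames(frame) <- NULL
  validate_sample_frame(frame)
  frame
}

#' @rdname read_sample_frame
#' @param frame a sample frame with `x`, `y` (and optionally `lat`, `lon`)
#'   coordinates and chemistry columns.
#' @param lat0,lon0 reference point used to synthesise GPS coordinates when
#'   the frame carries only planar `x`, `y`.
#' @export
write_sample_frame <- function(frame, metadata_path, chemistry_path,
                               lat0 = 38.318, lon0 = -123.07) {
  validate_sample_frame(frame)
  if (!all(c("lat", "lon") %in% names(frame))) {
    ll <- xy_to_latlon(frame$x, frame$y, lat0, lon0)
    frame$lat <- ll$lat
    frame$lon <- ll$lon
  }
  meta <- frame[, c("sample_id", "species", "genus", "lat", "lon")]
  utils::write.table(meta, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  chem <- frame[, c("sample_id", chemistry_vars())]
  utils::write.table(chem, chemistry_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(metadata_path, chemistry_path))
}

## z-score standardisation of the chemistry block; constant columns error.
standardize_chemistry <- function(frame) {
  chem <- as.matrix(frame[, chemistry_vars()])
  sds <- apply(chem, 2, stats::sd)
  if (any(sds == 0))
    stop("constant chemistry column(s): ",
         paste(chemistry_vars()[sds == 0], collapse = ", "))
  scale(chem)[, , drop = FALSE]
}
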