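#' Per-cell marker intensity metrics
#'
#' For every nucleus and marker channel computes the measurement scheme used
#' for immunofluorescence quantitation:
#' \itemize{
#'   \item `nuclear_intensity`: mean over the nuclear ROI minus the mean
#'     over the cytoplasm background ring (local background subtraction);
#'   \item `ne_intensity`: mean over the nuclear-envelope toroid minus the
#'     same background;
#'   \item `radial_distribution` and `peripheral_distribution`: mean over
#'     the chromatin periphery band divided by the mean over the nuclear
#'     ROI, computed on raw (non-subtracted) intensities. The two columns
#'     carry the same statistic under the two names used for
#'     chromatin-bound versus envelope markers.
#' }
#' Nuclei whose background ring is empty (crowded fields) keep raw means
#' with `bg_undefined = TRUE` and `NA` subtracted intensities; a zero
#' nuclear mean leaves the ratios `NA` with `ratio_undefined = TRUE`.
#'
#' @param field An `ImageField`.
#' @param rois A `RoiSet` sharing the field geometry.
#' @param markers Channel names to quantify; default all channels except
#'   `"chromatin"`.
#' @return data.frame with one row per nucleus x marker: `nucleus_id`,
#'   `marker`, `nuclear_intensity`, `ne_intensity`, `radial_distribution`,
#'   `peripheral_distribution`, `area_px2`, `degenerate`, `bg_undefined`,
#'   `ratio_undefined`.
#' @export
marker_intensities <- function(field, rois, markers = NULL) {
  stopifnot(inherits(field, "ImageField"), inherits(rois, "RoiSet"))
  if (!all(field$dim == rois$dim))
    stop("field and RoiSet geometries differ")
  if (is.null(markers))
    markers <- setdiff(names(field$channels), "chromatin")
  if (!length(markers)) stop("no marker channels to quantify")
  rows <- list()
  for (m in markers) {
    ch <- get_channel(field, m)
    for (r in rois$rois) {
      nuc_mean <- mean(ch[r$nuclear])
      band_mean <- mean(ch[r$periphery_band])
      ne_mean <- mean(ch[r$ne_toroid])
      bg_undef <- length(r$cytoplasm_ring) == 0
      bg <- if (bg_undef) NA_real_ else mean(ch[r$cytoplasm_ring])
      ratio_undef <- nuc_mean == 0
      rows[[length(rows) + 1L]] <- data.frame(
        nucleus_id = r$nucleus_id, marker = m,
        nuclear_intensity = if (bg_undef) NA_real_ else nuc_mean - bg,
        ne_intensity = if (bg_undef) NA_real_ else ne_mean - bg,
        radial_distribution = if (ratio_undef) NA_real_ else
          band_mean / nuc_mean,
        peripheral_distribution = if (ratio_undef) NA_real_ else
          band_mean / nuc_mean,
        area_px2 = length(r$nuclear),
        degenerate = r$degenerate,
        bg_undefined = bg_undef,
        ratio_undefined = ratio_undef)
    }
  }
  do.call(rbind, rows)
}

#' Cross-sectional area per nucleus
#'
#' @param labels Integer label matrix.
#' @param pixel_size Physical pixel size (length unit per px); areas are
#'   pixel counts times `pixel_size^2`.
#' @return data.frame with `nucleus_id` and `area` (in `pixel_size^2`
#'   units; px^2 when `pixel_size = 1`). Labels absent from the map yield
#'   no row.
#' @export
cross_sectional_area <- function(labels, pixel_size = 1) {
  stopifnot(is.matrix(labels), pixel_size > 0)
  ids <- sort(unique(labels[labels > 0]))
  data.frame(nucleus_id = ids,
             area = vapply(ids, function(i) sum(labels == i), 1L) *
               pixel_size^2)
}

#' Background-subtracted nuclear intensity of an H2A.Z-style marker
#'
#' Convenience accessor: the background-subtracted mean nuclear intensity
#' of one channel, the readout used to score H2A.Z depletion and rescue.
#'
#' @param field An `ImageField`.
#' @param rois A `RoiSet`.
#' @param channel Marker channel name (default `"H2A.Z"`).
#' @return data.frame with `nucleus_id` and `nuclear_intensity`.
#' @export
haz_intensity <- function(field, rois, channel = "H2A.Z") {
  tab <- marker_intensities(field, rois, markers = channel)
  tab[, c("nucleus_id", "nuclear_intensity")]
}
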