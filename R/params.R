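#' Segmentation and quantification parameters
#'
#' Bundles every tunable of the cell-identification and quantification
#' pipeline with its default. Windows are in pixels and must be odd; at the
#' 10x magnification the defaults were designed for, 41 px is about 30 um.
#'
#' @param nuclear_window_px Odd window (px) for nuclear local-mean
#'   thresholding. Default 41.
#' @param background_window_px Odd window (px) used to estimate the local
#'   background mean for the cell channel. Default 41.
#' @param local_sd_window_px Odd window (px) for the per-pixel SD whose
#'   histogram mode estimates the global background SD. Default 5.
#' @param cell_sd_multiplier Cell-channel threshold is the local background
#'   mean plus this many global background SDs. Default 3.
#' @param bright_object_sd_multiplier A labelled nuclear object is kept only
#'   if its mean intensity exceeds its local background mean by this many
#'   global background SDs; suppresses noise speckle picked up by strict
#'   local-mean thresholding. Default 3.
#' @param min_object_px Labelled nuclear objects smaller than this many
#'   pixels are discarded together with the brightness check; a real nucleus
#'   is two orders of magnitude larger, while bright noise speckle is almost
#'   always a few pixels. Default 16.
#' @param watershed_retention Limited-watershed split is accepted only when
#'   the intensity above the separating watermark exceeds this fraction of
#'   the parent object's total intensity. Default 0.85.
#' @param min_dna_fraction_of_g1 Nuclear objects whose total DNA intensity is
#'   below this fraction of the estimated G1 mode are removed as debris.
#'   Default 0.5.
#' @param min_objects_for_g1 Minimum number of nuclear objects required for a
#'   reliable G1-mode estimate; below it the dim-object filter is skipped
#'   with a warning. Default 20.
#' @param g1_total Optional absolute override for the typical G1 total DNA
#'   intensity; when given, the histogram-mode estimate is not used.
#' @param roundness_cutoff Cells with roundness (P^2 / (4 pi A)) below this
#'   value are regarded as single-nucleus cells. Default 1.2.
#' @param ill_coloc_threshold Cells whose background-subtracted
#'   Hoechst-CellMask cosine colocalization falls below this value are
#'   flagged as ill-identified (displaced channels, e.g. chromatic
#'   aberration). Default 0.3.
#' @param connectivity Pixel connectivity for objects, 4 or 8. Default 8.
#' @param watershed_levels `"exact"` scans every unique intensity when
#'   searching the separating watermark; `"quantized"` uses
#'   `watershed_n_levels` quantile levels for speed.
#' @param watershed_n_levels Number of levels in quantized mode. Default 256.
#' @param hcs HCS baseline geometry, see [hcs_params()].
#'
#' @return A list of class `"qic_params"`.
#' @export
qic_params <- function(nuclear_window_px = 41L,
                       background_window_px = 41L,
                       local_sd_window_px = 5L,
                       cell_sd_multiplier = 3,
                       bright_object_sd_multiplier = 3,
                       min_object_px = 16L,
                       watershed_retention = 0.85,
                       min_dna_fraction_of_g1 = 0.5,
                       min_objects_for_g1 = 20L,
                       g1_total = NULL,
                       roundness_cutoff = 1.2,
                       ill_coloc_threshold = 0.3,
                       connectivity = 8L,
                       watershed_levels = c("exact", "quantized"),
                       watershed_n_levels = 256L,
                       hcs = hcs_params()) {
  watershed_levels <- match.arg(watershed_levels)
  for (w in c(nuclear_window_px, background_window_px, local_sd_window_px)) {
    if (w < 1 || w %% 2 != 1)
      stop("window sizes must be odd positive integers", call. = FALSE)
  }
  if (!(connectivity %in% c(4L, 8L)))
    stop("connectivity must be 4 or 8", call. = FALSE)
  if (watershed_retention <= 0 || watershed_retention >= 1)
    stop("watershed_retention must be in (0, 1)", call. = FALSE)
  structure(list(
    nuclear_window_px = as.integer(nuclear_window_px),
    background_window_px = as.integer(background_window_px),
    local_sd_window_px = as.integer(local_sd_window_px),
    cell_sd_multiplier = cell_sd_multiplier,
    bright_object_sd_multiplier = bright_object_sd_multiplier,
    min_object_px = as.integer(min_object_px),
    watershed_retention = watershed_retention,
    min_dna_fraction_of_g1 = min_dna_fraction_of_g1,
    min_objects_for_g1 = as.integer(min_objects_for_g1),
    g1_total = g1_total,
    roundness_cutoff = roundness_cutoff,
    ill_coloc_threshold = ill_coloc_threshold,
    connectivity = as.integer(connectivity),
    watershed_levels = watershed_levels,
    watershed_n_levels = as.integer(watershed_n_levels),
    hcs = hcs
  ), class = "qic_params")
}

#' HCS baseline quantification geometry
#'
#' Pixel radii of the conventional high-content-screening regions drawn
#' around each nucleus: the dilated region of interest used for amounts, and
#' the Circ / Ring regions whose average-intensity ratio serves as a nuclear
#' translocation measure. Values are for a 10x objective and are not
#' rescaled.
#'
#' @param roi_dilation_px Nuclear contour dilation for the amount ROI.
#'   Default 16.
#' @param circ_erosion_px Erosion for the Circ disk. Default 2.
#' @param ring_inner_erosion_px Erosion for the inner Ring edge. Default 1.
#' @param ring_outer_dilation_px Dilation for the outer Ring edge. Default 4.
#' @return A list of class `"hcs_params"`.
#' @export
hcs_params <- function(roi_dilation_px = 16L, circ_erosion_px = 2L,
                       ring_inner_erosion_px = 1L, ring_outer_dilation_px = 4L) {
  stopifnot(roi_dilation_px >= 0, circ_erosion_px >= 0,
            ring_inner_erosion_px >= 0, ring_outer_dilation_px >= 0,
            ring_outer_dilation_px > -ring_inner_erosion_px)
  structure(list(
    roi_dilation_px = as.integer(roi_dilation_px),
    circ_erosion_px = as.integer(circ_erosion_px),
    ring_inner_erosion_px = as.integer(ring_inner_erosion_px),
    ring_outer_dilation_px = as.integer(ring_outer_dilation_px)
  ), class = "hcs_params")
}
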