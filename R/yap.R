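## Nuclear-to-cytoplasmic YAP ratio from ROI-integrated densities:
##   YAP_Cyto     = YAP_Cell - YAP_Nuc
##   YAP_Nuc/Cyto = YAP_Nuc / YAP_Cyto
## with the nucleus ROI drawn on the DNA stain and the cell ROI on the
## actin stain. The ratio is invariant to multiplicative intensity scaling
## but NOT to additive offsets; optional background subtraction handles
## the latter.

#' Integrated density of an ROI
#'
#' Sum of pixel intensities over a mask, optionally background-subtracted
#' using the mean intensity of a stated background ROI.
#'
#' @param image Single-channel image matrix.
#' @param roi Logical mask, nonempty, same shape as `image`.
#' @param background_roi Optional logical mask of background pixels; their
#'   mean is subtracted from every ROI pixel.
#' @return Integrated density (a.u.).
#' @export
integrated_density <- function(image, roi, background_roi = NULL) {
  if (!all(dim(image) == dim(roi))) stop("mask shape must match image")
  if (!any(roi)) stop("empty ROI")
  b <- 0
  if (!is.null(background_roi)) {
    if (!any(background_roi)) stop("empty background ROI")
    b <- mean(image[background_roi])
  }
  sum(image[roi] - b)
}

#' Nuclear-to-cytoplasmic YAP ratio from integrated densities
#'
#' @param cell_density Integrated YAP density over the cell ROI (a.u.).
#' @param nuc_density Integrated YAP density over the nucleus ROI (a.u.);
#'   must not exceed `cell_density`.
#' @param cell_id Optional identifier carried through.
#' @return List of class `yap_measurement`: `yap_cell`, `yap_nuc`,
#'   `yap_cyto`, `ratio` (`Inf` with `degenerate = TRUE` when the
#'   cytoplasmic density is zero).
#' @export
yap_ratio <- function(cell_density, nuc_density, cell_id = NA) {
  if (nuc_density > cell_density)
    stop("nucleus density exceeds cell density: nucleus ROI is not ",
         "contained in the cell signal (check upstream segmentation)")
  cyto <- cell_density - nuc_density
  degenerate <- cyto == 0
  structure(list(cell_id = cell_id, yap_cell = cell_density,
                 yap_nuc = nuc_density, yap_cyto = cyto,
                 ratio = if (degenerate) Inf else nuc_density / cyto,
                 degenerate = degenerate),
            class = "yap_measurement")
}

#' @export
print.yap_measurement <- function(x, ...) {
  cat(sprintf("YAP N/C ratio: %.4g (nuc %.4g / cyto %.4g)\n",
              x$ratio, x$yap_nuc, x$yap_cyto))
  invisible(x)
}

#' Per-cell YAP ratios from channel image and labelled masks
#'
#' @param yap_image YAP channel matrix.
#' @param cell_labels,nucleus_labels Integer label matrices (label N =
#'   cell N and its nucleus).
#' @param background_roi Optional background mask for subtraction.
#' @return data.frame: `cell_id`, `yap_cell`, `yap_nuc`, `yap_cyto`,
#'   `ratio`, `degenerate`.
#' @export
yap_table <- function(yap_image, cell_labels, nucleus_labels,
                      background_roi = NULL) {
  ids <- sort(setdiff(unique(as.vector(cell_labels)), 0))
  rows <- lapply(ids, function(id) {
    m <- yap_ratio(
      integrated_density(yap_image, cell_labels == id, background_roi),
      integrated_density(yap_image, nucleus_labels == id, background_roi),
      cell_id = id)
    data.frame(cell_id = id, yap_cell = m$yap_cell, yap_nuc = m$yap_nuc,
               yap_cyto = m$yap_cyto, ratio = m$ratio,
               degenerate = m$degenerate)
  })
  do.call(rbind, rows)
}
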