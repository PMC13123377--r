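#' Read a grayscale TIFF image or stack
#'
#' Returns intensities as numeric matrices in native counts (the `tiff`
#' package's 0--1 scale is multiplied back to 16-bit counts).
#'
#' @param path TIFF file path.
#' @param scale Count scale (default 65535 for 16-bit).
#' @return A matrix for single-frame files, otherwise a list of matrices.
#' @export
read_tiff_stack <- function(path, scale = 65535) {
  img <- tiff::readTIFF(path, all = TRUE)
  frames <- lapply(img, function(m) {
    if (length(dim(m)) == 3) m <- m[, , 1]
    m * scale
  })
  if (length(frames) == 1) frames[[1]] else frames
}

#' Write a 16-bit grayscale TIFF
#'
#' @param img Matrix of counts (clipped to \[0, 65535\]).
#' @param path Output path.
#' @export
write_tiff16 <- function(img, path) {
  m <- pmin(pmax(img, 0), 65535) / 65535
  tiff::writeTIFF(m, path, bits.per.sample = 16)
  invisible(path)
}
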