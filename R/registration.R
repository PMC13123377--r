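## Rigid drift compensation for bead image time series. Stage drift during
## multi-position imaging shifts the whole frame; it is estimated per frame
## against a reference frame and removed before displacement analysis.
## Gel deformation is signal, not drift, so only translation is modelled.

# Cross-correlation peak between two images with subpixel refinement.
# Returns the shift (dx, dy) such that moving `img` by (dx, dy) aligns it
# with `ref`, i.e. img(x) ~ ref(x - (dx, dy)) => img is ref shifted by +d.
xcorr_shift <- function(ref, img, normalize = TRUE) {
  a <- ref - mean(ref); b <- img - mean(img)
  fa <- stats::fft(a); fb <- stats::fft(b)
  cc <- Re(stats::fft(fa * Conj(fb), inverse = TRUE)) / length(a)
  ny <- nrow(cc); nx <- ncol(cc)
  pk <- unname(which(cc == max(cc), arr.ind = TRUE)[1, ])
  # wrap indices to signed shifts
  wrap <- function(i, n) ifelse(i - 1 > n / 2, i - 1 - n, i - 1)
  dy <- wrap(pk[1], ny); dx <- wrap(pk[2], nx)
  # 3-point parabolic subpixel refinement on the correlation surface
  at <- function(i, j) cc[(i - 1) %% ny + 1, (j - 1) %% nx + 1]
  i0 <- pk[1]; j0 <- pk[2]
  sub <- function(cm, c0, cp) {
    den <- cm - 2 * c0 + cp
    if (den >= 0) 0 else 0.5 * (cm - cp) / den
  }
  ddy <- sub(at(i0 - 1, j0), at(i0, j0), at(i0 + 1, j0))
  ddx <- sub(at(i0, j0 - 1), at(i0, j0), at(i0, j0 + 1))
  score <- if (normalize) {
    den <- sqrt(sum(a^2) * sum(b^2))
    if (den == 0) 0 else max(cc) / den
  } else max(cc)
  # cc peak at positive lag (dy, dx) means img = ref rolled by +d
  c(dx = -(dx + ddx), dy = -(dy + ddy), score = score)
}

#' Estimate rigid stage drift across an image stack
#'
#' Cross-correlates each frame (full frame by default, or a template
#' region, reproducing a template-matching workflow) against a reference
#' frame, with parabolic subpixel refinement. Frames whose correlation
#' score falls below `score_floor` are flagged and their shift linearly
#' interpolated from neighbouring accepted frames.
#'
#' @param stack List of image matrices (>= 2 frames).
#' @param template Optional `c(x, y, w, h)` region (1-based pixel indices)
#'   to correlate instead of the full frame.
#' @param reference_frame Index of the reference frame (default 1).
#' @param score_floor Minimum accepted correlation (default 0.2).
#' @return A data.frame of class `drift_track`: `frame`, `dx_px`, `dy_px`,
#'   `score`, `flagged`.
#' @export
estimate_drift <- function(stack, template = NULL, reference_frame = 1,
                           score_floor = 0.2) {
  if (!is.list(stack) || length(stack) < 2)
    stop("need a stack of at least 2 frames")
  crop <- function(img) {
    if (is.null(template)) return(img)
    x <- template[1]; y <- template[2]; w <- template[3]; h <- template[4]
    if (x < 1 || y < 1 || x + w - 1 > ncol(img) || y + h - 1 > nrow(img))
      stop("template region falls outside the frame")
    img[y:(y + h - 1), x:(x + w - 1)]
  }
  ref <- crop(stack[[reference_frame]])
  if (stats::sd(ref) == 0) stop("flat (zero-variance) template or reference")
  n <- length(stack)
  out <- data.frame(frame = seq_len(n), dx_px = 0, dy_px = 0,
                    score = 1, flagged = FALSE)
  for (f in seq_len(n)) {
    if (f == reference_frame) next
    s <- xcorr_shift(ref, crop(stack[[f]]))
    out$dx_px[f] <- s["dx"]; out$dy_px[f] <- s["dy"]
    out$score[f] <- s["score"]
    out$flagged[f] <- s["score"] < score_floor
  }
  if (any(out$flagged)) {
    ok <- !out$flagged
    for (comp in c("dx_px", "dy_px")) {
      out[[comp]][out$flagged] <- stats::approx(
        out$frame[ok], out[[comp]][ok], xout = out$frame[out$flagged],
        rule = 2)$y
    }
  }
  class(out) <- c("drift_track", "data.frame")
  out
}

#' Translate an image by a subpixel shift
#'
#' Resamples the image by the negated shift with bilinear (or bicubic)
#' interpolation, so that `apply_shift(img, s)` aligns a frame that had
#' drifted by `s` back onto the reference. Pixels sampled from outside the
#' frame are filled with `fill` (default: the image median, a background
#' estimate).
#'
#' @param img Image matrix.
#' @param shift Numeric `c(dx, dy)` in px (x = columns, y = rows).
#' @param method `"bilinear"` (default) or `"bicubic"`.
#' @param fill Out-of-frame fill value.
#' @return The translated image matrix.
#' @export
apply_shift <- function(img, shift, method = c("bilinear", "bicubic"),
                        fill = stats::median(img)) {
  method <- match.arg(method)
  if (any(!is.finite(shift))) stop("shift must be finite")
  if (all(shift == 0)) return(img)
  ny <- nrow(img); nx <- ncol(img)
  xs <- seq_len(nx) - 1; ys <- seq_len(ny) - 1
  xq <- matrix(xs + shift[1], ny, nx, byrow = TRUE)
  yq <- matrix(ys + shift[2], ny, nx)
  out <- if (method == "bilinear") {
    bilinear_at(img, as.vector(xq), as.vector(yq))
  } else {
    pracma::interp2(xs, ys, img, as.vector(xq), as.vector(yq),
                    method = "cubic")
  }
  out[is.na(out)] <- fill
  matrix(out, ny, nx)
}

#' Apply a drift track to a stack
#'
#' @param stack List of image matrices.
#' @param drift A `drift_track` from [estimate_drift()].
#' @param ... Passed to [apply_shift()].
#' @return The registered stack.
#' @export
register_stack <- function(stack, drift, ...) {
  lapply(seq_along(stack), function(f)
    apply_shift(stack[[f]], c(drift$dx_px[f], drift$dy_px[f]), ...))
}
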