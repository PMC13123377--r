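## Gel-surface displacement from loaded vs relaxed bead images.
##
## Window cross-correlation (PIV-style): the loaded and relaxed-reference
## images are cut into overlapping interrogation windows; the correlation
## peak of each pair gives the local bead displacement, refined to
## subpixel precision with a 3-point Gaussian fit. Displacement is
## loaded-relative-to-relaxed, so tractions reconstructed from it are the
## stresses the embryo exerts on the gel.

# Fast vectorized bilinear sampling of an image at 0-based continuous
# coordinates; queries outside the image return NA.
bilinear_at <- function(img, x, y) {
  ny <- nrow(img); nx <- ncol(img)
  out <- rep(NA_real_, length(x))
  ok <- x >= 0 & x <= nx - 1 & y >= 0 & y <= ny - 1 &
    is.finite(x) & is.finite(y)
  xo <- x[ok]; yo <- y[ok]
  j0 <- pmin(floor(xo), nx - 2); i0 <- pmin(floor(yo), ny - 2)
  fx <- xo - j0; fy <- yo - i0
  base <- i0 + 1 + j0 * ny
  out[ok] <- (1 - fx) * (1 - fy) * img[base] +
    (1 - fx) * fy * img[base + 1] +
    fx * (1 - fy) * img[base + ny] +
    fx * fy * img[base + ny + 1]
  out
}

# Gaussian 3-point subpixel interpolation (standard PIV estimator).
gauss3 <- function(cm, c0, cp) {
  cm <- max(cm, 1e-12); c0 <- max(c0, 1e-12); cp <- max(cp, 1e-12)
  den <- log(cm) - 2 * log(c0) + log(cp)
  if (den >= 0) 0 else 0.5 * (log(cm) - log(cp)) / den
}

# Displacement of window b relative to window a via circular
# cross-correlation, searching lags within +/- maxlag.
window_shift <- function(a, b, maxlag) {
  a <- a - mean(a); b <- b - mean(b)
  va <- sum(a^2); vb <- sum(b^2)
  if (va == 0 || vb == 0) return(c(dx = NA, dy = NA, q = 0))
  cc <- Re(stats::fft(stats::fft(b) * Conj(stats::fft(a)),
                      inverse = TRUE)) / length(a)
  ny <- nrow(cc); nx <- ncol(cc)
  lag <- function(i, n) ifelse(i - 1 > n / 2, i - 1 - n, i - 1)
  # quality: plain normalized correlation at the (biased) peak
  q <- max(cc) / sqrt(va * vb)
  # unbiased normalization: divide by the overlap area of the two windows
  # at each lag, removing the loss-of-pairs bias toward zero shift
  ovy <- ny - abs(lag(seq_len(ny), ny))
  ovx <- nx - abs(lag(seq_len(nx), nx))
  cc <- cc * length(a) / outer(ovy, ovx)
  ly <- lag(seq_len(ny), ny); lx <- lag(seq_len(nx), nx)
  ok <- outer(abs(ly) <= maxlag, abs(lx) <= maxlag)
  cc_m <- cc; cc_m[!ok] <- -Inf
  pk <- unname(which(cc_m == max(cc_m), arr.ind = TRUE)[1, ])
  at <- function(i, j) cc[(i - 1) %% ny + 1, (j - 1) %% nx + 1]
  i0 <- pk[1]; j0 <- pk[2]
  dy <- lag(i0, ny) + gauss3(at(i0 - 1, j0), at(i0, j0), at(i0 + 1, j0))
  dx <- lag(j0, nx) + gauss3(at(i0, j0 - 1), at(i0, j0), at(i0, j0 + 1))
  c(dx = dx, dy = dy, q = q)
}

#' Displacement field by window cross-correlation
#'
#' Multipass estimation with image deformation: a first pass on aligned
#' window pairs, then refinement passes in which the loaded image is
#' warped back by the current field estimate and the residual shift is
#' re-measured (suppressing loss-of-pairs and gradient-induced peak
#' smearing before the subpixel fit).
#'
#' @param loaded Image with the embryo load applied (matrix of counts).
#' @param reference Relaxed-state reference image (same shape).
#' @param window_size Interrogation window in px (>= 16).
#' @param overlap Window overlap fraction in \[0, 1).
#' @param pixel_size Pixel size in um/px.
#' @param min_quality Windows whose normalized correlation falls below
#'   this are masked invalid (default 0.2), as are windows with no texture
#'   (no beads).
#' @param passes Number of correlation passes (default 3).
#' @return A `displacement_field` (um) with per-node quality scores.
#'   Node coordinates are the window centers, 0-based pixel centers
#'   converted to um.
#' @export
compute_displacement_field <- function(loaded, reference, window_size = 32,
                                       overlap = 0.5, pixel_size = 0.5,
                                       min_quality = 0.2, passes = 3) {
  if (!all(dim(loaded) == dim(reference)))
    stop("loaded and reference images must have the same shape")
  if (window_size < 16) stop("window_size must be >= 16 px")
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  step <- max(1, round(window_size * (1 - overlap)))
  ny <- nrow(loaded); nx <- ncol(loaded)
  ys <- seq(1, ny - window_size + 1, by = step)
  xs <- seq(1, nx - window_size + 1, by = step)
  u <- v <- q <- matrix(NA_real_, length(ys), length(xs))
  maxlag <- window_size / 4
  one_pass <- function(img) {
    for (iy in seq_along(ys)) {
      ri <- ys[iy]:(ys[iy] + window_size - 1)
      for (ix in seq_along(xs)) {
        ci <- xs[ix]:(xs[ix] + window_size - 1)
        s <- window_shift(reference[ri, ci], img[ri, ci], maxlag)
        u[iy, ix] <<- s["dx"]; v[iy, ix] <<- s["dy"]; q[iy, ix] <<- s["q"]
      }
    }
  }
  one_pass(loaded)
  # image-deformation refinement: warp the loaded image back by the
  # current field estimate, re-correlate, and accumulate the residual;
  # removes the window-averaging bias in high-gradient regions
  cx_px <- xs - 1 + (window_size - 1) / 2
  cy_px <- ys - 1 + (window_size - 1) / 2
  for (p in seq_len(max(1, passes) - 1)) {
    u0 <- fill_invalid(u, is.finite(u)); v0 <- fill_invalid(v, is.finite(v))
    gx <- rep(0:(nx - 1), each = ny); gy <- rep(0:(ny - 1), times = nx)
    qx <- (pmin(pmax(gx, min(cx_px)), max(cx_px)) - cx_px[1]) / step
    qy <- (pmin(pmax(gy, min(cy_px)), max(cy_px)) - cy_px[1]) / step
    dxp <- bilinear_at(u0, qx, qy)
    dyp <- bilinear_at(v0, qx, qy)
    wq <- bilinear_at(loaded,
                      pmin(pmax(gx + dxp, 0), nx - 1),
                      pmin(pmax(gy + dyp, 0), ny - 1))
    warped <- matrix(wq, ny, nx)
    u_base <- u0; v_base <- v0
    one_pass(warped)
    u <- u_base + u; v <- v_base + v
  }
  mask <- is.finite(u) & q >= min_quality
  u[!mask] <- 0; v[!mask] <- 0
  cx <- (xs - 1 + (window_size - 1) / 2) * pixel_size
  cy <- (ys - 1 + (window_size - 1) / 2) * pixel_size
  displacement_field(cx, cy, u * pixel_size, v * pixel_size,
                     mask = mask, quality = q)
}

#' Median-MAD outlier filtering of a displacement field
#'
#' Nodes whose residual from the local median exceeds
#' `threshold * (local MAD + eps)` in either component are masked and
#' replaced by the local median; the replacement count is reported as an
#' attribute.
#'
#' @param field A `displacement_field`.
#' @param median_window Odd neighborhood size in nodes (default 3).
#' @param threshold MAD multiples tolerated (default 5; `Inf` disables).
#' @param eps Measurement-noise floor added to the MAD (um), the
#'   normalized-median-test convention of ~0.1 px acquisition noise
#'   (0.05 um at 0.5 um/px); prevents smooth curved fields from being
#'   flagged on their own curvature.
#' @return The filtered field with attribute `n_replaced`.
#' @export
filter_outliers <- function(field, median_window = 3, threshold = 5,
                            eps = 0.05) {
  stopifnot(inherits(field, "displacement_field"))
  if (!any(field$mask)) stop("all nodes invalid")
  if (is.infinite(threshold)) {
    attr(field, "n_replaced") <- 0L
    return(field)
  }
  h <- median_window %/% 2
  ny <- nrow(field$u); nx <- ncol(field$u)
  un <- field$u; vn <- field$v
  n_rep <- 0L
  for (i in seq_len(ny)) for (j in seq_len(nx)) {
    if (!field$mask[i, j]) next
    ii <- max(1, i - h):min(ny, i + h); jj <- max(1, j - h):min(nx, j + h)
    sel <- field$mask[ii, jj] & !outer(ii == i, jj == j)
    nb_u <- field$u[ii, jj][sel]; nb_v <- field$v[ii, jj][sel]
    if (length(nb_u) < 3) next
    mu <- stats::median(nb_u); mv <- stats::median(nb_v)
    madu <- stats::mad(nb_u) + eps; madv <- stats::mad(nb_v) + eps
    if (abs(field$u[i, j] - mu) > threshold * madu ||
        abs(field$v[i, j] - mv) > threshold * madv) {
      un[i, j] <- mu; vn[i, j] <- mv
      n_rep <- n_rep + 1L
    }
  }
  out <- displacement_field(field$x, field$y, un, vn,
                            mask = field$mask, quality = field$quality)
  attr(out, "n_replaced") <- n_rep
  out
}

#' Resample a displacement field onto a uniform grid
#'
#' Bilinear interpolation onto a new spacing. Invalid nodes are first
#' filled with the median of their valid neighbours (expanding rings) so
#' the interpolant is defined everywhere; target nodes outside the source
#' hull are flagged invalid.
#'
#' @param field A `displacement_field`.
#' @param spacing Target grid spacing (um).
#' @return A `displacement_field` on the new grid.
#' @export
interpolate_to_grid <- function(field, spacing) {
  stopifnot(inherits(field, "displacement_field"))
  if (sum(field$mask) < 4) stop("need >= 4 valid nodes")
  u <- fill_invalid(field$u, field$mask)
  v <- fill_invalid(field$v, field$mask)
  xt <- seq(min(field$x), max(field$x), by = spacing)
  yt <- seq(min(field$y), max(field$y), by = spacing)
  g <- expand.grid(y = yt, x = xt)
  ui <- pracma::interp2(field$x, field$y, u, g$x, g$y, method = "linear")
  vi <- pracma::interp2(field$x, field$y, v, g$x, g$y, method = "linear")
  mask <- matrix(is.finite(ui) & is.finite(vi), length(yt), length(xt))
  ui[!is.finite(ui)] <- 0; vi[!is.finite(vi)] <- 0
  displacement_field(xt, yt, matrix(ui, length(yt), length(xt)),
                     matrix(vi, length(yt), length(xt)), mask = mask)
}

# Fill masked-out nodes with the median of valid neighbours, growing the
# neighbourhood until every node has support.
fill_invalid <- function(m, mask) {
  if (all(mask)) return(m)
  ny <- nrow(m); nx <- ncol(m)
  bad <- which(!mask, arr.ind = TRUE)
  for (k in seq_len(nrow(bad))) {
    i <- bad[k, 1]; j <- bad[k, 2]
    for (h in 1:max(ny, nx)) {
      ii <- max(1, i - h):min(ny, i + h); jj <- max(1, j - h):min(nx, j + h)
      vals <- m[ii, jj][mask[ii, jj]]
      if (length(vals)) { m[i, j] <- stats::median(vals); break }
    }
  }
  m
}
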