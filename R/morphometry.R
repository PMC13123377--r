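## Shape, interface and motility quantifications: projected circularity
## and area, EPI/pTE interface geometry, the >80 um core-structure rule,
## migration statistics (speed, directionality ratio, MSD) and the
## adhesion-onset breakpoint of area-circularity series.

# Perimeter of the largest foreground component, measured as the arc
# length of the 0.5-level contour of a lightly smoothed mask. The
# smoothing (separable Gaussian, sigma in px) removes the pixelation bias
# that makes chain-code perimeters overestimate smooth outlines.
mask_perimeter <- function(mask, smooth_sigma = 2) {
  m <- smooth_mask(mask, smooth_sigma)
  cl <- grDevices::contourLines(x = seq_len(ncol(m)) - 1,
                                y = seq_len(nrow(m)) - 1,
                                z = t(m), levels = 0.5)
  if (!length(cl)) return(0)
  per <- vapply(cl, function(cc)
    sum(sqrt(diff(cc$x)^2 + diff(cc$y)^2)) +
      sqrt((cc$x[1] - cc$x[length(cc$x)])^2 +
             (cc$y[1] - cc$y[length(cc$y)])^2),
    numeric(1))
  max(per)   # outer contour of the largest component
}

smooth_mask <- function(mask, sigma) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  if (sigma <= 0) return(m)
  half <- ceiling(3 * sigma)
  k <- exp(-((-half):half)^2 / (2 * sigma^2)); k <- k / sum(k)
  # pad-replicate separable convolution
  convolve_rows <- function(mm) {
    padded <- cbind(mm[, rep(1, half)], mm, mm[, rep(ncol(mm), half)])
    out <- matrix(0, nrow(mm), ncol(mm))
    for (o in -half:half)
      out <- out + k[o + half + 1] * padded[, (1 + half + o):(ncol(mm) + half + o)]
    out
  }
  t(convolve_rows(t(convolve_rows(m))))
}

largest_component <- function(mask) {
  # 4-connected labelling by frontier dilation (vectorized BFS)
  ny <- nrow(mask); nx <- ncol(mask)
  lab <- matrix(0L, ny, nx)
  cur <- 0L
  todo <- which(mask)
  while (length(todo)) {
    s <- todo[1]
    if (lab[s] != 0L) { todo <- todo[lab[todo] == 0L]; next }
    cur <- cur + 1L
    frontier <- s
    lab[s] <- cur
    while (length(frontier)) {
      i <- (frontier - 1L) %% ny + 1L
      j <- (frontier - 1L) %/% ny + 1L
      nb <- c(frontier[i > 1] - 1L, frontier[i < ny] + 1L,
              frontier[j > 1] - ny, frontier[j < nx] + ny)
      nb <- unique(nb[mask[nb] & lab[nb] == 0L])
      lab[nb] <- cur
      frontier <- nb
    }
    todo <- todo[lab[todo] == 0L]
  }
  if (cur <= 1L) return(mask)
  sizes <- tabulate(lab[lab > 0L], cur)
  lab == which.max(sizes)
}

#' Projected shape metrics of a binary mask
#'
#' Area from the pixel count, perimeter from the smoothed mask contour,
#' circularity `4 pi A / P^2`, and the equivalent (area-matched circle)
#' diameter.
#'
#' @param mask Logical matrix (one foreground object; if several, the
#'   largest connected component is measured and a message emitted).
#' @param pixel_size Pixel size in um/px.
#' @return List of class `shape_metrics`: `area_um2`, `perimeter_um`,
#'   `circularity`, `equivalent_diameter_um`.
#' @export
shape_metrics <- function(mask, pixel_size = 1) {
  mask <- mask > 0
  if (!any(mask)) stop("empty mask")
  one <- largest_component(mask)
  if (sum(one) < sum(mask))
    message("multiple components: measuring the largest (",
            sum(one), " of ", sum(mask), " px)")
  area_px <- sum(one)
  per_px <- mask_perimeter(one)
  area <- area_px * pixel_size^2
  per <- per_px * pixel_size
  structure(list(area_um2 = area, perimeter_um = per,
                 circularity = 4 * pi * area / per^2,
                 equivalent_diameter_um = 2 * sqrt(area / pi)),
            class = "shape_metrics")
}

#' Core-structure rule
#'
#' An aggregate qualifies as a core structure when its equivalent
#' diameter exceeds 80 um (strictly).
#'
#' @param mask Logical matrix (nonempty).
#' @param pixel_size Pixel size in um/px.
#' @return List: `is_core` (logical), `equivalent_diameter_um`.
#' @export
core_structure_test <- function(mask, pixel_size = 1) {
  sm <- shape_metrics(mask, pixel_size)
  list(is_core = sm$equivalent_diameter_um > 80,
       equivalent_diameter_um = sm$equivalent_diameter_um)
}

# Ordered polyline of the EPI/pTE shared boundary: midpoints of adjacent
# EPI-pTE pixel pairs, chained by nearest-neighbour from an endpoint.
interface_polyline <- function(epi, pte) {
  pts <- NULL
  ny <- nrow(epi); nx <- ncol(epi)
  # horizontal neighbours
  a <- epi[, -nx] & pte[, -1]; b <- pte[, -nx] & epi[, -1]
  idx <- which(a | b, arr.ind = TRUE)
  if (nrow(idx)) pts <- rbind(pts, cbind(x = idx[, 2] - 1 + 0.5,
                                         y = idx[, 1] - 1))
  a <- epi[-ny, ] & pte[-1, ]; b <- pte[-ny, ] & epi[-1, ]
  idx <- which(a | b, arr.ind = TRUE)
  if (nrow(idx)) pts <- rbind(pts, cbind(x = idx[, 2] - 1,
                                         y = idx[, 1] - 1 + 0.5))
  if (is.null(pts) || nrow(pts) < 2) return(NULL)
  pts <- unique(pts)
  # chain from an extreme point by nearest neighbour
  n <- nrow(pts)
  d0 <- (pts[, 1] - mean(pts[, 1]))^2 + (pts[, 2] - mean(pts[, 2]))^2
  start <- which.max(d0)
  used <- logical(n); path <- integer(n)
  path[1] <- start; used[start] <- TRUE
  for (k in 2:n) {
    last <- path[k - 1]
    d <- (pts[, 1] - pts[last, 1])^2 + (pts[, 2] - pts[last, 2])^2
    d[used] <- Inf
    path[k] <- which.min(d)
    used[path[k]] <- TRUE
  }
  pts[path, , drop = FALSE]
}

# Least-squares (Kasa) circle fit; returns center and radius.
fit_circle <- function(x, y) {
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  sol <- tryCatch(qr.solve(A, b), error = function(e) NULL)
  if (is.null(sol)) return(NULL)
  r2 <- sol[3] + sol[1]^2 + sol[2]^2
  if (r2 <= 0) return(NULL)
  list(cx = sol[1], cy = sol[2], r = sqrt(r2))
}

#' EPI/pTE interface geometry
#'
#' The interface is the shared boundary polyline between the two lineage
#' masks. Reported metrics: arc length, chord (endpoint distance),
#' curvature as the subtended angle (degrees) of the least-squares circle
#' fit, relative interface = chord / EPI width (the EPI extent along the
#' chord direction, so a full-width interface gives 1), and bounding
#' heights/widths along and across the chord axis.
#'
#' @param epi,pte Logical masks, overlap-free, sharing a boundary.
#' @param pixel_size Pixel size in um/px.
#' @return List of class `interface_metrics`.
#' @export
interface_metrics <- function(epi, pte, pixel_size = 1) {
  epi <- epi > 0; pte <- pte > 0
  if (any(epi & pte)) stop("EPI and pTE masks must not overlap")
  poly <- interface_polyline(epi, pte)
  if (is.null(poly)) stop("masks share no boundary")
  px <- poly[, 1] * pixel_size; py <- poly[, 2] * pixel_size
  arc <- sum(sqrt(diff(px)^2 + diff(py)^2))
  n <- length(px)
  chord <- sqrt((px[n] - px[1])^2 + (py[n] - py[1])^2)
  # curvature: angular extent about the fitted circle center; straight
  # interfaces (huge fitted radius) report 0
  circ <- fit_circle(px, py)
  curvature <- 0
  if (!is.null(circ) && circ$r < 50 * chord && circ$r > 0) {
    ang <- atan2(py - circ$cy, px - circ$cx)
    ang <- sort(ang)
    gaps <- diff(c(ang, ang[1] + 2 * pi))
    curvature <- (2 * pi - max(gaps)) * 180 / pi
  }
  # axes: chord direction and its normal
  if (chord > 0) {
    ux <- (px[n] - px[1]) / chord; uy <- (py[n] - py[1]) / chord
  } else { ux <- 1; uy <- 0 }
  extent <- function(mask) {
    idx <- which(mask, arr.ind = TRUE)
    xs <- (idx[, 2] - 1) * pixel_size; ys <- (idx[, 1] - 1) * pixel_size
    along <- xs * ux + ys * uy
    across <- -xs * uy + ys * ux
    c(width = diff(range(along)), height = diff(range(across)))
  }
  e_epi <- extent(epi); e_pte <- extent(pte)
  structure(list(epi_area_um2 = sum(epi) * pixel_size^2,
                 pte_area_um2 = sum(pte) * pixel_size^2,
                 interface_arc_um = arc,
                 interface_chord_um = chord,
                 curvature_deg = curvature,
                 relative_interface = chord / e_epi["width"],
                 epi_width_um = unname(e_epi["width"]),
                 epi_height_um = unname(e_epi["height"]),
                 pte_height_um = unname(e_pte["height"])),
            class = "interface_metrics")
}

#' Migration statistics of a trajectory
#'
#' Average speed (total path length over elapsed time), directionality
#' ratio (net displacement over path length), and the time-averaged MSD
#' curve reported for lags up to a quarter of the track span. The
#' power-law exponent is fitted by log-log regression over the first
#' `fit_lags` lags only: time-averaged MSD estimates at long lags share
#' few independent increments and wander coherently, degrading an
#' exponent fit, so the short-lag regime is used (standard practice in
#' migration analysis).
#'
#' @param trajectory A `trajectory` data.frame (`t_min`, `x_um`, `y_um`),
#'   >= 3 points at uniform intervals.
#' @param fit_lags Number of initial lags used for the exponent fit
#'   (default 10, limited by the available lags).
#' @return List of class `migration_stats`: `speed_um_min`,
#'   `directionality_ratio` (`NA` with `stationary = TRUE` for zero path
#'   length), `msd` (data.frame `lag_min`, `msd_um2`), `msd_exponent`.
#' @export
migration_stats <- function(trajectory, fit_lags = 10) {
  t <- trajectory$t_min; x <- trajectory$x_um; y <- trajectory$y_um
  n <- length(t)
  if (n < 3) stop("need >= 3 trajectory points")
  if (any(diff(t) <= 0)) stop("times must be strictly increasing")
  steps <- sqrt(diff(x)^2 + diff(y)^2)
  path <- sum(steps)
  net <- sqrt((x[n] - x[1])^2 + (y[n] - y[1])^2)
  stationary <- path == 0
  max_lag <- max(1L, floor((n - 1) / 4))
  msd <- vapply(seq_len(max_lag), function(l)
    mean((x[(1 + l):n] - x[1:(n - l)])^2 +
           (y[(1 + l):n] - y[1:(n - l)])^2), numeric(1))
  lags <- (t[2] - t[1]) * seq_len(max_lag)
  expo <- NA_real_
  fit_n <- min(fit_lags, max_lag)
  pos <- seq_len(fit_n)[msd[seq_len(fit_n)] > 0]
  if (length(pos) >= 2)
    expo <- unname(stats::coef(stats::lm(log(msd[pos]) ~ log(lags[pos])))[2])
  structure(list(speed_um_min = path / (t[n] - t[1]),
                 directionality_ratio = if (stationary) NA_real_
                                        else net / path,
                 stationary = stationary,
                 msd = data.frame(lag_min = lags, msd_um2 = msd),
                 msd_exponent = expo),
            class = "migration_stats")
}

#' Adhesion-onset breakpoint of area/circularity series
#'
#' Fits a two-segment piecewise-linear model (common breakpoint, both
#' series standardized and fitted against time) and returns the breakpoint
#' minimizing the total squared residual — the inflection marking adhesion
#' onset in area-circularity trajectories.
#'
#' @param times Sample times (>= 8, shared by both series).
#' @param area Projected area series.
#' @param circularity Circularity series.
#' @return List: `breakpoint_time`, `sse`, `collinear` (TRUE when a single
#'   line fits as well, making the breakpoint meaningless).
#' @export
adhesion_inflection <- function(times, area, circularity) {
  n <- length(times)
  if (n < 8) stop("need >= 8 samples")
  if (length(area) != n || length(circularity) != n)
    stop("series must share the time base")
  z <- function(v) if (stats::sd(v) == 0) v * 0 else (v - mean(v)) / stats::sd(v)
  ys <- cbind(z(area), z(circularity))
  seg_sse <- function(idx) {
    sum(vapply(1:2, function(k) {
      f <- stats::lm.fit(cbind(1, times[idx]), ys[idx, k])
      sum(f$residuals^2)
    }, numeric(1)))
  }
  cands <- 3:(n - 2)   # >= 3 points per segment
  sse <- vapply(cands, function(b)
    seg_sse(1:b) + seg_sse(b:n), numeric(1))
  best <- cands[which.min(sse)]
  one_line <- seg_sse(1:n)
  collinear <- (one_line - min(sse)) < 1e-9 * max(one_line, 1e-12)
  list(breakpoint_time = if (collinear) NA_real_ else times[best],
       sse = min(sse), collinear = collinear)
}
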