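## Forward simulator: every input the pipeline consumes can be generated
## here with known ground truth, so downstream stages are testable by
## parameter recovery.

#' Synthetic contractile traction pattern
#'
#' Builds an inward-pointing radial traction field confined to an annulus,
#' emulating the peripheral pull an adherent embryo exerts on the gel. The
#' radial profile is a smooth sin^2 bump between the radii (a hard top-hat
#' is available via `profile = "flat"`). Any discrete net-force residual
#' from sampling is removed by a magnitude-weighted correction inside the
#' annulus, so the field is self-balanced to numerical tolerance.
#'
#' @param nx,ny Grid nodes per axis (> 2).
#' @param spacing Grid spacing in um (> 0).
#' @param center Annulus center (um), default the grid center.
#' @param r_inner,r_outer Annulus radii in um, `r_inner < r_outer`.
#' @param peak Peak stress in Pa.
#' @param profile `"smooth"` (sin^2 bump, default) or `"flat"`.
#' @return A `traction_field` whose vector sum is zero to ~1e-12 of the
#'   summed magnitude.
#' @export
make_contractile_traction <- function(nx = 64, ny = 64, spacing = 4,
                                      center = NULL, r_inner = 25,
                                      r_outer = 55, peak = 100,
                                      profile = c("smooth", "flat")) {
  profile <- match.arg(profile)
  if (nx <= 2 || ny <= 2) stop("degenerate grid: need > 2 nodes per axis")
  if (spacing <= 0) stop("grid spacing must be > 0")
  if (r_inner >= r_outer) stop("r_inner must be < r_outer")
  x <- (seq_len(nx) - 1) * spacing
  y <- (seq_len(ny) - 1) * spacing
  if (is.null(center)) center <- c(mean(range(x)), mean(range(y)))
  xm <- matrix(x, ny, nx, byrow = TRUE) - center[1]
  ym <- matrix(y, ny, nx) - center[2]
  r <- sqrt(xm^2 + ym^2)
  inside <- r > r_inner & r < r_outer
  mag <- matrix(0, ny, nx)
  if (profile == "smooth") {
    s <- (r[inside] - r_inner) / (r_outer - r_inner)
    mag[inside] <- peak * sin(pi * s)^2
  } else {
    mag[inside] <- peak
  }
  # inward radial direction
  rr <- pmax(r, .Machine$double.eps)
  tx <- -mag * xm / rr
  ty <- -mag * ym / rr
  # remove discrete net-force residual, weighted by local magnitude so the
  # correction stays confined to the annulus
  w <- mag
  sw <- sum(w)
  if (sw > 0) {
    tx <- tx - sum(tx) * w / sw
    ty <- ty - sum(ty) * w / sw
  }
  traction_field(x, y, tx, ty)
}

#' Ground-truth synthetic TFM scene
#'
#' Bundles a traction truth, gel, bead layout, per-frame drift and noise
#' model into one reproducible object consumed by [render_bead_images()].
#'
#' @param traction_truth A `traction_field` (the ground truth).
#' @param gel A [gel_properties()] object.
#' @param pixel_size Image pixel size in um/px.
#' @param image_size Image size in px, `c(ny, nx)`.
#' @param bead_density Beads per px^2 (default 0.015, ~15 beads per 32-px
#'   interrogation window, following standard PIV seeding guidance; the
#'   density is a free simulator choice reported in the sidecar).
#' @param bead_sigma Gaussian spot sigma in px (default 1.5).
#' @param bead_amplitude Peak spot intensity above background (16-bit
#'   counts, default 8000).
#' @param background Background level (counts, default 400).
#' @param poisson_noise Apply counting noise to each frame?
#' @param drift_per_frame Matrix of per-frame rigid shifts (px), one row
#'   per loaded frame; `NULL` for none.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return An object of class `tfm_scene`.
#' @export
simulate_scene <- function(traction_truth, gel = gel_properties(),
                           pixel_size = 0.5, image_size = c(512, 512),
                           bead_density = 0.015, bead_sigma = 1.5,
                           bead_amplitude = 8000, background = 400,
                           poisson_noise = FALSE, drift_per_frame = NULL,
                           seed = 1) {
  stopifnot(inherits(traction_truth, "traction_field"))
  set.seed(seed)
  n_beads <- round(bead_density * prod(image_size))
  # uniform bead monolayer over the field of view (um coordinates)
  bx <- stats::runif(n_beads, 0, (image_size[2] - 1) * pixel_size)
  by <- stats::runif(n_beads, 0, (image_size[1] - 1) * pixel_size)
  structure(list(traction_truth = traction_truth, gel = gel,
                 pixel_size = pixel_size, image_size = image_size,
                 beads = cbind(x = bx, y = by), bead_sigma = bead_sigma,
                 bead_amplitude = bead_amplitude, background = background,
                 poisson_noise = poisson_noise,
                 drift_per_frame = drift_per_frame, seed = seed),
            class = "tfm_scene")
}

# Render Gaussian spots at subpixel centers (px units) into an image.
render_spots <- function(centers_px, size, sigma, amplitude, background) {
  img <- matrix(background, size[1], size[2])
  if (nrow(centers_px) == 0) return(img)
  half <- ceiling(4 * sigma)
  for (b in seq_len(nrow(centers_px))) {
    cx <- centers_px[b, 1]; cy <- centers_px[b, 2]
    j0 <- max(1, floor(cx) - half + 1); j1 <- min(size[2], floor(cx) + half + 1)
    i0 <- max(1, floor(cy) - half + 1); i1 <- min(size[1], floor(cy) + half + 1)
    if (j0 > j1 || i0 > i1) next
    jj <- j0:j1; ii <- i0:i1
    gx <- exp(-((jj - 1 - cx)^2) / (2 * sigma^2))
    gy <- exp(-((ii - 1 - cy)^2) / (2 * sigma^2))
    img[ii, jj] <- img[ii, jj] + amplitude * outer(gy, gx)
  }
  img
}

#' Render reference and loaded bead images for a scene
#'
#' The reference frame shows beads at rest; each loaded frame shows them
#' displaced by the (interpolated) forward-model displacement plus the
#' frame's rigid drift. Beads pushed out of the field of view are dropped
#' and counted. Pixel (row i, col j) has its center at
#' `x = (j-1) * pixel_size`, `y = (i-1) * pixel_size`.
#'
#' @param scene A [simulate_scene()] object.
#' @param displacement A `displacement_field` covering the field of view
#'   (um); `NULL` computes it from the scene's traction truth via
#'   [forward_displacement()].
#' @param n_frames Number of loaded frames (default 1, or the number of
#'   drift rows).
#' @return List with `reference` (matrix), `frames` (list of matrices),
#'   `displacement` (the field used), `dropped` (beads lost per frame).
#'   Intensities are counts suitable for 16-bit TIFF.
#' @export
render_bead_images <- function(scene, displacement = NULL, n_frames = NULL) {
  stopifnot(inherits(scene, "tfm_scene"))
  if (is.null(displacement))
    displacement <- forward_displacement(scene$traction_truth, scene$gel)
  if (is.null(n_frames))
    n_frames <- if (is.null(scene$drift_per_frame)) 1
                else nrow(scene$drift_per_frame)
  set.seed(scene$seed + 1L)
  px <- scene$pixel_size
  size <- scene$image_size
  ref_px <- cbind(scene$beads[, "x"] / px, scene$beads[, "y"] / px)
  reference <- render_spots(ref_px, size, scene$bead_sigma,
                            scene$bead_amplitude, scene$background)
  ub <- interp_field_at(displacement, scene$beads[, "x"], scene$beads[, "y"])
  frames <- vector("list", n_frames)
  dropped <- integer(n_frames)
  for (f in seq_len(n_frames)) {
    drift <- if (is.null(scene$drift_per_frame)) c(0, 0)
             else scene$drift_per_frame[f, ]
    cx <- (scene$beads[, "x"] + ub$u) / px + drift[1]
    cy <- (scene$beads[, "y"] + ub$v) / px + drift[2]
    keep <- cx >= 0 & cx <= size[2] - 1 & cy >= 0 & cy <= size[1] - 1
    dropped[f] <- sum(!keep)
    img <- render_spots(cbind(cx[keep], cy[keep]), size, scene$bead_sigma,
                        scene$bead_amplitude, scene$background)
    if (scene$poisson_noise)
      img <- matrix(stats::rpois(length(img), lambda = img),
                    nrow(img), ncol(img))
    frames[[f]] <- img
  }
  if (any(dropped > 0))
    message(sum(dropped), " bead(s) displaced out of frame were dropped")
  list(reference = reference, frames = frames,
       displacement = displacement, dropped = dropped)
}

# Bilinear interpolation of a displacement field at scattered um points.
interp_field_at <- function(field, xq, yq) {
  u <- pracma::interp2(field$x, field$y, field$u, xq, yq, method = "linear")
  v <- pracma::interp2(field$x, field$y, field$v, xq, yq, method = "linear")
  u[is.na(u)] <- 0; v[is.na(v)] <- 0
  list(u = u, v = v)
}

#' Synthetic force time series with periodic peaks
#'
#' A monotone ramp up to `baseline` over `ramp_duration`, then baseline
#' plus Gaussian-shaped bumps of height `peak_amplitude` at jittered
#' multiples of `mean_period` — the shape of a maturing embryo's max
#' traction: growth, then bounded fluctuation with ~10-min recurrence.
#'
#' @param mean_period Mean inter-peak interval (min, > 0).
#' @param jitter_sd SD of the interval jitter (min).
#' @param peak_amplitude Bump height (Pa).
#' @param baseline Plateau level (Pa).
#' @param ramp_duration Ramp length (min).
#' @param sampling_interval Sample spacing (min, > 0).
#' @param duration Total length (min, >= sampling_interval).
#' @param n_peaks Alternatively, stop after this many peaks (overrides
#'   `duration` if longer).
#' @param peak_width_frac Bump sigma as a fraction of `mean_period`
#'   (default 1/8).
#' @param seed Integer seed.
#' @return List of class `peak_series`: `times`, `values`, and the
#'   ground-truth `peak_times`.
#' @export
gen_peak_series <- function(mean_period = 10, jitter_sd = 1,
                            peak_amplitude = 30, baseline = 60,
                            ramp_duration = 60, sampling_interval = 1,
                            duration = 240, n_peaks = NULL,
                            peak_width_frac = 1 / 8, seed = 1) {
  if (mean_period <= 0) stop("mean_period must be > 0")
  if (sampling_interval <= 0) stop("sampling_interval must be > 0")
  if (duration < sampling_interval) stop("duration must be >= sampling_interval")
  set.seed(seed)
  n_draw <- if (is.null(n_peaks)) ceiling(duration / mean_period) + 10
            else n_peaks
  gaps <- mean_period + stats::rnorm(n_draw, 0, jitter_sd)
  gaps <- pmax(gaps, mean_period / 10)   # keep intervals positive
  peak_times <- ramp_duration + cumsum(gaps)
  if (!is.null(n_peaks)) {
    peak_times <- peak_times[seq_len(n_peaks)]
    duration <- max(duration, max(peak_times) + mean_period)
  } else {
    peak_times <- peak_times[peak_times <= duration]
  }
  times <- seq(0, duration, by = sampling_interval)
  values <- ifelse(times < ramp_duration,
                   baseline * times / ramp_duration, baseline)
  sig <- peak_width_frac * mean_period
  for (tp in peak_times)
    values <- values + peak_amplitude * exp(-(times - tp)^2 / (2 * sig^2))
  structure(list(times = times, values = values, peak_times = peak_times,
                 baseline = baseline, ramp_duration = ramp_duration),
            class = "peak_series")
}

#' Persistent-random-walk trajectory
#'
#' Constant step speed with a heading that decorrelates over
#' `persistence_time`: `persistence_time = 0` gives an uncorrelated
#' (diffusive) walk, `Inf` a straight ballistic track.
#'
#' @param speed Mean speed in um/min (>= 0).
#' @param persistence_time Heading correlation time (min; 0 or `Inf`
#'   allowed).
#' @param n_steps Number of steps.
#' @param interval Sampling interval (min); embryo time-lapse used 20 min.
#' @param seed Integer seed.
#' @return A data.frame of class `trajectory`: `t_min`, `x_um`, `y_um`.
#' @export
gen_trajectory <- function(speed = 0.2, persistence_time = 40,
                           n_steps = 72, interval = 20, seed = 1) {
  if (speed < 0) stop("speed must be >= 0")
  set.seed(seed)
  theta0 <- stats::runif(1, 0, 2 * pi)
  if (speed == 0) {
    xy <- matrix(0, n_steps + 1, 2)
  } else {
    if (persistence_time == 0) {
      theta <- stats::runif(n_steps, 0, 2 * pi)
    } else if (is.infinite(persistence_time)) {
      theta <- rep(theta0, n_steps)
    } else {
      dtheta <- stats::rnorm(n_steps, 0, sqrt(2 * interval / persistence_time))
      theta <- theta0 + cumsum(dtheta)
    }
    step <- speed * interval
    xy <- rbind(c(0, 0),
                cbind(cumsum(step * cos(theta)), cumsum(step * sin(theta))))
  }
  structure(data.frame(t_min = (0:n_steps) * interval,
                       x_um = xy[, 1], y_um = xy[, 2]),
            class = c("trajectory", "data.frame"))
}

#' Synthetic Hertzian force-indentation curve
#'
#' `F(delta) = (4/3) E / (1 - nu^2) sqrt(R) delta_eff^(3/2)` past the
#' contact offset, zero-force baseline before contact; depths in um,
#' forces in nN, E in Pa, tip radius R in um.
#'
#' @param E Young's modulus (Pa, > 0).
#' @param nu Poisson's ratio.
#' @param R Tip radius (um, > 0); the nanoindenter tips were 3.000 um.
#' @param contact_offset Depth at which contact begins (um).
#' @param noise_sd Additive force noise SD (nN).
#' @param delta Depth sample vector (um); default 0 to 2 um.
#' @param seed Integer seed.
#' @return A data.frame of class `indentation_curve`: `delta_um`,
#'   `force_nN`, with `E`, `nu`, `R`, `contact_offset` attributes.
#' @export
gen_indentation_curve <- function(E = 1000, nu = 0.5, R = 3,
                                  contact_offset = 0.3, noise_sd = 0,
                                  delta = seq(0, 2, by = 0.01), seed = 1) {
  if (E <= 0) stop("E must be > 0")
  if (R <= 0) stop("R must be > 0")
  set.seed(seed)
  force <- hertz_force(delta, E, nu, R, contact_offset)
  if (noise_sd > 0) force <- force + stats::rnorm(length(force), 0, noise_sd)
  structure(data.frame(delta_um = delta, force_nN = force),
            class = c("indentation_curve", "data.frame"),
            E = E, nu = nu, R = R, contact_offset = contact_offset)
}

# Hertz spherical-contact force in nN (delta, R in um; E in Pa).
# 1 Pa * sqrt(um) * um^1.5 = 1e-12 N = 1e-3 nN.
hertz_force <- function(delta, E, nu, R, contact_offset = 0) {
  d_eff <- pmax(delta - contact_offset, 0)
  (4 / 3) * (E / (1 - nu^2)) * sqrt(R) * d_eff^1.5 * 1e-3
}

#' Synthetic two-channel YAP / nucleus cell image
#'
#' Renders a YAP channel with stated mean intensities over the nucleus and
#' the cytoplasm (cell minus nucleus), plus a nucleus-marker channel. The
#' analytic nuclear-to-cytoplasmic ratio of the noise-free image is
#' `(nuc_mean * A_nuc) / (cyto_mean * (A_cell - A_nuc))`.
#'
#' @param nuc_mean,cyto_mean Mean YAP intensity in the nucleus and the
#'   cytoplasm (a.u.).
#' @param cell_mask,nucleus_mask Logical matrices; the nucleus must be
#'   strictly inside the cell.
#' @param noise_sd Additive Gaussian noise SD (0 = noise-free).
#' @param seed Integer seed.
#' @return List: `yap` and `nucleus_channel` image matrices, the two
#'   masks, `true_ratio` (flagged `Inf` and `degenerate = TRUE` when the
#'   cytoplasmic signal is zero).
#' @export
gen_yap_cell_image <- function(nuc_mean, cyto_mean, cell_mask, nucleus_mask,
                               noise_sd = 0, seed = 1) {
  if (!all(dim(cell_mask) == dim(nucleus_mask)))
    stop("masks must have identical dimensions")
  if (any(nucleus_mask & !cell_mask))
    stop("nucleus mask must be a subset of the cell mask")
  set.seed(seed)
  yap <- matrix(0, nrow(cell_mask), ncol(cell_mask))
  cyto <- cell_mask & !nucleus_mask
  yap[cyto] <- cyto_mean
  yap[nucleus_mask] <- nuc_mean
  if (noise_sd > 0)
    yap <- yap + matrix(stats::rnorm(length(yap), 0, noise_sd),
                        nrow(yap), ncol(yap))
  nuc_channel <- matrix(0, nrow(cell_mask), ncol(cell_mask))
  nuc_channel[nucleus_mask] <- 1
  a_nuc <- sum(nucleus_mask); a_cyto <- sum(cyto)
  denom <- cyto_mean * a_cyto
  degenerate <- denom == 0
  true_ratio <- if (degenerate) Inf else (nuc_mean * a_nuc) / denom
  list(yap = yap, nucleus_channel = nuc_channel,
       cell_mask = cell_mask, nucleus_mask = nucleus_mask,
       true_ratio = true_ratio, degenerate = degenerate)
}

#' Write a simulated scene to disk
#'
#' Bead images as 16-bit grayscale TIFF, ground truth as CSV (node
#' coordinates, traction, displacement) and a JSON sidecar with gel
#' properties, pixel size, bead parameters and seed.
#'
#' @param scene A [simulate_scene()] object.
#' @param rendered Output of [render_bead_images()] for the scene.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, rendered, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tiff16(rendered$reference, file.path(dir, "reference.tif"))
  for (f in seq_along(rendered$frames))
    write_tiff16(rendered$frames[[f]],
                 file.path(dir, sprintf("frame_%03d.tif", f)))
  tt <- scene$traction_truth
  g <- expand.grid(y_um = tt$y, x_um = tt$x)
  utils::write.csv(
    data.frame(x_um = g$x_um, y_um = g$y_um,
               tx_Pa = as.vector(tt$tx), ty_Pa = as.vector(tt$ty),
               ux_um = as.vector(rendered$displacement$u),
               uy_um = as.vector(rendered$displacement$v)),
    file.path(dir, "ground_truth.csv"), row.names = FALSE)
  sidecar <- list(gel = unclass(scene$gel), pixel_size = scene$pixel_size,
                  image_size = scene$image_size,
                  n_beads = nrow(scene$beads),
                  bead_sigma = scene$bead_sigma,
                  bead_amplitude = scene$bead_amplitude,
                  background = scene$background,
                  poisson_noise = scene$poisson_noise, seed = scene$seed)
  jsonlite::write_json(sidecar, file.path(dir, "scene.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
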