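# Shared fixture builders: everything is generated in code at test time.

# Circularly roll a matrix so that out[i, j] = m[i - dy, j - dx] (an exact
# integer translation with periodic wrap).
roll_matrix <- function(m, dy, dx) {
  ny <- nrow(m); nx <- ncol(m)
  m[((seq_len(ny) - 1 - dy) %% ny) + 1, ((seq_len(nx) - 1 - dx) %% nx) + 1]
}

disk_mask <- function(n, radius, center = (n + 1) / 2) {
  d2 <- outer((seq_len(n) - center)^2, (seq_len(n) - center)^2, `+`)
  d2 <= radius^2
}

# A compact contractile scene small enough for per-test use.
small_scene_truth <- function(n = 48, spacing = 8, peak = 100) {
  make_contractile_traction(nx = n, ny = n, spacing = spacing,
                            r_inner = 25, r_outer = 55, peak = peak)
}

# Truth grid matched to a 512 px / 0.5 um-per-px field of view, annulus
# centred in frame.
scene_truth_fov256 <- function(peak = 100) {
  make_contractile_traction(nx = 64, ny = 64, spacing = 4,
                            r_inner = 25, r_outer = 55, peak = peak)
}

# Default-size scene matching live-imaging geometry (1024 px at 0.5 um/px).
render_default_scene <- function(seed = 11, E = 1000, poisson = TRUE,
                                 drift = NULL, peak = 100) {
  tt <- make_contractile_traction(nx = 64, ny = 64, spacing = 8,
                                  r_inner = 25, r_outer = 55, peak = peak)
  sc <- simulate_scene(tt, gel_properties(E, 0.5), pixel_size = 0.5,
                       image_size = c(1024, 1024), poisson_noise = poisson,
                       drift_per_frame = drift, seed = seed)
  rendered <- suppressMessages(render_bead_images(sc))
  list(truth = tt, scene = sc, rendered = rendered)
}

rel_l2 <- function(a, b) {
  sqrt(sum((a$tx - b$tx)^2 + (a$ty - b$ty)^2) / sum(b$tx^2 + b$ty^2))
}
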