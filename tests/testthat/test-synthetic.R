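# Forward simulator: traction patterns, elastic forward model, bead
# rendering, and the auxiliary generators (peak trains, trajectories,
# indentation curves, YAP images).

test_that("contractile traction is confined, balanced and symmetric", {
  tt <- make_contractile_traction(nx = 64, ny = 64, spacing = 4,
                                  r_inner = 20, r_outer = 40, peak = 100)
  # zero outside the annulus
  cx <- mean(range(tt$x)); cy <- mean(range(tt$y))
  r <- sqrt(outer((tt$y - cy)^2, (tt$x - cx)^2, `+`))
  expect_true(all(tt$magnitude[r <= 20 | r >= 40] == 0))
  # force balance against summed magnitude
  da <- tt$spacing^2
  nf <- net_force(tt)
  expect_lt(sqrt(sum(nf^2)), 1e-6 * sum(tt$magnitude) * da * 1e-3)
  # zero peak stress gives the zero field
  z <- make_contractile_traction(peak = 0)
  expect_true(all(z$magnitude == 0))
  # mirror-image annuli produce mirror-image fields: reflect about the
  # vertical midline, where tx flips sign and ty is preserved
  left <- make_contractile_traction(nx = 64, ny = 64, spacing = 4,
                                    center = c(80, 126), r_inner = 15,
                                    r_outer = 35, peak = 50)
  right <- make_contractile_traction(nx = 64, ny = 64, spacing = 4,
                                     center = c(max(left$x) - 80, 126),
                                     r_inner = 15, r_outer = 35, peak = 50)
  expect_equal(right$tx, -left$tx[, ncol(left$tx):1], tolerance = 1e-10)
  expect_equal(right$ty, left$ty[, ncol(left$ty):1], tolerance = 1e-10)
  expect_error(make_contractile_traction(nx = 2), "degenerate")
  expect_error(make_contractile_traction(r_inner = 50, r_outer = 40),
               "r_inner")
})

test_that("forward model matches the analytic single-mode kernel", {
  gel <- gel_properties(1000, 0.5)
  nx <- ny <- 32; h <- 4
  x <- (0:(nx - 1)) * h; y <- (0:(ny - 1)) * h
  kx <- 2 * pi * 3 / (nx * h); ky <- 2 * pi * 5 / (ny * h)
  phase <- outer(y * ky, x * kx, `+`)
  tf <- traction_field(x, y, cos(phase), 0 * phase)
  # pad = 1 keeps the single mode exactly periodic on the grid
  u <- forward_displacement(tf, gel, pad = 1)
  k2 <- kx^2 + ky^2; k <- sqrt(k2)
  pref <- 2 * (1 + 0.5) / (1000 * k^3)
  ux_true <- pref * ((1 - 0.5) * k2 + 0.5 * ky^2) * cos(phase)
  uy_true <- pref * (-0.5 * kx * ky) * cos(phase)
  expect_lt(max(abs(u$u - ux_true)) / max(abs(ux_true)), 1e-10)
  expect_lt(max(abs(u$v - uy_true)) / max(abs(uy_true)), 1e-10)
})

test_that("forward model is linear in traction and in compliance", {
  gel <- gel_properties(1000, 0.5)
  tt <- small_scene_truth()
  u1 <- forward_displacement(tt, gel)
  # zero traction -> zero displacement
  z <- traction_field(tt$x, tt$y, tt$tx * 0, tt$ty * 0)
  uz <- forward_displacement(z, gel)
  expect_true(all(uz$u == 0) && all(uz$v == 0))
  # doubling T doubles u
  t2 <- traction_field(tt$x, tt$y, 2 * tt$tx, 2 * tt$ty)
  u2 <- forward_displacement(t2, gel)
  expect_equal(u2$u, 2 * u1$u, tolerance = 1e-12)
  # doubling E halves u
  uE <- forward_displacement(tt, gel_properties(2000, 0.5))
  expect_equal(uE$u, u1$u / 2, tolerance = 1e-12)
  expect_error(gel_properties(-5), "youngs_modulus")
})

test_that("bead rendering respects displacement, units and determinism", {
  tt <- small_scene_truth()
  sc <- simulate_scene(tt, gel_properties(), pixel_size = 0.5,
                       image_size = c(256, 256), bead_density = 0.01,
                       seed = 7)
  # zero displacement, zero drift, zero noise: frames identical
  zf <- displacement_field(tt$x, tt$y, tt$tx * 0, tt$ty * 0)
  r0 <- render_bead_images(sc, displacement = zf)
  expect_identical(r0$reference, r0$frames[[1]])
  # uniform (1, 0) um at 0.5 um/px shifts every spot +2 px in x
  uf <- displacement_field(tt$x, tt$y, tt$tx * 0 + 1, tt$ty * 0)
  ru <- suppressMessages(render_bead_images(sc, displacement = uf))
  d <- estimate_drift(list(r0$reference, ru$frames[[1]]))
  expect_equal(d$dx_px[2], 2, tolerance = 0.05)
  expect_equal(d$dy_px[2], 0, tolerance = 0.05)
  # fixed seed renders byte-identical images
  r1 <- render_bead_images(sc, displacement = zf)
  expect_identical(r0$reference, r1$reference)
  expect_identical(r0$frames, r1$frames)
})

test_that("scene files round-trip through TIFF and sidecar", {
  tt <- small_scene_truth(n = 24)
  sc <- simulate_scene(tt, gel_properties(), pixel_size = 0.5,
                       image_size = c(128, 128), seed = 2)
  r <- suppressMessages(render_bead_images(sc))
  dir <- withr::local_tempdir()
  write_scene(sc, r, dir)
  back <- read_tiff_stack(file.path(dir, "reference.tif"))
  expect_equal(dim(back), dim(r$reference))
  # 16-bit quantization: counts agree to within one level
  expect_lte(max(abs(back - r$reference)), 1.0)
  side <- jsonlite::read_json(file.path(dir, "scene.json"))
  expect_equal(side$gel$youngs_modulus, 1000)
  expect_equal(side$seed, 2)
})

test_that("peak-train generator has the stated timing structure", {
  # zero jitter: successive peaks exactly one period apart
  s0 <- gen_peak_series(mean_period = 10, jitter_sd = 0,
                        sampling_interval = 1, duration = 200, seed = 1)
  expect_equal(unique(diff(s0$peak_times)), 10)
  # zero amplitude: pure ramp + baseline
  sa <- gen_peak_series(peak_amplitude = 0, baseline = 60,
                        ramp_duration = 60, sampling_interval = 1,
                        duration = 120, seed = 1)
  expect_equal(sa$values[sa$times >= 60], rep(60, sum(sa$times >= 60)))
  expect_equal(sa$values[sa$times < 60], 60 * sa$times[sa$times < 60] / 60)
  # law of large numbers on the generator's own draws
  sj <- gen_peak_series(mean_period = 10, jitter_sd = 1, n_peaks = 200,
                        sampling_interval = 1, seed = 5)
  iv <- diff(sj$peak_times)
  expect_lt(abs(mean(iv) - 10), 3 * sd(iv) / sqrt(length(iv)))
  expect_error(gen_peak_series(mean_period = -1), "mean_period")
})

test_that("trajectory generator spans stationary to ballistic regimes", {
  t0 <- gen_trajectory(speed = 0, n_steps = 20, seed = 1)
  expect_true(all(t0$x_um == 0) && all(t0$y_um == 0))
  m0 <- migration_stats(t0)
  expect_true(m0$stationary)
  expect_true(is.na(m0$directionality_ratio))
  # infinite persistence: straight line, directionality 1
  tb <- gen_trajectory(speed = 0.3, persistence_time = Inf, n_steps = 50,
                       seed = 2)
  expect_equal(migration_stats(tb)$directionality_ratio, 1, tolerance = 1e-12)
  # zero persistence: diffusive MSD exponent
  td <- gen_trajectory(speed = 0.3, persistence_time = 0, n_steps = 1000,
                       interval = 1, seed = 4)
  expect_gt(migration_stats(td)$msd_exponent, 0.9)
  expect_lt(migration_stats(td)$msd_exponent, 1.1)
})

test_that("indentation generator matches the Hertz closed form", {
  # F(delta_eff = 1 um; E = 1 kPa, nu = 0.5, R = 3 um)
  #   = (4/3) * (1000/0.75) * sqrt(3) * 1e-3 nN = 3.079 nN
  f_closed <- (4 / 3) * (1000 / (1 - 0.25)) * sqrt(3) * 1e-3
  cv <- gen_indentation_curve(E = 1000, nu = 0.5, R = 3, contact_offset = 0,
                              delta = c(0, 0.5, 1), noise_sd = 0)
  expect_equal(cv$force_nN[3], f_closed, tolerance = 1e-12)
  expect_equal(round(cv$force_nN[3], 2), 3.08)
  expect_equal(cv$force_nN[1], 0)
  # linear in E
  cv2 <- gen_indentation_curve(E = 2000, nu = 0.5, R = 3, contact_offset = 0,
                               delta = c(0, 0.5, 1), noise_sd = 0)
  expect_equal(cv2$force_nN, 2 * cv$force_nN, tolerance = 1e-12)
  expect_error(gen_indentation_curve(E = -1), "E must be > 0")
})

test_that("YAP image generator has computable analytic truth", {
  cm <- matrix(FALSE, 30, 30); cm[5:25, 5:25] <- TRUE
  nm <- matrix(FALSE, 30, 30); nm[12:18, 12:18] <- TRUE
  # equal intensities: ratio reduces to the area ratio
  g <- gen_yap_cell_image(80, 80, cm, nm)
  expect_equal(g$true_ratio, sum(nm) / (sum(cm) - sum(nm)))
  # noise-free measured ratio equals the analytic ratio
  meas <- yap_ratio(integrated_density(g$yap, cm),
                    integrated_density(g$yap, nm))
  expect_equal(meas$ratio, g$true_ratio, tolerance = 1e-12)
  # zero cytoplasmic intensity flagged degenerate
  gd <- gen_yap_cell_image(80, 0, cm, nm)
  expect_true(gd$degenerate)
  expect_identical(gd$true_ratio, Inf)
  # nucleus escaping the cell is rejected
  nm_bad <- nm; nm_bad[1, 1] <- TRUE
  expect_error(gen_yap_cell_image(80, 40, cm, nm_bad), "subset")
})
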