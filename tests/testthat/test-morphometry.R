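# Shape, interface, migration and adhesion-onset quantifications.

test_that("circularity matches closed forms for squares and disks", {
  sq <- matrix(FALSE, 260, 260); sq[31:230, 31:230] <- TRUE
  sm <- shape_metrics(sq, 1)
  expect_lt(abs(sm$circularity - pi / 4), 0.02)
  expect_equal(sm$area_um2, 200^2)
  dk <- disk_mask(260, 100, 130.5)
  dm <- shape_metrics(dk, 1)
  expect_gt(dm$circularity, 0.95)
  expect_lt(dm$circularity, 1.05)
  # scale invariance: doubling pixel_size scales area x4, circularity fixed
  sm2 <- shape_metrics(sq, 2)
  expect_equal(sm2$area_um2, 4 * sm$area_um2)
  expect_equal(sm2$circularity, sm$circularity, tolerance = 1e-12)
  expect_error(shape_metrics(matrix(FALSE, 10, 10)), "empty")
})

test_that("circularity is invariant to rigid motion within tolerance", {
  dk <- disk_mask(260, 80, 110.5)
  base <- shape_metrics(dk, 1)$circularity
  moved <- roll_matrix(dk, 25, 30)
  expect_lt(abs(shape_metrics(moved, 1)$circularity - base),
            0.02 * base)
})

test_that("largest component is measured when several are present", {
  m <- matrix(FALSE, 100, 100)
  m[10:60, 10:60] <- TRUE   # large square
  m[80:85, 80:85] <- TRUE   # small distractor
  expect_message(sm <- shape_metrics(m, 1), "largest")
  expect_equal(sm$area_um2, 51^2)
})

test_that("core-structure rule applies a strict 80-um threshold", {
  d85 <- disk_mask(120, 42.5, 60.5)
  expect_true(core_structure_test(d85, 1)$is_core)
  # pixel size chosen so the equivalent diameter is exactly 80 um:
  # strict inequality must reject it
  a_px <- sum(d85)
  ps_exact <- 80 / (2 * sqrt(a_px / pi))
  at80 <- core_structure_test(d85, ps_exact)
  expect_equal(at80$equivalent_diameter_um, 80, tolerance = 1e-12)
  expect_false(at80$is_core)
  expect_true(core_structure_test(d85, ps_exact * 1.001)$is_core)
  expect_error(core_structure_test(matrix(FALSE, 5, 5), 1), "empty")
})

test_that("interface geometry distinguishes straight from curved", {
  # straight interface: curvature 0, arc = chord, full width -> relative 1
  epi <- matrix(FALSE, 60, 60); pte <- matrix(FALSE, 60, 60)
  epi[10:30, 10:50] <- TRUE; pte[31:50, 10:50] <- TRUE
  im <- interface_metrics(epi, pte, 1)
  expect_equal(im$curvature_deg, 0)
  expect_equal(im$interface_arc_um, im$interface_chord_um)
  expect_equal(unname(im$relative_interface), 1, tolerance = 1e-12)
  # semicircular interface: subtended angle 180 degrees +/- 2
  n <- 200; epi2 <- matrix(FALSE, n, n); pte2 <- matrix(FALSE, n, n)
  R <- 60; cx <- 100
  for (i in 1:n) for (j in 1:n) {
    d2 <- (i - 100)^2 + (j - cx)^2
    if (i <= 100) {
      if (d2 <= R^2) epi2[i, j] <- TRUE
      else if (d2 <= (R + 4)^2) pte2[i, j] <- TRUE
    }
  }
  im2 <- interface_metrics(epi2, pte2, 1)
  expect_lt(abs(im2$curvature_deg - 180), 2)
  expect_gte(im2$interface_arc_um, im2$interface_chord_um)
  expect_error(interface_metrics(epi, epi, 1), "overlap")
  far <- matrix(FALSE, 60, 60); far[1:3, 1:3] <- TRUE
  expect_error(interface_metrics(epi, far, 1), "no boundary")
})

test_that("pixel-size scaling propagates through interface metrics", {
  epi <- matrix(FALSE, 60, 60); pte <- matrix(FALSE, 60, 60)
  epi[10:30, 10:50] <- TRUE; pte[31:50, 10:50] <- TRUE
  a <- interface_metrics(epi, pte, 1)
  b <- interface_metrics(epi, pte, 2)
  expect_equal(b$epi_area_um2, 4 * a$epi_area_um2)
  expect_equal(b$interface_chord_um, 2 * a$interface_chord_um)
  expect_equal(b$curvature_deg, a$curvature_deg)
})

test_that("migration statistics separate ballistic, diffusive, closed", {
  # straight constant-velocity track
  straight <- structure(data.frame(t_min = 0:20, x_um = 2 * (0:20),
                                   y_um = 0:20),
                        class = c("trajectory", "data.frame"))
  ms <- migration_stats(straight)
  expect_equal(ms$directionality_ratio, 1)
  expect_equal(ms$msd_exponent, 2, tolerance = 1e-6)
  expect_equal(ms$speed_um_min, sqrt(5), tolerance = 1e-12)
  # closed loop returns to start: directionality 0
  theta <- seq(0, 2 * pi, length.out = 21)
  loop <- structure(data.frame(t_min = 0:20, x_um = cos(theta),
                               y_um = sin(theta)),
                    class = c("trajectory", "data.frame"))
  expect_equal(migration_stats(loop)$directionality_ratio, 0,
               tolerance = 1e-12)
  # directionality always within [0, 1]
  for (s in 1:5) {
    tr <- gen_trajectory(speed = 0.4, persistence_time = 30, n_steps = 60,
                         seed = s)
    dr <- migration_stats(tr)$directionality_ratio
    expect_gte(dr, 0); expect_lte(dr, 1)
  }
  expect_error(migration_stats(straight[1:2, ]), ">= 3")
})

test_that("uncorrelated-walk MSD matches 4 D tau within 3 SEM over seeds", {
  # fixed step L each interval tau0 in a uniform random direction:
  # MSD(n tau0) = n L^2, i.e. 4 D tau with D = L^2 / (4 tau0)
  L <- 0.3 * 1; tau <- 5
  est <- vapply(1:20, function(s) {
    tr <- gen_trajectory(speed = 0.3, persistence_time = 0, n_steps = 400,
                         interval = 1, seed = s)
    ms <- migration_stats(tr)
    ms$msd[ms$msd$lag_min == tau, "msd_um2"]
  }, numeric(1))
  expect_lt(abs(mean(est) - 4 * (L^2 / 4) * tau),
            3 * sd(est) / sqrt(length(est)))
})

test_that("adhesion-onset breakpoint is recovered on bilinear series", {
  tt <- seq(20, 44, 2)
  area <- ifelse(tt < 32, 100 + 2 * (tt - 20), 124 + 10 * (tt - 32))
  circ <- ifelse(tt < 32, 0.9 - 0.002 * (tt - 20), 0.876 - 0.02 * (tt - 32))
  ai <- adhesion_inflection(tt, area, circ)
  expect_false(ai$collinear)
  expect_lte(abs(ai$breakpoint_time - 32), 2)
  # noise-free flat-then-ramp: breakpoint at the ramp start
  a2 <- ifelse(tt < 34, 100, 100 + 8 * (tt - 34))
  c2 <- ifelse(tt < 34, 0.9, 0.9 - 0.01 * (tt - 34))
  expect_lte(abs(adhesion_inflection(tt, a2, c2)$breakpoint_time - 34), 2)
  # a single straight line has no meaningful breakpoint
  expect_true(adhesion_inflection(tt, 2 * tt, 3 * tt)$collinear)
  expect_error(adhesion_inflection(tt[1:5], area[1:5], circ[1:5]),
               ">= 8")
})
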