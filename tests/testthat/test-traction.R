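# Regularized FTTC inversion, lambda selection, force metrics.

test_that("FTTC inverts the forward model on noise-free fields", {
  gel <- gel_properties(1000, 0.5)
  tt <- small_scene_truth()
  u <- forward_displacement(tt, gel)
  # zero displacement -> zero traction
  z <- displacement_field(u$x, u$y, u$u * 0, u$v * 0)
  expect_true(all(fttc_inverse(z, gel)$magnitude == 0))
  # round trip with lambda -> 0
  tr <- fttc_inverse(u, gel, lambda = 0)
  expect_lt(rel_l2(tr, tt), 0.05)
  # kernel linearity: doubling E doubles the reconstructed traction
  tr2 <- fttc_inverse(u, gel_properties(2000, 0.5), lambda = 0)
  expect_equal(tr2$tx, 2 * tr$tx, tolerance = 1e-10)
  expect_error(fttc_inverse(u, gel, lambda = -1), "lambda")
})

test_that("reconstructed fields stay force-balanced", {
  gel <- gel_properties(1000, 0.5)
  tt <- small_scene_truth()
  u <- forward_displacement(tt, gel)
  set.seed(2)
  un <- displacement_field(u$x, u$y,
                           u$u + matrix(rnorm(length(u$u), 0, 0.03),
                                        nrow(u$u)),
                           u$v + matrix(rnorm(length(u$v), 0, 0.03),
                                        nrow(u$v)))
  tr <- fttc_inverse(un, gel, lambda = 1e-3)
  nf <- net_force(tr)
  total <- sum(tr$magnitude) * tr$spacing^2 * 1e-3
  expect_lt(sqrt(sum(nf^2)), 0.05 * total)
})

test_that("forward-model residual is non-decreasing in lambda", {
  gel <- gel_properties(1000, 0.5)
  tt <- small_scene_truth()
  u <- forward_displacement(tt, gel)
  set.seed(3)
  un <- displacement_field(u$x, u$y,
                           u$u + matrix(rnorm(length(u$u), 0, 0.05),
                                        nrow(u$u)),
                           u$v)
  lams <- c(0, 10^seq(-6, -1, length.out = 8))
  resid <- vapply(lams, function(l) {
    uh <- forward_displacement(fttc_inverse(un, gel, lambda = l), gel)
    sqrt(mean((uh$u - un$u)^2 + (uh$v - un$v)^2))
  }, numeric(1))
  expect_true(all(diff(resid) >= -1e-12))
})

test_that("lambda selection strategies behave as designed", {
  gel <- gel_properties(1000, 0.5)
  expect_equal(select_lambda(NULL, gel, "fixed", lambda = 1e-3)$lambda, 1e-3)
  tt <- small_scene_truth()
  u <- forward_displacement(tt, gel)
  # L-curve pick is within 2x of the best candidate on its own sweep
  sl <- select_lambda(u, gel, "lcurve")
  errs <- vapply(sl$sweep$lambda, function(l)
    rel_l2(fttc_inverse(u, gel, lambda = l), tt), numeric(1))
  expect_lte(errs[sl$sweep$lambda == sl$lambda], 2 * min(errs))
  # noise-matched: a pure-noise field demands more regularization than a
  # high-signal field with the same noise level
  set.seed(4)
  n1 <- matrix(rnorm(length(u$u), 0, 0.05), nrow(u$u))
  n2 <- matrix(rnorm(length(u$u), 0, 0.05), nrow(u$u))
  pure <- displacement_field(u$x, u$y, n1, n2)
  sig <- displacement_field(u$x, u$y, u$u + n1, u$v + n2)
  border <- matrix(FALSE, nrow(u$u), ncol(u$u))
  border[c(1:5, (nrow(u$u) - 4):nrow(u$u)), ] <- TRUE
  l_pure <- select_lambda(pure, gel, "noise",
                          noise_region = matrix(TRUE, nrow(u$u),
                                                ncol(u$u)))$lambda
  l_sig <- select_lambda(sig, gel, "noise", noise_region = border)$lambda
  expect_gt(l_pure, l_sig)
  expect_error(select_lambda(sig, gel, "noise"), "noise_region")
})

test_that("wiener filter mode reconstructs comparably to tikhonov", {
  gel <- gel_properties(1000, 0.5)
  tt <- small_scene_truth()
  u <- forward_displacement(tt, gel)
  tw <- fttc_inverse(u, gel, lambda = 1e-3, filter_mode = "wiener")
  expect_lt(rel_l2(tw, tt), 0.2)
  expect_equal(tw$lambda, 1e-3)
})

test_that("force metrics integrate stress over the contact area", {
  x <- seq(0, 90, 10)   # 10 x 10 grid, 100 um^2 per node
  tx <- matrix(100, 10, 10)
  tr <- traction_field(x, x, tx, tx * 0)
  mask <- matrix(TRUE, 10, 10)
  m <- traction_metrics(tr, mask)
  # uniform 100 Pa over 10^4 um^2: 100 * 1e4 * 1e-3 nN = 1000 nN
  expect_equal(m$mean_Pa, 100)
  expect_equal(m$area_um2, 1e4)
  expect_equal(m$total_nN, 1000)
  expect_gte(m$max_Pa, m$mean_Pa)
  # single nonzero node: max = mean = that node
  t1 <- traction_field(x, x, matrix(0, 10, 10), matrix(0, 10, 10))
  t1$tx[5, 5] <- 30; t1$magnitude <- sqrt(t1$tx^2 + t1$ty^2)
  one <- matrix(FALSE, 10, 10); one[5, 5] <- TRUE
  m1 <- traction_metrics(t1, one)
  expect_equal(m1$max_Pa, 30); expect_equal(m1$mean_Pa, 30)
  expect_error(traction_metrics(tr, matrix(FALSE, 10, 10)), "empty")
})

test_that("ramping amplitude gives monotone per-frame max traction", {
  tt <- small_scene_truth()
  ramp <- gen_peak_series(peak_amplitude = 0, baseline = 1,
                          ramp_duration = 50, sampling_interval = 10,
                          duration = 50, seed = 1)
  mask <- tt$magnitude > 0
  maxs <- vapply(ramp$values, function(a) {
    tf <- traction_field(tt$x, tt$y, a * tt$tx, a * tt$ty)
    traction_metrics(tf, mask)$max_Pa
  }, numeric(1))
  expect_true(all(diff(maxs) > 0))
})

test_that("noise floor matches half-normal closed form and ignores embryo", {
  x <- seq(0, 99)
  set.seed(9)
  tx <- matrix(rnorm(10000), 100, 100)
  tr <- traction_field(x, x, tx, tx * 0)
  bg <- matrix(TRUE, 100, 100)
  # |T| half-normal with sigma = 1: mean + 2 SD = sqrt(2/pi) + 2 sqrt(1-2/pi)
  analytic <- sqrt(2 / pi) + 2 * sqrt(1 - 2 / pi)
  expect_lt(abs(noise_floor(tr, bg) - analytic) / analytic, 0.1)
  # zero-traction background
  tz <- traction_field(x, x, tx * 0, tx * 0)
  expect_equal(noise_floor(tz, bg), 0)
  # invariant to embryo-region values outside the background mask
  tr2 <- tr; tr2$tx[40:60, 40:60] <- 1e5
  tr2$magnitude <- sqrt(tr2$tx^2 + tr2$ty^2)
  bg2 <- bg; bg2[30:70, 30:70] <- FALSE
  base <- noise_floor(tr, bg2)
  expect_equal(noise_floor(tr2, bg2), base)
  expect_error(noise_floor(tr, matrix(FALSE, 100, 100)), "empty")
})
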