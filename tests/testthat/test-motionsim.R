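test_that("timeline starts stationary and follows the periodic pattern", {
  ms <- motion_schedule(Ts_in_EG = 2, EG = 3)
  tl <- build_timeline(ms, n_lines = 3 * (2 + 18 + 2 * 2) + 6)
  # initial Ts block
  expect_true(all(tl[1:6] == "original"))
  # then 9 EG leftward excursion (ramps counted at the displaced angle)
  expect_true(all(tl[7:(6 + 27)] == "rotated_left"))
  # rest Ts, then rightward excursion
  expect_true(all(tl[(6 + 27 + 1):(6 + 27 + 6)] == "original"))
  expect_true(all(tl[(6 + 33 + 1):(6 + 33 + 27)] == "rotated_right"))
})

test_that("timeline shorter than Ts stays entirely original", {
  ms <- motion_schedule(Ts_in_EG = 50, EG = 4)
  expect_true(all(build_timeline(ms, 100) == "original"))
})

test_that("corruption ratio closed form matches a 20-period label count", {
  for (Ts in c(9L, 18L, 36L, 72L)) {
    ms <- motion_schedule(Ts, EG = 2)
    period_eg <- 18L + 2L * Ts
    n <- 2L * (Ts + 20L * period_eg)          # >= 20 periods after the lead-in
    tl <- build_timeline(ms, n)
    periodic <- tl[(2L * Ts + 1L):(2L * (Ts + 20L * period_eg))]
    expect_equal(mean(periodic != "original"), corruption_ratio(ms))
  }
  expect_equal(corruption_ratio(motion_schedule(9)), 0.5)
  expect_equal(corruption_ratio(motion_schedule(18)), 1 / 3)
  expect_equal(corruption_ratio(motion_schedule(36)), 0.2)
  expect_equal(corruption_ratio(motion_schedule(72)), 18 / 162)
})

test_that("invalid schedules are rejected", {
  expect_error(motion_schedule(0), "Ts_in_EG")
  expect_error(build_timeline(motion_schedule(9), 0), "n_lines")
})

test_that("centric order walks outward from the center line", {
  expect_equal(centric_order(4), c(2L, 1L, 3L, 0L))
  expect_equal(centric_order(1), 0L)
  # first k lines of a centric order are the k most central lines
  n <- 256L
  ord <- centric_order(n)
  first80 <- sort(ord[1:80])
  ctr <- floor(n / 2)
  expect_equal(first80, sort(order(abs(0:(n - 1) - ctr))[1:80] - 1L))
  expect_setequal(ord, 0:(n - 1))
})

test_that("rotation is exact at angle zero and invertible within tolerance", {
  v <- tiny_phantom(seed = 11)
  expect_identical(rotate_volume(v, 0, "inplane"), v)
  smooth <- generate_phantom(phantom_spec(c(32, 32, 16), seed = 11,
                                          n_ellipsoids = 1))
  back <- rotate_volume(rotate_volume(smooth, 5, "inplane"), -5, "inplane")
  expect_lt(mean(abs(back - smooth)), 0.02)
  # centered phantom: mean intensity preserved within 2%
  r <- rotate_volume(v, 5, "inplane")
  expect_lt(abs(mean(r) - mean(v)) / mean(v), 0.02)
  expect_error(rotate_volume(v, 45, "inplane"), "30")
})

test_that("through-plane rotation mixes slices", {
  v <- tiny_phantom(seed = 12)
  r <- rotate_volume(v, 5, "throughplane")
  expect_false(identical(r, v))
  expect_equal(dim(r), dim(v))
})

test_that("zero-angle corruption is the identity up to rescale", {
  v <- tiny_phantom(seed = 13)
  ms <- motion_schedule(9, EG = 2, angle_inplane_deg = 0,
                        angle_throughplane_deg = 0)
  out <- corrupt(v, ms)
  expect_lt(max(abs(out$volume - rescale01(v))), 1e-8)
})

test_that("artifact severity is monotone in the corruption ratio", {
  v <- tiny_phantom(seed = 14)
  s <- vapply(c(9L, 18L, 72L), function(Ts) {
    ssim(corrupt(v, motion_schedule(Ts, EG = 2, angle_inplane_deg = 5))$volume, v)
  }, 0)
  expect_lt(s[1], s[2])
  expect_lt(s[2], s[3])
})

test_that("corrupted k-space energy stays finite and nonzero", {
  v <- tiny_phantom(seed = 15)
  out <- corrupt(v, motion_schedule(9, EG = 2, angle_throughplane_deg = 5))
  expect_true(all(is.finite(out$volume)))
  expect_gt(sum(out$volume^2), 0)
  expect_equal(out$ratio_periodic, 0.5)
  expect_gt(out$realized_corruption, 0.3)
})

test_that("per-slice timeline mode restarts at every slice", {
  v <- tiny_phantom(seed = 16, shape = c(16, 16, 8))
  ms <- motion_schedule(2, EG = 1, angle_inplane_deg = 5)
  a <- corrupt(v, ms, timeline = "continuous")
  b <- corrupt(v, ms, timeline = "per-slice")
  expect_false(identical(a$volume, b$volume))
})
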