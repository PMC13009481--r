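test_that("evidential moments follow the closed forms", {
  shp <- c(2, 2, 1)
  maps <- list(gamma = array(0.5, shp), v = array(1, shp),
               alpha = array(2, shp), beta = array(1, shp))
  mom <- evidential_moments(maps)
  expect_equal(mom$prediction, maps$gamma)
  expect_equal(mom$aleatoric, array(1, shp))
  expect_equal(mom$epistemic, array(1, shp))
  # v -> infinity: epistemic vanishes, aleatoric unchanged
  maps$v <- array(1e12, shp)
  mom2 <- evidential_moments(maps)
  expect_equal(mom2$aleatoric, mom$aleatoric)
  expect_lt(max(mom2$epistemic), 1e-11)
  maps$alpha <- array(1, shp)
  expect_error(evidential_moments(maps), "alpha")
})

test_that("epistemic times v equals aleatoric exactly", {
  set.seed(1)
  shp <- c(4, 4, 3)
  maps <- list(gamma = array(rnorm(48), shp),
               v = array(runif(48, 0.1, 5), shp),
               alpha = array(1 + runif(48, 0.1, 4), shp),
               beta = array(runif(48, 0.1, 5), shp))
  mom <- evidential_moments(maps)
  expect_equal(mom$epistemic * maps$v, mom$aleatoric)
})

test_that("moments agree with a Normal-Inverse-Gamma sampling oracle", {
  set.seed(2)
  n <- 2e5
  for (i in 1:5) {
    g <- runif(1, -1, 1); v <- runif(1, 0.5, 3)
    a <- runif(1, 2.5, 5); b <- runif(1, 0.5, 3)
    sig2 <- 1 / rgamma(n, shape = a, rate = b)
    mu <- rnorm(n, g, sqrt(sig2 / v))
    mom <- evidential_moments(list(gamma = array(g, c(1, 1, 1)),
                                   v = array(v, c(1, 1, 1)),
                                   alpha = array(a, c(1, 1, 1)),
                                   beta = array(b, c(1, 1, 1))))
    # E[sigma^2] has variance only for alpha > 2; use generous 3 SE bounds
    se_al <- stats::sd(sig2) / sqrt(n)
    se_ep <- stats::sd((mu - g)^2) / sqrt(n)
    expect_lt(abs(mean(sig2) - mom$aleatoric[1]), 3 * se_al)
    expect_lt(abs(stats::var(mu) - mom$epistemic[1]), 3 * se_ep)
  }
})

test_that("slice means summarize per-slice uncertainty", {
  u <- array(0.2, c(4, 4, 3))
  expect_equal(slice_mean(u), rep(0.2, 3))
  u[2, 3, 2] <- 1
  sm <- slice_mean(u)
  expect_gt(sm[2], sm[1])
  expect_equal(sm[1], sm[3])
  expect_equal(slice_mean(u[, , c(3, 1, 2)]), sm[c(3, 1, 2)])
})

test_that("noiseless calibrations are recovered exactly", {
  set.seed(3)
  u <- runif(50, 0.02, 0.3)
  fl <- fit_calibration(u, -2 * u + 1, "linear_ssim")
  expect_equal(unname(fl$coefficients["a"]), -2, tolerance = 1e-8)
  expect_equal(unname(fl$coefficients["b"]), 1, tolerance = 1e-8)
  expect_equal(fl$r_squared, 1)
  fe <- fit_calibration(u, 30 * exp(-8 * u) + 10, "exp_psnr")
  expect_equal(unname(fe$coefficients["c"]), 30, tolerance = 1e-6)
  expect_equal(unname(fe$coefficients["d"]), -8, tolerance = 1e-6)
  expect_equal(unname(fe$coefficients["e"]), 10, tolerance = 1e-5)
  expect_error(fit_calibration(u[1:5], u[1:5], "linear_ssim"), "10")
  expect_error(fit_calibration(rep(0.1, 50), -2 * rep(0.1, 50) + 1,
                               "linear_ssim"), "degenerate")
})

test_that("prediction intervals are narrowest at the predictor mean", {
  set.seed(4)
  u <- runif(100, 0.02, 0.3)
  y <- -2 * u + 1 + rnorm(100, sd = 0.01)
  fl <- fit_calibration(u, y, "linear_ssim")
  p <- predict_quality(fl, c(mean(u), max(u)))
  expect_lt(p$upr[1] - p$lwr[1], p$upr[2] - p$lwr[2])
  # refit on own predictions reproduces the point estimates
  p0 <- predict_quality(fl, u)
  fl2 <- fit_calibration(u, p0$fit, "linear_ssim")
  expect_equal(predict_quality(fl2, u)$fit, p0$fit, tolerance = 1e-10)
  expect_warning(predict_quality(fl, 2), "extrapolat")
})

test_that("prediction-interval coverage is near nominal on held-out data", {
  set.seed(5)
  n <- 200
  u <- runif(n, 0.02, 0.3)
  y <- -1.5 * u + 0.98 + rnorm(n, sd = 0.008)
  fl <- fit_calibration(u, y, "linear_ssim")
  u2 <- runif(160, 0.02, 0.3)
  y2 <- -1.5 * u2 + 0.98 + rnorm(160, sd = 0.008)
  p <- predict_quality(fl, u2)
  cov_lin <- mean(y2 >= p$lwr & y2 <= p$upr)
  expect_gte(cov_lin, 0.9)
  ye <- 25 * exp(-9 * u) + 12 + rnorm(n, sd = 0.25)
  fe <- fit_calibration(u, ye, "exp_psnr")
  y2e <- 25 * exp(-9 * u2) + 12 + rnorm(160, sd = 0.25)
  pe <- predict_quality(fe, u2)
  cov_exp <- mean(y2e >= pe$lwr & y2e <= pe$upr)
  expect_gte(cov_exp, 0.9)
})

test_that("calibration serializes to JSON and back", {
  set.seed(6)
  u <- runif(30, 0.05, 0.2)
  fl <- fit_calibration(u, -2 * u + 1 + rnorm(30, sd = 0.005), "linear_ssim")
  path <- tempfile(fileext = ".json")
  write_calibration(fl, path)
  j <- jsonlite::read_json(path)
  expect_equal(j$kind, "linear_ssim")
  expect_equal(j$coefficients$a, unname(fl$coefficients["a"]))
  expect_equal(j$n, 30)
  unlink(path)
})
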