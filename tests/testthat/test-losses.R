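test_that("Charbonnier has the printed lower bound and L1 asymptote", {
  a <- tiny_phantom(seed = 1, shape = c(8, 8, 8))
  expect_equal(charbonnier(a, a), 1e-2)
  one <- array(0.1, c(1, 1, 1)); zero <- array(0, c(1, 1, 1))
  expect_equal(charbonnier(one, zero), sqrt(0.01 + 1e-4))
  big <- array(50, c(1, 1, 1))
  expect_equal(charbonnier(big, zero) / 50, 1, tolerance = 1e-7)
  expect_error(charbonnier(a, a[, , 1:2]), "mismatch")
  # lower bound sqrt(eps) with equality iff identical
  b <- a; b[1] <- b[1] + 0.3
  expect_gt(charbonnier(b, a), 1e-2)
})

test_that("Charbonnier gradient matches finite differences", {
  set.seed(2)
  a <- array(runif(27), c(3, 3, 3)); b <- array(runif(27), c(3, 3, 3))
  g <- charbonnier(a, b, grad = TRUE)
  eps <- 1e-7
  a2 <- a; a2[5] <- a2[5] + eps
  expect_equal(g$grad[5], (charbonnier(a2, b) - g$value) / eps,
               tolerance = 1e-5)
})

test_that("squared-SSIM loss is zero at identity and near one for noise", {
  a <- tiny_phantom(seed = 3, shape = c(24, 24, 4))
  expect_equal(ssim_loss(a, a), 0)
  # SSIM = 0.9 would give 1 - 0.81 = 0.19: check the square via the map
  set.seed(3)
  noise <- array(runif(24 * 24 * 4), dim(a))
  expect_gt(ssim_loss(noise, a), 0.8)
  s <- ssim(a[, , 1], noise[, , 1])
  expect_equal(ssim_loss(a[, , 1], noise[, , 1]), 1 - s^2)
})

test_that("squared-SSIM loss gradient matches finite differences", {
  set.seed(4)
  a <- matrix(runif(18 * 18), 18); b <- matrix(runif(18 * 18), 18)
  g <- ssim_loss(a, b, grad = TRUE)
  eps <- 1e-6
  for (i in c(1L, 60L, 170L)) {
    a2 <- a; a2[i] <- a2[i] + eps
    expect_equal(g$grad[i], (ssim_loss(a2, b) - g$value) / eps,
                 tolerance = 1e-4)
  }
})

test_that("NIG loss matches the Student-t predictive oracle", {
  # the NIG marginal likelihood is Student-t with df = 2 alpha, location
  # gamma and scale^2 = beta (1 + v) / (v alpha); an independent route to
  # the same negative log-likelihood
  set.seed(5)
  n <- 1000
  y <- runif(n, -2, 2); g <- runif(n, -2, 2)
  v <- runif(n, 0.05, 5); a <- 1 + runif(n, 0.05, 4); b <- runif(n, 0.05, 5)
  one <- function(i) {
    nig_loss(array(y[i], c(1, 1, 1)), array(g[i], c(1, 1, 1)),
             array(v[i], c(1, 1, 1)), array(a[i], c(1, 1, 1)),
             array(b[i], c(1, 1, 1)), lambda_reg = 0)
  }
  ours <- vapply(seq_len(n), one, 0)
  s <- sqrt(b * (1 + v) / (v * a))
  oracle <- -log(stats::dt((y - g) / s, df = 2 * a) / s)
  expect_lt(max(abs(ours - oracle) / pmax(abs(oracle), 1)), 1e-10)
})

test_that("NIG regularizer and Omega follow their closed forms", {
  shp <- c(2, 2, 1)
  y <- array(0.5, shp)
  # y = gamma: regularizer exactly zero, so lambda does not matter
  l0 <- nig_loss(y, y, array(1, shp), array(2, shp), array(1, shp),
                 lambda_reg = 0)
  l1 <- nig_loss(y, y, array(1, shp), array(2, shp), array(1, shp),
                 lambda_reg = 100)
  expect_equal(l0, l1)
  # beta = 1, v = 1 -> Omega = 4: NLL reduces to the explicit expression
  a <- 2
  expl <- 0.5 * log(pi) - a * log(4) + (a + 0.5) * log(4) +
    lgamma(a) - lgamma(a + 0.5)
  expect_equal(l0, expl)
  expect_error(nig_loss(y, y, array(-1, shp), array(2, shp), array(1, shp)),
               "constraints")
  expect_error(nig_loss(y, y, array(1, shp), array(0.5, shp), array(1, shp)),
               "constraints")
})

test_that("NIG NLL is stationary in gamma at y = gamma", {
  shp <- c(1, 1, 1)
  f <- function(g) nig_loss(array(0.3, shp), array(g, shp), array(1.3, shp),
                            array(2.1, shp), array(0.7, shp), lambda_reg = 0)
  eps <- 1e-6
  expect_lt(abs((f(0.3 + eps) - f(0.3 - eps)) / (2 * eps)), 1e-6)
})

test_that("NIG gradients match finite differences", {
  set.seed(6)
  shp <- c(2, 2, 1)
  y <- array(runif(4), shp); g <- array(runif(4), shp)
  v <- array(runif(4) + 0.3, shp); a <- array(runif(4) + 1.2, shp)
  b <- array(runif(4) + 0.3, shp)
  gr <- nig_loss(y, g, v, a, b, lambda_reg = 0.05, grad = TRUE)
  eps <- 1e-7
  for (nm in c("gamma", "v", "alpha", "beta")) {
    args <- list(gamma = g, v = v, alpha = a, beta = b)
    args[[nm]][3] <- args[[nm]][3] + eps
    num <- (nig_loss(y, args$gamma, args$v, args$alpha, args$beta,
                     lambda_reg = 0.05) - gr$value) / eps
    expect_equal(gr$grad[[nm]][3], num, tolerance = 1e-4)
  }
})

test_that("combined loss assembles its components with the default weights", {
  a <- tiny_phantom(seed = 7, shape = c(16, 16, 2))
  b <- clamp01(a + array(rnorm(length(a), sd = 0.05), dim(a)))
  w <- loss_weights()
  expect_equal(w$w1, 0.5)
  expect_equal(w$w2, 1)
  # identical images, no evidential: sqrt(eps) + 0
  expect_equal(combined_loss(a, a, weights = w), 1e-2)
  # w1 = 0: Charbonnier alone
  expect_equal(combined_loss(b, a, weights = loss_weights(w1 = 0)),
               charbonnier(b, a))
  expect_equal(combined_loss(b, a, weights = w),
               charbonnier(b, a) + 0.5 * ssim_loss(b, a))
  # evidential: hand-assembled weighted sum on a toy tensor
  ev <- list(gamma = b, v = array(1, dim(a)), alpha = array(2, dim(a)),
             beta = array(1, dim(a)))
  expect_equal(combined_loss(NULL, a, evidential = ev, weights = w),
               charbonnier(b, a) + 0.5 * ssim_loss(b, a) +
                 nig_loss(a, b, ev$v, ev$alpha, ev$beta, lambda_reg = w$lambda_reg))
})
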