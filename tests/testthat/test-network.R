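test_that("output channel and size contracts hold", {
  m_srr <- build_network(network_config(M = 3, s_sl = 2, n_rg = 1, n_rcab = 1,
                                        n_feat = 8, reduction = 4))
  x <- array(runif(16 * 16 * 3), c(16, 16, 3))
  expect_equal(dim(forward_network(m_srr, x)$out), c(16L, 16L, 6L))
  m_mar <- build_network(tiny_net_cfg(M = 1))
  y <- array(runif(12 * 12), c(12, 12, 1))
  expect_equal(dim(forward_network(m_mar, y)$out), c(12L, 12L, 1L))
  m_up <- build_network(tiny_net_cfg(M = 1, inplane_scale = 2))
  expect_equal(dim(forward_network(m_up, y)$out), c(24L, 24L, 1L))
  m_up4 <- build_network(tiny_net_cfg(M = 1, inplane_scale = 4))
  expect_equal(dim(forward_network(m_up4, y)$out), c(48L, 48L, 1L))
  # fully convolutional: doubling the input doubles the output
  y2 <- array(runif(24 * 24), c(24, 24, 1))
  expect_equal(dim(forward_network(m_up, y2)$out), c(48L, 48L, 1L))
  expect_error(forward_network(m_srr, y), "channels")
  expect_error(network_config(n_feat = 10, reduction = 4), "divisible")
})

test_that("evidential head emits 4 constrained maps per output slice", {
  cfg <- network_config(M = 1, s_sl = 2, evidential = TRUE, n_rg = 1,
                        n_rcab = 1, n_feat = 8, reduction = 4)
  m <- build_network(cfg)
  x <- array(runif(12 * 12), c(12, 12, 1))
  f <- forward_network(m, x)
  expect_equal(dim(f$out)[3], 8L)            # 4 maps x N = 2 slices
  expect_equal(dim(f$maps$gamma)[3], 2L)
  # constraints hold across random weights and inputs
  for (i in 1:100) {
    mi <- build_network(network_config(M = 1, s_sl = 1, evidential = TRUE,
                                       n_rg = 1, n_rcab = 1, n_feat = 4,
                                       reduction = 2, seed = i))
    fi <- forward_network(mi, array(runif(8 * 8, -1, 2), c(8, 8, 1)))
    expect_true(all(fi$maps$v > 0))
    expect_true(all(fi$maps$alpha > 1))
    expect_true(all(fi$maps$beta > 0))
  }
})

test_that("parameter count matches a hand-derived formula", {
  count_formula <- function(M, N, F, red, n_rg, n_rcab, n_up, evidential) {
    conv <- function(cin, cout) 9 * cin * cout + cout
    ca <- function() (F * (F / red) + F / red) + ((F / red) * F + F)
    rcab <- 2 * conv(F, F) + ca()
    rg <- n_rcab * rcab + conv(F, F)
    out_ch <- if (evidential) 4 * N else N
    conv(M, F) + n_rg * rg + conv(F, F) + n_up * conv(F, 4 * F) +
      conv(F, out_ch)
  }
  cfg1 <- network_config(M = 3, s_sl = 2, n_rg = 1, n_rcab = 1, n_feat = 8,
                         reduction = 4)
  expect_equal(n_params(cfg1),
               count_formula(3, 6, 8, 4, 1, 1, 0, FALSE))
  cfg2 <- network_config(M = 1, s_sl = 1, inplane_scale = 4, n_rg = 2,
                         n_rcab = 3, n_feat = 16, reduction = 8,
                         evidential = TRUE)
  expect_equal(n_params(cfg2),
               count_formula(1, 1, 16, 8, 2, 3, 2, TRUE))
})

test_that("channel-attention gates lie strictly in (0, 1)", {
  m <- build_network(tiny_net_cfg(M = 1, seed = 3))
  x <- array(runif(16 * 16), c(16, 16, 1))
  f <- forward_network(m, x, cache = TRUE)
  a <- f$cache$groups[[1]]$blocks[[1]]$ca$a
  expect_true(all(a > 0 & a < 1))
})

test_that("backpropagation matches finite differences", {
  set.seed(10)
  cfg <- network_config(M = 2, N = 2, s_sl = 1, inplane_scale = 2, n_rg = 1,
                        n_rcab = 1, n_feat = 8, reduction = 4, seed = 10)
  m <- build_network(cfg)
  x <- array(runif(10 * 10 * 2), c(10, 10, 2))
  f <- forward_network(m, x, cache = TRUE)
  R <- array(rnorm(length(f$out)), dim(f$out))
  loss0 <- sum(f$out * R)
  g <- mrislab:::backward_network(m, f$cache, R)
  eps <- 1e-6
  probe <- function(path, k = 1L) {
    m2 <- m
    leaf <- m2$weights
    for (p in path) leaf <- leaf[[p]]
    leaf[k] <- leaf[k] + eps
    expr <- paste0("m2$weights",
                   paste0(vapply(path, function(p)
                     if (is.character(p)) sprintf('[["%s"]]', p)
                     else sprintf("[[%d]]", p), ""), collapse = ""))
    eval(parse(text = paste0(expr, " <- leaf")))
    num <- (sum(forward_network(m2, x)$out * R) - loss0) / eps
    ga <- g
    for (p in path) ga <- ga[[p]]
    expect_equal(ga[k], num, tolerance = 1e-4)
  }
  probe(list("head", "W"), 5L)
  probe(list("head", "b"), 1L)
  probe(list("groups", 1L, "blocks", 1L, "conv1", "W"), 11L)
  probe(list("groups", 1L, "blocks", 1L, "conv2", "b"), 2L)
  probe(list("groups", 1L, "blocks", 1L, "ca", "W2"), 3L)
  probe(list("groups", 1L, "tail", "W"), 20L)
  probe(list("body_tail", "W"), 7L)
  probe(list("upsample", 1L, "W"), 13L)
  probe(list("final", "W"), 2L)
})

test_that("pixel shuffle is invertible and rearranges channels spatially", {
  x <- array(seq_len(6 * 5 * 8), c(6, 5, 8))
  y <- mrislab:::pixel_shuffle(x, 2L)
  expect_equal(dim(y), c(12L, 10L, 2L))
  expect_equal(mrislab:::pixel_shuffle_bw(y, 2L), x)
})
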