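#' Configuration of the thin-slab restoration network
#'
#' A 2D residual channel-attention backbone whose input channels carry the
#' `M` slices of a thin slab and whose output channels carry the `N`
#' restored slices (`N = M * s_sl` for through-plane super-resolution,
#' `N = M` for motion artifact reduction). Structure: shallow 3x3 conv
#' (`M -> n_feat`), `n_rg` residual groups of `n_rcab` residual
#' channel-attention blocks each (plus a group tail conv and skip), a body
#' tail conv with a global skip from the shallow features, an optional
#' sub-pixel (pixel-shuffle) in-plane upsampler, and a final conv to `N`
#' output maps — or `4 N` when the evidential head is enabled (gamma, v,
#' alpha, beta per output slice, constrained by softplus links).
#'
#' @param M Input slab slices (channels).
#' @param N Output slices; defaults to `M * s_sl`.
#' @param s_sl Through-plane scale carried by the channel dimension.
#' @param inplane_scale In-plane upsampling factor (1, 2 or 4).
#' @param n_rg Residual groups (default 5).
#' @param n_rcab Blocks per group (default 5).
#' @param n_feat Feature channels (default 64).
#' @param reduction Channel-attention bottleneck ratio (default 16; must
#'   divide `n_feat`).
#' @param evidential Enable the evidential output head.
#' @param seed Seed for weight initialization.
#' @return An object of class `network_config`.
#' @export
network_config <- function(M = 1L, N = NULL, s_sl = 1L, inplane_scale = 1L,
                           n_rg = 5L, n_rcab = 5L, n_feat = 64L,
                           reduction = 16L, evidential = FALSE, seed = 1L) {
  if (!inplane_scale %in% c(1L, 2L, 4L))
    stop("inplane_scale must be 1, 2 or 4", call. = FALSE)
  if (n_feat %% reduction != 0L)
    stop("n_feat (", n_feat, ") must be divisible by reduction (", reduction,
         ")", call. = FALSE)
  if (is.null(N)) N <- M * s_sl
  structure(list(M = as.integer(M), N = as.integer(N), s_sl = as.integer(s_sl),
                 inplane_scale = as.integer(inplane_scale),
                 n_rg = as.integer(n_rg), n_rcab = as.integer(n_rcab),
                 n_feat = as.integer(n_feat), reduction = as.integer(reduction),
                 evidential = isTRUE(evidential), seed = as.integer(seed)),
            class = "network_config")
}

conv_init <- function(cin, cout, gain = 2) {
  W <- array(stats::rnorm(9 * cin * cout, sd = sqrt(gain / (9 * cin))),
             c(3L, 3L, cin, cout))
  list(W = W, b = numeric(cout))
}

dense_init <- function(cin, cout) {
  list(W = matrix(stats::rnorm(cin * cout, sd = sqrt(2 / cin)), cout, cin),
       b = numeric(cout))
}

#' Build a thin-slab restoration network
#'
#' Initializes all weights (He initialization, deterministic from the config
#' seed) and returns the model object consumed by [forward_network()],
#' [train_network()] and [infer()].
#'
#' @param cfg A [network_config()].
#' @return An object of class `restoration_model`.
#' @export
build_network <- function(cfg) {
  stopifnot(inherits(cfg, "network_config"))
  F <- cfg$n_feat; Cr <- F %/% cfg$reduction
  out_ch <- if (cfg$evidential) 4L * cfg$N else cfg$N
  n_up <- switch(as.character(cfg$inplane_scale), "1" = 0L, "2" = 1L, "4" = 2L)
  w <- with_seed(cfg$seed, {
    ca_init <- function() {
      d1 <- dense_init(F, Cr); d2 <- dense_init(Cr, F)
      list(W1 = d1$W, b1 = d1$b, W2 = d2$W, b2 = d2$b)
    }
    list(
      head = conv_init(cfg$M, F),
      groups = lapply(seq_len(cfg$n_rg), function(g) {
        list(blocks = lapply(seq_len(cfg$n_rcab), function(b) {
          list(conv1 = conv_init(F, F), conv2 = conv_init(F, F), ca = ca_init())
        }),
        tail = conv_init(F, F))
      }),
      body_tail = conv_init(F, F),
      upsample = lapply(seq_len(n_up), function(u) conv_init(F, 4L * F)),
      final = conv_init(F, out_ch)
    )
  })
  structure(list(cfg = cfg, weights = w), class = "restoration_model")
}

#' Number of trainable parameters
#'
#' @param model A `restoration_model` or [network_config()].
#' @return Integer parameter count.
#' @export
n_params <- function(model) {
  if (inherits(model, "network_config")) model <- build_network(model)
  sum(unlist(rapply(model$weights, length, how = "list")))
}

#' Forward pass of the restoration network
#'
#' Maps one `(H, W, M)` thin-slab input to the restored `(H', W', N)` output
#' slab (`H' = H * inplane_scale`). For evidential models the result also
#' carries the constrained parameter maps under `maps` (the `gamma` map is
#' the restored image). With `cache = TRUE` the returned object keeps every
#' layer input needed by the internal backward pass.
#'
#' @param model A [build_network()] model.
#' @param x Numeric `(H, W, M)` array.
#' @param cache Keep intermediates for backpropagation.
#' @return List with `out` (raw output maps), optional `maps`, and `cache`.
#' @export
forward_network <- function(model, x, cache = FALSE) {
  cfg <- model$cfg; w <- model$weights
  if (dim(x)[3] != cfg$M)
    stop("input slab has ", dim(x)[3], " channels; model expects ", cfg$M,
         call. = FALSE)
  cc <- if (cache) list(x = x) else NULL
  f0 <- conv_fw(x, w$head$W, w$head$b)
  f <- f0
  gcache <- if (cache) vector("list", length(w$groups)) else NULL
  for (g in seq_along(w$groups)) {
    grp <- w$groups[[g]]
    g_in <- f
    bcache <- if (cache) vector("list", length(grp$blocks)) else NULL
    for (b in seq_along(grp$blocks)) {
      blk <- grp$blocks[[b]]
      t1 <- conv_fw(f, blk$conv1$W, blk$conv1$b)
      r1 <- relu(t1)
      t2 <- conv_fw(r1, blk$conv2$W, blk$conv2$b)
      ca <- ca_fw(t2, blk$ca)
      if (cache) bcache[[b]] <- list(x = f, t1 = t1, r1 = r1, t2 = t2, ca = ca)
      f <- f + ca$out
    }
    tail_in <- f
    f <- g_in + conv_fw(f, grp$tail$W, grp$tail$b)
    if (cache) gcache[[g]] <- list(blocks = bcache, tail_in = tail_in)
  }
  bt_in <- f
  f <- f0 + conv_fw(f, w$body_tail$W, w$body_tail$b)
  ucache <- if (cache) vector("list", length(w$upsample)) else NULL
  for (u in seq_along(w$upsample)) {
    u_in <- f
    f <- pixel_shuffle(conv_fw(f, w$upsample[[u]]$W, w$upsample[[u]]$b), 2L)
    if (cache) ucache[[u]] <- list(x = u_in)
  }
  fin_in <- f
  out <- conv_fw(f, w$final$W, w$final$b)
  if (cache)
    cc <- c(cc, list(groups = gcache, bt_in = bt_in, up = ucache,
                     fin_in = fin_in))
  res <- list(out = out, cache = cc)
  if (cfg$evidential) res$maps <- split_evidential(out, cfg$N)
  res
}

# Split the 4N raw output maps into constrained evidential parameters.
split_evidential <- function(out, N) {
  g <- out[, , 1:N, drop = FALSE]
  rv <- out[, , (N + 1):(2 * N), drop = FALSE]
  ra <- out[, , (2 * N + 1):(3 * N), drop = FALSE]
  rb <- out[, , (3 * N + 1):(4 * N), drop = FALSE]
  list(gamma = g, v = softplus(rv), alpha = 1 + softplus(ra),
       beta = softplus(rb), raw_v = rv, raw_a = ra, raw_b = rb)
}

# Backward pass: dOut has the shape of the raw network output. Returns
# gradients with the same nested structure as model$weights.
backward_network <- function(model, cc, dOut) {
  w <- model$weights
  gr <- list()
  bw <- conv_bw(cc$fin_in, w$final$W, dOut)
  gr$final <- list(W = bw$dW, b = bw$db)
  df <- bw$dX
  gr$upsample <- vector("list", length(w$upsample))
  for (u in rev(seq_along(w$upsample))) {
    dconv <- pixel_shuffle_bw(df, 2L)
    bw <- conv_bw(cc$up[[u]]$x, w$upsample[[u]]$W, dconv)
    gr$upsample[[u]] <- list(W = bw$dW, b = bw$db)
    df <- bw$dX
  }
  df0 <- df                                   # global skip into shallow feats
  bw <- conv_bw(cc$bt_in, w$body_tail$W, df)
  gr$body_tail <- list(W = bw$dW, b = bw$db)
  df <- bw$dX
  gr$groups <- vector("list", length(w$groups))
  for (g in rev(seq_along(w$groups))) {
    grp <- w$groups[[g]]; gc <- cc$groups[[g]]
    dg_skip <- df                              # group skip
    bw <- conv_bw(gc$tail_in, grp$tail$W, df)
    gtail <- list(W = bw$dW, b = bw$db)
    df <- bw$dX
    gblocks <- vector("list", length(grp$blocks))
    for (b in rev(seq_along(grp$blocks))) {
      blk <- grp$blocks[[b]]; bc <- gc$blocks[[b]]
      d_res <- df                              # block skip
      cab <- ca_bw(bc$t2, blk$ca, bc$ca, df)
      bw2 <- conv_bw(bc$r1, blk$conv2$W, cab$dX)
      dr1 <- bw2$dX * (bc$t1 > 0)
      bw1 <- conv_bw(bc$x, blk$conv1$W, dr1)
      gblocks[[b]] <- list(conv1 = list(W = bw1$dW, b = bw1$db),
                           conv2 = list(W = bw2$dW, b = bw2$db),
                           ca = list(W1 = cab$dW1, b1 = cab$db1,
                                     W2 = cab$dW2, b2 = cab$db2))
      df <- d_res + bw1$dX
    }
    gr$groups[[g]] <- list(blocks = gblocks, tail = gtail)
    df <- df + dg_skip
  }
  df0 <- df0 + df                              # shallow features gradient
  bw <- conv_bw(cc$x, w$head$W, df0)
  gr$head <- list(W = bw$dW, b = bw$db)
  # order must mirror model$weights: tree_map2 pairs leaves by position
  gr[names(w)]
}

# --- nested parameter-tree helpers -----------------------------------------

tree_map <- function(f, a) {
  if (is.list(a)) return(lapply(a, function(x) tree_map(f, x)))
  f(a)
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) return(mapply(function(x, y) tree_map2(f, x, y), a, b,
                                SIMPLIFY = FALSE))
  f(a, b)
}

tree_map3 <- function(f, a, b, c) {
  if (is.list(a)) return(mapply(function(x, y, z) tree_map3(f, x, y, z),
                                a, b, c, SIMPLIFY = FALSE))
  f(a, b, c)
}

#' @export
print.restoration_model <- function(x, ...) {
  cfg <- x$cfg
  cat("thin-slab restoration network\n")
  cat(sprintf("  slab: M=%d -> N=%d, in-plane x%d%s\n", cfg$M, cfg$N,
              cfg$inplane_scale,
              if (cfg$evidential) ", evidential head" else ""))
  cat(sprintf("  %d residual groups x %d blocks, %d features (reduction %d)\n",
              cfg$n_rg, cfg$n_rcab, cfg$n_feat, cfg$reduction))
  cat(sprintf("  parameters: %d\n", n_params(x)))
  invisible(x)
}
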