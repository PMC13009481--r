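#' Training configuration
#'
#' Defaults mirror the reference training protocol: 50 epochs, batches of 8
#' randomly drawn patches, Adam (`beta1 = 0.9`, `beta2 = 0.999`,
#' `eps = 1e-8`) and a cosine-decay learning rate from 1e-4 to 1e-8.
#'
#' @param task `"srr"` or `"mar"`.
#' @param epochs Training epochs (default 50).
#' @param batch Patches per batch (default 8).
#' @param lr_max,lr_min Cosine schedule endpoints (defaults 1e-4, 1e-8).
#' @param steps Optional hard cap on total optimization steps (useful for
#'   scaled-down runs); `NULL` trains `epochs` full epochs.
#' @param weights A [loss_weights()].
#' @param seed Seed controlling batch order.
#' @return An object of class `train_config`.
#' @export
train_config <- function(task = c("srr", "mar"), epochs = 50L, batch = 8L,
                         lr_max = 1e-4, lr_min = 1e-8, steps = NULL,
                         weights = loss_weights(), seed = 1L) {
  task <- match.arg(task)
  structure(list(task = task, epochs = as.integer(epochs),
                 batch = as.integer(batch), lr_max = lr_max, lr_min = lr_min,
                 steps = if (is.null(steps)) NULL else as.integer(steps),
                 beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                 weights = weights, seed = as.integer(seed)),
            class = "train_config")
}

#' Cosine-decay learning rate
#'
#' @param step 0-based step index.
#' @param total Total number of steps.
#' @param lr_max,lr_min Schedule endpoints.
#' @return Learning rate at `step` (equals `lr_max` at step 0 and `lr_min`
#'   at the final step).
#' @export
cosine_lr <- function(step, total, lr_max = 1e-4, lr_min = 1e-8) {
  if (total <= 1) return(lr_max)
  lr_min + 0.5 * (lr_max - lr_min) * (1 + cos(pi * step / (total - 1)))
}

#' Train a thin-slab restoration network
#'
#' Minimizes the composite loss (Charbonnier + weighted SSIM, plus the
#' evidential loss when the model has an evidential head) with Adam under a
#' cosine learning-rate schedule. Patches are sampled in a per-epoch
#' reshuffled order; the run is deterministic given the seeds.
#'
#' @param model A [build_network()] model.
#' @param pairs List of training pairs `list(lr = array(H, W, M),
#'   hr = array(H', W', N))`.
#' @param cfg A [train_config()].
#' @return List with the trained `model` and a `log` data frame
#'   (step, epoch, lr, loss).
#' @export
train_network <- function(model, pairs, cfg = train_config()) {
  stopifnot(inherits(model, "restoration_model"), inherits(cfg, "train_config"))
  if (length(pairs) == 0) stop("empty training stream", call. = FALSE)
  n <- length(pairs)
  batches_per_epoch <- max(1L, n %/% cfg$batch)
  total <- if (!is.null(cfg$steps)) cfg$steps else cfg$epochs * batches_per_epoch
  w <- model$weights
  mstate <- tree_map(function(a) a * 0, w)
  vstate <- tree_map(function(a) a * 0, w)
  log_step <- integer(total); log_epoch <- integer(total)
  log_lr <- numeric(total); log_loss <- numeric(total)
  step <- 0L
  with_seed(cfg$seed, {
    repeat {
      ord <- sample.int(n)
      for (bi in seq_len(batches_per_epoch)) {
        if (step >= total) break
        idxs <- ((bi - 1L) * cfg$batch + seq_len(cfg$batch) - 1L) %% n + 1L
        sel <- ord[idxs]
        lr <- cosine_lr(step, total, cfg$lr_max, cfg$lr_min)
        acc <- NULL
        loss_sum <- 0
        for (s in sel) {
          p <- pairs[[s]]
          fwd <- forward_network(model, p$lr, cache = TRUE)
          gb <- loss_backward(fwd, p$hr, model$cfg, cfg$weights)
          loss_sum <- loss_sum + gb$loss
          g <- backward_network(model, fwd$cache, gb$dOut)
          acc <- if (is.null(acc)) g else tree_map2(`+`, acc, g)
        }
        loss <- loss_sum / length(sel)
        if (!is.finite(loss))
          stop(sprintf("non-finite loss at step %d (lr = %g)", step, lr),
               call. = FALSE)
        acc <- tree_map(function(a) a / length(sel), acc)
        step <- step + 1L
        b1t <- 1 - cfg$beta1^step; b2t <- 1 - cfg$beta2^step
        mstate <- tree_map2(function(m, g) cfg$beta1 * m + (1 - cfg$beta1) * g,
                            mstate, acc)
        vstate <- tree_map2(function(v, g) cfg$beta2 * v + (1 - cfg$beta2) * g * g,
                            vstate, acc)
        upd <- tree_map2(function(m, v) lr * (m / b1t) / (sqrt(v / b2t) + cfg$eps),
                        mstate, vstate)
        model$weights <- tree_map2(`-`, model$weights, upd)
        log_step[step] <- step; log_epoch[step] <- (step - 1L) %/% batches_per_epoch + 1L
        log_lr[step] <- lr; log_loss[step] <- loss
      }
      if (step >= total) break
    }
  })
  list(model = model,
       log = data.frame(step = log_step, epoch = log_epoch, lr = log_lr,
                        loss = log_loss))
}

# Loss value and gradient w.r.t. the raw network output for one sample.
loss_backward <- function(fwd, target, net_cfg, weights) {
  if (!net_cfg$evidential) {
    pred <- fwd$out
    ch <- charbonnier(pred, target, eps = weights$epsilon_char, grad = TRUE)
    val <- ch$value; dP <- ch$grad
    if (weights$w1 > 0) {
      sl <- ssim_loss(pred, target, grad = TRUE)
      val <- val + weights$w1 * sl$value
      dP <- dP + weights$w1 * sl$grad
    }
    return(list(loss = val, dOut = dP))
  }
  m <- fwd$maps
  N <- net_cfg$N
  ch <- charbonnier(m$gamma, target, eps = weights$epsilon_char, grad = TRUE)
  val <- ch$value; dG <- ch$grad
  if (weights$w1 > 0) {
    sl <- ssim_loss(m$gamma, target, grad = TRUE)
    val <- val + weights$w1 * sl$value
    dG <- dG + weights$w1 * sl$grad
  }
  dV <- array(0, dim(m$v)); dA <- dV; dB <- dV
  if (weights$w2 > 0) {
    ng <- nig_loss(target, m$gamma, m$v, m$alpha, m$beta,
                   lambda_reg = weights$lambda_reg, grad = TRUE)
    val <- val + weights$w2 * ng$value
    dG <- dG + weights$w2 * ng$grad$gamma
    dV <- weights$w2 * ng$grad$v
    dA <- weights$w2 * ng$grad$alpha
    dB <- weights$w2 * ng$grad$beta
  }
  dOut <- array(0, dim(fwd$out))
  dOut[, , 1:N] <- dG
  dOut[, , (N + 1):(2 * N)] <- dV * sigmoid(m$raw_v)     # softplus'
  dOut[, , (2 * N + 1):(3 * N)] <- dA * sigmoid(m$raw_a)
  dOut[, , (3 * N + 1):(4 * N)] <- dB * sigmoid(m$raw_b)
  list(loss = val, dOut = dOut)
}

#' Restore a full volume with slab-based inference
#'
#' Cuts the input into in-plane patches and through-plane thin slabs per the
#' geometry, runs the network on every slab, stitches outputs (central
#' regions tiled in-plane; slabs grouped by offset into candidate volumes
#' through-plane) and, with `self_ensemble = TRUE`, averages the candidate
#' volumes voxel-wise. Without self-ensemble, slabs are tiled at stride `M`
#' so each slice is reconstructed once. Evidential models additionally
#' return stitched aleatoric and epistemic uncertainty maps.
#'
#' @param model A `restoration_model`.
#' @param volume Input (degraded) volume.
#' @param geom A [patch_geometry()] consistent with the model.
#' @param ensemble Average overlapping slab reconstructions
#'   (self-ensemble).
#' @return List with `volume` and, for evidential models, `aleatoric` and
#'   `epistemic`.
#' @export
infer <- function(model, volume, geom, ensemble = TRUE) {
  assert_volume(volume)
  stopifnot(inherits(model, "restoration_model"), inherits(geom, "patch_geometry"))
  cfg <- model$cfg
  if (geom$M != cfg$M || geom$N != cfg$N)
    stop("geometry (M=", geom$M, ", N=", geom$N, ") does not match model (M=",
         cfg$M, ", N=", cfg$N, ")", call. = FALSE)
  d <- dim(volume)
  si <- patch_starts(d[1], geom$lr_size, geom$lr_overlap)
  sj <- patch_starts(d[2], geom$lr_size, geom$lr_overlap)
  ss <- if (ensemble) seq.int(0L, d[3] - geom$M, by = 1L)
        else patch_starts(d[3], geom$M, 0L)
  target_shape <- c(d[1] * geom$inplane_scale, d[2] * geom$inplane_scale,
                    d[3] * geom$s_sl)
  outs <- list(); al <- list(); ep <- list()
  k <- 0L
  for (s in ss) for (j in sj) for (i in si) {
    k <- k + 1L
    slab <- volume[(i + 1):(i + geom$lr_size), (j + 1):(j + geom$lr_size),
                   (s + 1):(s + geom$M), drop = FALSE]
    fwd <- forward_network(model, slab)
    pos <- c(i, j, s)
    if (cfg$evidential) {
      mom <- evidential_moments(fwd$maps[c("gamma", "v", "alpha", "beta")])
      outs[[k]] <- list(pos = pos, patch = mom$prediction)
      al[[k]] <- list(pos = pos, patch = mom$aleatoric)
      ep[[k]] <- list(pos = pos, patch = mom$epistemic)
    } else {
      outs[[k]] <- list(pos = pos, patch = fwd$out)
    }
  }
  res <- list(volume = self_ensemble(stitch(outs, target_shape, geom)))
  if (cfg$evidential) {
    res$aleatoric <- self_ensemble(stitch(al, target_shape, geom))
    res$epistemic <- self_ensemble(stitch(ep, target_shape, geom))
  }
  res
}

#' Build a super-resolution training set from synthetic phantoms
#'
#' Generates phantoms, degrades each by k-space truncation with the given
#' scale factor, and extracts matched low/high-resolution patch pairs.
#'
#' @param seeds Phantom seeds (one volume per seed).
#' @param shape Phantom matrix size.
#' @param sf A [scale_factor()].
#' @param geom A [patch_geometry()] for the pairs.
#' @param ... Passed to [phantom_spec()] (e.g. `noise_sd`, `texture_scale`).
#' @return List of `list(lr, hr, pos)` patch pairs over all volumes.
#' @export
srr_dataset <- function(seeds, shape, sf, geom, ...) {
  out <- list()
  for (sd in seeds) {
    hr <- generate_phantom(phantom_spec(shape, seed = sd, ...))
    lr <- degrade_lr(hr, sf)
    out <- c(out, extract_patch_pairs(hr, lr, geom))
  }
  out
}

#' Build a motion-artifact training set from synthetic phantoms
#'
#' Generates phantoms, corrupts each with the periodic motion schedule, and
#' extracts matched corrupted/clean patch pairs (equal shapes; `N = M`).
#'
#' @param seeds Phantom seeds.
#' @param shape Phantom matrix size.
#' @param ms A [motion_schedule()].
#' @param geom A [patch_geometry()] with `task = "mar"`.
#' @param ... Passed to [phantom_spec()].
#' @return List of `list(lr, hr, pos)` patch pairs.
#' @export
mar_dataset <- function(seeds, shape, ms, geom, ...) {
  out <- list()
  for (sd in seeds) {
    gt <- generate_phantom(phantom_spec(shape, seed = sd, ...))
    ma <- corrupt(gt, ms)$volume
    out <- c(out, extract_patch_pairs(gt, ma, geom))
  }
  out
}

#' Experiment grid of scale factors and slab sizes
#'
#' The factor grid studied for super-resolution: `{2x2x1, 1x1x2}` at x2
#' acceleration and `{4x4x1, 2x2x2, 1x1x4}` at x4, each crossed with
#' `M` in `{1, 3, 5}`; and the motion grid `Ts` in `{9, 18, 36, 72}` EG
#' crossed with `M` in `{1, 3}`.
#'
#' @return List with data frames `srr` and `mar`.
#' @export
experiment_grid <- function() {
  srr <- expand.grid(s_fe = 0, s_pe = 0, s_sl = 0, M = c(1L, 3L, 5L))[0, ]
  facs <- list(c(2, 2, 1), c(1, 1, 2), c(4, 4, 1), c(2, 2, 2), c(1, 1, 4))
  srr <- do.call(rbind, lapply(facs, function(f) {
    data.frame(s_fe = f[1], s_pe = f[2], s_sl = f[3], M = c(1L, 3L, 5L),
               acceleration = f[2] * f[3])
  }))
  mar <- expand.grid(Ts_in_EG = c(9L, 18L, 36L, 72L), M = c(1L, 3L))
  list(srr = srr, mar = mar)
}
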