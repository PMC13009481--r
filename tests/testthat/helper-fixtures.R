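# Shared fixtures, generated in code.

tiny_phantom <- function(seed = 7, shape = c(32, 32, 16), ...) {
  # the generator requires dims >= 8; crop down for thinner test fixtures
  gen_shape <- pmax(shape, 8)
  v <- generate_phantom(phantom_spec(gen_shape, seed = seed, ...))
  v[seq_len(shape[1]), seq_len(shape[2]), seq_len(shape[3]), drop = FALSE]
}

# Tiny network configuration used wherever a full model is overkill.
tiny_net_cfg <- function(M = 1L, s_sl = 1L, inplane_scale = 1L, ...) {
  network_config(M = M, s_sl = s_sl, inplane_scale = inplane_scale,
                 n_rg = 1L, n_rcab = 1L, n_feat = 8L, reduction = 4L, ...)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Identity "network" round trip: extract patches, pass through unchanged,
# stitch and self-ensemble; returns max abs reconstruction error.
identity_roundtrip_err <- function(v, hr_size, hr_overlap, M) {
  geom <- patch_geometry(scale_factor(1, 1, 1), M = M, hr_size = hr_size,
                         hr_overlap = hr_overlap, task = "mar")
  d <- dim(v)
  pairs <- extract_patch_pairs(v, v, geom)
  outs <- lapply(pairs, function(p) list(pos = p$pos, patch = p$lr))
  max(abs(self_ensemble(stitch(outs, d, geom)) - v))
}
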