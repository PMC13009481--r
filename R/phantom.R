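#' Specification for a synthetic anatomy-like phantom
#'
#' Defines a deterministic 3D test volume built from nested soft-edged
#' ellipsoids (emulating tissue layers of a head scan) plus a band-limited
#' Gaussian random field (texture with recoverable high-frequency detail) and
#' optional additive noise. Phantoms stand in for real T1-weighted volumes so
#' the degradation simulators, network and metrics are testable end to end
#' without any external data.
#'
#' @param shape Integer length-3 matrix size (FE, PE, SL); every component
#'   must be at least 8.
#' @param seed Integer seed; identical specs yield bit-identical volumes.
#' @param n_ellipsoids Number of nested ellipsoid shells (default 4).
#' @param texture_scale Correlation length, in voxels, of the smooth random
#'   texture field (default 4).
#' @param noise_sd Standard deviation of additive Gaussian noise applied
#'   before the final rescale (default 0).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape, seed = 1L, n_ellipsoids = 4L,
                         texture_scale = 4, noise_sd = 0) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 8L))
    stop("shape must have 3 components, each >= 8 (got ",
         paste(shape, collapse = "x"), ")", call. = FALSE)
  if (n_ellipsoids < 1L) stop("n_ellipsoids must be positive", call. = FALSE)
  if (texture_scale <= 0) stop("texture_scale must be positive", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be nonnegative", call. = FALSE)
  structure(list(shape = shape, seed = as.integer(seed),
                 n_ellipsoids = as.integer(n_ellipsoids),
                 texture_scale = texture_scale, noise_sd = noise_sd),
            class = "phantom_spec")
}

#' Generate a synthetic 3D phantom volume
#'
#' Deterministic given the spec: the same spec always produces a bit-identical
#' volume. Intensities are rescaled to \[0, 1\].
#'
#' @param spec A [phantom_spec()].
#' @return Numeric 3D array of the requested shape with values in \[0, 1\].
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape
  with_seed(spec$seed, {
    # normalized centered coordinates in [-1, 1]
    cx <- (seq_len(d[1]) - (d[1] + 1) / 2) / (d[1] / 2)
    cy <- (seq_len(d[2]) - (d[2] + 1) / 2) / (d[2] / 2)
    cz <- (seq_len(d[3]) - (d[3] + 1) / 2) / (d[3] / 2)
    X <- array(rep(cx, times = d[2] * d[3]), d)
    Y <- array(rep(rep(cy, each = d[1]), times = d[3]), d)
    Z <- array(rep(cz, each = d[1] * d[2]), d)
    v <- array(0, d)
    for (i in seq_len(spec$n_ellipsoids)) {
      # shells shrink inward; alternate contrast like tissue layers
      scale <- 0.9 * (1 - 0.8 * (i - 1) / spec$n_ellipsoids)
      ax <- scale * (1 + 0.12 * (runif(3) - 0.5))
      ctr <- 0.08 * (runif(3) - 0.5)
      r <- sqrt(((X - ctr[1]) / ax[1])^2 + ((Y - ctr[2]) / ax[2])^2 +
                  ((Z - ctr[3]) / ax[3])^2)
      # positive layered amplitudes keep the background at the intensity
      # minimum, so it rescales to ~0 (like air around a head)
      amp <- if (i %% 2 == 1) 0.8 else 0.35
      w <- 0.05 + 0.02 * runif(1)            # sigmoid edge softness
      v <- v + amp / (1 + exp((r - 1) / w))
    }
    if (spec$n_ellipsoids > 1L) {
      tex <- smooth_random_field(d, spec$texture_scale)
      # texture confined to the head: modulate by outermost shell support
      support <- abs(v) > 0.05 * max(abs(v))
      v <- v + 0.25 * tex * support
    }
    if (spec$noise_sd > 0)
      v <- v + array(rnorm(prod(d), sd = spec$noise_sd), d)
    rescale01(v)
  })
}

# Band-limited Gaussian random field: white noise convolved with a Gaussian
# of width `scale` voxels via the FFT, normalized to unit sd.
smooth_random_field <- function(d, scale) {
  w <- array(rnorm(prod(d)), d)
  kx <- fft_freq(d[1]); ky <- fft_freq(d[2]); kz <- fft_freq(d[3])
  K2 <- outer(outer(kx^2, ky^2, `+`), kz^2, `+`)
  filt <- exp(-2 * pi^2 * scale^2 * K2)
  f <- Re(stats::fft(stats::fft(w) * filt, inverse = TRUE)) / prod(d)
  s <- stats::sd(f)
  if (s == 0) return(f)
  f / s
}

fft_freq <- function(n) {
  k <- c(seq(0, floor((n - 1) / 2)), seq(-floor(n / 2), -1))
  k / n
}
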