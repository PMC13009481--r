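#' Scale factor for k-space down-sampling
#'
#' Integer down-sampling triple ordered frequency-encoding x phase-encoding x
#' slice-encoding (FE x PE x SL). Each component must divide the matching
#' volume dimension when applied.
#'
#' @param s_fe,s_pe,s_sl Positive integer sub-sampling ratios.
#' @return An object of class `scale_factor`.
#' @export
scale_factor <- function(s_fe, s_pe, s_sl) {
  s <- as.integer(c(s_fe, s_pe, s_sl))
  if (any(s < 1L) || any(is.na(s)))
    stop("scale factor components must be positive integers", call. = FALSE)
  structure(list(s = s), class = "scale_factor")
}

#' @export
format.scale_factor <- function(x, ...) paste(x$s, collapse = "x")

#' @export
print.scale_factor <- function(x, ...) {
  cat("scale factor (FE x PE x SL):", format(x), "\n"); invisible(x)
}

#' Acceleration factor of a scale factor
#'
#' 3D acquisition time scales with the number of phase- and slice-encoding
#' steps, so the effective scan-time acceleration is the product of the
#' sub-sampling ratios along PE and SL; FE sub-sampling does not shorten the
#' scan.
#'
#' @param sf A [scale_factor()].
#' @return Positive integer acceleration.
#' @export
acceleration <- function(sf) {
  stopifnot(inherits(sf, "scale_factor"))
  sf$s[2] * sf$s[3]
}

#' Fraction of k-space coefficients discarded by central truncation
#'
#' @param sf A [scale_factor()].
#' @return `1 - 1 / (s_fe * s_pe * s_sl)`.
#' @export
discard_fraction <- function(sf) {
  stopifnot(inherits(sf, "scale_factor"))
  1 - 1 / prod(sf$s)
}

#' Forward 3D FFT to a DC-centered k-space volume
#'
#' @param v Numeric 3D array with finite values.
#' @return An object of class `kspace_volume` holding the complex DC-centered
#'   spectrum.
#' @export
to_kspace <- function(v) {
  assert_volume(v)
  spec <- fftshift3(stats::fft(v))
  structure(list(spectrum = spec, shape = dim(v)), class = "kspace_volume")
}

#' Inverse 3D FFT from a DC-centered k-space volume
#'
#' Returns the real part; for spectra arising from real images (possibly
#' centrally truncated) the residual imaginary component is checked to be
#' negligible (< 1e-8 of the signal magnitude) to guard against silent phase
#' errors.
#'
#' @param k A `kspace_volume`.
#' @param check Assert the residual imaginary part is negligible.
#' @return Numeric 3D array.
#' @export
from_kspace <- function(k, check = TRUE) {
  stopifnot(inherits(k, "kspace_volume"))
  x <- stats::fft(ifftshift3(k$spectrum), inverse = TRUE) / prod(k$shape)
  if (check) {
    m <- max(Mod(x))
    if (m > 0 && max(abs(Im(x))) > 1e-8 * m)
      warning("non-negligible imaginary component after inverse FFT")
  }
  Re(x)
}

#' Centrally truncate a k-space volume
#'
#' Keeps the centered block of size `dim/s` along each axis, i.e. the
#' low-frequency core of the spectrum. For even dimensions the retained
#' 0-based half-open window along an axis of length `n` is
#' `[n/2 - n/(2s), n/2 + n/(2s))`, which always contains the DC line at `n/2`.
#'
#' @param k A `kspace_volume` (DC-centered).
#' @param sf A [scale_factor()]; each component must divide the matching
#'   dimension.
#' @param keep_matrix If `TRUE`, zero out the discarded coefficients but keep
#'   the original matrix size (same-voxel-grid output). If `FALSE` (default),
#'   return the reduced matrix — the true low-resolution acquisition, where
#'   the smaller matrix over a fixed field of view means proportionally larger
#'   voxels.
#' @return A `kspace_volume`.
#' @export
truncate_central <- function(k, sf, keep_matrix = FALSE) {
  stopifnot(inherits(k, "kspace_volume"), inherits(sf, "scale_factor"))
  d <- k$shape
  axes <- c("FE", "PE", "SL")
  for (ax in 1:3) {
    if (d[ax] %% sf$s[ax] != 0L)
      stop(sprintf("%s dimension (%d) not divisible by scale factor %d",
                   axes[ax], d[ax], sf$s[ax]), call. = FALSE)
  }
  keep <- lapply(1:3, function(ax) {
    n <- d[ax]; s <- sf$s[ax]
    lo <- floor(n / 2) - floor(n / (2 * s))        # 0-based start
    seq.int(lo + 1L, length.out = n %/% s)
  })
  if (keep_matrix) {
    spec <- array(0 + 0i, d)
    spec[keep[[1]], keep[[2]], keep[[3]]] <-
      k$spectrum[keep[[1]], keep[[2]], keep[[3]]]
    structure(list(spectrum = spec, shape = d), class = "kspace_volume")
  } else {
    spec <- k$spectrum[keep[[1]], keep[[2]], keep[[3]], drop = FALSE]
    structure(list(spectrum = spec, shape = d %/% sf$s),
              class = "kspace_volume")
  }
}

#' Simulate a low-resolution acquisition by k-space truncation
#'
#' The standard retrospective low-resolution simulation: forward 3D FFT,
#' symmetric central truncation according to the scale factor, inverse FFT,
#' and rescale to \[0, 1\]. With `keep_matrix = FALSE` (default) the output
#' matrix is `dim(v) / sf` — the genuine low-resolution grid.
#'
#' @param v Numeric 3D array (high-resolution volume).
#' @param sf A [scale_factor()].
#' @param keep_matrix Keep the original matrix size (zero-filled spectrum).
#' @return Low-resolution volume with intensities in \[0, 1\].
#' @export
degrade_lr <- function(v, sf, keep_matrix = FALSE) {
  k <- to_kspace(v)
  kt <- truncate_central(k, sf, keep_matrix = keep_matrix)
  rescale01(from_kspace(kt, check = FALSE))
}

# DC-centering shifts (circular shift by floor(n/2) per axis).
fftshift3 <- function(x) shift3(x, dim(x) %/% 2L)
ifftshift3 <- function(x) shift3(x, -(dim(x) %/% 2L))

shift3 <- function(x, by) {
  d <- dim(x)
  idx <- lapply(1:3, function(ax) {
    n <- d[ax]
    1L + (seq_len(n) - 1L - by[ax]) %% n
  })
  x[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}
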