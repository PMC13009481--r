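#' @keywords internal
"_PACKAGE"

# Axis convention used throughout: a Volume is a numeric 3D array indexed
# [FE, PE, SL] (frequency-encoding, phase-encoding, slice-encoding). In-plane
# operations act on the first two axes; thin slabs stack along the third.

assert_volume <- function(v, name = "volume") {
  if (!is.array(v) || length(dim(v)) != 3L)
    stop(name, " must be a 3D array", call. = FALSE)
  if (!all(is.finite(v)))
    stop(name, " contains non-finite values", call. = FALSE)
  invisible(v)
}

assert_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("shape mismatch: ", paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"), call. = FALSE)
  invisible(NULL)
}

#' Rescale intensities to the unit interval
#'
#' Linearly maps intensities to \[0, 1\]. A constant input maps to all zeros
#' (there is no contrast to preserve, and this avoids division by zero).
#' The operation is idempotent.
#'
#' @param v Numeric array (any dimensionality).
#' @return Array of the same shape with `min = 0`, `max = 1` unless constant.
#' @export
rescale01 <- function(v) {
  rng <- range(v)
  if (!all(is.finite(rng))) stop("non-finite values in input", call. = FALSE)
  if (rng[2] == rng[1]) return(array(0, dim = dim(v) %||% length(v)))
  (v - rng[1]) / (rng[2] - rng[1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Read a 3D volume from a NIfTI file
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param rescale Rescale intensities to \[0, 1\] on load (default `TRUE`).
#' @return A numeric 3D array.
#' @export
read_volume <- function(path, rescale = TRUE) {
  img <- RNifti::readNifti(path)
  v <- array(as.numeric(img), dim = dim(img)[1:3])
  if (rescale) v <- rescale01(v)
  v
}

#' Write a 3D volume to a NIfTI file
#'
#' @param v Numeric 3D array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_size Numeric length-3 voxel dimensions in mm, written to the
#'   NIfTI header.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path, voxel_size = c(1, 1, 1)) {
  assert_volume(v)
  img <- RNifti::asNifti(v, pixdim = voxel_size)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Separable cubic (tricubic) interpolation of a volume
#'
#' Catmull-Rom cubic interpolation applied separably along each axis with an
#' integer upsampling factor. This is the conventional non-learned baseline
#' for super-resolution comparisons.
#'
#' @param v Numeric 3D array (low-resolution volume).
#' @param factor Integer length-3 upsampling factor per axis (FE, PE, SL).
#' @return Volume of shape `dim(v) * factor`, rescaled to \[0, 1\].
#' @export
interp_tricubic <- function(v, factor) {
  assert_volume(v)
  factor <- as.integer(factor)
  stopifnot(length(factor) == 3L, all(factor >= 1L))
  out <- v
  for (ax in 1:3) if (factor[ax] > 1L) out <- upsample_axis_cubic(out, ax, factor[ax])
  rescale01(out)
}

# Cubic upsampling along one axis. Sample positions follow the centre-aligned
# convention x_hr = (i + 0.5)/s - 0.5 on the LR grid, with edge clamping.
upsample_axis_cubic <- function(v, axis, s) {
  d <- dim(v)
  n <- d[axis]
  m <- n * s
  x <- (seq_len(m) - 0.5) / s - 0.5          # LR-grid coordinates, 0-based
  i1 <- floor(x)
  t <- x - i1
  # Catmull-Rom weights for the 4 taps i1-1 .. i1+2
  w0 <- ((-0.5 * t + 1) * t - 0.5) * t
  w1 <- (1.5 * t - 2.5) * t * t + 1
  w2 <- ((-1.5 * t + 2) * t + 0.5) * t
  w3 <- (0.5 * t - 0.5) * t * t
  idx <- function(k) pmin(pmax(i1 + k, 0), n - 1) + 1
  # Build m x n interpolation matrix (dense; axes are small)
  A <- matrix(0, m, n)
  rows <- seq_len(m)
  A[cbind(rows, idx(-1))] <- A[cbind(rows, idx(-1))] + w0
  A[cbind(rows, idx(0))]  <- A[cbind(rows, idx(0))]  + w1
  A[cbind(rows, idx(1))]  <- A[cbind(rows, idx(1))]  + w2
  A[cbind(rows, idx(2))]  <- A[cbind(rows, idx(2))]  + w3
  apply_axis_matrix(v, axis, A)
}

# Multiply a matrix A (m x n) along the given axis of a 3D array.
apply_axis_matrix <- function(v, axis, A) {
  d <- dim(v)
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  vp <- aperm(v, perm)
  dp <- dim(vp)
  res <- A %*% matrix(vp, dp[1], dp[2] * dp[3])
  out <- array(res, c(nrow(A), dp[2], dp[3]))
  aperm(out, order(perm))
}
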