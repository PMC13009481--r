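#' Peak signal-to-noise ratio
#'
#' `10 log10(1 / MSE)` with peak value 1.0 (volumes are expected in \[0, 1\]).
#' Identical inputs give `Inf`.
#'
#' @param a,b Equally shaped numeric arrays.
#' @return PSNR in dB.
#' @export
psnr <- function(a, b) {
  assert_same_shape(a, b)
  mse <- mean((a - b)^2)
  if (mse == 0) return(Inf)
  10 * log10(1 / mse)
}

# 1D Gaussian window (11 taps, sigma 1.5 by default), normalized.
gaussian_window <- function(size = 11L, sigma = 1.5) {
  x <- seq_len(size) - (size + 1) / 2
  w <- exp(-x^2 / (2 * sigma^2))
  w / sum(w)
}

# Dense band matrix implementing a valid 1D correlation with window w:
# (n - size + 1) x n. Small sizes make dense matrices cheap and let the
# adjoint (needed for the SSIM loss gradient) be a plain transpose.
valid_filter_matrix <- function(n, w) {
  size <- length(w)
  m <- n - size + 1L
  if (m < 1L) stop("image smaller than the filter window", call. = FALSE)
  A <- matrix(0, m, n)
  for (k in seq_len(size)) A[cbind(seq_len(m), seq_len(m) + k - 1L)] <- w[k]
  A
}

# Separable valid Gaussian filtering of a 2D matrix: Br %*% X %*% t(Bc).
ssim_env <- new.env(parent = emptyenv())
filter_mats <- function(h, wdt, w) {
  key <- paste(h, wdt, length(w), sep = ":")
  if (is.null(ssim_env[[key]]))
    ssim_env[[key]] <- list(Br = valid_filter_matrix(h, w),
                            Bc = valid_filter_matrix(wdt, w))
  ssim_env[[key]]
}

# SSIM map between two 2D slices plus the intermediates needed for gradients.
ssim_map_2d <- function(x, y, window = 11L, sigma = 1.5,
                        K1 = 0.01, K2 = 0.03, data_range = 1) {
  w <- gaussian_window(window, sigma)
  fm <- filter_mats(nrow(x), ncol(x), w)
  G <- function(z) fm$Br %*% z %*% t(fm$Bc)
  C1 <- (K1 * data_range)^2
  C2 <- (K2 * data_range)^2
  mx <- G(x); my <- G(y)
  sxx <- G(x * x) - mx * mx
  syy <- G(y * y) - my * my
  sxy <- G(x * y) - mx * my
  A1 <- 2 * mx * my + C1; A2 <- 2 * sxy + C2
  B1 <- mx * mx + my * my + C1; B2 <- sxx + syy + C2
  list(map = (A1 * A2) / (B1 * B2),
       mx = mx, my = my, sxx = sxx, sxy = sxy,
       A1 = A1, A2 = A2, B1 = B1, B2 = B2, fm = fm)
}

#' Structural similarity index
#'
#' Mean local SSIM with the standard constants (`K1 = 0.01`, `K2 = 0.03`,
#' data range 1) and an 11x11 Gaussian window (`sigma = 1.5`), computed on
#' the valid region (window-width borders cropped). Volumes are evaluated per
#' 2D slice along the chosen plane and averaged; the per-slice means and the
#' SSIM map of each slice are available via `map = TRUE`.
#'
#' @param a,b Equally shaped 2D matrices or 3D arrays with values in \[0, 1\].
#' @param map If `TRUE`, also return per-slice means and SSIM maps.
#' @return Scalar mean SSIM, or a list with `ssim`, `per_slice`, `maps`.
#' @export
ssim <- function(a, b, map = FALSE) {
  assert_same_shape(a, b)
  if (is.matrix(a)) { a <- array(a, c(dim(a), 1L)); b <- array(b, c(dim(b), 1L)) }
  D <- dim(a)[3]
  maps <- vector("list", D)
  per_slice <- numeric(D)
  for (s in seq_len(D)) {
    m <- ssim_map_2d(a[, , s], b[, , s])$map
    maps[[s]] <- m
    per_slice[s] <- mean(m)
  }
  val <- mean(per_slice)
  if (!map) return(val)
  list(ssim = val, per_slice = per_slice, maps = maps)
}

#' Image-quality report for a restored volume
#'
#' @param pred Restored volume in \[0, 1\].
#' @param gt Ground-truth volume in \[0, 1\].
#' @param plane Label recorded in the report; slices are taken along the
#'   third axis.
#' @return List with volume-level `psnr_db` and `ssim` and per-slice vectors.
#' @export
quality_report <- function(pred, gt, plane = "sagittal") {
  assert_same_shape(pred, gt)
  D <- dim(pred)[3]
  ps <- vapply(seq_len(D), function(s) psnr(pred[, , s], gt[, , s]), 0)
  ss <- ssim(pred, gt, map = TRUE)
  list(psnr_db = psnr(pred, gt), ssim = ss$ssim,
       psnr_per_slice = ps, ssim_per_slice = ss$per_slice, plane = plane)
}

# JSON-safe rendering (Inf PSNR becomes the string sentinel "inf").
report_to_json <- function(report, path) {
  enc <- function(x) {
    if (is.numeric(x) && length(x) == 1L)
      return(if (is.infinite(x)) "inf" else x)
    if (is.numeric(x))
      return(lapply(as.list(x), function(v) if (is.infinite(v)) "inf" else v))
    x
  }
  out <- lapply(report, enc)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
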