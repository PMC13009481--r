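#' Evidential moment maps
#'
#' Converts Normal-Inverse-Gamma hyperparameter maps into the prediction and
#' the two uncertainty maps: prediction `E[mu] = gamma`, aleatoric
#' `E[sigma^2] = beta / (alpha - 1)` (irreducible data noise) and epistemic
#' `Var[mu] = beta / (v (alpha - 1))` (model uncertainty, vanishing as the
#' virtual-observation count `v` grows). Note the algebraic identity
#' `epistemic * v = aleatoric`.
#'
#' @param maps List with arrays `gamma`, `v`, `alpha`, `beta` (equal shapes;
#'   `v > 0`, `alpha > 1`, `beta > 0`).
#' @return List with `prediction`, `aleatoric`, `epistemic`.
#' @export
evidential_moments <- function(maps) {
  with(maps, {
    if (any(alpha <= 1)) stop("alpha must exceed 1 everywhere (moments undefined)",
                              call. = FALSE)
    if (any(v <= 0) || any(beta <= 0))
      stop("v and beta must be positive everywhere", call. = FALSE)
    list(prediction = gamma,
         aleatoric = beta / (alpha - 1),
         epistemic = beta / (v * (alpha - 1)))
  })
}

#' Slice-mean uncertainty
#'
#' Mean over in-plane voxels for each slice along the third axis — the
#' per-slice summary used to calibrate uncertainty against image quality.
#'
#' @param u 3D uncertainty map.
#' @return Numeric vector, one mean per slice.
#' @export
slice_mean <- function(u) {
  assert_volume(u)
  apply(u, 3, mean)
}

#' Calibrate image quality against slice-mean epistemic uncertainty
#'
#' Fits the quality-prediction regression: `linear_ssim` fits
#' `SSIM = a u + b` by least squares; `exp_psnr` fits
#' `PSNR = c exp(d u) + e` by nonlinear least squares (log-linear
#' initialization, Levenberg-Marquardt refinement), reflecting the
#' logarithmic nature of PSNR. Both models provide 95% prediction intervals
#' (classical for the linear fit; delta-method for the exponential fit).
#'
#' @param u_means Slice-mean epistemic uncertainties (predictor).
#' @param metric_values Matching SSIM or PSNR values (response).
#' @param kind `"linear_ssim"` or `"exp_psnr"`.
#' @param level Prediction-interval level (default 0.95).
#' @return An object of class `quality_calibration` with elements
#'   `coefficients`, `r_squared`, `sigma` (residual scale), `fit_range`.
#' @export
fit_calibration <- function(u_means, metric_values,
                            kind = c("linear_ssim", "exp_psnr"),
                            level = 0.95) {
  kind <- match.arg(kind)
  u <- as.numeric(u_means); y <- as.numeric(metric_values)
  stopifnot(length(u) == length(y))
  if (length(u) < 10) stop("need at least 10 paired observations", call. = FALSE)
  if (!all(is.finite(u)) || !all(is.finite(y)))
    stop("non-finite observations", call. = FALSE)
  if (stats::sd(u) == 0) stop("degenerate predictor (zero variance)", call. = FALSE)
  if (kind == "linear_ssim") {
    fit <- stats::lm(y ~ u, data = data.frame(u = u, y = y))
    co <- stats::coef(fit)
    rss <- sum(stats::resid(fit)^2)
    tss <- sum((y - mean(y))^2)
    obj <- list(kind = kind, fit = fit,
                coefficients = c(a = unname(co[2]), b = unname(co[1])),
                r_squared = 1 - rss / tss,
                sigma = sqrt(rss / fit$df.residual))
  } else {
    # log-linear init: pick an offset below the data range, fit log(y - e0)
    e0 <- min(y) - 0.05 * max(diff(range(y)), 1e-8)
    lf <- stats::lm(log(y - e0) ~ u)
    start <- list(c = exp(unname(stats::coef(lf)[1])),
                  d = unname(stats::coef(lf)[2]), e = e0)
    fit <- minpack.lm::nlsLM(y ~ c * exp(d * u) + e,
                             data = data.frame(u = u, y = y), start = start,
                             control = minpack.lm::nls.lm.control(maxiter = 200))
    co <- stats::coef(fit)
    rss <- sum(stats::resid(fit)^2)
    tss <- sum((y - mean(y))^2)
    obj <- list(kind = kind, fit = fit, coefficients = co,
                r_squared = 1 - rss / tss,
                sigma = summary(fit)$sigma)
  }
  obj$level <- level
  obj$n <- length(u)
  obj$fit_range <- range(u)
  class(obj) <- "quality_calibration"
  obj
}

#' Predict image quality from mean epistemic uncertainty
#'
#' Point prediction with its prediction interval at the calibration's level.
#' Predictors more than twice the fitted range from its midpoint raise an
#' extrapolation warning.
#'
#' @param model A [fit_calibration()] result.
#' @param u_mean Numeric vector of slice-mean epistemic uncertainties.
#' @return Data frame with columns `u`, `fit`, `lwr`, `upr`.
#' @export
predict_quality <- function(model, u_mean) {
  stopifnot(inherits(model, "quality_calibration"))
  u <- as.numeric(u_mean)
  fr <- model$fit_range
  half <- diff(fr) / 2
  mid <- mean(fr)
  if (any(abs(u - mid) > 2 * max(half, .Machine$double.eps)))
    warning("predictor outside twice the fitted range; extrapolating")
  if (model$kind == "linear_ssim") {
    p <- stats::predict(model$fit, newdata = data.frame(u = u),
                        interval = "prediction", level = model$level)
    out <- data.frame(u = u, fit = p[, "fit"], lwr = p[, "lwr"],
                      upr = p[, "upr"])
  } else {
    co <- stats::coef(model$fit)
    V <- stats::vcov(model$fit)
    fitv <- co["c"] * exp(co["d"] * u) + co["e"]
    # delta method: grad w.r.t. (c, d, e)
    se2 <- vapply(seq_along(u), function(i) {
      g <- c(exp(co["d"] * u[i]), co["c"] * u[i] * exp(co["d"] * u[i]), 1)
      as.numeric(t(g) %*% V %*% g)
    }, 0)
    df <- model$n - length(co)
    tq <- stats::qt(1 - (1 - model$level) / 2, df)
    hw <- tq * sqrt(se2 + model$sigma^2)
    out <- data.frame(u = u, fit = fitv, lwr = fitv - hw, upr = fitv + hw)
  }
  rownames(out) <- NULL
  out
}

#' @export
print.quality_calibration <- function(x, ...) {
  cat("quality calibration (", x$kind, ")\n", sep = "")
  cat("  coefficients:",
      paste(sprintf("%s = %.6g", names(x$coefficients), x$coefficients),
            collapse = ", "), "\n")
  cat(sprintf("  R^2 = %.4f, residual sigma = %.4g, n = %d\n",
              x$r_squared, x$sigma, x$n))
  invisible(x)
}

#' Coefficients of a calibration fit
#' @param object A `quality_calibration`.
#' @param ... Unused.
#' @return Named numeric coefficient vector.
#' @export
coef.quality_calibration <- function(object, ...) object$coefficients

#' Serialize a calibration model to JSON
#'
#' @param model A `quality_calibration`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(model, path) {
  jsonlite::write_json(
    list(kind = model$kind,
         coefficients = as.list(model$coefficients),
         sigma = model$sigma, r_squared = model$r_squared,
         level = model$level, n = model$n,
         fit_range = model$fit_range),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
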