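#' Loss weights for the composite restoration objective
#'
#' The restoration objective is `L_Char + w1 * L_SSIM`, extended with
#' `w2 * L_NIG` when the evidential head is active. The defaults `w1 = 0.5`
#' and `w2 = 1` are the configuration found to perform best; `epsilon_char`
#' is the Charbonnier smoothing constant (1e-4); `lambda_reg` weights the
#' evidential regularizer (no canonical value exists, 0.01 by default).
#'
#' @param w1 SSIM-loss weight (default 0.5).
#' @param w2 Evidential-loss weight (default 1).
#' @param lambda_reg Evidence regularizer coefficient (default 0.01).
#' @param epsilon_char Charbonnier constant (default 1e-4).
#' @return An object of class `loss_weights`.
#' @export
loss_weights <- function(w1 = 0.5, w2 = 1, lambda_reg = 0.01,
                         epsilon_char = 1e-4) {
  stopifnot(w1 >= 0, w2 >= 0, lambda_reg >= 0, epsilon_char > 0)
  structure(list(w1 = w1, w2 = w2, lambda_reg = lambda_reg,
                 epsilon_char = epsilon_char), class = "loss_weights")
}

#' Charbonnier loss
#'
#' Differentiable L1 surrogate: `mean(sqrt((target - pred)^2 + eps))`. Note
#' the constant sits un-squared inside the root, so identical images give
#' `sqrt(eps)` (1e-2 at the default), the loss's lower bound.
#'
#' @param pred,target Equally shaped numeric arrays.
#' @param eps Smoothing constant (default 1e-4).
#' @param grad If `TRUE`, also return the gradient w.r.t. `pred`.
#' @return Scalar loss, or `list(value, grad)`.
#' @export
charbonnier <- function(pred, target, eps = 1e-4, grad = FALSE) {
  assert_same_shape(pred, target)
  d <- pred - target
  r <- sqrt(d * d + eps)
  val <- mean(r)
  if (!grad) return(val)
  list(value = val, grad = d / r / length(d))
}

#' Squared-SSIM loss
#'
#' `mean(1 - SSIM(pred_i, target_i)^2)` over the slices/patches `i` of the
#' batch, where `SSIM_i` is the mean SSIM of slice `i`. Squaring sharpens the
#' penalty near `SSIM = 1`.
#'
#' @param pred,target Equally shaped 2D or 3D arrays (third axis = batch) in
#'   \[0, 1\].
#' @param grad If `TRUE`, also return the gradient w.r.t. `pred`.
#' @return Scalar loss, or `list(value, grad)`.
#' @export
ssim_loss <- function(pred, target, grad = FALSE) {
  assert_same_shape(pred, target)
  if (is.matrix(pred)) {
    pred <- array(pred, c(dim(pred), 1L)); target <- array(target, c(dim(target), 1L))
  }
  D <- dim(pred)[3]
  vals <- numeric(D)
  g <- if (grad) array(0, dim(pred)) else NULL
  for (s in seq_len(D)) {
    sm <- ssim_map_2d(pred[, , s], target[, , s])
    m <- mean(sm$map)
    vals[s] <- 1 - m * m
    if (grad) {
      # d(1 - m^2)/dx = -2 m * dm/dx, averaged over slices
      g[, , s] <- ssim_mean_grad_2d(pred[, , s], target[, , s], sm) *
        (-2 * m) / D
    }
  }
  val <- mean(vals)
  if (!grad) return(val)
  list(value = val, grad = g)
}

# Gradient of mean(SSIM map) w.r.t. x for one 2D slice, via adjoints of the
# separable valid Gaussian filter (transpose of the band matrices).
ssim_mean_grad_2d <- function(x, y, sm) {
  fm <- sm$fm
  Gt <- function(z) t(fm$Br) %*% z %*% fm$Bc
  nm <- length(sm$map)
  gS <- matrix(1 / nm, nrow(sm$map), ncol(sm$map))
  S <- sm$map
  gA1 <- gS * sm$A2 / (sm$B1 * sm$B2)
  gA2 <- gS * sm$A1 / (sm$B1 * sm$B2)
  gB1 <- -gS * S / sm$B1
  gB2 <- -gS * S / sm$B2
  gsxy <- 2 * gA2
  gsxx <- gB2
  gmx <- 2 * sm$my * gA1 + 2 * sm$mx * gB1 - sm$my * gsxy - 2 * sm$mx * gsxx
  Gt(gmx) + 2 * x * Gt(gsxx) + y * Gt(gsxy)
}

#' Normal-Inverse-Gamma evidential loss
#'
#' Negative log-likelihood of the Student-t predictive implied by the NIG
#' evidential parameterization, plus an evidence regularizer that scales the
#' absolute error by the total evidence `2v + alpha`:
#' `L_NLL = 1/2 log(pi/v) - alpha log(Omega) + (alpha + 1/2) log((y - gamma)^2 v + Omega)
#'  + log(Gamma(alpha) / Gamma(alpha + 1/2))` with `Omega = 2 beta (1 + v)`,
#' and `L_Reg = |y - gamma| (2v + alpha)`; total `L_NLL + lambda * L_Reg`,
#' averaged over voxels.
#'
#' @param y Target array.
#' @param gamma,v,alpha,beta Evidential parameter maps (same shape as `y`);
#'   must satisfy `v > 0`, `alpha > 1`, `beta > 0`.
#' @param lambda_reg Regularizer weight.
#' @param grad If `TRUE`, also return gradients w.r.t. the four maps.
#' @return Scalar loss, or `list(value, grad = list(gamma, v, alpha, beta))`.
#' @export
nig_loss <- function(y, gamma, v, alpha, beta, lambda_reg = 0.01,
                     grad = FALSE) {
  assert_same_shape(y, gamma); assert_same_shape(y, v)
  assert_same_shape(y, alpha); assert_same_shape(y, beta)
  if (any(v <= 0) || any(alpha <= 1) || any(beta <= 0))
    stop("evidential constraints violated (need v > 0, alpha > 1, beta > 0)",
         call. = FALSE)
  n <- length(y)
  D <- y - gamma
  Om <- 2 * beta * (1 + v)
  S <- D * D * v + Om
  nll <- 0.5 * log(pi / v) - alpha * log(Om) + (alpha + 0.5) * log(S) +
    lgamma(alpha) - lgamma(alpha + 0.5)
  reg <- abs(D) * (2 * v + alpha)
  val <- mean(nll) + lambda_reg * mean(reg)
  if (!grad) return(val)
  gg <- (alpha + 0.5) * (-2 * D * v) / S / n +
    lambda_reg * (-sign(D)) * (2 * v + alpha) / n
  gv <- (-0.5 / v - alpha * 2 * beta / Om + (alpha + 0.5) * (D * D + 2 * beta) / S) / n +
    lambda_reg * 2 * abs(D) / n
  ga <- (-log(Om) + log(S) + digamma(alpha) - digamma(alpha + 0.5)) / n +
    lambda_reg * abs(D) / n
  gb <- (-alpha / beta + (alpha + 0.5) * 2 * (1 + v) / S) / n
  list(value = val, grad = list(gamma = gg, v = gv, alpha = ga, beta = gb))
}

#' Composite restoration loss
#'
#' `L_Char + w1 * L_SSIM` plus `w2 * L_NIG` when evidential maps are
#' supplied; the prediction compared to the target is the evidential mean
#' `gamma` in that case.
#'
#' @param pred Predicted patch/volume (ignored when `evidential` is given —
#'   `evidential$gamma` is the prediction).
#' @param target Ground-truth array.
#' @param evidential Optional list with maps `gamma`, `v`, `alpha`, `beta`.
#' @param weights A [loss_weights()].
#' @return Scalar loss value.
#' @export
combined_loss <- function(pred, target, evidential = NULL,
                          weights = loss_weights()) {
  stopifnot(inherits(weights, "loss_weights"))
  if (!is.null(evidential)) pred <- evidential$gamma
  val <- charbonnier(pred, target, eps = weights$epsilon_char)
  if (weights$w1 > 0) val <- val + weights$w1 * ssim_loss(pred, target)
  if (!is.null(evidential) && weights$w2 > 0)
    val <- val + weights$w2 *
      nig_loss(target, evidential$gamma, evidential$v, evidential$alpha,
               evidential$beta, lambda_reg = weights$lambda_reg)
  val
}
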