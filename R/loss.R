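#' Mean absolute error (L1 loss)
#'
#' @param pred,target numeric matrices of identical shape.
#' @return Mean absolute difference.
#' @export
l1_loss <- function(pred, target) {
  if (!identical(dim(as.matrix(pred)), dim(as.matrix(target))))
    stop("l1_loss: shape mismatch")
  mean(abs(pred - target))
}

#' Loss specification for training
#'
#' `L = L1 + alpha_ssim * (1 - SSIM) + beta_shape * mean(W * |pred - target|)`
#' where `W` is the target's gradient-magnitude map normalized to mean 1
#' (uniform when the target is constant). `alpha_ssim = beta_shape = 0`
#' reduces to plain L1.
#'
#' @param alpha_ssim weight of the structural (1 - SSIM) term, >= 0.
#' @param beta_shape weight of the shape-aware gradient-weighted L1 term, >= 0.
#' @return An object of class `xfct_loss_spec`.
#' @export
loss_spec <- function(alpha_ssim = 0.5, beta_shape = 1) {
  if (alpha_ssim < 0 || beta_shape < 0) stop("loss weights must be >= 0")
  structure(list(alpha_ssim = alpha_ssim, beta_shape = beta_shape),
            class = "xfct_loss_spec")
}

# gradient-magnitude weight map of the target, normalized to mean 1
shape_weight_map <- function(target) {
  H <- nrow(target); W <- ncol(target)
  gy <- matrix(0, H, W); gx <- matrix(0, H, W)
  gy[2:(H - 1), ] <- (target[3:H, ] - target[1:(H - 2), ]) / 2
  gx[, 2:(W - 1)] <- (target[, 3:W] - target[, 1:(W - 2)]) / 2
  w <- sqrt(gy^2 + gx^2)
  mw <- mean(w)
  if (mw == 0) return(matrix(1, H, W))
  w / mw
}

#' Compound shape-aware training loss
#'
#' @param pred,target numeric matrices in \[0, 1\] of identical shape.
#' @param spec a [loss_spec()].
#' @return Scalar loss value.
#' @export
compound_loss <- function(pred, target, spec = loss_spec()) {
  stopifnot(inherits(spec, "xfct_loss_spec"))
  L <- l1_loss(pred, target)
  if (spec$alpha_ssim > 0)
    L <- L + spec$alpha_ssim * (1 - ssim(pred, target, data_range = 1))
  if (spec$beta_shape > 0) {
    Wm <- shape_weight_map(target)
    L <- L + spec$beta_shape * mean(Wm * abs(pred - target))
  }
  L
}

# analytic gradient of mean SSIM w.r.t. pred (x in ssim_map(pred, target))
ssim_grad_pred <- function(pred, target, data_range = 1, window_size = 11,
                           sigma = 1.5) {
  m <- ssim_map(pred, target, data_range, window_size, sigma)
  S <- m$S; mx <- m$mx; my <- m$my
  A1 <- m$A1; A2 <- m$A2; B1 <- m$B1; B2 <- m$B2
  P1 <- 2 * my * A2 / (B1 * B2) - 2 * mx * S / B1
  P2 <- -S / B2
  P3 <- 2 * A1 / (B1 * B2)
  k <- window_size
  g <- m$g
  # adjoint of the valid Gaussian correlation: conv with pad k-1
  adj <- function(P) {
    out <- cpp_conv2d_fw(array(P, c(nrow(P), ncol(P), 1L)),
                         matrix(as.vector(g), ncol = 1L), 0, k, 1L, k - 1L)
    matrix(out, nrow(P) + k - 1L, ncol(P) + k - 1L)
  }
  x <- as.matrix(pred); y <- as.matrix(target)
  gx <- adj(P1) + 2 * x * adj(P2) - 2 * adj(P2 * mx) +
    y * adj(P3) - adj(P3 * my)
  gx / length(S)
}

# gradient of compound_loss w.r.t. pred
compound_loss_grad <- function(pred, target, spec = loss_spec()) {
  n <- length(pred)
  g <- sign(pred - target) / n
  if (spec$alpha_ssim > 0)
    g <- g - spec$alpha_ssim * ssim_grad_pred(pred, target)
  if (spec$beta_shape > 0) {
    Wm <- shape_weight_map(target)
    g <- g + spec$beta_shape * Wm * sign(pred - target) / n
  }
  g
}
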