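#' Peak signal-to-noise ratio
#'
#' `10 * log10(data_range^2 / MSE)` in dB. Identical images return `Inf`
#' (rendered as the string `"inf"` in CSV tables).
#'
#' @param ref,test numeric matrices of identical shape.
#' @param data_range dynamic range of the data (1 for normalized images).
#' @return PSNR in dB.
#' @export
psnr <- function(ref, test, data_range = 1) {
  ref <- as.matrix(ref); test <- as.matrix(test)
  if (!identical(dim(ref), dim(test))) stop("psnr: shape mismatch")
  stopifnot(data_range > 0)
  mse <- mean((ref - test)^2)
  if (mse == 0) return(Inf)
  10 * log10(data_range^2 / mse)
}

#' Structural similarity index (mean SSIM)
#'
#' The local-statistics form of Wang et al.: Gaussian-weighted means,
#' variances and covariance in sliding windows (valid positions only),
#' combined as `[(2 mx my + C1)(2 sxy + C2)] / [(mx^2 + my^2 + C1)(sx^2 +
#' sy^2 + C2)]` with `C1 = (K1 R)^2`, `C2 = (K2 R)^2`, then averaged.
#'
#' @param ref,test numeric matrices of identical shape, at least as large as
#'   the window.
#' @param data_range dynamic range `R`.
#' @param window_size odd Gaussian window size (default 11).
#' @param sigma Gaussian window sigma (default 1.5).
#' @param K1,K2 stabilization constants (defaults 0.01, 0.03).
#' @return Mean SSIM in \[-1, 1\].
#' @export
ssim <- function(ref, test, data_range = 1, window_size = 11, sigma = 1.5,
                 K1 = 0.01, K2 = 0.03) {
  mean(ssim_map(ref, test, data_range, window_size, sigma, K1, K2)$S)
}

# Full per-window SSIM map plus the intermediates needed by the loss gradient.
ssim_map <- function(ref, test, data_range = 1, window_size = 11,
                     sigma = 1.5, K1 = 0.01, K2 = 0.03) {
  x <- as.matrix(ref); y <- as.matrix(test)
  if (!identical(dim(x), dim(y))) stop("ssim: shape mismatch")
  stopifnot(data_range > 0)
  if (nrow(x) < window_size || ncol(x) < window_size)
    stop("ssim: image smaller than the window")
  r <- (window_size - 1) / 2
  g <- gaussian_kernel_2d(sigma, r)
  filt <- function(m) {
    out <- cpp_conv2d_fw(array(m, c(nrow(m), ncol(m), 1L)),
                         matrix(as.vector(g), ncol = 1L), 0,
                         window_size, 1L, 0L)
    matrix(out, nrow(m) - window_size + 1L, ncol(m) - window_size + 1L)
  }
  C1 <- (K1 * data_range)^2; C2 <- (K2 * data_range)^2
  mx <- filt(x); my <- filt(y)
  sxx <- filt(x * x) - mx^2
  syy <- filt(y * y) - my^2
  sxy <- filt(x * y) - mx * my
  A1 <- 2 * mx * my + C1; A2 <- 2 * sxy + C2
  B1 <- mx^2 + my^2 + C1; B2 <- sxx + syy + C2
  list(S = A1 * A2 / (B1 * B2), mx = mx, my = my, A1 = A1, A2 = A2,
       B1 = B1, B2 = B2, g = g, window_size = window_size)
}

#' Per-pair metric record
#'
#' @param ref,test images; @param data_range dynamic range.
#' @return A one-row tibble with `psnr_db`, `ssim`, `data_range`.
#' @export
metric_record <- function(ref, test, data_range = 1) {
  tibble::tibble(psnr_db = psnr(ref, test, data_range),
                 ssim = ssim(ref, test, data_range),
                 data_range = data_range)
}
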