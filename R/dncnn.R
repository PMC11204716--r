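#' DnCNN configuration
#'
#' Residual-learning CNN baseline: the network predicts the noise component
#' and subtracts it from the input. First layer Conv3x3 + ReLU, middle layers
#' Conv3x3 + per-channel affine + ReLU, last layer Conv3x3 to one channel.
#' The per-channel affine is the inference-time form of batch normalization
#' (batch statistics are degenerate at the study's batch size of 2).
#'
#' @param depth total number of convolutional layers, >= 3 (default 17).
#' @param channels feature channels (default 64).
#' @return An object of class `xfct_dncnn_config`.
#' @export
dncnn_config <- function(depth = 17L, channels = 64L) {
  if (depth < 3) stop("DnCNN depth must be >= 3")
  structure(list(depth = as.integer(depth), channels = as.integer(channels)),
            class = "xfct_dncnn_config")
}

#' Desk-scale DnCNN preset (depth 7, 16 channels)
#' @export
dncnn_tiny_config <- function() dncnn_config(depth = 7L, channels = 16L)

#' Build a DnCNN model
#'
#' @param config a [dncnn_config()].
#' @param seed weight-initialization seed.
#' @return An object of class `xfct_dncnn`.
#' @export
dncnn_build <- function(config = dncnn_config(), seed = 1L) {
  stopifnot(inherits(config, "xfct_dncnn_config"))
  with_local_seed(seed, {
    m <- new.env(parent = emptyenv())
    m$config <- config
    m$seed <- as.integer(seed)
    ch <- config$channels
    m$first <- nn_conv(1L, ch, 3L)
    m$mid <- lapply(seq_len(config$depth - 2L), function(i)
      list(conv = nn_conv(ch, ch, 3L), aff = nn_affine(ch)))
    m$last <- nn_conv(ch, 1L, 3L, init = "small")
    units <- list(m$first)
    for (lay in m$mid) units <- c(units, list(lay$conv, lay$aff))
    units <- c(units, list(m$last))
    m$units <- units
    class(m) <- "xfct_dncnn"
    zero_grads(m$units)
    m
  })
}

#' DnCNN forward pass
#'
#' Returns `y - v_hat` where `v_hat` is the predicted noise; shape preserved.
#'
#' @param model an `xfct_dncnn`.
#' @param img H x W numeric matrix (single channel).
#' @return H x W numeric matrix.
#' @export
dncnn_forward <- function(model, img) {
  if (length(dim(img)) == 3) {
    if (dim(img)[3] != 1) stop("dncnn_forward expects a single-channel image")
    img <- img[, , 1]
  }
  img <- as.matrix(img)
  x <- array(img, c(nrow(img), ncol(img), 1L))
  a <- conv_fw(model$first, x)
  model$c_first <- a
  h <- relu(a)
  model$c_mid <- vector("list", length(model$mid))
  for (i in seq_along(model$mid)) {
    lay <- model$mid[[i]]
    z <- affine_fw(lay$aff, conv_fw(lay$conv, h))
    model$c_mid[[i]] <- z
    h <- relu(z)
  }
  v <- conv_fw(model$last, h)
  img - matrix(v, nrow(img), ncol(img))
}

dncnn_backward <- function(model, gy) {
  H <- nrow(gy); W <- ncol(gy)
  gv <- array(-gy, c(H, W, 1L))  # out = img - v
  g <- conv_bw(model$last, gv)
  for (i in rev(seq_along(model$mid))) {
    lay <- model$mid[[i]]
    g <- g * relu_grad(model$c_mid[[i]])
    g <- conv_bw(lay$conv, affine_bw(lay$aff, g))
  }
  g <- g * relu_grad(model$c_first)
  gx <- conv_bw(model$first, g)
  matrix(gx, H, W) + gy
}

#' Receptive field side length of a DnCNN configuration
#'
#' All layers use 3x3 kernels, so the receptive field is `2 * depth + 1`
#' (35 for the default depth 17).
#' @param config a [dncnn_config()].
#' @export
dncnn_receptive_field <- function(config) 2L * config$depth + 1L
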