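#' SC-UNet hyperparameter configuration
#'
#' Four-scale UNet with swin-conv (SC) blocks. Defaults follow the study
#' conditions: channels 64/128/256/512, four SC blocks per scale, 8x8
#' attention windows, 256x256 nominal input.
#'
#' @param in_channels input image channels (1 for grayscale XRF slices).
#' @param scale_channels integer vector of length 4, all even.
#' @param blocks_per_scale SC blocks per scale (encoder, bottleneck, decoder).
#' @param window_size Swin attention window side length.
#' @param head_dim per-head channel count of the attention branch.
#' @param mlp_ratio MLP expansion factor.
#' @param input_size_hint nominal (H, W).
#' @return An object of class `xfct_scunet_config`.
#' @export
scunet_config <- function(in_channels = 1L,
                          scale_channels = c(64L, 128L, 256L, 512L),
                          blocks_per_scale = 4L, window_size = 8L,
                          head_dim = 32L, mlp_ratio = 4,
                          input_size_hint = c(256L, 256L)) {
  if (length(scale_channels) != 4) stop("scale_channels must have length 4")
  if (any(scale_channels %% 2 != 0)) stop("scale channels must all be even")
  if (window_size <= 0) stop("window_size must be > 0")
  structure(list(in_channels = as.integer(in_channels),
                 scale_channels = as.integer(scale_channels),
                 blocks_per_scale = as.integer(blocks_per_scale),
                 window_size = as.integer(window_size),
                 head_dim = as.integer(head_dim), mlp_ratio = mlp_ratio,
                 input_size_hint = as.integer(input_size_hint)),
            class = "xfct_scunet_config")
}

#' Desk-scale tiny preset of the SC-UNet
#'
#' Channels 16/32/64/128, one SC block per scale, 4x4 windows. Intended for
#' fast experiments and tests on 32-128 px images.
#' @export
scunet_tiny_config <- function() {
  scunet_config(scale_channels = c(16L, 32L, 64L, 128L), blocks_per_scale = 1L,
                window_size = 4L, input_size_hint = c(64L, 64L))
}

# ---- SC block --------------------------------------------------------------
# z = Conv1x1(Concat(SwinT(x1), RConv(x2))) + x, (x1, x2) = Split(Conv1x1(x))

nn_sc_block <- function(C, win, shift, head_dim, mlp_ratio) {
  if (C %% 2 != 0) stop("SC block requires an even channel count")
  ch <- C %/% 2
  b <- new.env(parent = emptyenv())
  b$kind <- "sc_block"
  b$C <- C
  b$pin <- nn_conv(C, C, 1L, pad = 0L, init = "xavier")
  b$swin <- nn_swin(ch, win, shift, head_dim, mlp_ratio)
  b$ra <- nn_conv(ch, ch, 3L)
  b$rb <- nn_conv(ch, ch, 3L, init = "xavier")
  b$pout <- nn_conv(C, C, 1L, pad = 0L, init = "small")
  b
}

sc_units <- function(b) list(b$pin, b$swin, b$ra, b$rb, b$pout)

sc_fw <- function(b, x) {
  C <- b$C; ch <- C %/% 2
  t0 <- conv_fw(b$pin, x)
  x1 <- t0[, , seq_len(ch), drop = FALSE]
  x2 <- t0[, , ch + seq_len(ch), drop = FALSE]
  y1 <- swin_fw(b$swin, x1)
  a <- conv_fw(b$ra, x2)
  b$a <- a
  y2 <- x2 + conv_fw(b$rb, relu(a))
  cat12 <- array(c(y1, y2), c(dim(x)[1], dim(x)[2], C))
  conv_fw(b$pout, cat12) + x
}

sc_bw <- function(b, gz) {
  C <- b$C; ch <- C %/% 2
  gcat <- conv_bw(b$pout, gz)
  gy1 <- gcat[, , seq_len(ch), drop = FALSE]
  gy2 <- gcat[, , ch + seq_len(ch), drop = FALSE]
  gx1 <- swin_bw(b$swin, gy1)
  gr <- conv_bw(b$rb, gy2)
  gx2 <- gy2 + conv_bw(b$ra, gr * relu_grad(b$a))
  gt <- array(c(gx1, gx2), c(dim(gz)[1], dim(gz)[2], C))
  conv_bw(b$pin, gt) + gz
}

#' Apply one swin-conv block to a feature map
#'
#' The input is passed through a 1x1 convolution, split evenly into a
#' Swin-transformer branch and a residual-convolution branch, fused by a
#' 1x1 convolution and connected residually to the input. Shape-preserving.
#'
#' @param x H x W x C array with C even and H, W multiples of `window_size`.
#' @param window_size,shift,head_dim,mlp_ratio attention branch settings.
#' @param seed weight-initialization seed.
#' @param block optionally, a block environment from a previous call (its
#'   weights are reused; other arguments are then ignored).
#' @return List with `out` and `block`.
#' @export
sc_block <- function(x, window_size = 8, shift = 0, head_dim = 32,
                     mlp_ratio = 4, seed = 1L, block = NULL) {
  C <- dim(x)[3]
  if (C %% 2 != 0) stop("SC block requires an even channel count")
  if (is.null(block))
    block <- with_local_seed(seed,
      nn_sc_block(C, window_size, shift, head_dim, mlp_ratio))
  zero_grads(sc_units(block))
  list(out = sc_fw(block, x), block = block)
}

#' Apply a residual convolution block
#'
#' `x + Conv3x3(ReLU(Conv3x3(x)))` with zero padding at borders.
#'
#' @param x H x W x C array.
#' @param seed weight-initialization seed.
#' @param units optional list `(ra, rb)` of conv units to reuse.
#' @return List with `out` and `units`.
#' @export
rconv_block <- function(x, seed = 1L, units = NULL) {
  C <- dim(x)[3]
  if (is.null(units))
    units <- with_local_seed(seed, list(ra = nn_conv(C, C, 3L),
                                        rb = nn_conv(C, C, 3L)))
  zero_grads(units)
  a <- conv_fw(units$ra, x)
  list(out = x + conv_fw(units$rb, relu(a)), units = units)
}

# ---- full network ----------------------------------------------------------

#' Build an SC-UNet model
#'
#' Head 3x3 convolution, three encoder scales of SC blocks with 2x2
#' strided-convolution downscaling, SC blocks at the bottleneck, three
#' decoder scales with 2x2 transposed-convolution upscaling and additive
#' skip connections, tail 3x3 convolution back to one channel. Within each
#' run of SC blocks the attention shift alternates 0, window/2, 0, ...
#'
#' @param config an [scunet_config()].
#' @param seed weight-initialization seed (truncated normal for
#'   attention/MLP, Kaiming for convolutions).
#' @return An object of class `xfct_scunet`.
#' @export
scunet_build <- function(config = scunet_config(), seed = 1L) {
  stopifnot(inherits(config, "xfct_scunet_config"))
  cs <- config$scale_channels
  nb <- config$blocks_per_scale
  win <- config$window_size
  shift_of <- function(i) if (i %% 2 == 0) win %/% 2 else 0L
  with_local_seed(seed, {
    m <- new.env(parent = emptyenv())
    m$config <- config
    m$seed <- as.integer(seed)
    mk_blocks <- function(C) lapply(seq_len(nb), function(i)
      nn_sc_block(C, win, shift_of(i), config$head_dim, config$mlp_ratio))
    m$head <- nn_conv(config$in_channels, cs[1], 3L, init = "xavier")
    m$enc <- lapply(1:3, function(s) mk_blocks(cs[s]))
    m$down <- lapply(1:3, function(s) nn_conv(cs[s], cs[s + 1], 2L,
                                              stride = 2L, pad = 0L,
                                              init = "xavier"))
    m$mid <- mk_blocks(cs[4])
    m$up <- lapply(3:1, function(s) nn_tconv(cs[s + 1], cs[s]))
    m$dec <- lapply(3:1, function(s) mk_blocks(cs[s]))
    m$tail <- nn_conv(cs[1], config$in_channels, 3L, init = "xavier")
    units <- list(m$head)
    for (s in 1:3) units <- c(units, unlist(lapply(m$enc[[s]], sc_units)),
                              list(m$down[[s]]))
    units <- c(units, unlist(lapply(m$mid, sc_units)))
    for (k in 1:3) units <- c(units, list(m$up[[k]]),
                              unlist(lapply(m$dec[[k]], sc_units)))
    units <- c(units, list(m$tail))
    m$units <- units
    class(m) <- "xfct_scunet"
    zero_grads(m$units)
    m
  })
}

run_blocks_fw <- function(blocks, x) {
  for (b in blocks) x <- sc_fw(b, x)
  x
}

run_blocks_bw <- function(blocks, g) {
  for (b in rev(blocks)) g <- sc_bw(b, g)
  g
}

# reflect-pad an image matrix to multiples of `mult`, centered
pad_to_multiple <- function(img, mult) {
  H <- nrow(img); W <- ncol(img)
  Hp <- mult * ceiling(H / mult); Wp <- mult * ceiling(W / mult)
  pt <- (Hp - H) %/% 2; pb <- Hp - H - pt
  pl <- (Wp - W) %/% 2; pr <- Wp - W - pl
  list(img = reflect_pad(img, pt, pb, pl, pr), pt = pt, pl = pl, H = H, W = W)
}

#' SC-UNet forward pass
#'
#' Accepts any single-channel image; sizes not divisible by
#' `8 * window_size` are reflect-padded and cropped back, so the output
#' shape always equals the input shape.
#'
#' @param model an `xfct_scunet` from [scunet_build()].
#' @param img H x W numeric matrix (or H x W x 1 array).
#' @return H x W numeric matrix.
#' @export
scunet_forward <- function(model, img) {
  if (length(dim(img)) == 3) {
    if (dim(img)[3] != 1) stop("scunet_forward expects a single-channel image")
    img <- img[, , 1]
  }
  img <- as.matrix(img)
  mult <- 8L * model$config$window_size
  pd <- pad_to_multiple(img, mult)
  x <- array(pd$img, c(nrow(pd$img), ncol(pd$img), 1L))
  h0 <- conv_fw(model$head, x)
  e1 <- run_blocks_fw(model$enc[[1]], h0)
  d1 <- conv_fw(model$down[[1]], e1)
  e2 <- run_blocks_fw(model$enc[[2]], d1)
  d2 <- conv_fw(model$down[[2]], e2)
  e3 <- run_blocks_fw(model$enc[[3]], d2)
  d3 <- conv_fw(model$down[[3]], e3)
  mb <- run_blocks_fw(model$mid, d3)
  u3 <- tconv_fw(model$up[[1]], mb) + e3
  o3 <- run_blocks_fw(model$dec[[1]], u3)
  u2 <- tconv_fw(model$up[[2]], o3) + e2
  o2 <- run_blocks_fw(model$dec[[2]], u2)
  u1 <- tconv_fw(model$up[[3]], o2) + e1
  o1 <- run_blocks_fw(model$dec[[3]], u1)
  out <- conv_fw(model$tail, o1)
  model$pad <- pd
  matrix(out[pd$pt + seq_len(pd$H), pd$pl + seq_len(pd$W), 1],
         pd$H, pd$W)
}

# backward through the whole net; gy is the gradient w.r.t. the cropped output
scunet_backward <- function(model, gy) {
  pd <- model$pad
  Hp <- nrow(pd$img); Wp <- ncol(pd$img)
  g <- array(0, c(Hp, Wp, 1L))
  g[pd$pt + seq_len(pd$H), pd$pl + seq_len(pd$W), 1] <- gy
  g_o1 <- conv_bw(model$tail, g)
  g_u1 <- run_blocks_bw(model$dec[[3]], g_o1)
  g_o2 <- tconv_bw(model$up[[3]], g_u1)
  g_u2 <- run_blocks_bw(model$dec[[2]], g_o2)
  g_o3 <- tconv_bw(model$up[[2]], g_u2)
  g_u3 <- run_blocks_bw(model$dec[[1]], g_o3)
  g_mb <- tconv_bw(model$up[[1]], g_u3)
  g_d3 <- run_blocks_bw(model$mid, g_mb)
  g_e3 <- g_u3 + conv_bw(model$down[[3]], g_d3)
  g_d2 <- run_blocks_bw(model$enc[[3]], g_e3)
  g_e2 <- g_u2 + conv_bw(model$down[[2]], g_d2)
  g_d1 <- run_blocks_bw(model$enc[[2]], g_e2)
  g_e1 <- g_u1 + conv_bw(model$down[[1]], g_d1)
  g_h0 <- run_blocks_bw(model$enc[[1]], g_e1)
  g_x <- conv_bw(model$head, g_h0)
  # gradient w.r.t. the unpadded input (rarely needed; completeness)
  matrix(g_x[pd$pt + seq_len(pd$H), pd$pl + seq_len(pd$W), 1], pd$H, pd$W)
}

#' Analytic SC-UNet parameter count
#'
#' Closed-form count as a function of the configuration; used to cross-check
#' the materialized model.
#'
#' @param config an [scunet_config()].
#' @return Integer parameter count.
#' @export
scunet_param_count <- function(config) {
  cs <- config$scale_channels; nb <- config$blocks_per_scale
  cin <- config$in_channels; mr <- config$mlp_ratio
  conv_n <- function(ci, co, k) k * k * ci * co + co
  swin_n <- function(c) {
    hid <- round(c * mr)
    2 * c +                 # ln1
      c * 3 * c + 3 * c +   # qkv
      c * c + c +           # proj
      2 * c +               # ln2
      c * hid + hid + hid * c + c
  }
  sc_n <- function(C) {
    ch <- C / 2
    conv_n(C, C, 1) + swin_n(ch) + 2 * conv_n(ch, ch, 3) + conv_n(C, C, 1)
  }
  total <- conv_n(cin, cs[1], 3) + conv_n(cs[1], cin, 3)
  for (s in 1:3) total <- total +
    2 * nb * sc_n(cs[s]) +                 # encoder + decoder blocks
    conv_n(cs[s], cs[s + 1], 2) +          # down
    4 * cs[s + 1] * cs[s] + cs[s]          # up (tconv)
  total <- total + nb * sc_n(cs[4])        # bottleneck
  as.integer(round(total))
}
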