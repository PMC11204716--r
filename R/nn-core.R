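# Minimal neural-network primitives with hand-written backward passes.
# A "unit" is an environment holding parameters (fields named in $pnames),
# gradient accumulators (g<name>) and forward caches. Heavy lifting
# (im2col convolution, window attention) is in C++.

new_unit <- function(kind, pnames) {
  u <- new.env(parent = emptyenv())
  u$kind <- kind
  u$pnames <- pnames
  u
}

trunc_normal <- function(n, sd = 0.02) {
  x <- rnorm(n, 0, sd)
  pmin(pmax(x, -2 * sd), 2 * sd)
}

# ---- convolution -----------------------------------------------------------

# init: kaiming for ReLU-followed convs, xavier for linear ones, small
# (0.1 x xavier) for residual-branch fusions so deep residual stacks start
# close to identity while keeping gradient flow to every branch
nn_conv <- function(cin, cout, k, stride = 1L, pad = (k - 1L) %/% 2L,
                    init = c("kaiming", "xavier", "small", "zero")) {
  init <- match.arg(init)
  u <- new_unit("conv", c("W", "b"))
  u$cin <- cin; u$cout <- cout; u$k <- as.integer(k)
  u$stride <- as.integer(stride); u$pad <- as.integer(pad)
  fan_in <- k * k * cin
  sd <- switch(init, kaiming = sqrt(2 / fan_in), xavier = sqrt(1 / fan_in),
               small = 0.1 * sqrt(1 / fan_in), zero = 0)
  u$W <- matrix(rnorm(fan_in * cout, 0, sd), fan_in, cout)
  u$b <- numeric(cout)
  u
}

conv_fw <- function(u, x) {
  u$x <- x
  cpp_conv2d_fw(x, u$W, u$b, u$k, u$stride, u$pad)
}

conv_bw <- function(u, gy) {
  r <- cpp_conv2d_bw(u$x, u$W, gy, u$k, u$stride, u$pad)
  u$gW <- u$gW + r$gW
  u$gb <- u$gb + as.vector(r$gb)
  r$gx
}

# ---- 2x2 stride-2 transposed convolution ----------------------------------

nn_tconv <- function(cin, cout) {
  u <- new_unit("tconv", c("W", "b"))
  u$cin <- cin; u$cout <- cout
  fan_in <- cin  # each output pixel receives one tap per input channel
  u$W <- matrix(rnorm(4 * cin * cout, 0, sqrt(1 / fan_in)), 4 * cin, cout)
  u$b <- numeric(cout)
  u
}

tconv_fw <- function(u, x) {
  u$x <- x
  cpp_tconv2x2_fw(x, u$W, u$b)
}

tconv_bw <- function(u, gy) {
  r <- cpp_tconv2x2_bw(u$x, u$W, gy)
  u$gW <- u$gW + r$gW
  u$gb <- u$gb + as.vector(r$gb)
  r$gx
}

# ---- per-channel affine (inference-form normalization) ---------------------

nn_affine <- function(c) {
  u <- new_unit("affine", c("g", "b"))
  u$g <- rep(1, c); u$b <- numeric(c)
  u
}

affine_fw <- function(u, x) {
  u$x <- x
  C <- dim(x)[3]
  sweep(sweep(x, 3, u$g, "*"), 3, u$b, "+")
}

affine_bw <- function(u, gy) {
  u$gg <- u$gg + apply(gy * u$x, 3, sum)
  u$gb <- u$gb + apply(gy, 3, sum)
  sweep(gy, 3, u$g, "*")
}

# ---- activations (stateless; caches kept by caller) ------------------------

relu <- function(x) { x[x < 0] <- 0; x }
relu_grad <- function(x) (x > 0) * 1

gelu <- function(x) x * pnorm(x)
gelu_grad <- function(x) pnorm(x) + x * dnorm(x)

# ---- layer norm over the channel axis of [N, C] token matrices -------------

ln_fw <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  N <- nrow(X)
  y <- xhat * rep(g, each = N) + rep(b, each = N)
  list(y = y, xhat = xhat, inv = inv)
}

ln_bw <- function(cache, g, gy) {
  N <- nrow(gy)
  dxhat <- gy * rep(g, each = N)
  gg <- colSums(gy * cache$xhat)
  gb <- colSums(gy)
  dx <- cache$inv *
    (dxhat - rowMeans(dxhat) - cache$xhat * rowMeans(dxhat * cache$xhat))
  list(dx = dx, gg = gg, gb = gb)
}

# ---- grads / optimizer plumbing --------------------------------------------

zero_grads <- function(units) {
  for (u in units)
    for (nm in u$pnames) {
      p <- u[[nm]]
      z <- p; z[] <- 0
      u[[paste0("g", nm)]] <- z
    }
  invisible(NULL)
}

adam_init <- function(units) {
  opt <- new.env(parent = emptyenv())
  opt$t <- 0L
  opt$beta1 <- 0.9; opt$beta2 <- 0.999; opt$eps <- 1e-8
  for (u in units)
    for (nm in u$pnames) {
      z <- u[[nm]]; z[] <- 0
      u[[paste0("m_", nm)]] <- z
      u[[paste0("v_", nm)]] <- z
    }
  opt
}

adam_step <- function(units, opt, lr) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  bc1 <- 1 - b1^opt$t; bc2 <- 1 - b2^opt$t
  for (u in units)
    for (nm in u$pnames) {
      g <- u[[paste0("g", nm)]]
      m <- b1 * u[[paste0("m_", nm)]] + (1 - b1) * g
      v <- b2 * u[[paste0("v_", nm)]] + (1 - b2) * g * g
      u[[paste0("m_", nm)]] <- m
      u[[paste0("v_", nm)]] <- v
      u[[nm]] <- u[[nm]] - lr * (m / bc1) / (sqrt(v / bc2) + opt$eps)
    }
  invisible(NULL)
}

#' Extract all weights of a model as a flat named list
#'
#' @param model an `xfct_scunet` or `xfct_dncnn` model.
#' @return Named list of numeric arrays; names are `unit<i>.<param>`.
#' @export
get_weights <- function(model) {
  w <- list()
  for (i in seq_along(model$units)) {
    u <- model$units[[i]]
    for (nm in u$pnames) w[[sprintf("unit%03d.%s", i, nm)]] <- u[[nm]]
  }
  w
}

#' Load weights produced by [get_weights()] back into a model
#'
#' @param model target model of the same architecture.
#' @param weights named list from [get_weights()].
#' @export
set_weights <- function(model, weights) {
  expect <- names(get_weights(model))
  if (!identical(sort(expect), sort(names(weights))))
    stop("weight names do not match the model architecture")
  for (i in seq_along(model$units)) {
    u <- model$units[[i]]
    for (nm in u$pnames) {
      w <- weights[[sprintf("unit%03d.%s", i, nm)]]
      if (length(w) != length(u[[nm]]))
        stop("weight shape mismatch on ", sprintf("unit%03d.%s", i, nm))
      p <- u[[nm]]; p[] <- w
      u[[nm]] <- p
    }
  }
  invisible(model)
}

#' Total number of trainable parameters
#' @param model a network model.
#' @export
count_params <- function(model) {
  sum(vapply(model$units, function(u)
    sum(vapply(u$pnames, function(nm) length(u[[nm]]), 0)), 0))
}

# deterministic fingerprint of all weights (for checkpoint identity checks)
weights_fingerprint <- function(weights) {
  v <- unlist(weights, use.names = FALSE)
  c(n = length(v), sum = sum(v), sumsq = sum(v * v),
    dot = sum(v * seq_along(v)))
}
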