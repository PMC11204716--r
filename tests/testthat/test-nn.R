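# Numerical gradient checks for the hand-written backward passes.

numgrad_input <- function(lossf, x, g, n = 15, eps = 1e-5, tol = 1e-6) {
  set.seed(1)
  for (k in sample(length(x), n)) {
    xp <- x; xp[k] <- xp[k] + eps
    xm <- x; xm[k] <- xm[k] - eps
    num <- (lossf(xp) - lossf(xm)) / (2 * eps)
    expect_lt(abs(num - g[k]), tol * max(1, abs(num)))
  }
}

test_that("convolution and transposed convolution gradients are exact", {
  ns <- asNamespace("xfctdn")
  set.seed(2)
  u <- ns$with_local_seed(3, ns$nn_conv(3L, 4L, 3L))
  ns$zero_grads(list(u))
  x <- array(rnorm(10 * 10 * 3), c(10, 10, 3))
  R <- array(rnorm(10 * 10 * 4), c(10, 10, 4))
  ns$conv_fw(u, x)
  gx <- ns$conv_bw(u, R)
  numgrad_input(function(z) sum(ns$conv_fw(u, z) * R), x, gx)
  # weight gradient at a few entries
  eps <- 1e-6
  for (k in sample(length(u$W), 8)) {
    w0 <- u$W[k]
    u$W[k] <- w0 + eps; lp <- sum(ns$conv_fw(u, x) * R)
    u$W[k] <- w0 - eps; lm <- sum(ns$conv_fw(u, x) * R)
    u$W[k] <- w0
    expect_lt(abs((lp - lm) / (2 * eps) - u$gW[k]), 1e-5)
  }
  ut <- ns$with_local_seed(4, ns$nn_tconv(3L, 2L))
  ns$zero_grads(list(ut))
  Rt <- array(rnorm(20 * 20 * 2), c(20, 20, 2))
  ns$tconv_fw(ut, x)
  gxt <- ns$tconv_bw(ut, Rt)
  numgrad_input(function(z) sum(ns$tconv_fw(ut, z) * Rt), x, gxt)
})

test_that("swin block backward matches numerical gradients", {
  ns <- asNamespace("xfctdn")
  u <- ns$with_local_seed(7, ns$nn_swin(4L, 4L, 2L, head_dim = 2L,
                                        mlp_ratio = 2))
  ns$zero_grads(list(u))
  set.seed(5)
  x <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  R <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  ns$swin_fw(u, x)
  g <- ns$swin_bw(u, R)
  lossf <- function(z) sum(ns$swin_fw(u, z) * R)
  numgrad_input(lossf, x, g, tol = 1e-5)
  eps <- 1e-5
  for (nm in c("Wqkv", "Wo", "W1", "W2", "ln1_g", "ln2_b")) {
    p <- u[[nm]]; gp <- u[[paste0("g", nm)]]
    for (k in sample(length(p), min(6, length(p)))) {
      p0 <- p[k]
      u[[nm]][k] <- p0 + eps; lp <- lossf(x)
      u[[nm]][k] <- p0 - eps; lm <- lossf(x)
      u[[nm]][k] <- p0
      expect_lt(abs((lp - lm) / (2 * eps) - gp[k]), 1e-6)
    }
  }
})

test_that("attention rows are normalized and the shift path is deterministic", {
  ns <- asNamespace("xfctdn")
  u <- ns$with_local_seed(9, ns$nn_swin(4L, 4L, 2L, head_dim = 4L,
                                        mlp_ratio = 2))
  ns$zero_grads(list(u))
  set.seed(6)
  x <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  y1 <- ns$swin_fw(u, x)
  for (h in seq_along(u$cache_h)) {
    A <- u$cache_h[[h]]$A
    sums <- apply(A, c(1, 3), sum)
    expect_true(all(abs(sums - 1) < 1e-6))
  }
  # constant image through the shifted path: two runs identical
  xc <- array(0.5, c(8, 8, 4))
  expect_identical(ns$swin_fw(u, xc), ns$swin_fw(u, xc))
  expect_error(swin_transformer_block(x, window_size = 0), "window_size")
})

test_that("rconv block is residual and its conv path is linear", {
  ns <- asNamespace("xfctdn")
  set.seed(8)
  x <- array(rnorm(12 * 12 * 4), c(12, 12, 4))
  r <- rconv_block(x, seed = 3)
  expect_identical(dim(r$out), dim(x))
  # zeroing the second conv gives the identity
  r$units$rb$W[] <- 0; r$units$rb$b[] <- 0
  r2 <- rconv_block(x, units = r$units)
  expect_identical(r2$out, x)
  # with the ReLU bypassed, the conv composition is a linear operator
  ua <- r$units$ra; ub <- r$units$rb
  ub$W <- matrix(rnorm(length(ub$W), 0, 0.1), nrow(ub$W), ncol(ub$W))
  ub$b[] <- 0; ua$b[] <- 0
  lin <- function(z) ns$conv_fw(ub, ns$conv_fw(ua, z))
  expect_equal(lin(2 * x), 2 * lin(x), tolerance = 1e-12)
})
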