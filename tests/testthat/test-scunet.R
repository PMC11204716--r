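test_that("configuration invariants are enforced", {
  expect_error(scunet_config(scale_channels = c(64, 128, 256)), "length 4")
  expect_error(scunet_config(scale_channels = c(63, 128, 256, 512)), "even")
  expect_error(scunet_config(window_size = 0), "window_size")
  expect_equal(scunet_config()$scale_channels, c(64L, 128L, 256L, 512L))
  expect_equal(scunet_config()$blocks_per_scale, 4L)
})

test_that("sc_block splits channels evenly and preserves shape", {
  ns <- asNamespace("xfctdn")
  for (C in c(8L, 16L)) for (side in c(16L, 32L)) {
    x <- array(rnorm(side * side * C), c(side, side, C))
    r <- sc_block(x, window_size = 4, seed = 2)
    expect_identical(dim(r$out), dim(x))
    expect_equal(r$block$swin$C, C %/% 2)
  }
  x <- array(rnorm(16 * 16 * 3), c(16, 16, 3))
  expect_error(sc_block(x, window_size = 4), "even")
})

test_that("forward pass preserves arbitrary input shapes via pad-and-crop", {
  m <- scunet_build(tiny_test_scunet_config(), seed = 3)
  for (side in c(32L, 70L)) {
    img <- matrix(runif(side * side), side, side)
    out <- scunet_forward(m, img)
    expect_identical(dim(out), c(side, side))
    expect_true(all(is.finite(out)))
  }
  expect_error(scunet_forward(m, array(0, c(32, 32, 2))), "single-channel")
})

test_that("forward pass is deterministic for fixed weights", {
  m <- scunet_build(tiny_test_scunet_config(), seed = 4)
  img <- matrix(runif(32 * 32), 32, 32)
  expect_identical(scunet_forward(m, img), scunet_forward(m, img))
})

test_that("parameter count matches the analytic closed form and scales ~4x", {
  cfg <- scunet_tiny_config()
  m <- scunet_build(cfg, seed = 1)
  expect_equal(count_params(m), scunet_param_count(cfg))
  half <- scunet_config(scale_channels = cfg$scale_channels %/% 2,
                        blocks_per_scale = 1L, window_size = 4L)
  ratio <- scunet_param_count(cfg) / scunet_param_count(half)
  expect_gt(ratio, 3.4)
  expect_lt(ratio, 4.6)
  expect_equal(scunet_param_count(scunet_config()),
               count_params(scunet_build(scunet_config(), seed = 1)))
})

test_that("gradient flows to every unit on a random batch", {
  ns <- asNamespace("xfctdn")
  m <- scunet_build(tiny_test_scunet_config(), seed = 5)
  img <- matrix(runif(32 * 32), 32, 32)
  targ <- matrix(runif(32 * 32), 32, 32)
  ns$zero_grads(m$units)
  out <- scunet_forward(m, img)
  ns$scunet_backward(m, ns$compound_loss_grad(out, targ, loss_spec(0, 0)))
  for (u in m$units) {
    unit_has_grad <- FALSE
    for (nm in u$pnames) {
      g <- u[[paste0("g", nm)]]
      expect_true(all(is.finite(g)))
      if (any(g != 0)) unit_has_grad <- TRUE
    }
    # no dead branch: every unit receives gradient
    expect_true(unit_has_grad)
  }
})

test_that("whole-network gradient agrees with finite differences", {
  ns <- asNamespace("xfctdn")
  m <- scunet_build(tiny_test_scunet_config(), seed = 6)
  img <- matrix(runif(32 * 32), 32, 32)
  R <- matrix(rnorm(32 * 32), 32, 32)
  ns$zero_grads(m$units)
  scunet_forward(m, img)
  gin <- ns$scunet_backward(m, R)
  lossf <- function(z) sum(scunet_forward(m, z) * R)
  set.seed(2)
  eps <- 1e-5
  for (k in sample(length(img), 8)) {
    ip <- img; ip[k] <- ip[k] + eps
    im <- img; im[k] <- im[k] - eps
    num <- (lossf(ip) - lossf(im)) / (2 * eps)
    expect_lt(abs(num - gin[k]), 1e-4 * max(1, abs(num)))
  }
})

test_that("checkpoints round-trip weights exactly", {
  ns <- asNamespace("xfctdn")
  m <- scunet_build(tiny_test_scunet_config(), seed = 7)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(m, path, meta = list(note = "test"))
  m2 <- load_checkpoint(path)
  expect_identical(ns$weights_fingerprint(get_weights(m)),
                   ns$weights_fingerprint(get_weights(m2)))
  img <- matrix(runif(32 * 32), 32, 32)
  expect_identical(scunet_forward(m, img), scunet_forward(m2, img))
})
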