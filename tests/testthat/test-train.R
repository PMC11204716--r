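test_that("learning-rate history follows the closed-form schedule exactly", {
  cfg <- train_config(lr0 = 1e-4, decay = 0.9, epochs = 12)
  expect_equal(lr_schedule(cfg), 1e-4 * 0.9^(0:11), tolerance = 1e-15)
  expect_error(train_config(lr0 = 0), "lr0")
  expect_error(train_config(decay = 1.2), "decay")
  expect_error(train_config(epochs = 0), "epochs")
})

test_that("training overfits a single pair and records a faithful history", {
  ds <- small_train_dataset()
  pair <- dataset_pairs(ds, "train")[[1]]
  m <- scunet_build(tiny_test_scunet_config(), seed = 2)
  cfg <- train_config(lr0 = 5e-3, decay = 0.995, epochs = 300, batch_size = 1,
                      loss = loss_spec(0, 0), seed = 3)
  fit <- train_denoiser(m, list(pair), list(), cfg)
  h <- fit$history
  expect_equal(nrow(h), 300)
  expect_equal(h$lr, 5e-3 * 0.995^(0:299), tolerance = 1e-12)
  expect_lt(h$train_loss[300], 0.1 * h$train_loss[1])
  expect_s3_class(tidy(h), "tbl_df")
  expect_equal(glance(h)$epochs, 300)
})

test_that("two runs with one seed produce identical loss sequences", {
  ds <- small_train_dataset()
  pairs <- dataset_pairs(ds, "train")[1:4]
  run <- function() {
    m <- scunet_build(tiny_test_scunet_config(), seed = 5)
    train_denoiser(m, pairs, list(), train_config(lr0 = 1e-3, epochs = 2,
                                                  seed = 9))$history
  }
  h1 <- run(); h2 <- run()
  expect_identical(h1$train_loss, h2$train_loss)
})

test_that("fine-tuning starts from the checkpoint weights, never re-initialized", {
  ns <- asNamespace("xfctdn")
  m1 <- scunet_build(tiny_test_scunet_config(), seed = 11)
  ck <- tempfile(fileext = ".rds")
  save_checkpoint(m1, ck)
  m2 <- scunet_build(tiny_test_scunet_config(), seed = 99)
  expect_false(identical(ns$weights_fingerprint(get_weights(m2)),
                         ns$weights_fingerprint(get_weights(m1))))
  init_from_checkpoint(m2, ck)
  expect_identical(ns$weights_fingerprint(get_weights(m2)),
                   ns$weights_fingerprint(get_weights(m1)))
  # architecture mismatch is refused
  md <- dncnn_build(dncnn_tiny_config(), seed = 1)
  expect_error(init_from_checkpoint(md, ck), "architecture")
  # config mismatch is refused
  m3 <- scunet_build(scunet_tiny_config(), seed = 1)
  expect_error(init_from_checkpoint(m3, ck), "mismatch")
  expect_error(train_denoiser(m2, list(), list(),
                              train_config(epochs = 1)), "empty")
})

test_that("the shared pipeline also trains the DnCNN baseline", {
  ds <- small_train_dataset()
  pairs <- dataset_pairs(ds, "train")[1:2]
  m <- dncnn_build(dncnn_tiny_config(), seed = 6)
  fit <- train_denoiser(m, pairs, list(),
                        train_config(lr0 = 1e-3, epochs = 2, batch_size = 2,
                                     seed = 6))
  expect_equal(nrow(fit$history), 2)
  expect_true(all(is.finite(fit$history$train_loss)))
  out <- denoise_image(fit$model, pairs[[1]]$noisy)
  expect_identical(dim(out), dim(pairs[[1]]$noisy))
})

test_that("validation tracking restores the best-PSNR weights", {
  ds <- small_train_dataset()
  tr <- dataset_pairs(ds, "train")[1:4]
  va <- dataset_pairs(ds, "test")[1:2]
  m <- scunet_build(tiny_test_scunet_config(), seed = 4)
  fit <- train_denoiser(m, tr, va, train_config(lr0 = 1e-3, epochs = 2,
                                                seed = 2))
  expect_true(all(is.finite(fit$history$val_psnr)))
  expect_true(all(fit$history$val_ssim <= 1))
  # restored weights reproduce the best epoch's validation PSNR
  best <- max(fit$history$val_psnr)
  got <- mean(vapply(va, function(p)
    psnr(p$clean, denoise_image(fit$model, p$noisy)), 0))
  expect_equal(got, best, tolerance = 1e-10)
})
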