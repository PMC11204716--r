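# Shared small fixtures, built once per test run.

.fixtures <- new.env()

# 2 phantoms x full (bin x level) grid at 32x32: 72 pairs after augmentation
small_grid_dataset <- function() {
  if (is.null(.fixtures$grid)) {
    specs <- lapply(1:2, function(i)
      random_phantom_spec(c(32L, 32L), seed = child_seed(11, i)))
    .fixtures$grid <- build_dataset(specs, seed = 11)
  }
  .fixtures$grid
}

# single-category 32x32 dataset for quick training tests
small_train_dataset <- function() {
  if (is.null(.fixtures$train)) {
    specs <- lapply(1:4, function(i)
      random_phantom_spec(c(32L, 32L), seed = child_seed(21, i)))
    .fixtures$train <- build_dataset(specs, noise_levels = 75,
                                     bin_widths = 0.5, seed = 21)
  }
  .fixtures$train
}

tiny_test_scunet_config <- function() {
  scunet_config(scale_channels = c(4L, 8L, 8L, 8L), blocks_per_scale = 1L,
                window_size = 4L, head_dim = 4L, mlp_ratio = 2,
                input_size_hint = c(32L, 32L))
}
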