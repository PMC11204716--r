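#' Training configuration
#'
#' Defaults follow the study protocol: Adam, learning rate 1e-4 decaying by
#' 0.9 per epoch, 40 epochs, batch size 2. The protocol first trains at the
#' 25% noise level and then fine-tunes for the other levels; fine-tuning is
#' expressed by `finetune_from`, which initializes weights from an existing
#' checkpoint instead of random initialization.
#'
#' @param lr0 initial learning rate, > 0.
#' @param decay per-epoch multiplicative learning-rate decay in (0, 1].
#' @param epochs number of epochs, >= 1.
#' @param batch_size minibatch size.
#' @param loss a [loss_spec()].
#' @param seed RNG seed for shuffling (and weight init when the model is
#'   built by the caller with the same seed).
#' @param finetune_from optional checkpoint path to initialize from.
#' @return An object of class `xfct_train_config`.
#' @export
train_config <- function(lr0 = 1e-4, decay = 0.9, epochs = 40L,
                         batch_size = 2L, loss = loss_spec(), seed = 1L,
                         finetune_from = NULL) {
  if (lr0 <= 0) stop("lr0 must be > 0")
  if (decay <= 0 || decay > 1) stop("decay must lie in (0, 1]")
  if (epochs < 1) stop("epochs must be >= 1")
  structure(list(lr0 = lr0, decay = decay, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), loss = loss,
                 seed = as.integer(seed), finetune_from = finetune_from),
            class = "xfct_train_config")
}

#' Closed-form learning-rate schedule
#'
#' `lr(e) = lr0 * decay^e` with `e` the zero-based epoch index.
#' @param config an [train_config()].
#' @export
lr_schedule <- function(config) {
  config$lr0 * config$decay^(seq_len(config$epochs) - 1)
}

# forward/backward dispatch over the two learned architectures
net_forward <- function(model, img) {
  if (inherits(model, "xfct_scunet")) scunet_forward(model, img)
  else if (inherits(model, "xfct_dncnn")) dncnn_forward(model, img)
  else stop("unknown model class")
}

net_backward <- function(model, gy) {
  if (inherits(model, "xfct_scunet")) scunet_backward(model, gy)
  else if (inherits(model, "xfct_dncnn")) dncnn_backward(model, gy)
  else stop("unknown model class")
}

#' Denoise a single image with a trained model
#'
#' Forward pass followed by clipping into \[0, 1\].
#' @param model a trained model.
#' @param img H x W matrix in \[0, 1\].
#' @export
denoise_image <- function(model, img) clip01(net_forward(model, img))

#' Save a model checkpoint
#'
#' Single-file archive holding the architecture class, configuration,
#' weights and training metadata.
#'
#' @param model model to save.
#' @param path destination file.
#' @param meta optional metadata list (seed, epochs, loss weights, ...).
#' @export
save_checkpoint <- function(model, path, meta = list()) {
  obj <- list(arch = class(model)[1], config = model$config,
              weights = get_weights(model), meta = meta)
  saveRDS(obj, path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' Rebuilds the architecture from the stored configuration and restores the
#' weights.
#' @param path checkpoint file written by [save_checkpoint()].
#' @return The restored model; metadata in attribute `"meta"`.
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  model <- switch(obj$arch,
                  xfct_scunet = scunet_build(obj$config, seed = 1L),
                  xfct_dncnn = dncnn_build(obj$config, seed = 1L),
                  stop("unknown checkpoint architecture ", obj$arch))
  set_weights(model, obj$weights)
  attr(model, "meta") <- obj$meta
  model
}

#' Initialize a model's weights from a checkpoint (fine-tuning start)
#'
#' Loads the checkpoint weights into `model` in place; never re-initializes.
#' Errors on architecture or shape mismatch.
#'
#' @param model target model.
#' @param path checkpoint file written by [save_checkpoint()].
#' @export
init_from_checkpoint <- function(model, path) {
  ck <- readRDS(path)
  if (!identical(ck$arch, class(model)[1]))
    stop("fine-tune checkpoint architecture mismatch")
  tryCatch(set_weights(model, ck$weights),
           error = function(e) stop("fine-tune checkpoint/config mismatch: ",
                                    conditionMessage(e)))
  invisible(model)
}

#' Train a denoising network
#'
#' Adam optimization of the compound loss under the exponential
#' learning-rate schedule, with seeded shuffling, per-epoch validation
#' PSNR/SSIM, and tracking of the best-validation-PSNR weights. When
#' `config$finetune_from` is set, weights are initialized from that
#' checkpoint (never re-initialized); the study's 25%-noise-first protocol
#' is two successive calls, the second fine-tuning from the first's
#' checkpoint.
#'
#' @param model an `xfct_scunet` or `xfct_dncnn` (freshly built or loaded).
#' @param train_pairs non-empty list of [image_pair()]s.
#' @param val_pairs list of validation pairs (may be empty; validation
#'   metrics are then `NA` and the final weights are kept).
#' @param config an [train_config()].
#' @param checkpoint_path optional path; the best weights are saved there.
#' @param verbose print per-epoch progress.
#' @return List with `model` (weights set to the best-validation state, or
#'   final state if no validation pairs), `history` (tibble: epoch, lr,
#'   train_loss, val_psnr, val_ssim) of class `xfct_history`, and
#'   `best_weights`.
#' @export
train_denoiser <- function(model, train_pairs, val_pairs = list(),
                           config = train_config(), checkpoint_path = NULL,
                           verbose = FALSE) {
  if (!length(train_pairs)) stop("empty training set")
  stopifnot(inherits(config, "xfct_train_config"))
  if (!is.null(config$finetune_from))
    init_from_checkpoint(model, config$finetune_from)
  opt <- adam_init(model$units)
  lrs <- lr_schedule(config)
  n <- length(train_pairs)
  hist <- vector("list", config$epochs)
  best_psnr <- -Inf
  best_weights <- get_weights(model)
  have_val <- length(val_pairs) > 0
  for (e in seq_len(config$epochs)) {
    ord <- with_local_seed(child_seed(config$seed, 1000L + e), sample.int(n))
    losses <- numeric(0)
    i <- 1L
    while (i <= n) {
      js <- ord[i:min(i + config$batch_size - 1L, n)]
      zero_grads(model$units)
      bl <- 0
      for (j in js) {
        p <- train_pairs[[j]]
        out <- net_forward(model, p$noisy)
        bl <- bl + compound_loss(out, p$clean, config$loss)
        gy <- compound_loss_grad(out, p$clean, config$loss) / length(js)
        net_backward(model, gy)
      }
      adam_step(model$units, opt, lrs[e])
      losses <- c(losses, bl / length(js))
      i <- i + config$batch_size
    }
    vp <- vs <- NA_real_
    if (have_val) {
      rec <- vapply(val_pairs, function(p) {
        dn <- denoise_image(model, p$noisy)
        c(psnr(p$clean, dn), ssim(p$clean, dn))
      }, numeric(2))
      finite <- rec[1, ][is.finite(rec[1, ])]
      vp <- if (length(finite)) mean(finite) else Inf
      vs <- mean(rec[2, ])
      if (vp > best_psnr) {
        best_psnr <- vp
        best_weights <- get_weights(model)
      }
    } else {
      best_weights <- get_weights(model)
    }
    hist[[e]] <- tibble::tibble(epoch = e, lr = lrs[e],
                                train_loss = mean(losses),
                                val_psnr = vp, val_ssim = vs)
    if (verbose)
      message(sprintf("epoch %d/%d lr %.3g loss %.5f val_psnr %.2f",
                      e, config$epochs, lrs[e], mean(losses), vp))
  }
  set_weights(model, best_weights)
  history <- dplyr::bind_rows(hist)
  class(history) <- c("xfct_history", class(history))
  if (!is.null(checkpoint_path))
    save_checkpoint(model, checkpoint_path,
                    meta = list(seed = config$seed, epochs = config$epochs,
                                lr0 = config$lr0, decay = config$decay,
                                loss = unclass(config$loss),
                                best_val_psnr = best_psnr))
  list(model = model, history = history, best_weights = best_weights)
}

#' @export
tidy.xfct_history <- function(x, ...) tibble::as_tibble(unclass(x))

#' @export
glance.xfct_history <- function(x, ...) {
  tibble::tibble(epochs = nrow(x), final_loss = x$train_loss[nrow(x)],
                 best_val_psnr = suppressWarnings(max(x$val_psnr, na.rm = TRUE)),
                 final_lr = x$lr[nrow(x)])
}

#' Plot a training history
#'
#' @param object an `xfct_history`.
#' @param ... unused.
#' @export
autoplot.xfct_history <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(unclass(object)),
                            c("train_loss", "val_psnr"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL)
}
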