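# Independent brute-force oracles, deliberately written as direct loops over
# the defining formulas so they share no code with the package internals.

brute_psnr <- function(ref, test, data_range = 1) {
  s <- 0
  for (i in seq_len(nrow(ref)))
    for (j in seq_len(ncol(ref)))
      s <- s + (ref[i, j] - test[i, j])^2
  mse <- s / (nrow(ref) * ncol(ref))
  if (mse == 0) return(Inf)
  10 * log10(data_range^2 / mse)
}

brute_ssim <- function(x, y, data_range = 1, win = 11, sigma = 1.5,
                       K1 = 0.01, K2 = 0.03) {
  r <- (win - 1) / 2
  u <- seq(-r, r)
  g1 <- exp(-u^2 / (2 * sigma^2)); g1 <- g1 / sum(g1)
  g <- outer(g1, g1)
  C1 <- (K1 * data_range)^2; C2 <- (K2 * data_range)^2
  H <- nrow(x); W <- ncol(x)
  vals <- c()
  for (i in seq_len(H - win + 1))
    for (j in seq_len(W - win + 1)) {
      px <- x[i:(i + win - 1), j:(j + win - 1)]
      py <- y[i:(i + win - 1), j:(j + win - 1)]
      mx <- sum(g * px); my <- sum(g * py)
      vx <- sum(g * px^2) - mx^2
      vy <- sum(g * py^2) - my^2
      cxy <- sum(g * px * py) - mx * my
      vals <- c(vals, ((2 * mx * my + C1) * (2 * cxy + C2)) /
                  ((mx^2 + my^2 + C1) * (vx + vy + C2)))
    }
  mean(vals)
}

# quadruple-loop non-local means on a reflect-padded image, mirroring the
# documented weight definition exp(-sum patch sq diff / h^2)
brute_nlm <- function(img, patch_radius, search_radius, h) {
  H <- nrow(img); W <- ncol(img)
  P <- patch_radius; S <- search_radius
  pad <- S + P
  ri <- c(rev(seq_len(pad) + 1L), seq_len(H), H - seq_len(pad))
  ci <- c(rev(seq_len(pad) + 1L), seq_len(W), W - seq_len(pad))
  Z <- img[ri, ci]
  out <- matrix(0, H, W)
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      ci0 <- i + pad; cj0 <- j + pad
      num <- 0; den <- 0
      for (dy in -S:S) {
        for (dx in -S:S) {
          d <- 0
          for (py in -P:P)
            for (px in -P:P)
              d <- d + (Z[ci0 + py, cj0 + px] -
                        Z[ci0 + dy + py, cj0 + dx + px])^2
          w <- exp(-d / h^2)
          num <- num + w * Z[ci0 + dy, cj0 + dx]
          den <- den + w
        }
      }
      out[i, j] <- num / den
    }
  }
  out
}

# dense single-window self-attention computed directly from Q, K, V matrices
dense_attention <- function(Q, K, V, scale) {
  S <- scale * Q %*% t(K)
  A <- t(apply(S, 1, function(r) { e <- exp(r - max(r)); e / sum(e) }))
  A %*% V
}
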