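#' Derive a child seed from a master seed
#'
#' All randomness in the simulation pipeline flows from one master seed;
#' individual stages (Poisson sampling, thinning, splitting, weight
#' initialization, shuffling) draw their own child seed through this counter
#' scheme so that any single stage can be reproduced in isolation.
#'
#' The scheme is `(master * 48271 + counter * 1299709) mod (2^31 - 1)`, a
#' Lehmer-style mixing of the master seed with the stage counter.
#'
#' @param master integer master seed.
#' @param counter non-negative integer stage counter.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
child_seed <- function(master, counter) {
  m <- 2147483647
  s <- (as.numeric(master) %% m) * 48271 + as.numeric(counter) * 1299709
  as.integer(s %% (m - 1) + 1)
}

# Evaluate expr with a locally seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Reflect-pad a matrix by (pt, pb, pl, pr) pixels.
reflect_pad <- function(m, pt, pb = pt, pl = pt, pr = pt) {
  H <- nrow(m); W <- ncol(m)
  stopifnot(pt < H, pb < H, pl < W, pr < W)
  ri <- c(rev(seq_len(pt) + 1L), seq_len(H), H - seq_len(pb))
  ci <- c(rev(seq_len(pl) + 1L), seq_len(W), W - seq_len(pr))
  m[ri, ci, drop = FALSE]
}

gaussian_kernel_1d <- function(sigma, radius = ceiling(3 * sigma)) {
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

gaussian_kernel_2d <- function(sigma, radius = ceiling(3 * sigma)) {
  k1 <- gaussian_kernel_1d(sigma, radius)
  outer(k1, k1)
}

# Gaussian blur with reflected borders (used for the phantom PSF).
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- ceiling(3 * sigma)
  ker <- gaussian_kernel_2d(sigma, r)
  mp <- reflect_pad(m, r)
  x <- array(mp, c(nrow(mp), ncol(mp), 1L))
  wmat <- matrix(as.vector(ker), ncol = 1L)
  out <- cpp_conv2d_fw(x, wmat, 0, nrow(ker), 1L, 0L)
  matrix(out, nrow(m), ncol(m))
}

clip01 <- function(m) {
  m[m < 0] <- 0
  m[m > 1] <- 1
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
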