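#' Non-local means parameters
#'
#' @param patch_radius half-width of the similarity patch (patch side
#'   `2*patch_radius + 1`).
#' @param search_radius half-width of the search window; must be >=
#'   `patch_radius`.
#' @param h decay bandwidth in intensity units; weights are
#'   `exp(-||P_i - P_j||^2 / h^2)` on raw patch sum-of-squared differences.
#' @export
nlm_params <- function(patch_radius = 2L, search_radius = 7L, h = 0.1) {
  if (patch_radius <= 0 || search_radius <= 0) stop("radii must be positive")
  if (search_radius < patch_radius)
    stop("search_radius must be >= patch_radius")
  if (h <= 0) stop("h must be > 0")
  structure(list(patch_radius = as.integer(patch_radius),
                 search_radius = as.integer(search_radius), h = h),
            class = "xfct_nlm_params")
}

#' Robust noise standard-deviation estimate
#'
#' Median absolute deviation of the finest diagonal-detail (HH) band,
#' scaled by 1/0.6745 (the Donoho estimator).
#' @param image numeric matrix.
#' @export
estimate_noise_sd <- function(image) {
  H <- nrow(image); W <- ncol(image)
  d <- (image[seq(1, H - 1), seq(1, W - 1)] - image[seq(2, H), seq(1, W - 1)] -
        image[seq(1, H - 1), seq(2, W)] + image[seq(2, H), seq(2, W)]) / 2
  stats::median(abs(d - stats::median(d))) / 0.6745
}

# default bandwidth tied to the noise estimate: a pure-noise patch distance
# has expectation 2 * sigma^2 * Npatch, so h^2 is set on that scale
nlm_params_auto <- function(image, patch_radius = 2L, search_radius = 7L) {
  np <- (2 * patch_radius + 1)^2
  sd <- max(estimate_noise_sd(image), 1e-6)
  nlm_params(patch_radius, search_radius, h = sd * sqrt(2 * np))
}

#' Non-local means denoising
#'
#' For every pixel, a weighted mean over its search window with weights
#' `exp(-||P_i - P_j||^2 / h^2)` computed on raw reflect-padded patches.
#'
#' @param image numeric matrix larger than `2*search_radius + 1`.
#' @param params an [nlm_params()]; by default the bandwidth is tied to the
#'   image's estimated noise level.
#' @return Denoised matrix of the same shape. Deterministic.
#' @export
nlm_denoise <- function(image, params = NULL) {
  image <- as.matrix(image)
  if (is.null(params)) params <- nlm_params_auto(image)
  stopifnot(inherits(params, "xfct_nlm_params"))
  P <- params$patch_radius; S <- params$search_radius; h <- params$h
  H <- nrow(image); W <- ncol(image)
  if (min(H, W) <= 2 * S + 1)
    stop("image must be larger than the search window")
  pad <- S + P
  Z <- reflect_pad(image, pad)
  k <- 2L * P + 1L
  ones <- matrix(1, k * k, 1)
  patch_sum <- function(D) {
    # valid sum over the (2P+1)^2 patch via an all-ones convolution
    out <- cpp_conv2d_fw(array(D, c(nrow(D), ncol(D), 1L)), ones, 0, k, 1L, 0L)
    matrix(out, nrow(D) - k + 1L, ncol(D) - k + 1L)
  }
  num <- matrix(0, H, W); den <- matrix(0, H, W)
  rowsA <- (pad + 1L - P):(pad + H + P)
  colsA <- (pad + 1L - P):(pad + W + P)
  A <- Z[rowsA, colsA]
  for (dy in -S:S) {
    for (dx in -S:S) {
      B <- Z[rowsA + dy, colsA + dx]
      dist <- patch_sum((A - B)^2)
      w <- exp(-dist / h^2)
      val <- Z[(pad + 1L + dy):(pad + H + dy), (pad + 1L + dx):(pad + W + dx)]
      num <- num + w * val
      den <- den + w
    }
  }
  num / den
}

# ---- simplified BM3D -------------------------------------------------------

#' Simplified BM3D parameters
#'
#' @param block_size 4 or 8.
#' @param max_group maximum blocks per group, a power of two.
#' @param match_threshold maximum mean squared block difference for a match.
#' @param sigma noise standard deviation (hard threshold `2.7 * sigma`).
#' @param stage `"hard"` or `"hard+wiener"`.
#' @param stride reference-block stride.
#' @param search_radius block-matching search half-width.
#' @export
bm3d_params <- function(block_size = 8L, max_group = 16L,
                        match_threshold = 0.05, sigma = 0.05,
                        stage = c("hard", "hard+wiener"), stride = 3L,
                        search_radius = 16L) {
  stage <- match.arg(stage)
  if (!block_size %in% c(4L, 8L)) stop("block_size must be 4 or 8")
  if (max_group < 1 || bitwAnd(max_group, max_group - 1L) != 0)
    stop("max_group must be a power of two")
  structure(list(block_size = as.integer(block_size),
                 max_group = as.integer(max_group),
                 match_threshold = match_threshold, sigma = sigma,
                 stage = stage, stride = as.integer(stride),
                 search_radius = as.integer(search_radius)),
            class = "xfct_bm3d_params")
}

# orthonormal DCT-II matrix
dct_matrix <- function(n) {
  D <- sqrt(2 / n) * cos(pi / n * outer(0:(n - 1) + 0, 0:(n - 1) + 0.5))
  D[1, ] <- D[1, ] / sqrt(2)
  D
}

# orthonormal Haar matrix for power-of-two n
haar_matrix <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  Hs <- haar_matrix(n / 2)
  rbind(kronecker(Hs, matrix(c(1, 1) / sqrt(2), 1, 2)),
        kronecker(diag(n / 2), matrix(c(1, -1) / sqrt(2), 1, 2)))
}

block_positions <- function(n, bs, stride) {
  p <- seq(1L, n - bs + 1L, by = stride)
  if (p[length(p)] != n - bs + 1L) p <- c(p, n - bs + 1L)
  p
}

#' Simplified two-stage BM3D denoising
#'
#' Stage 1 (hard thresholding): for each reference block, the most similar
#' blocks (mean squared difference below `match_threshold`, at most
#' `max_group`, count truncated to a power of two) inside a search window
#' are stacked; the stack is transformed by a 2-D orthonormal DCT per block
#' and a 1-D Haar transform across the stack; coefficients below
#' `2.7 * sigma` are zeroed (the stack-DC/block-DC coefficient is kept);
#' the inverse-transformed blocks are aggregated with weights inversely
#' proportional to the number of retained coefficients. The optional Wiener
#' stage repeats matching on the stage-1 pilot and applies empirical Wiener
#' shrinkage `p^2 / (p^2 + sigma^2)` to the noisy coefficients.
#'
#' @param image numeric matrix at least `block_size` on each side.
#' @param params a [bm3d_params()].
#' @return Denoised matrix. Deterministic.
#' @export
bm3d_denoise <- function(image, params = bm3d_params()) {
  image <- as.matrix(image)
  stopifnot(inherits(params, "xfct_bm3d_params"))
  if (params$sigma <= 0) stop("sigma must be > 0")
  bs <- params$block_size
  if (nrow(image) < bs || ncol(image) < bs)
    stop("block_size larger than image")
  est <- bm3d_stage(image, image, params, wiener = FALSE)
  if (params$stage == "hard+wiener")
    est <- bm3d_stage(image, est, params, wiener = TRUE)
  est
}

# all stride-1 candidate blocks of an image, flattened column-wise
bm3d_candidates <- function(pilot, bs) {
  ar <- block_positions(nrow(pilot), bs, 1L)
  ac <- block_positions(ncol(pilot), bs, 1L)
  cand <- matrix(0, bs * bs, length(ar) * length(ac))
  cidx <- matrix(0L, 2, ncol(cand))
  k <- 0L
  for (j in ac) for (i in ar) {
    k <- k + 1L
    cand[, k] <- as.vector(pilot[i:(i + bs - 1L), j:(j + bs - 1L)])
    cidx[, k] <- c(i, j)
  }
  list(cand = cand, cidx = cidx)
}

# group the most similar blocks for the reference at (i0, j0); returns the
# candidate indices (power-of-two count, closest first) and their distances
bm3d_group <- function(cc, refv, i0, j0, params) {
  inwin <- which(abs(cc$cidx[1, ] - i0) <= params$search_radius &
                 abs(cc$cidx[2, ] - j0) <= params$search_radius)
  d2 <- colMeans((cc$cand[, inwin, drop = FALSE] - refv)^2)
  sel <- d2 <= params$match_threshold
  ok <- inwin[sel][order(d2[sel])]
  if (!length(ok)) ok <- inwin[which.min(d2)]
  ng <- min(length(ok), params$max_group)
  ng <- 2^floor(log2(ng))
  list(grp = ok[seq_len(ng)], dist = sort(d2[sel])[seq_len(ng)])
}

# pilot: image used for block matching (and Wiener energies); noisy: image
# whose coefficients are filtered
bm3d_stage <- function(noisy, pilot, params, wiener) {
  bs <- params$block_size
  H <- nrow(noisy); W <- ncol(noisy)
  D <- dct_matrix(bs)
  rp <- block_positions(H, bs, params$stride)
  cp <- block_positions(W, bs, params$stride)
  cc <- bm3d_candidates(pilot, bs)
  cidx <- cc$cidx
  thr <- 2.7 * params$sigma
  num <- matrix(0, H, W); den <- matrix(0, H, W)
  for (j0 in cp) for (i0 in rp) {
    refv <- as.vector(pilot[i0:(i0 + bs - 1L), j0:(j0 + bs - 1L)])
    grp <- bm3d_group(cc, refv, i0, j0, params)$grp
    ng <- length(grp)
    Hm <- haar_matrix(ng)
    # 2-D DCT of each noisy block in the group
    get_stack <- function(img) {
      st <- matrix(0, bs * bs, ng)
      for (g in seq_len(ng)) {
        i <- cidx[1, grp[g]]; j <- cidx[2, grp[g]]
        st[, g] <- as.vector(D %*% img[i:(i + bs - 1L), j:(j + bs - 1L)] %*% t(D))
      }
      st %*% t(Hm)  # Haar along the stack
    }
    coef <- get_stack(noisy)
    if (wiener) {
      pcoef <- get_stack(pilot)
      shrink <- pcoef^2 / (pcoef^2 + params$sigma^2)
      shrink[1, 1] <- 1  # block-DC / stack-DC passes unshrunk
      coef <- coef * shrink
      wgt <- 1 / (sum(shrink^2) + 1e-8)
    } else {
      keep <- abs(coef) >= thr
      keep[1, 1] <- TRUE  # block-DC / stack-DC survives
      coef[!keep] <- 0
      wgt <- 1 / max(sum(keep), 1)
    }
    back <- coef %*% Hm  # inverse Haar (orthonormal)
    for (g in seq_len(ng)) {
      i <- cidx[1, grp[g]]; j <- cidx[2, grp[g]]
      blk <- t(D) %*% matrix(back[, g], bs, bs) %*% D
      ri <- i:(i + bs - 1L); rj <- j:(j + bs - 1L)
      num[ri, rj] <- num[ri, rj] + wgt * blk
      den[ri, rj] <- den[ri, rj] + wgt
    }
  }
  out <- noisy
  covered <- den > 0
  out[covered] <- num[covered] / den[covered]
  out
}

# ---- denoiser registry -----------------------------------------------------

.denoisers <- new.env(parent = emptyenv())

#' Register a denoiser
#'
#' A denoiser is `function(image, ctx)` mapping an \[0, 1\] image to an image
#' of the same shape; `ctx` carries method context (model, parameter
#' objects). External plug-ins (e.g. a reference BM3D/BM4D) register through
#' this same mechanism.
#'
#' @param name method name.
#' @param fn the denoiser function.
#' @export
register_denoiser <- function(name, fn) {
  stopifnot(is.character(name), is.function(fn))
  .denoisers[[name]] <- fn
  invisible(name)
}

#' @rdname register_denoiser
#' @export
list_denoisers <- function() sort(ls(.denoisers))

#' @rdname register_denoiser
#' @export
get_denoiser <- function(name) {
  fn <- .denoisers[[name]]
  if (is.null(fn)) stop("unknown denoiser: ", name)
  fn
}

register_builtin_denoisers <- function() {
  register_denoiser("identity", function(img, ctx = list()) img)
  register_denoiser("nlm", function(img, ctx = list())
    clip01(nlm_denoise(img, ctx$nlm_params %||% nlm_params_auto(img))))
  register_denoiser("bm3d", function(img, ctx = list()) {
    p <- ctx$bm3d_params
    if (is.null(p)) {
      s <- max(estimate_noise_sd(img), 1e-4)
      p <- bm3d_params(sigma = s, match_threshold = max(16 * s^2, 1e-4))
    }
    clip01(bm3d_denoise(img, p))
  })
  learned <- function(img, ctx) {
    if (is.null(ctx$model)) stop("learned denoiser requires ctx$model")
    denoise_image(ctx$model, img)
  }
  register_denoiser("dncnn", learned)
  register_denoiser("scunet", learned)
  register_denoiser("proposed", learned)
}
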