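# Shifted-window transformer block: layer norm -> windowed multi-head
# self-attention (cyclic shift + cross-boundary mask on shifted blocks) ->
# residual -> layer norm -> 2-layer GELU MLP -> residual.

# Window bookkeeping: token indices (into the H*W column-major pixel order)
# per window, and the additive attention mask for shifted windows.
.win_cache <- new.env(parent = emptyenv())

win_info <- function(H, W, win, shift) {
  key <- paste(H, W, win, shift)
  if (!is.null(.win_cache[[key]])) return(.win_cache[[key]])
  stopifnot(H %% win == 0, W %% win == 0)
  nwi <- H %/% win; nwj <- W %/% win
  Tn <- win * win; nwin <- nwi * nwj
  idx <- matrix(0L, Tn, nwin)
  w <- 0L
  for (wj in 0:(nwj - 1)) for (wi in 0:(nwi - 1)) {
    w <- w + 1L
    t <- 0L
    for (tj in 0:(win - 1)) for (ti in 0:(win - 1)) {
      t <- t + 1L
      oi <- (wi * win + ti + shift) %% H
      oj <- (wj * win + tj + shift) %% W
      idx[t, w] <- oi + H * oj + 1L
    }
  }
  mask <- NULL
  if (shift > 0) {
    cls <- function(i, n) ifelse(i < n - win, 0L, ifelse(i < n - shift, 1L, 2L))
    region <- function(lin) {
      oi <- (lin - 1L) %% H
      oj <- (lin - 1L) %/% H
      3L * cls(oi, H) + cls(oj, W)
    }
    mask <- array(0, c(Tn, Tn, nwin))
    for (w in seq_len(nwin)) {
      id <- region(idx[, w])
      mask[, , w] <- ifelse(outer(id, id, "!="), -1e9, 0)
    }
  }
  out <- list(idx = idx, mask = mask, Tn = Tn, nwin = nwin)
  .win_cache[[key]] <- out
  out
}

nn_swin <- function(C, win, shift, head_dim = 32, mlp_ratio = 4) {
  u <- new_unit("swin", c("ln1_g", "ln1_b", "Wqkv", "bqkv", "Wo", "bo",
                          "ln2_g", "ln2_b", "W1", "b1", "W2", "b2"))
  nheads <- max(1L, C %/% head_dim)
  if (C %% nheads != 0) stop("channels not divisible into heads")
  hidden <- as.integer(round(C * mlp_ratio))
  u$C <- C; u$win <- as.integer(win); u$shift <- as.integer(shift)
  u$nheads <- nheads; u$hd <- C %/% nheads; u$hidden <- hidden
  u$ln1_g <- rep(1, C); u$ln1_b <- numeric(C)
  u$Wqkv <- matrix(trunc_normal(C * 3 * C), C, 3 * C)
  u$bqkv <- numeric(3 * C)
  u$Wo <- matrix(trunc_normal(C * C), C, C)
  u$bo <- numeric(C)
  u$ln2_g <- rep(1, C); u$ln2_b <- numeric(C)
  u$W1 <- matrix(trunc_normal(C * hidden), C, hidden)
  u$b1 <- numeric(hidden)
  u$W2 <- matrix(trunc_normal(hidden * C), hidden, C)
  u$b2 <- numeric(C)
  u
}

# gather a [N, hd] matrix into a [T, hd, nwin] cube following idx
gather_cube <- function(M, idx) {
  Tn <- nrow(idx); nwin <- ncol(idx)
  aperm(array(M[as.vector(idx), , drop = FALSE], c(Tn, nwin, ncol(M))),
        c(1, 3, 2))
}

scatter_cube <- function(cube, idx) {
  Tn <- nrow(idx); nwin <- ncol(idx)
  M <- matrix(0, length(idx), dim(cube)[2])
  M[as.vector(idx), ] <- matrix(aperm(cube, c(1, 3, 2)), Tn * nwin, dim(cube)[2])
  M
}

swin_fw <- function(u, x3) {
  d <- dim(x3); H <- d[1]; W <- d[2]; C <- d[3]
  stopifnot(C == u$C)
  # shift is skipped when the window covers the whole map
  eff_shift <- if (u$shift > 0 && (H > u$win || W > u$win)) u$shift else 0L
  wi <- win_info(H, W, u$win, eff_shift)
  N <- H * W
  X <- matrix(x3, N, C)
  u$H <- H; u$W <- W; u$wi <- wi
  u$X0 <- X
  l1 <- ln_fw(X, u$ln1_g, u$ln1_b)
  u$l1 <- l1
  QKV <- l1$y %*% u$Wqkv + rep(u$bqkv, each = N)
  u$cache_h <- vector("list", u$nheads)
  O <- matrix(0, N, C)
  scale <- 1 / sqrt(u$hd)
  dummy <- array(0, c(1, 1, 1))
  for (h in seq_len(u$nheads)) {
    cols <- (h - 1) * u$hd + seq_len(u$hd)
    Qc <- gather_cube(QKV[, cols, drop = FALSE], wi$idx)
    Kc <- gather_cube(QKV[, C + cols, drop = FALSE], wi$idx)
    Vc <- gather_cube(QKV[, 2 * C + cols, drop = FALSE], wi$idx)
    r <- if (is.null(wi$mask))
      cpp_attn_fw(Qc, Kc, Vc, dummy, scale, FALSE)
    else cpp_attn_fw(Qc, Kc, Vc, wi$mask, scale, TRUE)
    u$cache_h[[h]] <- list(Q = Qc, K = Kc, V = Vc, A = r$A)
    O[, cols] <- scatter_cube(r$O, wi$idx)
  }
  u$ln1y <- l1$y
  u$O <- O
  X1 <- X + O %*% u$Wo + rep(u$bo, each = N)
  u$X1 <- X1
  l2 <- ln_fw(X1, u$ln2_g, u$ln2_b)
  u$l2 <- l2
  Hh <- l2$y %*% u$W1 + rep(u$b1, each = N)
  u$Hh <- Hh
  Ac <- gelu(Hh)
  u$Ac <- Ac
  X2 <- X1 + Ac %*% u$W2 + rep(u$b2, each = N)
  array(X2, c(H, W, C))
}

swin_bw <- function(u, gy3) {
  H <- u$H; W <- u$W; C <- u$C; N <- H * W
  G2 <- matrix(gy3, N, C)
  # MLP branch
  gM <- G2
  u$gW2 <- u$gW2 + t(u$Ac) %*% gM
  u$gb2 <- u$gb2 + colSums(gM)
  gA <- gM %*% t(u$W2)
  gH <- gA * gelu_grad(u$Hh)
  u$gW1 <- u$gW1 + t(u$l2$y) %*% gH
  u$gb1 <- u$gb1 + colSums(gH)
  gY2 <- gH %*% t(u$W1)
  r2 <- ln_bw(u$l2, u$ln2_g, gY2)
  u$gln2_g <- u$gln2_g + r2$gg
  u$gln2_b <- u$gln2_b + r2$gb
  gX1 <- G2 + r2$dx
  # attention projection
  u$gWo <- u$gWo + t(u$O) %*% gX1
  u$gbo <- u$gbo + colSums(gX1)
  gO <- gX1 %*% t(u$Wo)
  wi <- u$wi
  scale <- 1 / sqrt(u$hd)
  gQKV <- matrix(0, N, 3 * C)
  for (h in seq_len(u$nheads)) {
    cols <- (h - 1) * u$hd + seq_len(u$hd)
    ch <- u$cache_h[[h]]
    gOc <- gather_cube(gO[, cols, drop = FALSE], wi$idx)
    r <- cpp_attn_bw(gOc, ch$A, ch$Q, ch$K, ch$V, scale)
    gQKV[, cols] <- scatter_cube(r$gQ, wi$idx)
    gQKV[, C + cols] <- scatter_cube(r$gK, wi$idx)
    gQKV[, 2 * C + cols] <- scatter_cube(r$gV, wi$idx)
  }
  u$gWqkv <- u$gWqkv + t(u$ln1y) %*% gQKV
  u$gbqkv <- u$gbqkv + colSums(gQKV)
  gY1 <- gQKV %*% t(u$Wqkv)
  r1 <- ln_bw(u$l1, u$ln1_g, gY1)
  u$gln1_g <- u$gln1_g + r1$gg
  u$gln1_b <- u$gln1_b + r1$gb
  gX <- gX1 + r1$dx
  array(gX, c(H, W, C))
}

#' Apply one shifted-window transformer block to a feature map
#'
#' Exposed as a standalone operation so that the windowed attention can be
#' checked against a dense self-attention oracle. The block is
#' `LN -> windowed MHSA (cyclic shift + boundary mask when shift > 0) ->
#' residual -> LN -> GELU MLP -> residual`; shape is preserved.
#'
#' @param x H x W x C feature array; H and W must be multiples of
#'   `window_size`.
#' @param window_size attention window side length, > 0.
#' @param shift cyclic shift in pixels (0 or `window_size/2`).
#' @param head_dim per-head channel count (heads = max(1, C / head_dim)).
#' @param mlp_ratio MLP expansion factor.
#' @param seed seed for the block's weight initialization.
#' @return List with `out` (H x W x C array) and `unit` (the parameter
#'   environment, reusable for further calls via [swin_block_apply()]).
#' @export
swin_transformer_block <- function(x, window_size = 8, shift = 0,
                                   head_dim = 32, mlp_ratio = 4, seed = 1L) {
  if (window_size <= 0) stop("window_size must be > 0")
  C <- dim(x)[3]
  u <- with_local_seed(seed, nn_swin(C, window_size, shift, head_dim, mlp_ratio))
  zero_grads(list(u))
  list(out = swin_fw(u, x), unit = u)
}

#' @rdname swin_transformer_block
#' @param unit a swin unit returned by [swin_transformer_block()].
#' @export
swin_block_apply <- function(unit, x) swin_fw(unit, x)
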