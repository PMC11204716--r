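test_that("nlm preserves constants and degenerates to the window mean", {
  cst <- matrix(0.37, 20, 20)
  out <- nlm_denoise(cst, nlm_params(1, 3, h = 0.1))
  expect_equal(out, cst, tolerance = 1e-12)

  set.seed(3)
  img <- matrix(runif(400), 20, 20)
  p <- nlm_params(1, 2, h = 1e9)  # weights -> uniform
  out <- nlm_denoise(img, p)
  # compare one interior pixel with the plain mean of its (reflect-padded)
  # search window
  pad <- 3
  Z <- xfctdn:::reflect_pad(img, pad)
  i <- 10; j <- 10
  expect_equal(out[i, j], mean(Z[(i + pad - 2):(i + pad + 2),
                                 (j + pad - 2):(j + pad + 2)]),
               tolerance = 1e-9)
  expect_error(nlm_params(2, 7, h = 0), "h must be")
  expect_error(nlm_params(3, 2, h = 1), "search_radius")
})

test_that("nlm equals the quadruple-loop brute force on 8x8 images", {
  set.seed(9)
  img <- matrix(runif(64), 8, 8)
  p <- nlm_params(patch_radius = 1, search_radius = 2, h = 0.3)
  got <- nlm_denoise(img, p)
  want <- brute_nlm(img, 1, 2, 0.3)
  expect_lt(max(abs(got - want)), 1e-10)
})

test_that("bm3d preserves constants and near-noiseless structure", {
  cst <- matrix(0.6, 24, 24)
  p <- bm3d_params(block_size = 8, max_group = 8, match_threshold = 1,
                   sigma = 0.05, stride = 4)
  expect_equal(bm3d_denoise(cst, p), cst, tolerance = 1e-10)

  pw <- matrix(0.2, 32, 32); pw[9:20, 13:28] <- 0.8  # piecewise constant
  p2 <- bm3d_params(block_size = 8, max_group = 8, match_threshold = 1,
                    sigma = 1e-6, stride = 3)
  expect_lt(max(abs(bm3d_denoise(pw, p2) - pw)), 1e-4)
  expect_error(bm3d_denoise(matrix(0.1, 4, 4),
                            bm3d_params(block_size = 8, sigma = 0.1)),
               "block_size larger")
  expect_error(bm3d_params(block_size = 5), "4 or 8")
  expect_error(bm3d_params(max_group = 6), "power of two")
})

test_that("block matching groups exact duplicates at distance zero", {
  ns <- asNamespace("xfctdn")
  set.seed(11)
  img <- matrix(runif(24 * 24), 24, 24)
  blk <- img[1:8, 1:8]
  img[13:20, 13:20] <- blk  # exact duplicate elsewhere
  p <- bm3d_params(block_size = 8, max_group = 2, match_threshold = 1,
                   sigma = 0.1, search_radius = 24)
  cc <- ns$bm3d_candidates(img, 8L)
  g <- ns$bm3d_group(cc, as.vector(blk), 1L, 1L, p)
  pos <- cc$cidx[, g$grp]
  expect_equal(g$dist, c(0, 0))
  expect_setequal(paste(pos[1, ], pos[2, ]), c("1 1", "13 13"))
  # cross-check with brute-force pairwise distances over all stride-1 blocks
  best <- Inf; where <- NULL
  for (i in 1:17) for (j in 1:17) {
    if (i == 1 && j == 1) next
    d <- mean((img[i:(i + 7), j:(j + 7)] - blk)^2)
    if (d < best) { best <- d; where <- c(i, j) }
  }
  expect_identical(best, 0)
  expect_equal(where, c(13, 13))
})

test_that("wiener stage runs and keeps constants fixed", {
  cst <- matrix(0.5, 16, 16)
  p <- bm3d_params(block_size = 8, max_group = 4, match_threshold = 1,
                   sigma = 0.03, stage = "hard+wiener", stride = 4)
  expect_equal(bm3d_denoise(cst, p), cst, tolerance = 1e-8)
})

test_that("classical denoisers are deterministic and registry-conformant", {
  set.seed(5)
  img <- matrix(runif(24 * 24), 24, 24)
  expect_identical(nlm_denoise(img, nlm_params(1, 3, 0.2)),
                   nlm_denoise(img, nlm_params(1, 3, 0.2)))
  p <- bm3d_params(sigma = 0.1, stride = 4)
  expect_identical(bm3d_denoise(img, p), bm3d_denoise(img, p))
  expect_true(all(c("identity", "nlm", "bm3d", "dncnn", "scunet",
                    "proposed") %in% list_denoisers()))
  for (m in c("identity", "nlm", "bm3d")) {
    out <- get_denoiser(m)(img, list())
    expect_identical(dim(out), dim(img))
    expect_true(all(out >= 0 & out <= 1))
  }
  expect_error(get_denoiser("nope"), "unknown")
})
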