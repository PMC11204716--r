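test_that("Poisson sampling honours its contracts", {
  z <- structure(list(pixels = matrix(0, 40, 40), pixel_size_mm = 1),
                 class = "xfct_clean_image")
  expect_true(all(sample_counts(z, 0.5, 1, seed = 1)$counts == 0))

  sp <- matrix(10, 100, 100)
  a <- sample_counts(sp, 0.5, 1, seed = 7)
  b <- sample_counts(sp, 0.5, 1, seed = 7)
  expect_identical(a$counts, b$counts)

  # Poisson mean law: constant 10, 1e4 pixels
  expect_lt(abs(mean(a$counts) - 10), 3 * sqrt(10 / 1e4))

  bad <- matrix(c(NaN, rep(1, 99)), 10, 10)
  expect_error(sample_counts(bad, 0.5, 1, 1), "non-finite")
  expect_error(sample_counts(sp, 0.5, exposure_scale = 0, 1), "> 0")
})

test_that("bin width rescales expected counts relative to the 0.5 keV reference", {
  sp <- matrix(100, 100, 100)
  c05 <- sample_counts(sp, 0.05, 1, seed = 3)
  expect_lt(abs(mean(c05$counts) - 10), 3 * sqrt(10 / 1e4))
})

test_that("binomial thinning: identity, degenerate and moment contracts", {
  img <- sample_counts(matrix(100, 100, 100), 0.5, 1, seed = 2)
  expect_identical(thin_counts(img, 1, seed = 1), img)
  expect_true(all(thin_counts(img, 0, seed = 1)$counts == 0))
  expect_error(thin_counts(img, 1.5, 1), "\\[0, 1\\]")

  Tt <- sum(img$counts)  # ~1e6 photons
  th <- thin_counts(img, 0.25, seed = 9)
  expect_lt(abs(sum(th$counts) - 0.25 * Tt), 3 * sqrt(Tt * 0.25 * 0.75))
  expect_equal(th$dose_fraction, 0.25)

  a <- thin_counts(img, 0.5, seed = 4)
  b <- thin_counts(img, 0.5, seed = 4)
  expect_identical(a$counts, b$counts)
})

test_that("thinned Poisson counts remain Poisson (variance/mean near 1)", {
  lam <- 100
  img <- sample_counts(matrix(lam, 100, 100), 0.5, 1, seed = 5)
  th <- thin_counts(img, 0.5, seed = 6)  # lambda * p = 50 >= 25, n = 1e4
  ratio <- stats::var(as.vector(th$counts)) / mean(th$counts)
  expect_gt(ratio, 0.9)
  expect_lt(ratio, 1.1)
})

test_that("thinning composes: p then q matches single thinning by p*q in law", {
  img <- sample_counts(matrix(60, 100, 100), 0.5, 1, seed = 8)
  two <- thin_counts(thin_counts(img, 0.6, seed = 1), 0.5, seed = 2)
  one <- thin_counts(img, 0.3, seed = 3)
  # compare means and variances over 1e4 pixels
  m1 <- mean(one$counts); m2 <- mean(two$counts)
  expect_lt(abs(m1 - m2), 4 * sqrt(m1 / 1e4) * sqrt(2))
  v1 <- stats::var(as.vector(one$counts)); v2 <- stats::var(as.vector(two$counts))
  expect_lt(abs(v1 - v2) / v1, 0.15)
})

test_that("count-to-float normalization modes behave as documented", {
  ci <- count_image(matrix(0:99, 10, 10), 1, 0.5)
  f <- counts_to_float(ci, norm_fixed_range(100))
  expect_equal(f, matrix(0:99, 10, 10) / 100)

  f2 <- counts_to_float(count_image(matrix(c(0, 512, 256, 64), 2, 2), 1, 0.5),
                        norm_per_image_max())
  expect_equal(max(f2), 1)

  zero <- count_image(matrix(0, 4, 4), 1, 0.5)
  expect_warning(fz <- counts_to_float(zero, norm_per_image_max()), "all-zero")
  expect_true(all(fz == 0))
  expect_true(all(counts_to_float(zero, norm_fixed_range(10)) == 0))

  big <- count_image(matrix(200, 4, 4), 1, 0.5)
  expect_true(all(counts_to_float(big, norm_fixed_range(100)) == 1))  # clipped
})
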