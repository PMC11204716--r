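test_that("identity evaluation reproduces the no-denoising floor", {
  ds <- small_train_dataset()
  te <- dataset_pairs(ds, "test")
  rec <- evaluate_method("identity", te)
  expect_equal(nrow(rec), length(te))
  want <- vapply(te, function(p) psnr(p$clean, p$noisy), 0)
  expect_equal(rec$psnr_db, want, tolerance = 1e-12)
})

test_that("a perfect oracle denoiser scores inf PSNR and SSIM 1", {
  ds <- small_train_dataset()
  te <- dataset_pairs(ds, "test")[1:3]
  register_denoiser("oracle_clean", function(img, ctx) ctx$clean)
  rec <- dplyr::bind_rows(lapply(te, function(p)
    evaluate_method("oracle_clean", list(p), ctx = list(clean = p$clean))))
  expect_true(all(rec$psnr_db == Inf))
  expect_true(all(abs(rec$ssim - 1) < 1e-12))
  expect_error(evaluate_method("proposed", te), "checkpoint")
  expect_error(evaluate_method("never_registered", te), "unknown")
})

test_that("tables average per category, exclude inf, and keep the 9-row grid", {
  ds <- small_grid_dataset()
  te <- dataset_pairs(ds, "test")
  rec <- evaluate_method("identity", te)
  tab <- build_tables(rec)
  expect_equal(nrow(tab$psnr), 9)
  expect_equal(nrow(tab$ssim), 9)
  expect_identical(names(tab$psnr), c("bin_width", "noise_level", "identity"))
  # single method, single category cross-check by direct averaging
  one <- rec[rec$bin_width == 0.1 & rec$noise_level == 50, ]
  cell <- tab$psnr$identity[tab$psnr$bin_width == 0.1 &
                            tab$psnr$noise_level == 50]
  expect_equal(cell, mean(one$psnr_db), tolerance = 1e-12)
  # infinite PSNR rows are excluded from means and counted
  rec2 <- rec
  rec2$psnr_db[1] <- Inf
  tab2 <- build_tables(rec2)
  expect_equal(tab2$metadata$n_inf_excluded, 1L)
  expect_true(all(is.finite(as.matrix(tab2$psnr[, 3]))))
})

test_that("csv rendering round-trips losslessly including inf cells", {
  ds <- small_train_dataset()
  rec <- evaluate_method("identity", dataset_pairs(ds, "test"))
  rec$psnr_db[1] <- Inf  # force an inf cell in a one-pair category? keep mean finite
  tab <- build_tables(rec)
  p1 <- tempfile(fileext = ".csv")
  write_metrics_csv(tab$psnr, p1)
  back <- read_metrics_csv(p1)
  expect_equal(back$identity, round(tab$psnr$identity, 6), tolerance = 1e-9)
  p2 <- tempfile(fileext = ".csv")
  write_metrics_csv(back, p2)
  expect_identical(readLines(p1), readLines(p2))
  # markdown report renders
  md <- tempfile(fileext = ".md")
  write_metrics_markdown(tab, md)
  expect_true(any(grepl("Mean PSNR", readLines(md))))
})

test_that("tidy, glance and autoplot surfaces work on metric tables", {
  ds <- small_train_dataset()
  rec <- evaluate_method("identity", dataset_pairs(ds, "test"))
  tab <- build_tables(rec)
  d <- tidy(tab)
  expect_identical(names(d), c("bin_width", "noise_level", "method",
                               "psnr_db", "ssim"))
  g <- glance(tab)
  expect_identical(g$best_method, "identity")
  p <- autoplot(tab)
  expect_s3_class(p, "ggplot")
})

test_that("qualitative panels are written as readable PNG files", {
  ds <- small_train_dataset()
  te <- dataset_pairs(ds, "test")[1]
  dir <- file.path(tempdir(), "panels")
  paths <- render_panels(te, c("identity", "nlm", "bm3d"), dir)
  expect_length(paths, 1)
  expect_true(file.exists(paths[1]))
  img <- png::readPNG(paths[1])
  expect_gte(length(dim(img)), 2)  # decodes as an image: 5 tiles side by side
  expect_error(render_panels(list(), "identity", dir), "at least one")
})
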