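#' Evaluate a registered denoiser on test pairs
#'
#' Denoises every noisy test image and scores it against its clean target
#' with PSNR and SSIM.
#'
#' @param method_name a name from [list_denoisers()].
#' @param test_pairs list of [image_pair()]s.
#' @param checkpoint optional checkpoint path for learned methods (loaded
#'   into `ctx$model`).
#' @param ctx extra context passed to the denoiser (e.g. `model`,
#'   `nlm_params`).
#' @return A tibble with one row per pair: `method`, `pair_id`, `bin_width`,
#'   `noise_level`, `psnr_db`, `ssim`.
#' @export
evaluate_method <- function(method_name, test_pairs, checkpoint = NULL,
                            ctx = list()) {
  fn <- get_denoiser(method_name)
  if (!is.null(checkpoint)) ctx$model <- load_checkpoint(checkpoint)
  if (method_name %in% c("dncnn", "scunet", "proposed") && is.null(ctx$model))
    stop("method '", method_name, "' requires a checkpoint or ctx$model")
  rows <- lapply(test_pairs, function(p) {
    dn <- fn(p$noisy, ctx)
    tibble::tibble(method = method_name,
                   pair_id = p$meta$pair_id %||% NA_integer_,
                   bin_width = p$meta$bin_width %||% NA_real_,
                   noise_level = p$meta$noise_level %||% NA_real_,
                   psnr_db = psnr(p$clean, dn, 1),
                   ssim = ssim(p$clean, dn, 1))
  })
  dplyr::bind_rows(rows)
}

#' Assemble PSNR and SSIM benchmark tables
#'
#' Cells are arithmetic means over the test pairs of each
#' (bin width, noise level) category, one column per method — the layout of
#' the study's quantitative comparison (9 rows on the full default grid).
#' Infinite PSNR values are excluded from means and counted in the
#' `n_inf_excluded` attribute; a category with no records yields `NA`.
#'
#' @param records row-bound output of [evaluate_method()] calls.
#' @param bin_widths,noise_levels the grid to tabulate (defaults to the
#'   values present in `records`).
#' @return An object of class `xfct_metrics_table`: list of tibbles `psnr`
#'   and `ssim` plus `metadata`.
#' @export
build_tables <- function(records, bin_widths = NULL, noise_levels = NULL) {
  stopifnot(nrow(records) > 0)
  if (is.null(bin_widths)) bin_widths <- sort(unique(records$bin_width))
  if (is.null(noise_levels)) noise_levels <- sort(unique(records$noise_level))
  methods <- unique(records$method)
  grid <- tidyr::expand_grid(bin_width = bin_widths,
                             noise_level = noise_levels)
  n_inf <- 0L
  cell <- function(bw, nl, m, what) {
    v <- records[[what]][records$bin_width == bw &
                         records$noise_level == nl & records$method == m]
    if (!length(v)) return(NA_real_)
    if (what == "psnr_db") {
      inf <- !is.finite(v)
      n_inf <<- n_inf + sum(inf)
      v <- v[!inf]
      if (!length(v)) return(Inf)
    }
    mean(v)
  }
  mk <- function(what) {
    t <- grid
    for (m in methods)
      t[[m]] <- mapply(function(b, n) cell(b, n, m, what),
                       grid$bin_width, grid$noise_level)
    t
  }
  psnr_t <- mk("psnr_db")
  ssim_t <- mk("ssim")
  if (anyNA(psnr_t[methods]))
    message("metrics table has gaps (NA cells) for uncovered categories")
  structure(list(psnr = psnr_t, ssim = ssim_t,
                 metadata = list(methods = methods,
                                 n_inf_excluded = n_inf,
                                 ssim_window = 11, ssim_sigma = 1.5,
                                 K1 = 0.01, K2 = 0.03, data_range = 1)),
            class = "xfct_metrics_table")
}

format_table_cells <- function(t) {
  out <- as.data.frame(t)
  for (j in seq_along(out))
    if (is.numeric(out[[j]]) && !(names(out)[j] %in% c("bin_width", "noise_level")))
      out[[j]] <- ifelse(is.infinite(out[[j]]), "inf",
                         ifelse(is.na(out[[j]]), "NA",
                                sprintf("%.6f", out[[j]])))
  out
}

#' Write one benchmark table as CSV
#'
#' Numeric cells use six decimals; infinite PSNR is rendered as `"inf"`.
#' The CSV round-trips losslessly through [read_metrics_csv()].
#'
#' @param table the `psnr` or `ssim` member of an `xfct_metrics_table`.
#' @param path output path.
#' @export
write_metrics_csv <- function(table, path) {
  utils::write.csv(format_table_cells(table), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_metrics_csv
#' @export
read_metrics_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  for (j in setdiff(names(df), c("bin_width", "noise_level")))
    df[[j]] <- ifelse(df[[j]] == "inf", Inf,
                      suppressWarnings(as.numeric(df[[j]])))
  tibble::as_tibble(df)
}

#' Render a Markdown benchmark report
#'
#' @param tables an `xfct_metrics_table`.
#' @param path output Markdown file.
#' @export
write_metrics_markdown <- function(tables, path) {
  md_table <- function(t, title) {
    f <- format_table_cells(t)
    c(paste0("## ", title), "",
      paste0("| ", paste(names(f), collapse = " | "), " |"),
      paste0("|", paste(rep("---", ncol(f)), collapse = "|"), "|"),
      apply(f, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |")),
      "")
  }
  lines <- c("# Denoising benchmark", "",
             sprintf("SSIM: %dx%d Gaussian window, sigma %.1f, K1 %.2f, K2 %.2f, data range %g.",
                     tables$metadata$ssim_window, tables$metadata$ssim_window,
                     tables$metadata$ssim_sigma, tables$metadata$K1,
                     tables$metadata$K2, tables$metadata$data_range),
             sprintf("Infinite PSNR values excluded from means: %d.",
                     tables$metadata$n_inf_excluded), "",
             md_table(tables$psnr, "Mean PSNR (dB)"),
             md_table(tables$ssim, "Mean SSIM"))
  writeLines(lines, path)
  invisible(path)
}

#' @export
tidy.xfct_metrics_table <- function(x, ...) {
  long <- function(t, what)
    tidyr::pivot_longer(t, -c("bin_width", "noise_level"),
                        names_to = "method", values_to = what)
  dplyr::left_join(long(x$psnr, "psnr_db"), long(x$ssim, "ssim"),
                   by = c("bin_width", "noise_level", "method"))
}

#' @export
glance.xfct_metrics_table <- function(x, ...) {
  d <- tidy(x)
  tibble::tibble(n_cells = nrow(d),
                 n_methods = length(x$metadata$methods),
                 best_method = d$method[which.max(d$psnr_db)],
                 max_psnr_db = max(d$psnr_db[is.finite(d$psnr_db)], na.rm = TRUE),
                 max_ssim = max(d$ssim, na.rm = TRUE))
}

#' Plot a benchmark table as a method-by-condition heat map
#'
#' @param object an `xfct_metrics_table`.
#' @param metric `"psnr_db"` or `"ssim"`.
#' @param ... unused.
#' @export
autoplot.xfct_metrics_table <- function(object, metric = c("psnr_db", "ssim"),
                                        ...) {
  metric <- match.arg(metric)
  d <- tidy(object)
  d$cond <- sprintf("BW %.2g / %g%%", d$bin_width, d$noise_level)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$method, y = .data$cond,
                                  fill = .data[[metric]])) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data[[metric]])),
                       size = 3) +
    ggplot2::labs(x = NULL, y = NULL, fill = metric)
}

#' Write qualitative comparison panels
#'
#' For each pair, one PNG with tiles `clean | noisy | <method>...` in the
#' given method order, grey-scale, labelled. Purely presentational.
#'
#' @param pairs list of [image_pair()]s (at least one).
#' @param methods character vector of registered method names.
#' @param out_dir output directory (created if needed).
#' @param ctx context passed to learned methods (e.g. `model`).
#' @return Character vector of written file paths.
#' @export
render_panels <- function(pairs, methods, out_dir, ctx = list()) {
  if (!length(pairs)) stop("render_panels needs at least one pair")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(pairs))
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    tiles <- c(list(clean = p$clean, noisy = p$noisy),
               setNames(lapply(methods, function(m)
                 get_denoiser(m)(p$noisy, ctx)), methods))
    path <- file.path(out_dir, sprintf("panel_%03d.png", i))
    grDevices::png(path, width = 220 * length(tiles), height = 240)
    op <- graphics::par(mfrow = c(1, length(tiles)), mar = c(0.5, 0.5, 2, 0.5))
    for (nm in names(tiles)) {
      m <- tiles[[nm]]
      graphics::image(t(m[nrow(m):1, , drop = FALSE]), col = grDevices::gray.colors(256, 0, 1),
                      zlim = c(0, 1), axes = FALSE, main = nm)
    }
    graphics::par(op)
    grDevices::dev.off()
    paths[i] <- path
  }
  paths
}
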