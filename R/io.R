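#' Write a count image as 16-bit grayscale TIFF
#'
#' @param img an `xfct_count_image`.
#' @param path output path.
#' @export
write_count_tiff <- function(img, path) {
  stopifnot(inherits(img, "xfct_count_image"))
  if (max(img$counts) > 65535) stop("counts exceed 16-bit range")
  tiff::writeTIFF(img$counts / 65535, path, bits.per.sample = 16)
  invisible(path)
}

#' Read a 16-bit count TIFF written by [write_count_tiff()]
#'
#' @param path file path.
#' @param dose_fraction,bin_width_keV metadata to attach.
#' @export
read_count_tiff <- function(path, dose_fraction = 1, bin_width_keV = 0.5) {
  m <- tiff::readTIFF(path)
  count_image(round(m * 65535), dose_fraction, bin_width_keV)
}

#' Write a normalized float image as 32-bit float TIFF
#' @param img numeric matrix in \[0, 1\]; @param path output path.
#' @export
write_float_tiff <- function(img, path) {
  tiff::writeTIFF(img, path, bits.per.sample = 32)
  invisible(path)
}

#' @rdname write_float_tiff
#' @export
read_float_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  m
}

#' Write a dataset to disk (float TIFF pairs + JSON manifest)
#'
#' The manifest records pair paths, metadata, split membership, the
#' normalization constants and the master seed; it is byte-deterministic
#' for a fixed dataset.
#'
#' @param dataset an `xfct_dataset` from [build_dataset()].
#' @param dir output directory.
#' @return The manifest path.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "xfct_dataset"))
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  man <- dataset$manifest
  man$noisy_path <- sprintf("images/pair_%04d_noisy.tif", man$pair_id)
  man$clean_path <- sprintf("images/pair_%04d_clean.tif", man$pair_id)
  for (i in seq_len(nrow(man))) {
    p <- dataset$pairs[[man$pair_id[i]]]
    write_float_tiff(p$noisy, file.path(dir, man$noisy_path[i]))
    write_float_tiff(p$clean, file.path(dir, man$clean_path[i]))
  }
  manifest <- list(
    seed = dataset$seed,
    bin_widths = dataset$bin_widths,
    noise_levels = dataset$noise_levels,
    test_fraction = dataset$split$test_fraction,
    norms = lapply(dataset$norms, unclass),
    pairs = man)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir dataset directory containing `manifest.json`.
#' @return An `xfct_dataset` (pairs, split, manifest, norms, seed).
#' @export
read_dataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  man <- tibble::as_tibble(manifest$pairs)
  pairs <- lapply(seq_len(nrow(man)), function(i) {
    image_pair(read_float_tiff(file.path(dir, man$noisy_path[i])),
               read_float_tiff(file.path(dir, man$clean_path[i])),
               meta = list(noise_level = man$noise_level[i],
                           bin_width = man$bin_width[i],
                           augmentation = man$augmentation[i],
                           phantom_id = man$phantom_id[i],
                           pair_id = man$pair_id[i]))
  })
  split <- dataset_split(man$pair_id[man$split == "train"],
                         man$pair_id[man$split == "test"],
                         manifest$test_fraction)
  norms <- lapply(manifest$norms, function(n)
    if (n$type == "fixed_range") norm_fixed_range(n$cmax) else norm_per_image_max())
  structure(list(pairs = pairs, split = split,
                 manifest = man[, c("pair_id", "phantom_id", "bin_width",
                                    "noise_level", "augmentation", "split")],
                 norms = norms, seed = manifest$seed,
                 bin_widths = manifest$bin_widths,
                 noise_levels = manifest$noise_levels),
            class = "xfct_dataset")
}

#' Write phantom specifications to a YAML config
#'
#' @param specs list of [phantom_spec()]s.
#' @param path output YAML path.
#' @export
write_phantom_config <- function(specs, path) {
  if (inherits(specs, "xfct_phantom_spec")) specs <- list(specs)
  out <- lapply(specs, function(s) {
    s <- unclass(s)
    s$tubes <- lapply(s$tubes, unclass)
    s
  })
  yaml::write_yaml(list(phantoms = out), path)
  invisible(path)
}

#' @rdname write_phantom_config
#' @export
read_phantom_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  lapply(cfg$phantoms, function(s)
    phantom_spec(image_size = unlist(s$image_size),
                 hexagon_circumradius = s$hexagon_circumradius,
                 water_level = s$water_level, compton_level = s$compton_level,
                 signal_gain = s$signal_gain, psf_sigma = s$psf_sigma,
                 tubes = lapply(s$tubes, function(tb)
                   tube_spec(unlist(tb$center), tb$radius, tb$concentration)),
                 pixel_size_mm = s$pixel_size_mm))
}
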