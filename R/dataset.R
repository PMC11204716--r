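#' Construct a (noisy, clean) training pair
#'
#' @param noisy,clean H x W numeric matrices in \[0, 1\] of identical shape.
#' @param meta list with `noise_level` (percent of photons removed),
#'   `bin_width`, `augmentation` tag and `phantom_id`.
#' @return An object of class `xfct_image_pair`.
#' @export
image_pair <- function(noisy, clean, meta = list()) {
  noisy <- as.matrix(noisy); clean <- as.matrix(clean)
  if (!identical(dim(noisy), dim(clean))) stop("noisy/clean shape mismatch")
  if (min(noisy, clean) < 0 || max(noisy, clean) > 1)
    stop("pair values must lie in [0, 1]")
  structure(list(noisy = noisy, clean = clean, meta = meta),
            class = "xfct_image_pair")
}

# counter-clockwise quarter rotation
rot90_ccw <- function(m) {
  mt <- t(m)
  mt[nrow(mt):1, , drop = FALSE]
}

#' Augment image pairs by quarter rotations
#'
#' Returns the original pairs plus their 90, 180 and 270 degree rotations
#' (counter-clockwise, applied identically to the noisy and clean member),
#' tagged `r0`, `r90`, `r180`, `r270`. Output size is 4x the input.
#'
#' @param pairs list of [image_pair()] objects with square images.
#' @return list of `xfct_image_pair`, length `4 * length(pairs)`.
#' @export
augment_rotations <- function(pairs) {
  out <- vector("list", 4L * length(pairs))
  k <- 0L
  for (p in pairs) {
    stopifnot(inherits(p, "xfct_image_pair"))
    if (nrow(p$noisy) != ncol(p$noisy))
      stop("rotation augmentation requires square images")
    n <- p$noisy; c <- p$clean
    for (tag in c("r0", "r90", "r180", "r270")) {
      k <- k + 1L
      meta <- p$meta
      meta$augmentation <- tag
      out[[k]] <- image_pair(n, c, meta)
      n <- rot90_ccw(n); c <- rot90_ccw(c)
    }
  }
  out
}

#' Stratified train/test split
#'
#' @param train_ids,test_ids disjoint integer id vectors covering the dataset.
#' @param test_fraction nominal test fraction.
#' @export
dataset_split <- function(train_ids, test_ids, test_fraction = 0.2) {
  if (length(intersect(train_ids, test_ids)))
    stop("train and test ids overlap")
  structure(list(train_ids = sort(train_ids), test_ids = sort(test_ids),
                 test_fraction = test_fraction),
            class = "xfct_dataset_split")
}

#' Build an augmented, split, multi-dose synthetic dataset
#'
#' For each phantom spec and bin width one full-dose Poisson count image is
#' sampled; for each noise level a binomially thinned copy provides the noisy
#' input, while the clean target is always the normalized full-dose image of
#' the same geometry. Pairs are then rotation-augmented and split into
#' train/test with `round(test_fraction * N)` test pairs per
#' (noise level, bin width) category. Every random draw is derived from the
#' single master `seed` through [child_seed()].
#'
#' Normalization is fixed-range with `cmax` the 99.5th percentile of the
#' full-dose counts, computed per bin width and shared across dose levels,
#' so that dose reduction visibly darkens images.
#'
#' @param specs non-empty list of [phantom_spec()] objects.
#' @param noise_levels percent of photons removed, default `c(25, 50, 75)`.
#' @param bin_widths energy-bin widths in keV, default `c(0.05, 0.1, 0.5)`.
#' @param seed master integer seed.
#' @param test_fraction held-out fraction per category (default 0.2).
#' @param exposure_scale exposure factor passed to [sample_counts()].
#' @param augment apply rotation augmentation (default TRUE).
#' @param cmax_quantile quantile of full-dose counts defining `cmax`.
#' @return An object of class `xfct_dataset`: list with `pairs` (list of
#'   `xfct_image_pair`), `split` (`xfct_dataset_split`), `manifest` (tibble),
#'   `norms` (per-bin normalization objects) and `seed`.
#' @export
build_dataset <- function(specs, noise_levels = c(25, 50, 75),
                          bin_widths = c(0.05, 0.1, 0.5), seed = 1L,
                          test_fraction = 0.2, exposure_scale = 1,
                          augment = TRUE, cmax_quantile = 0.995) {
  if (inherits(specs, "xfct_phantom_spec")) specs <- list(specs)
  if (!length(specs)) stop("specs must be a non-empty list of phantom specs")
  stopifnot(all(noise_levels > 0), all(noise_levels < 100))

  cleans <- lapply(specs, render_phantom)
  ctr <- 0L
  full <- list()   # full[[bin]][[spec]]
  for (b in seq_along(bin_widths)) {
    full[[b]] <- list()
    for (s in seq_along(specs)) {
      ctr <- ctr + 1L
      full[[b]][[s]] <- sample_counts(cleans[[s]], bin_widths[b],
                                      exposure_scale,
                                      seed = child_seed(seed, ctr))
    }
  }
  norms <- lapply(seq_along(bin_widths), function(b) {
    allc <- unlist(lapply(full[[b]], function(ci) as.vector(ci$counts)))
    cmax <- as.numeric(quantile(allc, cmax_quantile, names = FALSE))
    norm_fixed_range(max(cmax, 1))
  })
  names(norms) <- format(bin_widths, trim = TRUE)

  pairs <- list()
  for (b in seq_along(bin_widths)) {
    for (s in seq_along(specs)) {
      clean01 <- counts_to_float(full[[b]][[s]], norms[[b]])
      for (L in noise_levels) {
        ctr <- ctr + 1L
        thin <- thin_counts(full[[b]][[s]], keep_fraction = 1 - L / 100,
                            seed = child_seed(seed, ctr))
        noisy01 <- counts_to_float(thin, norms[[b]])
        pairs[[length(pairs) + 1L]] <- image_pair(
          noisy01, clean01,
          meta = list(noise_level = L, bin_width = bin_widths[b],
                      augmentation = "r0", phantom_id = s))
      }
    }
  }
  if (augment) pairs <- augment_rotations(pairs)
  for (i in seq_along(pairs)) pairs[[i]]$meta$pair_id <- i

  manifest <- tibble::tibble(
    pair_id = seq_along(pairs),
    phantom_id = vapply(pairs, function(p) p$meta$phantom_id, 0),
    bin_width = vapply(pairs, function(p) p$meta$bin_width, 0),
    noise_level = vapply(pairs, function(p) p$meta$noise_level, 0),
    augmentation = vapply(pairs, function(p) p$meta$augmentation, ""))

  # stratified split per (noise level, bin width) category
  test_ids <- integer(0)
  cat_key <- paste(manifest$bin_width, manifest$noise_level)
  for (k in unique(cat_key)) {
    ids <- manifest$pair_id[cat_key == k]
    n_test <- round(test_fraction * length(ids))
    ctr <- ctr + 1L
    picked <- with_local_seed(child_seed(seed, ctr),
                              sample(ids, n_test))
    test_ids <- c(test_ids, picked)
  }
  split <- dataset_split(setdiff(manifest$pair_id, test_ids), test_ids,
                         test_fraction)
  manifest$split <- ifelse(manifest$pair_id %in% split$test_ids,
                           "test", "train")
  structure(list(pairs = pairs, split = split, manifest = manifest,
                 norms = norms, seed = as.integer(seed),
                 bin_widths = bin_widths, noise_levels = noise_levels),
            class = "xfct_dataset")
}

#' Extract the train or test pairs of a dataset
#'
#' @param dataset an `xfct_dataset`.
#' @param which `"train"` or `"test"`.
#' @export
dataset_pairs <- function(dataset, which = c("train", "test")) {
  which <- match.arg(which)
  ids <- if (which == "train") dataset$split$train_ids else dataset$split$test_ids
  dataset$pairs[ids]
}
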