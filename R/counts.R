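#' Construct a photon-count image
#'
#' Integer count image carrying its dose fraction (fraction of photons kept
#' relative to the full-dose acquisition) and energy-bin width.
#'
#' @param counts H x W non-negative integer matrix.
#' @param dose_fraction fraction of photons kept, in (0, 1].
#' @param bin_width_keV energy-bin width in keV.
#' @param seed seed that produced the counts (for provenance).
#' @return An object of class `xfct_count_image`.
#' @export
count_image <- function(counts, dose_fraction = 1, bin_width_keV = 0.5,
                        seed = NA_integer_) {
  counts <- as.matrix(counts)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (!is.finite(dose_fraction) || dose_fraction <= 0 || dose_fraction > 1)
    stop("dose_fraction must lie in (0, 1]")
  structure(list(counts = counts, dose_fraction = dose_fraction,
                 bin_width_keV = bin_width_keV, seed = seed),
            class = "xfct_count_image")
}

#' Sample a Poisson count image from a clean expected-count image
#'
#' Each pixel is drawn as `Poisson(clean * exposure_scale * bin_width/0.5)`;
#' 0.5 keV is the reference bin width, so narrower energy bins proportionally
#' reduce the expected number of entries per bin. The result is a full-dose
#' acquisition (`dose_fraction = 1`).
#'
#' @param clean an `xfct_clean_image` (or non-negative matrix).
#' @param bin_width_keV energy-bin width in keV.
#' @param exposure_scale multiplicative exposure factor, > 0.
#' @param seed integer seed; the same seed yields bit-identical counts.
#' @return An `xfct_count_image` with `dose_fraction = 1`.
#' @export
sample_counts <- function(clean, bin_width_keV = 0.5, exposure_scale = 1,
                          seed = 1L) {
  px <- if (inherits(clean, "xfct_clean_image")) clean$pixels else as.matrix(clean)
  if (any(!is.finite(px))) stop("clean image contains non-finite pixels")
  if (any(px < 0)) stop("clean image contains negative pixels")
  if (!is.finite(exposure_scale) || exposure_scale <= 0)
    stop("exposure_scale must be > 0")
  lam <- px * exposure_scale * bin_width_keV / 0.5
  counts <- with_local_seed(seed,
    matrix(rpois(length(lam), as.vector(lam)), nrow(lam), ncol(lam)))
  count_image(counts, dose_fraction = 1, bin_width_keV = bin_width_keV,
              seed = as.integer(seed))
}

#' Thin a count image by binomial photon subsampling
#'
#' Physically faithful dose reduction: every photon is independently kept
#' with probability `keep_fraction`, i.e. each pixel count is replaced by a
#' `Binomial(count, keep_fraction)` draw. The study's "noise level L%" label
#' maps to `keep_fraction = 1 - L/100`.
#'
#' @param img an `xfct_count_image`.
#' @param keep_fraction probability of keeping each photon, in \[0, 1\].
#' @param seed integer seed.
#' @return An `xfct_count_image` whose `dose_fraction` is multiplied by
#'   `keep_fraction`.
#' @export
thin_counts <- function(img, keep_fraction, seed = 1L) {
  stopifnot(inherits(img, "xfct_count_image"))
  if (!is.finite(keep_fraction) || keep_fraction < 0 || keep_fraction > 1)
    stop("keep_fraction must lie in [0, 1]")
  if (keep_fraction == 1) return(img)
  cts <- img$counts
  thinned <- with_local_seed(seed,
    matrix(rbinom(length(cts), size = as.vector(cts), prob = keep_fraction),
           nrow(cts), ncol(cts)))
  df <- img$dose_fraction * keep_fraction
  if (df <= 0) df <- .Machine$double.xmin  # keep_fraction 0: degenerate all-zero image
  out <- count_image(thinned, dose_fraction = min(df, 1),
                     bin_width_keV = img$bin_width_keV, seed = as.integer(seed))
  if (keep_fraction == 0) out$counts[] <- 0L
  out
}

#' Fixed-range count normalization
#'
#' Divides counts by `cmax` and clips into \[0, 1\]. Shared across dose levels
#' so that dose reduction visibly darkens images.
#' @param cmax positive count ceiling.
#' @export
norm_fixed_range <- function(cmax) {
  stopifnot(is.finite(cmax), cmax > 0)
  structure(list(type = "fixed_range", cmax = cmax), class = "xfct_norm")
}

#' Per-image maximum normalization
#' @export
norm_per_image_max <- function() {
  structure(list(type = "per_image_max"), class = "xfct_norm")
}

#' Convert a count image to a normalized float image in \[0, 1\]
#'
#' @param img an `xfct_count_image`.
#' @param norm a normalization object from [norm_fixed_range()] or
#'   [norm_per_image_max()].
#' @return H x W numeric matrix in \[0, 1\].
#' @export
counts_to_float <- function(img, norm) {
  stopifnot(inherits(img, "xfct_count_image"), inherits(norm, "xfct_norm"))
  cts <- img$counts
  if (norm$type == "per_image_max") {
    mx <- max(cts)
    if (mx == 0) {
      warning("all-zero count image under per_image_max normalization")
      return(cts * 0)
    }
    return(cts / mx)
  }
  clip01(cts / norm$cmax)
}
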