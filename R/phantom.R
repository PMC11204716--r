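#' Specify a gadolinium tube insert
#'
#' A circular Gd-filled tube inside the water phantom. Concentrations are Gd
#' weight fractions; the benchtop study conditions span 0 to 0.0031 (0 to
#' 3.1 mg/mL).
#'
#' @param center numeric length-2 `(row, col)` center in pixels (1-based).
#' @param radius tube radius in pixels, > 0.
#' @param concentration Gd weight fraction, >= 0.
#' @return An object of class `xfct_tube_spec`.
#' @export
tube_spec <- function(center, radius, concentration) {
  stopifnot(length(center) == 2, is.finite(center))
  if (!is.finite(radius) || radius <= 0) stop("tube radius must be > 0")
  if (!is.finite(concentration) || concentration < 0)
    stop("tube concentration must be >= 0")
  structure(list(center = as.numeric(center), radius = as.numeric(radius),
                 concentration = as.numeric(concentration)),
            class = "xfct_tube_spec")
}

#' Specify a synthetic hexagonal XRF phantom slice
#'
#' Geometric and intensity description of one reconstructed XRF slice of a
#' water-filled hexagonal container with circular Gd tube inserts. Intensity
#' levels are expected photon counts per pixel at the reference exposure
#' (full dose, 0.5 keV bin).
#'
#' Defaults emulate the benchtop conditions at a 64 mm field of view: a
#' hexagon of 50 mm maximum diameter (25 mm circumradius) and 8 mm diameter
#' tubes, scaled to the requested image size.
#'
#' @param image_size integer length-2 `(H, W)`, both >= 32.
#' @param hexagon_circumradius circumradius of the flat-top hexagon in pixels.
#' @param water_level expected counts/pixel inside the water region.
#' @param compton_level expected diffuse Compton background counts/pixel,
#'   added over the whole field of view.
#' @param signal_gain expected counts/pixel per unit Gd weight fraction.
#' @param psf_sigma Gaussian point-spread sigma in pixels (0 disables).
#' @param tubes list of [tube_spec()] objects.
#' @param pixel_size_mm physical pixel pitch.
#' @return An object of class `xfct_phantom_spec`.
#' @export
phantom_spec <- function(image_size = c(64L, 64L),
                         hexagon_circumradius = 25 / (64 / image_size[1]),
                         water_level = 20,
                         compton_level = 5,
                         signal_gain = 65000,
                         psf_sigma = 1,
                         tubes = list(),
                         pixel_size_mm = 64 / image_size[1]) {
  image_size <- as.integer(image_size)
  stopifnot(length(image_size) == 2)
  if (any(image_size < 32)) stop("image_size must be at least 32 x 32")
  if (water_level < 0 || compton_level < 0 || signal_gain < 0)
    stop("intensity levels must be >= 0")
  H <- image_size[1]; W <- image_size[2]
  if (2 * hexagon_circumradius > min(H, W))
    stop("hexagon does not fit in the image")
  if (length(tubes) && inherits(tubes, "xfct_tube_spec")) tubes <- list(tubes)
  for (tb in tubes) stopifnot(inherits(tb, "xfct_tube_spec"))
  structure(list(image_size = image_size,
                 hexagon_circumradius = hexagon_circumradius,
                 water_level = water_level, compton_level = compton_level,
                 signal_gain = signal_gain, psf_sigma = psf_sigma,
                 tubes = tubes, pixel_size_mm = pixel_size_mm),
            class = "xfct_phantom_spec")
}

# Pixel-center membership mask of a centered, flat-top regular hexagon.
hexagon_mask <- function(H, W, R) {
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  y <- matrix(seq_len(H) - cy, H, W)
  x <- matrix(rep(seq_len(W) - cx, each = H), H, W)
  h <- sqrt(3) * R / 2
  (abs(y) <= h) & (abs(sqrt(3) * x + y) <= 2 * h) & (abs(sqrt(3) * x - y) <= 2 * h)
}

disc_mask <- function(H, W, center, radius) {
  y <- matrix(seq_len(H) - center[1], H, W)
  x <- matrix(rep(seq_len(W) - center[2], each = H), H, W)
  y^2 + x^2 <= radius^2
}

#' Render a clean (noise-free expected-count) phantom image
#'
#' Deterministically paints the water hexagon, adds the diffuse Compton
#' background over the whole field of view, adds `signal_gain * concentration`
#' on every tube disc, and finally applies a Gaussian point-spread blur.
#' The result is on the expected-count scale, ready for Poisson sampling with
#' [sample_counts()].
#'
#' @param spec an [phantom_spec()] object.
#' @return An object of class `xfct_clean_image` with fields `pixels`
#'   (H x W matrix, >= 0) and `pixel_size_mm`.
#' @export
render_phantom <- function(spec) {
  stopifnot(inherits(spec, "xfct_phantom_spec"))
  H <- spec$image_size[1]; W <- spec$image_size[2]
  hex <- hexagon_mask(H, W, spec$hexagon_circumradius)
  img <- matrix(spec$compton_level, H, W)
  img[hex] <- img[hex] + spec$water_level
  for (k in seq_along(spec$tubes)) {
    tb <- spec$tubes[[k]]
    disc <- disc_mask(H, W, tb$center, tb$radius)
    if (!any(disc)) stop(sprintf("tube %d covers no pixels", k))
    if (any(disc & !hex))
      stop(sprintf("tube %d lies outside the hexagonal phantom", k))
    img[disc] <- img[disc] + spec$signal_gain * tb$concentration
  }
  if (spec$psf_sigma > 0) img <- gaussian_blur(img, spec$psf_sigma)
  img[img < 0] <- 0
  structure(list(pixels = img, pixel_size_mm = spec$pixel_size_mm),
            class = "xfct_clean_image")
}

#' Gd concentrations used in the benchtop study conditions
#'
#' Weight fractions corresponding to 0, 0.31, 1.0, 2.0 and 3.1 mg/mL.
#' @export
gd_concentrations <- c(0, 0.00031, 0.001, 0.002, 0.0031)

#' Draw a random phantom specification
#'
#' Places 1-4 tubes (8 mm diameter at the default field of view) uniformly
#' inside the hexagon with concentrations drawn from [gd_concentrations].
#' Used to build synthetic training/evaluation datasets.
#'
#' @param image_size integer length-2.
#' @param seed integer seed for the placement RNG.
#' @param n_tubes number of tubes; by default drawn in 1..4.
#' @inheritParams phantom_spec
#' @return An `xfct_phantom_spec`.
#' @export
random_phantom_spec <- function(image_size = c(64L, 64L), seed = 1L,
                                n_tubes = NULL, water_level = 20,
                                compton_level = 5, signal_gain = 65000,
                                psf_sigma = 1) {
  with_local_seed(seed, {
    H <- image_size[1]; W <- image_size[2]
    px_mm <- 64 / H
    R <- 25 / px_mm
    r_tube <- 4 / px_mm
    if (is.null(n_tubes)) n_tubes <- sample(1:4, 1)
    hex <- hexagon_mask(H, W, R)
    tubes <- list()
    tries <- 0
    while (length(tubes) < n_tubes && tries < 500) {
      tries <- tries + 1
      cy <- runif(1, (H + 1) / 2 - R, (H + 1) / 2 + R)
      cx <- runif(1, (W + 1) / 2 - R, (W + 1) / 2 + R)
      disc <- disc_mask(H, W, c(cy, cx), r_tube)
      if (!any(disc) || any(disc & !hex)) next
      ok <- TRUE
      for (tb in tubes)
        if (sum((tb$center - c(cy, cx))^2) < (2 * r_tube + 1)^2) ok <- FALSE
      if (!ok) next
      conc <- sample(gd_concentrations, 1)
      tubes <- c(tubes, list(tube_spec(c(cy, cx), r_tube, conc)))
    }
    phantom_spec(image_size = image_size, hexagon_circumradius = R,
                 water_level = water_level, compton_level = compton_level,
                 signal_gain = signal_gain, psf_sigma = psf_sigma,
                 tubes = tubes, pixel_size_mm = px_mm)
  })
}
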