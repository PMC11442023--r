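#' Generate a synthetic immunofluorescence image with known positive area
#'
#' Exactly `round(positive_fraction * prod(shape))` pixels are drawn positive
#' (uniformly at random across the grid), set to `fg_intensity`, the rest to
#' `bg_intensity`, and i.i.d. Gaussian noise of SD `noise_sd` is added.
#' Intensities are clamped at zero (fluorescence is non-negative).
#'
#' @param shape `c(nrow, ncol)` image grid.
#' @param positive_fraction target positive-area fraction in `[0, 1]`.
#' @param fg_intensity,bg_intensity mean intensities of positive/background
#'   pixels.
#' @param noise_sd additive Gaussian noise SD.
#' @param seed integer RNG seed.
#' @return a list with `image` (intensity matrix), `positive_mask` (logical
#'   matrix, the true positives) and `positive_fraction` (the realized
#'   count-based fraction, within one pixel of the request).
#' @export
#' @examples
#' h <- generate_histology_image(positive_fraction = 0.25, seed = 1)
#' positive_area_fraction(h$image, method = "otsu")  # ~25
generate_histology_image <- function(shape = c(256, 256),
                                     positive_fraction,
                                     fg_intensity = 0.8,
                                     bg_intensity = 0.2,
                                     noise_sd = 0.1, seed) {
  if (missing(seed) || !is.finite(seed))
    stop("'seed' is required", call. = FALSE)
  if (!is.finite(positive_fraction) || positive_fraction < 0 ||
      positive_fraction > 1)
    stop("'positive_fraction' must be in [0, 1]", call. = FALSE)
  if (fg_intensity <= bg_intensity)
    stop("'fg_intensity' must exceed 'bg_intensity'", call. = FALSE)
  set.seed(seed)
  n <- prod(shape)
  npos <- round(positive_fraction * n)
  img <- matrix(bg_intensity, shape[1], shape[2])
  mask <- matrix(FALSE, shape[1], shape[2])
  if (npos > 0) {
    idx <- sample.int(n, npos)
    img[idx] <- fg_intensity
    mask[idx] <- TRUE
  }
  if (noise_sd > 0) img <- img + matrix(stats::rnorm(n, 0, noise_sd),
                                        shape[1], shape[2])
  img[img < 0] <- 0
  list(image = img, positive_mask = mask, positive_fraction = npos / n)
}

#' Printed immunohistochemistry percent-area presets
#'
#' Mean percent-positive tissue areas reported for tyrosine hydroxylase (TH,
#' sympathetic nerve density) and chondroitin sulfate proteoglycan (CSPG) in
#' the remote and infarct regions of MI hearts: TH 6.41% remote vs 0.56%
#' infarct; CSPG 2.2% remote vs 21.1% infarct.
#'
#' @return a named list of fractions (not percent) keyed
#'   `th_remote`, `th_infarct`, `cspg_remote`, `cspg_infarct`.
#' @export
histology_presets <- function() {
  list(th_remote = 0.0641, th_infarct = 0.0056,
       cspg_remote = 0.022, cspg_infarct = 0.211)
}
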