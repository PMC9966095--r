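# Photometric (pixel-value) operators: brightness / contrast / saturation
# jitter, single-channel isolation, and RGB <-> HSL conversion. All are
# image-only in paired segmentation mode: they move no pixels, so the mask
# passes through untouched.

# Luma weights (ITU-601), pinned so every grayscale reduction in the package
# agrees.
.luma <- c(0.299, 0.587, 0.114)

# Internal: per-pixel luma of an image (H x W matrix).
luma_plane <- function(image) {
  arr <- as_image_array(image)
  if (dim(arr)[3] == 1L) arr[, , 1]
  else .luma[1] * arr[, , 1] + .luma[2] * arr[, , 2] + .luma[3] * arr[, , 3]
}

#' Adjust image brightness
#'
#' Multiplicative brightness: `out = clip01(factor * in)`.
#'
#' @param image numeric matrix or H x W x C array in \[0, 1\].
#' @param factor positive scale; 1 is the identity.
#' @return the adjusted image.
#' @export
adjust_brightness <- function(image, factor) {
  stopifnot(is.numeric(factor), length(factor) == 1L)
  if (factor <= 0) stop("brightness factor must be positive")
  validate_image(image)
  clip01(factor * image)
}

#' Adjust image contrast
#'
#' `out = clip01(m + factor * (in - m))` where `m` is the image's mean luma,
#' so factor 0 collapses the image to its mean gray and factor 1 is the
#' identity.
#'
#' @inheritParams adjust_brightness
#' @export
adjust_contrast <- function(image, factor) {
  stopifnot(is.numeric(factor), length(factor) == 1L)
  if (factor <= 0) stop("contrast factor must be positive")
  validate_image(image)
  m <- mean(luma_plane(image))
  clip01(m + factor * (image - m))
}

#' Adjust colour saturation
#'
#' `out = clip01(g + factor * (in - g))` where `g` is the per-pixel luma
#' replicated across channels; factor 0 yields grayscale, 1 is the identity.
#'
#' @param image 3-channel H x W x 3 array in \[0, 1\].
#' @param factor non-negative scale.
#' @export
adjust_saturation <- function(image, factor) {
  stopifnot(is.numeric(factor), length(factor) == 1L, factor >= 0)
  validate_image(image)
  if (n_channels(image) != 3L) stop("saturation requires a 3-channel image")
  g <- luma_plane(image)
  garr <- array(g, dim = dim(image))
  clip01(garr + factor * (image - garr))
}

#' Colour jitter specification
#'
#' @param brightness_range,contrast_range,saturation_range ordered pairs of
#'   positive reals; defaults `c(0.7, 1.3)`. Factors are drawn uniformly and
#'   applied in the fixed order brightness, contrast, saturation.
#' @return an object of class `jitter_spec`.
#' @export
jitter_spec <- function(brightness_range = c(0.7, 1.3),
                        contrast_range = c(0.7, 1.3),
                        saturation_range = c(0.7, 1.3)) {
  chk <- function(r, nm) {
    if (length(r) != 2L || r[1] <= 0 || r[1] > r[2])
      stop(nm, " must be an ordered strictly positive pair")
    as.numeric(r)
  }
  structure(list(brightness_range = chk(brightness_range, "brightness_range"),
                 contrast_range = chk(contrast_range, "contrast_range"),
                 saturation_range = chk(saturation_range, "saturation_range")),
            class = "jitter_spec")
}

#' Random colour jitter
#'
#' Draws one factor per property from `spec` and applies brightness, contrast
#' then saturation (saturation is skipped for single-channel images).
#'
#' @param image numeric matrix or H x W x C array in \[0, 1\].
#' @param spec a [jitter_spec()].
#' @return a list: `image` and `factors` (named vector of the sampled factors).
#' @export
color_jitter <- function(image, spec = jitter_spec()) {
  validate_image(image)
  b <- stats::runif(1, spec$brightness_range[1], spec$brightness_range[2])
  ct <- stats::runif(1, spec$contrast_range[1], spec$contrast_range[2])
  s <- stats::runif(1, spec$saturation_range[1], spec$saturation_range[2])
  out <- adjust_contrast(adjust_brightness(image, b), ct)
  if (n_channels(image) == 3L) out <- adjust_saturation(out, s)
  list(image = out, factors = c(brightness = b, contrast = ct, saturation = s))
}

#' Isolate one colour channel
#'
#' Keeps the selected channel and sets the other two to black.
#'
#' @param image 3-channel H x W x 3 array.
#' @param channel_index 0-based channel index in `{0, 1, 2}` (R, G, B).
#' @export
isolate_channel <- function(image, channel_index) {
  validate_image(image)
  if (n_channels(image) != 3L) stop("channel isolation requires a 3-channel image")
  if (!channel_index %in% 0:2) stop("channel_index must be 0, 1 or 2")
  out <- array(0, dim = dim(image))
  out[, , channel_index + 1] <- image[, , channel_index + 1]
  out
}

#' Convert RGB to HSL
#'
#' Standard hexcone conversion; all three output channels are scaled to
#' \[0, 1\] (hue stored as angle / 360).
#'
#' @param image 3-channel RGB array in \[0, 1\].
#' @return H x W x 3 array of (H, S, L).
#' @export
rgb_to_hsl <- function(image) {
  validate_image(image, require_unit = TRUE)
  if (n_channels(image) != 3L) stop("rgb_to_hsl requires a 3-channel image")
  r <- image[, , 1]; g <- image[, , 2]; b <- image[, , 3]
  mx <- pmax(r, g, b); mn <- pmin(r, g, b)
  l <- (mx + mn) / 2
  d <- mx - mn
  s <- ifelse(d == 0, 0, d / (1 - abs(2 * l - 1)))
  h <- matrix(0, nrow(r), ncol(r))
  nz <- d > 0
  hr <- nz & mx == r
  hg <- nz & mx == g & !hr
  hb <- nz & !hr & !hg
  h[hr] <- (((g - b) / d)[hr]) %% 6
  h[hg] <- ((b - r) / d)[hg] + 2
  h[hb] <- ((r - g) / d)[hb] + 4
  h <- h / 6
  out <- array(0, dim = dim(image))
  out[, , 1] <- h; out[, , 2] <- s; out[, , 3] <- l
  out
}

#' Convert HSL back to RGB
#'
#' Inverse of [rgb_to_hsl()]; the round trip is accurate to better than 1e-6
#' per channel.
#'
#' @param image H x W x 3 array of (H, S, L), each channel in \[0, 1\].
#' @return 3-channel RGB array.
#' @export
hsl_to_rgb <- function(image) {
  validate_image(image, require_unit = TRUE)
  if (n_channels(image) != 3L) stop("hsl_to_rgb requires a 3-channel image")
  h <- image[, , 1] * 6; s <- image[, , 2]; l <- image[, , 3]
  c <- (1 - abs(2 * l - 1)) * s
  x <- c * (1 - abs(h %% 2 - 1))
  m <- l - c / 2
  sector <- pmin(floor(h), 5)
  r1 <- ifelse(sector == 0 | sector == 5, c, ifelse(sector == 1 | sector == 4, x, 0))
  g1 <- ifelse(sector == 0 | sector == 3, x, ifelse(sector == 1 | sector == 2, c, 0))
  b1 <- ifelse(sector == 2 | sector == 5, x, ifelse(sector == 3 | sector == 4, c, 0))
  out <- array(0, dim = dim(image))
  out[, , 1] <- r1 + m; out[, , 2] <- g1 + m; out[, , 3] <- b1 + m
  clip01(out)
}
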