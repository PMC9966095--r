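# Noise injectors (Gaussian, salt-and-pepper, speckle) and random erasing.
# All draw from R's current RNG stream; all are image-only in paired
# segmentation mode (mask semantics under erasing are genuinely undefined —
# the rectangle may delete the object — so the mask is never touched).

#' Additive Gaussian noise
#'
#' `out = clip01(in + e)` with `e` i.i.d. normal(0, sigma^2) per pixel per
#' channel, independent of the signal.
#'
#' @param image numeric matrix or H x W x C array in \[0, 1\].
#' @param sigma non-negative noise standard deviation in intensity units.
#' @return the corrupted image.
#' @export
add_gaussian_noise <- function(image, sigma) {
  stopifnot(is.numeric(sigma), length(sigma) == 1L)
  if (sigma < 0) stop("sigma must be non-negative")
  validate_image(image)
  if (sigma == 0) return(image)
  clip01(image + stats::rnorm(length(image), 0, sigma))
}

#' Salt-and-pepper noise
#'
#' Each pixel is independently corrupted with probability `fraction`;
#' corrupted pixels are set jointly across channels to 1 (salt) or 0 (pepper)
#' with equal probability.
#'
#' @param image numeric matrix or H x W x C array in \[0, 1\].
#' @param fraction corruption probability in \[0, 1\].
#' @return the corrupted image.
#' @export
add_salt_pepper <- function(image, fraction) {
  stopifnot(is.numeric(fraction), length(fraction) == 1L)
  if (fraction < 0 || fraction > 1) stop("fraction must lie in [0, 1]")
  validate_image(image)
  if (fraction == 0) return(image)
  arr <- as_image_array(image)
  H <- dim(arr)[1]; W <- dim(arr)[2]
  hit <- stats::runif(H * W) < fraction
  val <- ifelse(stats::runif(H * W) < 0.5, 1, 0)
  for (ch in seq_len(dim(arr)[3])) {
    plane <- arr[, , ch]
    plane[hit] <- val[hit]
    arr[, , ch] <- plane
  }
  restore_dims(arr, image)
}

#' Multiplicative speckle noise
#'
#' `out = clip01(in * (1 + e))` with `e` i.i.d. normal(0, sigma^2), so the
#' noise amplitude scales with the signal (zero pixels stay zero).
#'
#' @inheritParams add_gaussian_noise
#' @export
add_speckle <- function(image, sigma) {
  stopifnot(is.numeric(sigma), length(sigma) == 1L)
  if (sigma < 0) stop("sigma must be non-negative")
  validate_image(image)
  if (sigma == 0) return(image)
  clip01(image * (1 + stats::rnorm(length(image), 0, sigma)))
}

#' Random-erasing specification
#'
#' @param area_fraction_range rectangle area as a fraction of the image area;
#'   default `c(0.02, 0.33)`.
#' @param aspect_ratio_range width / height bounds, drawn log-uniformly;
#'   default `c(0.3, 3.33)`.
#' @param fill_mode `"per_pixel_uniform"` (default: every erased pixel and
#'   channel gets an independent uniform \[0, 1\] value), `"single_uniform"`
#'   (one uniform value for the whole rectangle) or `"constant"`.
#' @param constant_value fill intensity for `"constant"`, default 0.
#' @return an object of class `erase_spec`.
#' @export
erase_spec <- function(area_fraction_range = c(0.02, 0.33),
                       aspect_ratio_range = c(0.3, 3.33),
                       fill_mode = c("per_pixel_uniform", "single_uniform",
                                     "constant"),
                       constant_value = 0) {
  fill_mode <- match.arg(fill_mode)
  a <- area_fraction_range; r <- aspect_ratio_range
  stopifnot(length(a) == 2L, a[1] > 0, a[1] <= a[2], a[2] <= 1,
            length(r) == 2L, r[1] > 0, r[1] <= r[2],
            constant_value >= 0, constant_value <= 1)
  structure(list(area_fraction_range = as.numeric(a),
                 aspect_ratio_range = as.numeric(r),
                 fill_mode = fill_mode,
                 constant_value = constant_value),
            class = "erase_spec")
}

#' Random erasing
#'
#' Overwrites a random axis-aligned rectangle with random values to simulate
#' occlusion; all pixels outside the rectangle are bitwise unchanged. The
#' realised rectangle is guaranteed to honour the configured area-fraction
#' bounds (draws whose rounding falls outside are retried).
#'
#' @param image numeric matrix or H x W x C array in \[0, 1\].
#' @param spec an [erase_spec()].
#' @param max_retries bounded retries for infeasible draws.
#' @return a list: `image` and `rect` (0-based `row`, `col`, `h`, `w` plus the
#'   fill record, for the manifest).
#' @export
random_erase <- function(image, spec = erase_spec(), max_retries = 100L) {
  validate_image(image)
  arr <- as_image_array(image)
  H <- dim(arr)[1]; W <- dim(arr)[2]
  a <- spec$area_fraction_range; r <- spec$aspect_ratio_range
  rect <- NULL
  for (i in seq_len(max_retries)) {
    af <- stats::runif(1, a[1], a[2])
    ar <- exp(stats::runif(1, log(r[1]), log(r[2])))
    target <- af * H * W
    w <- round(sqrt(target * ar))
    h <- round(sqrt(target / ar))
    realised <- h * w / (H * W)
    if (h >= 1 && w >= 1 && h <= H && w <= W &&
        realised >= a[1] && realised <= a[2]) {
      row <- if (H == h) 0L else sample.int(H - h + 1L, 1L) - 1L
      col <- if (W == w) 0L else sample.int(W - w + 1L, 1L) - 1L
      rect <- list(row = row, col = col, h = h, w = w)
      break
    }
  }
  if (is.null(rect))
    stop("no feasible erase rectangle found after ", max_retries, " draws")
  C <- dim(arr)[3]
  fill <- switch(spec$fill_mode,
                 per_pixel_uniform = stats::runif(rect$h * rect$w * C),
                 single_uniform = rep(stats::runif(1), rect$h * rect$w * C),
                 constant = rep(spec$constant_value, rect$h * rect$w * C))
  arr[rect$row + seq_len(rect$h), rect$col + seq_len(rect$w), ] <-
    array(fill, dim = c(rect$h, rect$w, C))
  rect$fill_mode <- spec$fill_mode
  if (spec$fill_mode == "single_uniform") rect$fill_value <- fill[1]
  if (spec$fill_mode == "constant") rect$fill_value <- spec$constant_value
  list(image = restore_dims(arr, image), rect = rect)
}
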