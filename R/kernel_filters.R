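# Convolution-based augmenters: Gaussian blur, Sobel edge response and
# unsharp-mask sharpening. All use reflect (edge-inclusive symmetric) borders
# and are image-only in paired segmentation mode.

# Internal: edge-inclusive symmetric reflection of 1-based indices.
reflect_idx <- function(idx, n) {
  m <- (idx - 1) %% (2 * n)
  m <- ifelse(m < 0, m + 2 * n, m)
  ifelse(m >= n, 2 * n - 1 - m, m) + 1
}

# Internal: 1-d convolution of matrix rows/cols with a symmetric kernel and
# reflect borders.
conv_axis <- function(plane, w, along = c("rows", "cols")) {
  along <- match.arg(along)
  k <- (length(w) - 1L) / 2L
  out <- matrix(0, nrow(plane), ncol(plane))
  n <- if (along == "rows") nrow(plane) else ncol(plane)
  for (j in -k:k) {
    idx <- reflect_idx(seq_len(n) + j, n)
    shifted <- if (along == "rows") plane[idx, , drop = FALSE]
               else plane[, idx, drop = FALSE]
    out <- out + w[j + k + 1] * shifted
  }
  out
}

# Internal: normalised Gaussian kernel truncated at ceil(3*sigma).
gaussian_kernel <- function(sigma) {
  k <- ceiling(3 * sigma)
  w <- stats::dnorm(-k:k, sd = sigma)
  w / sum(w)
}

#' Gaussian blur
#'
#' Separable convolution with a normalised Gaussian kernel truncated at a
#' half-width of `ceiling(3 * sigma)` pixels, reflect borders. The symmetric
#' kernel plus symmetric padding preserve the image mean exactly (up to
#' floating-point rounding).
#'
#' @param image numeric matrix or H x W x C array.
#' @param sigma positive blur scale in pixels.
#' @return the blurred image, same shape.
#' @export
gaussian_blur <- function(image, sigma) {
  stopifnot(is.numeric(sigma), length(sigma) == 1L)
  if (sigma <= 0) stop("sigma must be positive")
  validate_image(image)
  w <- gaussian_kernel(sigma)
  arr <- as_image_array(image)
  out <- arr
  for (ch in seq_len(dim(arr)[3]))
    out[, , ch] <- conv_axis(conv_axis(arr[, , ch], w, "rows"), w, "cols")
  restore_dims(out, image)
}

#' Sobel edge magnitude
#'
#' Gradient magnitude `sqrt(Gx^2 + Gy^2)` from the 3 x 3 Sobel pair on the
#' image luma, reflect borders, rescaled by the maximum possible response
#' (`4 * sqrt(2)` on a unit-range image) so the output lies in \[0, 1\].
#'
#' @param image single- or 3-channel grid in \[0, 1\] (3-channel images are
#'   reduced to luma first).
#' @return an H x W matrix of edge magnitudes in \[0, 1\].
#' @export
sobel_edges <- function(image) {
  validate_image(image)
  g <- luma_plane(image)
  smooth <- c(1, 2, 1)
  diff <- c(-1, 0, 1)
  gx <- conv_axis(conv_axis(g, smooth, "rows"), diff, "cols")
  gy <- conv_axis(conv_axis(g, diff, "rows"), smooth, "cols")
  sqrt(gx^2 + gy^2) / (4 * sqrt(2))
}

#' Unsharp-mask sharpening
#'
#' `out = clip01(in + amount * (in - gaussian_blur(in, sigma)))`.
#'
#' @param image numeric matrix or H x W x C array in \[0, 1\].
#' @param amount non-negative sharpening strength; 0 is the identity.
#' @param sigma blur scale of the unsharp mask, default 1.
#' @return the sharpened image.
#' @export
sharpen <- function(image, amount, sigma = 1) {
  stopifnot(is.numeric(amount), length(amount) == 1L)
  if (amount < 0) stop("amount must be non-negative")
  validate_image(image)
  if (amount == 0) return(image)
  clip01(image + amount * (image - gaussian_blur(image, sigma)))
}
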