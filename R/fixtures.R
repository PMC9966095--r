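# Synthetic data generators: nuclei-style microscopy image/mask pairs with
# exact ground-truth masks, and deterministic oracle patterns used by the
# geometric tests. Everything is generated in code; no downloads, no binary
# fixtures.

#' Configuration for the synthetic nuclei generator
#'
#' Emulates a fluorescence-microscopy nuclei field: bright elliptical blobs
#' with Gaussian intensity profiles on a dim noisy background, paired with a
#' binary mask that is exactly the union of the blob support ellipses.
#' Realism is secondary to having exact ground truth.
#'
#' @param canvas image shape `c(H, W)`, default `c(128, 128)`.
#' @param n_blobs number of nuclei; default `NULL` keeps a constant density of
#'   about 12 nuclei per 128 x 128 canvas.
#' @param radius_range semi-axis bounds in pixels; default `NULL` scales
#'   `c(4, 10)` (the 128 x 128 reference) with the canvas, never below 2 px.
#' @param intensity_range peak blob intensity bounds in (0, 1\], default
#'   `c(0.5, 1)`.
#' @param background_level mean background intensity, default 0.08.
#' @param background_sigma background Gaussian noise sd, default 0.02.
#' @param allow_overlap may blobs overlap? Default `FALSE` (placement is
#'   retried so masks stay disjoint and nuclei remain countable).
#' @return an object of class `nuclei_config`.
#' @export
nuclei_config <- function(canvas = c(128, 128), n_blobs = NULL,
                          radius_range = NULL,
                          intensity_range = c(0.5, 1),
                          background_level = 0.08,
                          background_sigma = 0.02,
                          allow_overlap = FALSE) {
  if (is.null(n_blobs))
    n_blobs <- max(2L, as.integer(round(prod(canvas) / 1365)))
  if (is.null(radius_range))
    radius_range <- pmax(2, c(4, 10) * min(canvas) / 128)
  stopifnot(length(canvas) == 2L, all(canvas >= 8),
            n_blobs >= 0,
            radius_range[1] > 0, radius_range[1] <= radius_range[2],
            intensity_range[1] > 0, intensity_range[1] <= intensity_range[2],
            intensity_range[2] <= 1,
            background_sigma >= 0, background_level >= 0)
  if (2 * radius_range[2] + 4 > min(canvas))
    stop("largest blob does not fit the canvas")
  structure(list(canvas = as.integer(canvas), n_blobs = as.integer(n_blobs),
                 radius_range = as.numeric(radius_range),
                 intensity_range = as.numeric(intensity_range),
                 background_level = background_level,
                 background_sigma = background_sigma,
                 allow_overlap = isTRUE(allow_overlap)),
            class = "nuclei_config")
}

#' Generate a synthetic nuclei image and its segmentation mask
#'
#' Blobs are rotated ellipses: a blob with semi-axes (a, b), orientation phi
#' and peak intensity A contributes `A * exp(-2 * q)` to the image, where
#' `q = (u/a)^2 + (v/b)^2 <= 1` inside its support ellipse; the mask is the
#' binary union of the support ellipses. With `allow_overlap = FALSE` blob
#' centres are rejected until every pair of support ellipses is separated by
#' at least two pixels, so the mask has exactly `n_blobs` connected
#' components. Deterministic given the RNG state (`set.seed()`).
#'
#' @param config a [nuclei_config()].
#' @param max_retries placement retries per blob when overlap is disallowed.
#' @return a list: `image` (H x W matrix in \[0, 1\]) and `mask` (H x W
#'   integer matrix, 1 = nucleus, 0 = background).
#' @examples
#' set.seed(7)
#' pair <- gen_nuclei(nuclei_config(canvas = c(64, 64), n_blobs = 4))
#' @export
gen_nuclei <- function(config = nuclei_config(), max_retries = 200L) {
  H <- config$canvas[1]; W <- config$canvas[2]
  img <- matrix(config$background_level, H, W)
  if (config$background_sigma > 0)
    img <- img + matrix(stats::rnorm(H * W, 0, config$background_sigma), H, W)
  img <- clip01(img)
  mask <- matrix(0L, H, W)
  if (config$n_blobs == 0) return(list(image = img, mask = mask))
  rows <- matrix(rep(seq_len(H) - 1, times = W), H, W)
  cols <- matrix(rep(seq_len(W) - 1, each = H), H, W)
  placed <- list()
  for (b in seq_len(config$n_blobs)) {
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      a <- stats::runif(1, config$radius_range[1], config$radius_range[2])
      bb <- stats::runif(1, config$radius_range[1], config$radius_range[2])
      phi <- stats::runif(1, 0, pi)
      rmax <- max(a, bb)
      cr <- stats::runif(1, rmax + 1, H - 2 - rmax)
      cc <- stats::runif(1, rmax + 1, W - 2 - rmax)
      if (!config$allow_overlap && length(placed) > 0) {
        # conservative separation test: centre distance vs summed extents + 2
        clash <- vapply(placed, function(p) {
          sqrt((p$cr - cr)^2 + (p$cc - cc)^2) < p$rmax + rmax + 2
        }, logical(1))
        if (any(clash)) next
      }
      ok <- TRUE
      break
    }
    if (!ok) stop("could not place blob ", b, " without overlap after ",
                  max_retries, " retries; reduce n_blobs or radius_range")
    A <- stats::runif(1, config$intensity_range[1], config$intensity_range[2])
    u <- cos(phi) * (rows - cr) + sin(phi) * (cols - cc)
    v <- -sin(phi) * (rows - cr) + cos(phi) * (cols - cc)
    q <- (u / a)^2 + (v / bb)^2
    inside <- q <= 1
    img[inside] <- clip01(img[inside] + A * exp(-2 * q[inside]))
    mask[inside] <- 1L
    placed[[b]] <- list(cr = cr, cc = cc, rmax = rmax)
  }
  list(image = clip01(img), mask = mask)
}

#' Coordinate-encoded oracle image
#'
#' Pixel (i, j) (0-based) carries the value `(i * W + j) / (H * W - 1)`, which
#' decodes uniquely back to (i, j). Used as a permutation oracle: after any
#' geometric transform with nearest interpolation, decoding each pixel reveals
#' exactly which source pixel it came from.
#'
#' @param shape `c(H, W)` with `H * W <= 2^31` (exact in double precision).
#' @return an H x W matrix in \[0, 1\].
#' @export
gen_coordinate_image <- function(shape) {
  H <- shape[1]; W <- shape[2]
  if (H * W > 2^31) stop("shape too large for exact coordinate encoding")
  k <- outer(seq_len(H) - 1, seq_len(W) - 1, function(i, j) i * W + j)
  k / (H * W - 1)
}

#' Decode a coordinate-encoded value back to (row, col)
#'
#' @param values numeric vector or matrix of encoded values.
#' @param shape the `c(H, W)` used when encoding.
#' @return a list of integer vectors/matrices `row`, `col` (0-based).
#' @export
decode_coordinates <- function(values, shape) {
  H <- shape[1]; W <- shape[2]
  k <- round(values * (H * W - 1))
  list(row = k %/% W, col = k %% W)
}

#' Canonical deterministic test patterns
#'
#' @param shape `c(H, W)`.
#' @param kind `"checkerboard"` (period-2, values 0/1), `"gradient"`
#'   (strictly increasing along columns) or `"constant"` (0.5 everywhere).
#' @return an H x W matrix in \[0, 1\].
#' @export
gen_pattern <- function(shape, kind = c("checkerboard", "gradient", "constant")) {
  kind <- match.arg(kind)
  H <- shape[1]; W <- shape[2]
  switch(kind,
         checkerboard = outer(seq_len(H) - 1, seq_len(W) - 1,
                              function(i, j) (i + j) %% 2),
         gradient = matrix(rep(seq_len(W) - 1, each = H) / (W - 1), H, W),
         constant = matrix(0.5, H, W))
}

#' Generate a synthetic nuclei dataset
#'
#' Builds `n` image/mask pairs with [gen_nuclei()], varying the blob count
#' around `config$n_blobs`, as an in-memory segmentation [aug_dataset()].
#'
#' @param n number of pairs.
#' @param config base [nuclei_config()].
#' @return an [aug_dataset()] of type `"segmentation"`.
#' @export
gen_nuclei_dataset <- function(n, config = nuclei_config()) {
  images <- vector("list", n)
  masks <- vector("list", n)
  for (i in seq_len(n)) {
    nb <- max(1L, config$n_blobs +
                sample.int(5L, 1L) - 3L)  # jitter blob count by -2..+2
    cfg <- config
    cfg$n_blobs <- nb
    pair <- gen_nuclei(cfg)
    images[[i]] <- pair$image
    masks[[i]] <- pair$mask
  }
  ids <- sprintf("nuclei_%04d", seq_len(n))
  names(images) <- ids
  names(masks) <- ids
  aug_dataset(images, masks = masks)
}
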