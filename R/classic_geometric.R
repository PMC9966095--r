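# Traditional geometric operators: flips, whole-image rotation with the four
# boundary fill policies, and random crop-and-resize.

#' Boundary fill policy for whole-image rotation
#'
#' When the inverse rotation map lands outside the image grid, the source
#' value is resolved by one of four policies: `"constant"` (traditional
#' rotation, TR: fill with `constant_value`, black by default), `"nearest"`
#' (RNR: clamp indices to the border), `"reflect"` (RRR: edge-inclusive
#' mirroring) or `"wrap"` (RWR: periodic indices).
#'
#' @param kind one of `"constant"`, `"nearest"`, `"reflect"`, `"wrap"`.
#' @param constant_value fill intensity in \[0, 1\] for `"constant"`; default 0.
#' @return an object of class `fill_policy`.
#' @export
fill_policy <- function(kind = c("constant", "nearest", "reflect", "wrap"),
                        constant_value = 0) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(constant_value), length(constant_value) == 1L,
            constant_value >= 0, constant_value <= 1)
  structure(list(kind = kind, constant_value = constant_value),
            class = "fill_policy")
}

# Internal: resolve 0-based integer indices against a grid of size n under a
# fill policy. Constant is handled by the caller (via the oob flag).
resolve_index <- function(idx, n, kind) {
  switch(kind,
         nearest = pmin(pmax(idx, 0), n - 1),
         reflect = {
           m <- idx %% (2 * n)
           ifelse(m >= n, 2 * n - 1 - m, m)
         },
         wrap = idx %% n,
         stop("unknown fill policy kind: ", kind))
}

# Internal: sample one plane at 0-based (sr, sc) with nearest interpolation
# and a fill policy.
sample_plane_fill <- function(plane, sr, sc, fill) {
  H <- nrow(plane); W <- ncol(plane)
  ri <- round(sr); ci <- round(sc)
  if (fill$kind == "constant") {
    oob <- ri < 0 | ri > H - 1 | ci < 0 | ci > W - 1
    ri2 <- pmin(pmax(ri, 0), H - 1)
    ci2 <- pmin(pmax(ci, 0), W - 1)
    vals <- plane[cbind(ri2 + 1, ci2 + 1)]
    vals[oob] <- fill$constant_value
    vals
  } else {
    plane[cbind(resolve_index(ri, H, fill$kind) + 1,
                resolve_index(ci, W, fill$kind) + 1)]
  }
}

#' Flip an image or mask
#'
#' @param x numeric matrix, H x W x C array, or label matrix.
#' @param mode `"horizontal"` (reverse columns), `"vertical"` (reverse rows)
#'   or `"both"`.
#' @return the flipped grid, same shape and type.
#' @examples
#' flip(matrix(1:4, 2, byrow = TRUE), "horizontal")
#' @export
flip <- function(x, mode = c("horizontal", "vertical", "both")) {
  mode <- match.arg(mode)
  arr <- as_image_array(x)
  H <- dim(arr)[1]; W <- dim(arr)[2]
  if (mode %in% c("horizontal", "both")) arr <- arr[, W:1, , drop = FALSE]
  if (mode %in% c("vertical", "both"))   arr <- arr[H:1, , , drop = FALSE]
  restore_dims(arr, x)
}

#' Rotate a whole image about its centre
#'
#' Inverse-mapping rotation about the continuous centre
#' `((H-1)/2, (W-1)/2)`; the output keeps the input shape, so corners of the
#' rotated content are cut and uncovered regions are resolved by the fill
#' policy. With the `"constant"` policy this reproduces the classic black
#' corner artefact of traditional rotation.
#'
#' @param image numeric matrix or H x W x C array.
#' @param angle rotation angle in radians, counter-clockwise.
#' @param fill a [fill_policy()].
#' @param interp `"nearest"` or `"bilinear"` (bilinear resolves each of the
#'   four neighbour indices under the same policy).
#' @return the rotated image, same shape as the input.
#' @export
rotate_full <- function(image, angle, fill = fill_policy("constant"),
                        interp = c("nearest", "bilinear")) {
  interp <- match.arg(interp)
  validate_image(image)
  arr <- as_image_array(image)
  H <- dim(arr)[1]; W <- dim(arr)[2]
  theta <- normalize_angle(angle)
  cr <- (H - 1) / 2; cc <- (W - 1) / 2
  ii <- rep(seq_len(H) - 1, times = W)
  jj <- rep(seq_len(W) - 1, each = H)
  ca <- cos(theta); sa <- sin(theta)
  sr <- cr + ca * (ii - cr) + sa * (jj - cc)
  sc <- cc - sa * (ii - cr) + ca * (jj - cc)
  out <- arr
  for (ch in seq_len(dim(arr)[3])) {
    plane <- arr[, , ch]
    vals <- if (interp == "nearest") {
      sample_plane_fill(plane, sr, sc, fill)
    } else {
      bilinear_sample_fill(plane, sr, sc, fill)
    }
    out[, , ch] <- matrix(vals, H, W)
  }
  restore_dims(out, image)
}

# Internal: bilinear sampling with per-neighbour fill resolution.
bilinear_sample_fill <- function(plane, sr, sc, fill) {
  H <- nrow(plane); W <- ncol(plane)
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  corner <- function(ri, ci) {
    if (fill$kind == "constant") {
      oob <- ri < 0 | ri > H - 1 | ci < 0 | ci > W - 1
      v <- plane[cbind(pmin(pmax(ri, 0), H - 1) + 1,
                       pmin(pmax(ci, 0), W - 1) + 1)]
      v[oob] <- fill$constant_value
      v
    } else {
      plane[cbind(resolve_index(ri, H, fill$kind) + 1,
                  resolve_index(ci, W, fill$kind) + 1)]
    }
  }
  (1 - fr) * ((1 - fc) * corner(r0, c0) + fc * corner(r0, c0 + 1)) +
    fr * ((1 - fc) * corner(r0 + 1, c0) + fc * corner(r0 + 1, c0 + 1))
}

#' Paired whole-image rotation of an image and mask
#'
#' Applies [rotate_full()] with the same angle to both grids. The mask uses
#' nearest interpolation; under the `"constant"` policy uncovered mask pixels
#' receive label 0 (background).
#'
#' @inheritParams rotate_full
#' @param mask integer label matrix, same H x W as `image`.
#' @return a list: `image`, `mask`.
#' @export
rotate_full_pair <- function(image, mask, angle, fill = fill_policy("constant"),
                             interp = c("nearest", "bilinear")) {
  validate_mask(mask, image)
  mask_fill <- if (fill$kind == "constant") fill_policy("constant", 0) else fill
  out_mask <- rotate_full(mask, angle, mask_fill, "nearest")
  storage.mode(out_mask) <- storage.mode(mask)
  list(image = rotate_full(image, angle, fill, interp), mask = out_mask)
}

#' Crop window specification
#'
#' @param area_fraction_range pair in (0, 1\]: the window area as a fraction
#'   of the image area; default `c(0.08, 1)` (windows as small as 8% of the
#'   image, the conventional lower bound for crop augmentation).
#' @param aspect_ratio_range pair of positive reals (width / height), default
#'   `c(3/4, 4/3)`; the ratio is drawn log-uniformly.
#' @param out_size target `c(H, W)` of the resized output, or `NULL` to keep
#'   the input size.
#' @return an object of class `crop_spec`.
#' @export
crop_spec <- function(area_fraction_range = c(0.08, 1),
                      aspect_ratio_range = c(3 / 4, 4 / 3),
                      out_size = NULL) {
  a <- area_fraction_range; r <- aspect_ratio_range
  stopifnot(length(a) == 2L, a[1] > 0, a[1] <= a[2], a[2] <= 1,
            length(r) == 2L, r[1] > 0, r[1] <= r[2])
  if (!is.null(out_size)) stopifnot(length(out_size) == 2L, all(out_size >= 1))
  structure(list(area_fraction_range = as.numeric(a),
                 aspect_ratio_range = as.numeric(r),
                 out_size = out_size),
            class = "crop_spec")
}

# Internal: sample a feasible crop window; returns 0-based (row, col, h, w)
# plus the drawn fraction/ratio.
sample_crop_window <- function(shape, spec, max_retries = 100L) {
  H <- shape[1]; W <- shape[2]
  a <- spec$area_fraction_range; r <- spec$aspect_ratio_range
  for (i in seq_len(max_retries)) {
    af <- stats::runif(1, a[1], a[2])
    ar <- exp(stats::runif(1, log(r[1]), log(r[2])))
    target <- af * H * W
    w <- round(sqrt(target * ar))
    h <- round(sqrt(target / ar))
    if (h >= 1 && w >= 1 && h <= H && w <= W) {
      row <- if (H == h) 0L else sample.int(H - h + 1L, 1L) - 1L
      col <- if (W == w) 0L else sample.int(W - w + 1L, 1L) - 1L
      return(list(row = row, col = col, h = h, w = w,
                  area_fraction = af, aspect_ratio = ar))
    }
  }
  stop("no feasible crop window found for the given spec after ",
       max_retries, " draws")
}

#' Resize an image or mask to a target shape
#'
#' Coordinate mapping `src = (dst + 0.5) * scale - 0.5` per axis, so a resize
#' to the same shape is the identity. Masks should use nearest interpolation.
#'
#' @param x numeric matrix or H x W x C array.
#' @param out_size target `c(H, W)`.
#' @param interp `"nearest"` or `"bilinear"`.
#' @return the resized grid.
#' @export
resize <- function(x, out_size, interp = c("nearest", "bilinear")) {
  interp <- match.arg(interp)
  arr <- as_image_array(x)
  H <- dim(arr)[1]; W <- dim(arr)[2]
  Ho <- out_size[1]; Wo <- out_size[2]
  sr <- (rep(seq_len(Ho) - 1, times = Wo) + 0.5) * (H / Ho) - 0.5
  sc <- (rep(seq_len(Wo) - 1, each = Ho) + 0.5) * (W / Wo) - 0.5
  out <- array(0, dim = c(Ho, Wo, dim(arr)[3]))
  for (ch in seq_len(dim(arr)[3])) {
    plane <- arr[, , ch]
    vals <- if (interp == "nearest") {
      plane[cbind(pmin(pmax(round(sr), 0), H - 1) + 1,
                  pmin(pmax(round(sc), 0), W - 1) + 1)]
    } else {
      bilinear_sample(plane, sr, sc)
    }
    out[, , ch] <- matrix(vals, Ho, Wo)
  }
  res <- restore_dims(out, x)
  if (is.matrix(x) && is.integer(x)) storage.mode(res) <- "integer"
  res
}

#' Random crop-and-resize
#'
#' Draws a window honouring the configured area fraction and aspect ratio,
#' crops it, and resizes it to `out_size`. The class label of a cropped image
#' is inherited unchanged from its source (the usual caveat: the window may
#' miss the labelled object).
#'
#' @param image numeric matrix or H x W x C array.
#' @param spec a [crop_spec()].
#' @param interp `"nearest"` or `"bilinear"` resize.
#' @return a list: `image` (cropped + resized) and `window` (the sampled
#'   0-based window record for the manifest).
#' @export
random_crop_resize <- function(image, spec = crop_spec(),
                               interp = c("nearest", "bilinear")) {
  interp <- match.arg(interp)
  validate_image(image)
  arr <- as_image_array(image)
  win <- sample_crop_window(dim(arr)[1:2], spec)
  out_size <- if (is.null(spec$out_size)) dim(arr)[1:2] else spec$out_size
  crop <- arr[win$row + seq_len(win$h), win$col + seq_len(win$w), , drop = FALSE]
  list(image = restore_dims(resize(crop, out_size, interp),
                            if (is.matrix(image)) crop[, , 1] else crop),
       window = win)
}

# Internal: apply a recorded crop window to a grid (used by paired mode and
# manifest replay).
apply_crop_window <- function(x, win, out_size, interp) {
  arr <- as_image_array(x)
  crop <- arr[win$row + seq_len(win$h), win$col + seq_len(win$w), , drop = FALSE]
  out <- resize(crop, out_size, interp)
  res <- restore_dims(out, x)
  if (is.matrix(x) && is.integer(x)) storage.mode(res) <- "integer"
  res
}
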