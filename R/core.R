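# Core types and coordinate conventions.
#
# Conventions used by every geometric operator in the package:
#   * images are numeric matrices (1 channel) or H x W x C arrays (C = 1 or 3),
#     intensities in [0, 1];
#   * masks are integer matrices of non-negative labels, 0 = background;
#   * pixel coordinates are 0-based (row, col) with pixel centres at integer
#     coordinates, so the continuous image centre is ((H-1)/2, (W-1)/2);
#   * rotation angles are counter-clockwise in radians, normalised to [0, 2*pi).

#' Validate an image grid
#'
#' Checks that `image` is a numeric matrix or an H x W x C array with C equal
#' to 1 or 3, at least 2 x 2, with all intensities finite. When
#' `require_unit = TRUE` intensities must also lie in \[0, 1\].
#'
#' @param image numeric matrix or 3-d array.
#' @param require_unit logical; also check the \[0, 1\] range.
#' @return `image`, invisibly.
#' @export
validate_image <- function(image, require_unit = FALSE) {
  if (!is.numeric(image)) stop("image must be numeric")
  d <- dim(image)
  if (is.null(d) || !(length(d) %in% c(2L, 3L)))
    stop("image must be a matrix or an H x W x C array")
  if (length(d) == 3L && !(d[3] %in% c(1L, 3L)))
    stop("image must have 1 or 3 channels, got ", d[3])
  if (d[1] < 2L || d[2] < 2L) stop("image must be at least 2 x 2")
  if (!all(is.finite(image))) stop("image contains non-finite values")
  if (require_unit && (min(image) < 0 || max(image) > 1))
    stop("image intensities must lie in [0, 1]")
  invisible(image)
}

#' Validate a label mask
#'
#' A mask is an integer-valued matrix of non-negative class labels. If
#' `image` is supplied the mask must share its H x W shape.
#'
#' @param mask integer-valued matrix.
#' @param image optional paired image for the shape check.
#' @return `mask`, invisibly.
#' @export
validate_mask <- function(mask, image = NULL) {
  if (!is.numeric(mask) || !is.matrix(mask)) stop("mask must be a numeric matrix")
  if (any(mask < 0) || any(mask != round(mask)))
    stop("mask labels must be non-negative integers")
  if (!is.null(image)) {
    d <- dim(image)
    if (nrow(mask) != d[1] || ncol(mask) != d[2])
      stop("mask shape (", nrow(mask), " x ", ncol(mask),
           ") does not match image shape (", d[1], " x ", d[2], ")")
  }
  invisible(mask)
}

# Internal: coerce matrix/array to H x W x C array; restore_dims undoes it.
as_image_array <- function(image) {
  if (is.matrix(image)) array(image, dim = c(dim(image), 1L)) else image
}

restore_dims <- function(arr, template) {
  if (is.matrix(template)) matrix(arr[, , 1L], nrow = dim(arr)[1]) else arr
}

n_channels <- function(image) if (is.matrix(image)) 1L else dim(image)[3]

#' Circular region of interest
#'
#' Describes the disk C(x, y, r): centre at 0-based pixel coordinates
#' (`center_row`, `center_col`) and radius `radius` in pixels. The disk plus a
#' one-pixel guard band must fit inside any image it is applied to; the guard
#' ensures nearest-neighbour rounding of rotated source points can never index
#' outside the image.
#'
#' @param center_row,center_col real 0-based pixel coordinates of the centre.
#' @param radius positive radius in pixels.
#' @return an object of class `disk_region`.
#' @examples
#' disk_region(8, 8, 5)
#' @export
disk_region <- function(center_row, center_col, radius) {
  stopifnot(is.numeric(center_row), is.numeric(center_col), is.numeric(radius),
            length(center_row) == 1L, length(center_col) == 1L, length(radius) == 1L)
  if (!is.finite(radius) || radius <= 0) stop("radius must be a positive real")
  structure(list(center_row = as.numeric(center_row),
                 center_col = as.numeric(center_col),
                 radius = as.numeric(radius)),
            class = "disk_region")
}

#' @export
print.disk_region <- function(x, ...) {
  cat(sprintf("disk_region: centre (%.3f, %.3f), radius %.3f px\n",
              x$center_row, x$center_col, x$radius))
  invisible(x)
}

#' Check that a disk (plus guard band) lies inside an image
#'
#' The containment rule is `radius + 1 <= min(center_row, center_col,
#' H - 1 - center_row, W - 1 - center_col)`.
#'
#' @param region a [disk_region()].
#' @param shape integer vector `c(H, W)`.
#' @return `TRUE` invisibly, or an error.
#' @export
check_disk_containment <- function(region, shape) {
  H <- shape[1]; W <- shape[2]
  margin <- min(region$center_row, region$center_col,
                H - 1 - region$center_row, W - 1 - region$center_col)
  if (region$radius + 1 > margin)
    stop(sprintf(paste0("disk (centre %.2f,%.2f radius %.2f) plus 1-pixel guard ",
                        "does not fit in a %d x %d image"),
                 region$center_row, region$center_col, region$radius, H, W))
  invisible(TRUE)
}

#' Rasterise a disk to a binary membership mask
#'
#' Pixel (i, j) belongs to the disk iff
#' `(i - center_row)^2 + (j - center_col)^2 <= radius^2`, evaluated at pixel
#' centres (no anti-aliasing), so the outside-disk invariance of local
#' rotation is exact and testable bit-for-bit.
#'
#' @param shape integer vector `c(H, W)`.
#' @param region a [disk_region()]; must satisfy containment for `shape`.
#' @return an H x W integer matrix of 0/1 memberships.
#' @examples
#' sum(rasterize_disk(c(9, 9), disk_region(4, 4, 3)))  # 29 pixels
#' @export
rasterize_disk <- function(shape, region) {
  check_disk_containment(region, shape)
  H <- shape[1]; W <- shape[2]
  dr2 <- (seq_len(H) - 1 - region$center_row)^2
  dc2 <- (seq_len(W) - 1 - region$center_col)^2
  m <- outer(dr2, dc2, "+") <= region$radius^2
  storage.mode(m) <- "integer"
  m
}

#' Clamp intensities to the unit interval
#'
#' @param image numeric matrix or array with finite values.
#' @return the same structure with every value mapped to `min(1, max(0, v))`.
#' @export
clip01 <- function(image) {
  if (!all(is.finite(image))) stop("image contains non-finite values")
  image[image > 1] <- 1
  image[image < 0] <- 0
  image
}

# Internal: normalise an angle to [0, 2*pi).
normalize_angle <- function(angle) {
  a <- angle %% (2 * pi)
  if (a < 0) a <- a + 2 * pi
  a
}

# Internal: 0-based bilinear sampling of one channel plane, neighbour indices
# clamped to the grid.
bilinear_sample <- function(plane, sr, sc) {
  H <- nrow(plane); W <- ncol(plane)
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  cl <- function(v, n) pmin(pmax(v, 0), n - 1)
  r0c <- cl(r0, H); r1c <- cl(r0 + 1, H)
  c0c <- cl(c0, W); c1c <- cl(c0 + 1, W)
  v00 <- plane[cbind(r0c + 1, c0c + 1)]
  v01 <- plane[cbind(r0c + 1, c1c + 1)]
  v10 <- plane[cbind(r1c + 1, c0c + 1)]
  v11 <- plane[cbind(r1c + 1, c1c + 1)]
  (1 - fr) * ((1 - fc) * v00 + fc * v01) + fr * ((1 - fc) * v10 + fc * v11)
}
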