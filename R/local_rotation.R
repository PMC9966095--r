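# Random local rotation (RLR) and its random centre rotation (RCR) special
# case: rotate the content of a circular region in place, leave everything
# outside the disk untouched. Unlike whole-image rotation this never has to
# invent fill values at the image boundary.

#' Configuration for random local rotation
#'
#' The sampled radius is uniform on `radius_fraction_range * min(H, W)`;
#' the centre is uniform over all positions for which the disk (plus the
#' one-pixel guard) stays inside the image; the angle is uniform on
#' `angle_range`.
#'
#' @param radius_fraction_range pair of reals in (0, 0.5): radius bounds as a
#'   fraction of `min(H, W)`. Default `c(0.10, 0.45)`: the lower bound avoids
#'   no-op specks, the upper bound guarantees at least one legal centre.
#' @param angle_range pair of angles in radians, default `c(0, 2*pi)`.
#' @param interp interpolation for the image: `"nearest"` (default, exact
#'   invariants, no new values) or `"bilinear"`. Masks always use nearest.
#' @return an object of class `rlr_config`.
#' @export
rlr_config <- function(radius_fraction_range = c(0.10, 0.45),
                       angle_range = c(0, 2 * pi),
                       interp = c("nearest", "bilinear")) {
  interp <- match.arg(interp)
  r <- radius_fraction_range
  if (length(r) != 2L || r[1] <= 0 || r[1] > r[2])
    stop("radius_fraction_range must be an ordered positive pair")
  if (length(angle_range) != 2L || angle_range[1] > angle_range[2])
    stop("angle_range must be an ordered pair")
  structure(list(radius_fraction_range = as.numeric(r),
                 angle_range = as.numeric(angle_range),
                 interp = interp),
            class = "rlr_config")
}

#' Sample a local-rotation draw for a given image shape
#'
#' Draws radius, centre and angle per [rlr_config()] using R's current RNG
#' stream, so results are reproducible under `set.seed()`. If a drawn radius
#' admits no legal centre the radius is resampled (up to `max_retries`).
#'
#' @param shape integer vector `c(H, W)`.
#' @param config an [rlr_config()].
#' @param max_retries resample attempts for an infeasible radius.
#' @return a list with elements `region` ([disk_region()]), `angle`, `interp`.
#' @export
sample_rlr_draw <- function(shape, config = rlr_config(), max_retries = 100L) {
  H <- shape[1]; W <- shape[2]
  s <- min(H, W)
  lo <- config$radius_fraction_range[1] * s
  hi <- config$radius_fraction_range[2] * s
  for (i in seq_len(max_retries)) {
    r <- stats::runif(1, lo, hi)
    # legal centre band: r + 1 <= c <= (dim - 1) - (r + 1) on each axis
    if (r + 1 <= (H - 1) - (r + 1) && r + 1 <= (W - 1) - (r + 1)) {
      cr <- stats::runif(1, r + 1, H - 1 - (r + 1))
      cc <- stats::runif(1, r + 1, W - 1 - (r + 1))
      theta <- normalize_angle(stats::runif(1, config$angle_range[1],
                                            config$angle_range[2]))
      return(list(region = disk_region(cr, cc, r), angle = theta,
                  interp = config$interp))
    }
  }
  stop("no legal disk centre exists for any radius drawn from the configured ",
       "range on a ", H, " x ", W, " image")
}

#' Rotate the content of a disk in place
#'
#' For every destination pixel p inside the disk the value is taken at the
#' source point `centre + R(-angle) (p - centre)` (inverse mapping); every
#' pixel outside the disk is returned bit-identical to the input. Under
#' nearest interpolation every output value already occurs in the input, so
#' no fill value is ever introduced.
#'
#' @param image numeric matrix or H x W x C array.
#' @param region a [disk_region()] satisfying containment.
#' @param angle rotation angle in radians, counter-clockwise.
#' @param interp `"nearest"` or `"bilinear"`.
#' @return the transformed image, same shape and type as the input.
#' @examples
#' img <- gen_coordinate_image(c(21, 21))
#' out <- rotate_disk(img, disk_region(10, 10, 5), pi)
#' @export
rotate_disk <- function(image, region, angle, interp = c("nearest", "bilinear")) {
  interp <- match.arg(interp)
  validate_image(image)
  arr <- as_image_array(image)
  H <- dim(arr)[1]; W <- dim(arr)[2]
  check_disk_containment(region, c(H, W))
  theta <- normalize_angle(angle)
  m <- rasterize_disk(c(H, W), region)
  idx <- which(m == 1L)                    # column-major linear indices
  dr <- ((idx - 1L) %% H) - region$center_row
  dc <- ((idx - 1L) %/% H) - region$center_col
  ca <- cos(theta); sa <- sin(theta)
  sr <- region$center_row + ca * dr + sa * dc
  sc <- region$center_col - sa * dr + ca * dc
  out <- arr
  for (ch in seq_len(dim(arr)[3])) {
    plane <- arr[, , ch]
    vals <- if (interp == "nearest")
      plane[cbind(round(sr) + 1, round(sc) + 1)]
    else
      bilinear_sample(plane, sr, sc)
    p <- plane
    p[idx] <- vals
    out[, , ch] <- p
  }
  restore_dims(out, image)
}

#' Random local rotation of an image
#'
#' Samples a disk and an angle per `config` and applies [rotate_disk()].
#' The composition is `M * rot(I) + (1 - M) * I` where `M` is the rasterised
#' disk membership mask.
#'
#' @inheritParams rotate_disk
#' @param config an [rlr_config()].
#' @return a list: `image` (transformed) and `draw` (the sampled parameters,
#'   recorded for the manifest).
#' @examples
#' set.seed(1)
#' res <- rlr(gen_pattern(c(64, 64), "checkerboard"))
#' res$draw$region
#' @export
rlr <- function(image, config = rlr_config()) {
  validate_image(image)
  d <- dim(as_image_array(image))
  draw <- sample_rlr_draw(d[1:2], config)
  list(image = rotate_disk(image, draw$region, draw$angle, draw$interp),
       draw = draw)
}

#' Random centre rotation of an image
#'
#' The special case of [rlr()] that uses the largest inscribed disk centred at
#' the continuous image centre `((H-1)/2, (W-1)/2)` with radius
#' `(min(H, W) - 1) / 2 - 1` (the largest radius honouring the one-pixel
#' guard); only the angle is random.
#'
#' @inheritParams rlr
#' @param angle_range pair of angles in radians, default `c(0, 2*pi)`.
#' @param interp `"nearest"` or `"bilinear"`.
#' @return a list: `image` and `draw`, as for [rlr()].
#' @export
rcr <- function(image, angle_range = c(0, 2 * pi),
                interp = c("nearest", "bilinear")) {
  interp <- match.arg(interp)
  validate_image(image)
  d <- dim(as_image_array(image))
  H <- d[1]; W <- d[2]
  r <- (min(H, W) - 1) / 2 - 1
  if (r <= 0) stop("image too small for a positive centred radius")
  region <- disk_region((H - 1) / 2, (W - 1) / 2, r)
  theta <- normalize_angle(stats::runif(1, angle_range[1], angle_range[2]))
  draw <- list(region = region, angle = theta, interp = interp)
  list(image = rotate_disk(image, region, theta, interp), draw = draw)
}

#' Paired local rotation of an image and its segmentation mask
#'
#' One draw is sampled and applied to both grids so the transform is
#' equivariant: mask content moves exactly as the image content does. The
#' mask always uses nearest interpolation, so its output labels are a subset
#' of the input labels.
#'
#' @param image numeric matrix or H x W x C array.
#' @param mask integer label matrix, same H x W as `image`.
#' @param config an [rlr_config()].
#' @return a list: `image`, `mask`, `draw`.
#' @export
rlr_pair <- function(image, mask, config = rlr_config()) {
  validate_image(image)
  validate_mask(mask, image)
  d <- dim(as_image_array(image))
  draw <- sample_rlr_draw(d[1:2], config)
  out_img <- rotate_disk(image, draw$region, draw$angle, draw$interp)
  out_mask <- rotate_disk(mask, draw$region, draw$angle, "nearest")
  storage.mode(out_mask) <- storage.mode(mask)
  list(image = out_img, mask = out_mask, draw = draw)
}
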