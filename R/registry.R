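# Operator registry: one entry per named augmentation operator, each with a
# `sample` step (draws every random parameter, using the RNG stream seeded by
# the caller) and a deterministic `apply` step (transforms image and, for
# geometric operators, the paired mask). Draws are flat named lists of
# scalars so they serialise directly into the JSON-lines manifest; noise-field
# operators additionally record the per-item seed from which their pixel
# fields are regenerated on replay.

# Internal: merge user params over defaults, keeping only known names.
merge_params <- function(defaults, params) {
  for (nm in names(params)) defaults[[nm]] <- params[[nm]]
  defaults
}

mask_identity <- function(image, mask, out_image) {
  list(image = out_image, mask = mask)
}

# Internal: the registry itself, built once.
build_registry <- function() {
  geometric_pair <- function(out_image, out_mask, mask) {
    if (!is.null(mask)) storage.mode(out_mask) <- storage.mode(mask)
    list(image = out_image, mask = out_mask)
  }

  rlr_entry <- list(
    sample = function(image, params, item_seed) {
      cfg <- do.call(rlr_config, params[names(params) %in%
                       c("radius_fraction_range", "angle_range", "interp")])
      d <- sample_rlr_draw(dim(as_image_array(image))[1:2], cfg)
      list(center_row = d$region$center_row, center_col = d$region$center_col,
           radius = d$region$radius, angle = d$angle, interp = d$interp)
    },
    apply = function(image, mask, draw) {
      region <- disk_region(draw$center_row, draw$center_col, draw$radius)
      out <- rotate_disk(image, region, draw$angle, draw$interp)
      out_mask <- if (is.null(mask)) NULL
                  else rotate_disk(mask, region, draw$angle, "nearest")
      geometric_pair(out, out_mask, mask)
    })

  rcr_entry <- list(
    sample = function(image, params, item_seed) {
      d <- dim(as_image_array(image))
      r <- (min(d[1], d[2]) - 1) / 2 - 1
      ar <- merge_params(list(angle_range = c(0, 2 * pi)), params)$angle_range
      list(center_row = (d[1] - 1) / 2, center_col = (d[2] - 1) / 2,
           radius = r, angle = normalize_angle(stats::runif(1, ar[1], ar[2])),
           interp = if (is.null(params$interp)) "nearest" else params$interp)
    },
    apply = rlr_entry$apply)

  rotate_entry <- function(kind) list(
    sample = function(image, params, item_seed) {
      p <- merge_params(list(angle_range = c(0, 2 * pi), constant_value = 0,
                             interp = "nearest"), params)
      list(angle = normalize_angle(stats::runif(1, p$angle_range[1],
                                                p$angle_range[2])),
           fill_kind = kind, constant_value = p$constant_value,
           interp = p$interp)
    },
    apply = function(image, mask, draw) {
      fp <- fill_policy(draw$fill_kind, draw$constant_value)
      if (is.null(mask))
        list(image = rotate_full(image, draw$angle, fp, draw$interp),
             mask = NULL)
      else
        rotate_full_pair(image, mask, draw$angle, fp, draw$interp)
    })

  flip_entry <- list(
    sample = function(image, params, item_seed) {
      mode <- if (!is.null(params$mode)) params$mode
              else sample(c("horizontal", "vertical", "both"), 1)
      list(mode = mode)
    },
    apply = function(image, mask, draw) {
      out_mask <- if (is.null(mask)) NULL else flip(mask, draw$mode)
      geometric_pair(flip(image, draw$mode), out_mask, mask)
    })

  crop_entry <- list(
    sample = function(image, params, item_seed) {
      spec <- do.call(crop_spec, params[names(params) %in%
                        c("area_fraction_range", "aspect_ratio_range", "out_size")])
      shape <- dim(as_image_array(image))[1:2]
      win <- sample_crop_window(shape, spec)
      out_size <- if (is.null(spec$out_size)) shape else spec$out_size
      list(row = win$row, col = win$col, h = win$h, w = win$w,
           out_h = out_size[1], out_w = out_size[2],
           area_fraction = win$area_fraction, aspect_ratio = win$aspect_ratio,
           interp = if (is.null(params$interp)) "nearest" else params$interp)
    },
    apply = function(image, mask, draw) {
      win <- list(row = draw$row, col = draw$col, h = draw$h, w = draw$w)
      out_size <- c(draw$out_h, draw$out_w)
      out <- apply_crop_window(image, win, out_size, draw$interp)
      out_mask <- if (is.null(mask)) NULL
                  else apply_crop_window(mask, win, out_size, "nearest")
      geometric_pair(out, out_mask, mask)
    })

  jitter_entry <- list(
    sample = function(image, params, item_seed) {
      spec <- do.call(jitter_spec, params[names(params) %in%
                        c("brightness_range", "contrast_range", "saturation_range")])
      list(brightness = stats::runif(1, spec$brightness_range[1],
                                     spec$brightness_range[2]),
           contrast = stats::runif(1, spec$contrast_range[1],
                                   spec$contrast_range[2]),
           saturation = stats::runif(1, spec$saturation_range[1],
                                     spec$saturation_range[2]))
    },
    apply = function(image, mask, draw) {
      out <- adjust_contrast(adjust_brightness(image, draw$brightness),
                             draw$contrast)
      if (n_channels(image) == 3L) out <- adjust_saturation(out, draw$saturation)
      mask_identity(image, mask, out)
    })

  fixed_param_entry <- function(defaults, fn) list(
    sample = function(image, params, item_seed) {
      merge_params(defaults, params[names(params) %in% names(defaults)])
    },
    apply = function(image, mask, draw) mask_identity(image, mask, fn(image, draw)))

  noise_entry <- function(defaults, fn) list(
    sample = function(image, params, item_seed) {
      d <- merge_params(defaults, params[names(params) %in% names(defaults)])
      d$noise_seed <- item_seed
      d
    },
    apply = function(image, mask, draw) {
      set.seed(draw$noise_seed)
      mask_identity(image, mask, fn(image, draw))
    })

  erase_entry <- list(
    sample = function(image, params, item_seed) {
      d <- merge_params(list(area_fraction_range = c(0.02, 0.33),
                             aspect_ratio_range = c(0.3, 3.33),
                             fill_mode = "per_pixel_uniform",
                             constant_value = 0), params)
      d$noise_seed <- item_seed
      d
    },
    apply = function(image, mask, draw) {
      spec <- erase_spec(draw$area_fraction_range, draw$aspect_ratio_range,
                         draw$fill_mode, draw$constant_value)
      set.seed(draw$noise_seed)
      res <- random_erase(image, spec)
      out <- mask_identity(image, mask, res$image)
      out$extra <- list(rect_row = res$rect$row, rect_col = res$rect$col,
                        rect_h = res$rect$h, rect_w = res$rect$w)
      out
    })

  list(
    rlr = rlr_entry,
    rcr = rcr_entry,
    tr = rotate_entry("constant"),
    rnr = rotate_entry("nearest"),
    rrr = rotate_entry("reflect"),
    rwr = rotate_entry("wrap"),
    flip = flip_entry,
    crop = crop_entry,
    jitter = jitter_entry,
    blur = fixed_param_entry(list(sigma = 1),
                             function(img, d) gaussian_blur(img, d$sigma)),
    sobel = fixed_param_entry(list(unused = 0),
                              function(img, d) sobel_edges(img)),
    sharpen = fixed_param_entry(list(amount = 1, sigma = 1),
                                function(img, d) sharpen(img, d$amount, d$sigma)),
    `gauss-noise` = noise_entry(list(sigma = 0.05),
                                function(img, d) add_gaussian_noise(img, d$sigma)),
    `salt-pepper` = noise_entry(list(fraction = 0.05),
                                function(img, d) add_salt_pepper(img, d$fraction)),
    speckle = noise_entry(list(sigma = 0.1),
                          function(img, d) add_speckle(img, d$sigma)),
    erase = erase_entry)
}

.registry_env <- new.env(parent = emptyenv())

#' The augmentation operator registry
#'
#' Maps operator names (as used by [augment_plan()] and the CLI) to their
#' sampling and application steps. Available operators: `rlr`, `rcr`, `tr`,
#' `rnr`, `rrr`, `rwr`, `flip`, `crop`, `jitter`, `blur`, `sobel`, `sharpen`,
#' `gauss-noise`, `salt-pepper`, `speckle`, `erase`.
#'
#' @return a named list of registry entries.
#' @export
op_registry <- function() {
  if (is.null(.registry_env$reg)) .registry_env$reg <- build_registry()
  .registry_env$reg
}

# Internal: draws are flat lists of scalars / short vectors, so they
# serialise to JSON as-is and decode back into a usable draw unchanged.
serialize_draw <- function(draw) draw

deserialize_draw <- function(op, params, seed) params
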