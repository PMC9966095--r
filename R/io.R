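# Standard-format I/O: PNG and TIFF images, single-channel integer-label
# masks, the on-disk dataset layout (images/, masks/, labels.csv) and the
# JSON-lines manifest. Integer bit depths are converted to the internal
# floating [0, 1] domain by dividing by the type maximum.

#' Read a raster image
#'
#' Supports 8-bit PNG, 8/16-bit TIFF, 1 or 3 channels (an alpha channel is
#' dropped). Intensities are returned in \[0, 1\].
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @return a numeric matrix (1 channel) or H x W x 3 array.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                stop("unsupported image format: .", ext))
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] == 4L) img <- img[, , 1:3]         # drop alpha
    if (dim(img)[3] == 2L) img <- img[, , 1]           # gray + alpha
    if (length(dim(img)) == 3L && dim(img)[3] == 1L) img <- img[, , 1]
  }
  img
}

#' Write a raster image
#'
#' PNG output is 8-bit; TIFF output is 8- or 16-bit via `bits`. Writing then
#' reading back is bit-exact at the file's native depth when the intensities
#' are multiples of `1 / (2^bits - 1)` (as they are for anything read from an
#' integer file).
#'
#' @param path output path (`.png`, `.tif`, `.tiff`).
#' @param image numeric matrix or H x W x 3 array in \[0, 1\].
#' @param bits bit depth for TIFF output: 8 (default) or 16.
#' @return `path`, invisibly.
#' @export
write_image <- function(path, image, bits = 8L) {
  validate_image(image, require_unit = TRUE)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::writePNG(image, path),
         tif = ,
         tiff = tiff::writeTIFF(image, path, bits.per.sample = as.integer(bits)),
         stop("unsupported image format: .", ext))
  invisible(path)
}

#' Read a segmentation mask
#'
#' Masks are stored as single-channel images holding raw integer labels
#' (label / type-maximum on disk); reading restores the integers exactly.
#'
#' @param path mask file path (`.png`, `.tif`, `.tiff`).
#' @param bits bit depth the mask was written at (8 or 16).
#' @return an H x W integer matrix of labels.
#' @export
read_mask <- function(path, bits = 8L) {
  img <- read_image(path)
  if (!is.matrix(img)) stop("mask files must be single-channel")
  m <- round(img * (2^bits - 1))
  storage.mode(m) <- "integer"
  m
}

#' Write a segmentation mask
#'
#' @param path output path.
#' @param mask integer label matrix; labels must fit the bit depth.
#' @param bits 8 (default, labels up to 255) or 16.
#' @return `path`, invisibly.
#' @export
write_mask <- function(path, mask, bits = 8L) {
  validate_mask(mask)
  mx <- 2^bits - 1
  if (max(mask) > mx) stop("labels exceed ", bits, "-bit range")
  write_image(path, matrix(mask / mx, nrow(mask), ncol(mask)), bits = bits)
}

#' Write a dataset to disk
#'
#' Layout: `images/<id>.png` (or `.tif`), `labels.csv` with columns `id,class`
#' for classification, `masks/<id>.png` for segmentation.
#'
#' @param dataset an [aug_dataset()].
#' @param dir output directory (created if needed).
#' @param format `"png"` or `"tiff"`.
#' @param bits bit depth for TIFF output.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir, format = c("png", "tiff"), bits = 8L) {
  format <- match.arg(format)
  ext <- if (format == "png") "png" else "tif"
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  for (id in names(dataset$images))
    write_image(file.path(dir, "images", paste0(id, ".", ext)),
                quantize(dataset$images[[id]], bits), bits = bits)
  if (dataset$type == "classification") {
    utils::write.csv(data.frame(id = names(dataset$labels),
                                class = unname(dataset$labels)),
                     file.path(dir, "labels.csv"), row.names = FALSE)
  } else {
    dir.create(file.path(dir, "masks"), showWarnings = FALSE)
    for (id in names(dataset$masks))
      write_mask(file.path(dir, "masks", paste0(id, ".", ext)),
                 dataset$masks[[id]], bits = bits)
  }
  invisible(dir)
}

# Internal: snap intensities to the representable grid of the target depth so
# write/read round trips are bit-exact.
quantize <- function(image, bits) {
  mx <- 2^bits - 1
  round(image * mx) / mx
}

#' Read a dataset from disk
#'
#' Inverse of [write_dataset()].
#'
#' @param dir dataset directory.
#' @param bits bit depth used for masks.
#' @return an [aug_dataset()].
#' @export
read_dataset <- function(dir, bits = 8L) {
  img_dir <- file.path(dir, "images")
  files <- sort(list.files(img_dir, pattern = "\\.(png|tif|tiff)$"))
  if (length(files) == 0) stop("no images found under ", img_dir)
  ids <- tools::file_path_sans_ext(files)
  images <- lapply(file.path(img_dir, files), read_image)
  names(images) <- ids
  mask_dir <- file.path(dir, "masks")
  if (dir.exists(mask_dir)) {
    mfiles <- sort(list.files(mask_dir, pattern = "\\.(png|tif|tiff)$"))
    masks <- lapply(file.path(mask_dir, mfiles), read_mask, bits = bits)
    names(masks) <- tools::file_path_sans_ext(mfiles)
    aug_dataset(images, masks = masks)
  } else {
    lab <- utils::read.csv(file.path(dir, "labels.csv"),
                           colClasses = c("character", "character"))
    labels <- stats::setNames(lab$class, lab$id)
    aug_dataset(images, labels = labels)
  }
}

#' Write a manifest as JSON lines
#'
#' One JSON object per generated sample, full floating-point precision.
#'
#' @param manifest manifest list from [augment_dataset()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  lines <- vapply(manifest, function(rec)
    as.character(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = I(17))),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a JSON-lines manifest
#'
#' @param path manifest file written by [write_manifest()].
#' @return a manifest list usable by [replay()].
#' @export
read_manifest <- function(path) {
  lapply(readLines(path), function(l)
    jsonlite::fromJSON(l, simplifyVector = TRUE))
}

#' Read an operator configuration file
#'
#' YAML or JSON mapping of parameter overrides passed to the operator's spec
#' (e.g. `radius_fraction_range: [0.1, 0.3]`).
#'
#' @param path `.yaml`, `.yml` or `.json` file.
#' @return a named list of parameters.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         yaml = ,
         yml = yaml::read_yaml(path),
         json = jsonlite::fromJSON(path, simplifyVector = TRUE),
         stop("unsupported config format: .", ext))
}
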