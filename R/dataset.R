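# Dataset container and dataset-level operations: class-balanced subsetting
# and the two ways of forming an augmented dataset (replace keeps the size,
# append doubles it when n = |D|).

#' In-memory augmentation dataset
#'
#' An ordered collection of samples: images paired either with class labels
#' (classification) or with segmentation masks.
#'
#' @param images named list of image grids (matrices or H x W x C arrays);
#'   names are the sample identifiers and must be unique.
#' @param labels named vector of class labels (classification mode), or `NULL`.
#' @param masks named list of label matrices (segmentation mode), or `NULL`.
#' @return an object of class `aug_dataset` with fields `images`, `labels` or
#'   `masks`, and `type`.
#' @export
aug_dataset <- function(images, labels = NULL, masks = NULL) {
  if (is.null(names(images)) || anyDuplicated(names(images)))
    stop("images must be a named list with unique identifiers")
  if (!is.null(labels) && !is.null(masks))
    stop("supply labels (classification) or masks (segmentation), not both")
  ids <- names(images)
  type <- if (!is.null(masks)) "segmentation" else "classification"
  if (type == "segmentation") {
    if (!identical(sort(names(masks)), sort(ids)))
      stop("mask identifiers must match image identifiers")
    masks <- masks[ids]
    for (id in ids) validate_mask(masks[[id]], images[[id]])
  } else {
    if (is.null(labels)) stop("classification datasets need labels")
    if (!identical(sort(names(labels)), sort(ids)))
      stop("label identifiers must match image identifiers")
    labels <- labels[ids]
  }
  structure(list(images = images, labels = labels, masks = masks, type = type),
            class = "aug_dataset")
}

#' @export
print.aug_dataset <- function(x, ...) {
  d <- dim(as_image_array(x$images[[1]]))
  cat(sprintf("aug_dataset: %d samples (%s), first image %d x %d x %d\n",
              length(x$images), x$type, d[1], d[2], d[3]))
  if (x$type == "classification")
    cat("  classes:", paste(names(table(x$labels)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.aug_dataset <- function(x) length(x$images)

#' Class-balanced random subset
#'
#' Selects `floor(fraction * |D|)` samples (or `count`) with per-class counts
#' differing by at most one; any remainder is assigned deterministically to
#' the classes that sort lowest. Selection within a class is uniform without
#' replacement, driven by R's current RNG stream.
#'
#' @param dataset a classification [aug_dataset()].
#' @param fraction fraction of the dataset to keep, or `NULL`.
#' @param count absolute number of samples, used when `fraction` is `NULL`.
#' @return the subset as an [aug_dataset()], in original dataset order.
#' @export
balanced_subset <- function(dataset, fraction = NULL, count = NULL) {
  if (dataset$type != "classification")
    stop("balanced_subset requires class labels")
  N <- length(dataset)
  n <- if (!is.null(fraction)) floor(fraction * N) else count
  if (is.null(n) || n < 0 || n > N) stop("requested subset size out of range")
  classes <- sort(unique(dataset$labels))
  k <- length(classes)
  per <- rep(n %/% k, k)
  rem <- n %% k
  if (rem > 0) per[seq_len(rem)] <- per[seq_len(rem)] + 1
  keep <- character(0)
  for (i in seq_len(k)) {
    pool <- names(dataset$labels)[dataset$labels == classes[i]]
    if (per[i] > length(pool))
      stop("class ", classes[i], " has only ", length(pool),
           " samples; ", per[i], " requested")
    keep <- c(keep, if (per[i] > 0) sample(pool, per[i]) else character(0))
  }
  keep <- names(dataset$images)[names(dataset$images) %in% keep]
  aug_dataset(dataset$images[keep], labels = dataset$labels[keep])
}

#' Augmentation plan
#'
#' Describes one dataset-level augmentation pass: which operator, how many
#' source images, and how the generated images enter the output. With
#' `way = "replace"` each generated image replaces its source, so the output
#' keeps the input size; with `way = "append"` generated images are added, so
#' `n = |D|` yields an augmented copy twice the size of the original.
#'
#' @param op operator name registered in [op_registry()]: one of `rlr`, `rcr`,
#'   `tr`, `rnr`, `rrr`, `rwr`, `flip`, `crop`, `jitter`, `blur`, `sobel`,
#'   `sharpen`, `gauss-noise`, `salt-pepper`, `speckle`, `erase`.
#' @param params list of operator parameters / spec objects overriding the
#'   operator defaults.
#' @param n number of images to augment; default `NULL` means all of them.
#' @param way `"append"` (default) or `"replace"`.
#' @param seed integer seed controlling subset selection and every sampled
#'   parameter.
#' @return an object of class `augment_plan`.
#' @export
augment_plan <- function(op, params = list(), n = NULL,
                         way = c("append", "replace"), seed = 1L) {
  way <- match.arg(way)
  if (!op %in% names(op_registry())) stop("unknown operator: ", op)
  structure(list(op = op, params = params, n = n, way = way,
                 seed = as.integer(seed)),
            class = "augment_plan")
}

#' Augment a dataset
#'
#' Selects `n` source images per the plan's seed, applies the operator to
#' each (paired with its mask in segmentation mode, following the operator's
#' mask rule), and assembles the output dataset Way-1 (replace) or Way-2
#' (append) style. Every sampled parameter is recorded in the returned
#' manifest, which [replay()] can use to reproduce the output bit-exactly.
#'
#' @param dataset an [aug_dataset()].
#' @param plan an [augment_plan()].
#' @return a list: `dataset` (the augmented [aug_dataset()]) and `manifest`
#'   (list of per-sample records).
#' @export
augment_dataset <- function(dataset, plan) {
  N <- length(dataset)
  n <- if (is.null(plan$n)) N else plan$n
  if (n < 0) stop("n must be non-negative")
  if (plan$way == "replace" && n > N)
    stop("replace mode requires n <= |D|")
  set.seed(plan$seed)
  ids <- names(dataset$images)
  sel <- if (n == 0) character(0)
         else if (plan$way == "replace") sample(ids, n)
         else sample(ids, n, replace = n > N)
  item_seeds <- if (n > 0) sample.int(.Machine$integer.max, n) else integer(0)
  entry <- op_registry()[[plan$op]]
  new_images <- vector("list", n)
  new_masks <- if (dataset$type == "segmentation") vector("list", n) else NULL
  manifest <- vector("list", n)
  out_ids <- if (plan$way == "replace") sel
             else sprintf("%s_aug_%s_%04d", sel, plan$op, seq_len(n))
  for (i in seq_len(n)) {
    src <- sel[i]
    mask <- if (dataset$type == "segmentation") dataset$masks[[src]] else NULL
    set.seed(item_seeds[i])
    draw <- entry$sample(dataset$images[[src]], plan$params, item_seeds[i])
    res <- entry$apply(dataset$images[[src]], mask, draw)
    new_images[[i]] <- res$image
    if (!is.null(new_masks)) new_masks[[i]] <- res$mask
    rec <- serialize_draw(draw)
    if (!is.null(res$extra)) rec <- c(rec, res$extra)
    manifest[[i]] <- list(source_id = src, output_id = out_ids[i],
                          op = plan$op, seed = item_seeds[i],
                          params = rec,
                          version = as.character(utils::packageVersion("rlraug")))
  }
  names(new_images) <- out_ids
  if (!is.null(new_masks)) names(new_masks) <- out_ids
  if (plan$way == "replace") {
    images <- dataset$images
    images[out_ids] <- new_images
    masks <- dataset$masks
    if (!is.null(masks)) masks[out_ids] <- new_masks
    labels <- dataset$labels
  } else {
    images <- c(dataset$images, new_images)
    masks <- if (!is.null(dataset$masks)) c(dataset$masks, new_masks) else NULL
    labels <- dataset$labels
    if (!is.null(labels)) {
      extra <- labels[sel]
      names(extra) <- out_ids
      labels <- c(labels, extra)
    }
  }
  out <- aug_dataset(images, labels = labels, masks = masks)
  list(dataset = out, manifest = manifest)
}

#' Replay a manifest against a dataset
#'
#' Rebuilds the generated samples from the recorded parameters, without
#' re-sampling: geometric and photometric draws are applied directly from
#' their recorded values; noise-field draws are regenerated from their
#' recorded per-item seed, which is bit-exact. Records are matched to sources
#' by identifier, so the dataset order may differ from the original run.
#'
#' @param dataset the source [aug_dataset()] (matching identifiers).
#' @param manifest a manifest list from [augment_dataset()] or
#'   [read_manifest()].
#' @param way `"append"` or `"replace"`, as in the original plan.
#' @return the reconstructed augmented [aug_dataset()].
#' @export
replay <- function(dataset, manifest, way = c("append", "replace")) {
  way <- match.arg(way)
  reg <- op_registry()
  n <- length(manifest)
  new_images <- vector("list", n)
  new_masks <- if (dataset$type == "segmentation") vector("list", n) else NULL
  out_ids <- character(n)
  src_ids <- character(n)
  for (i in seq_len(n)) {
    rec <- manifest[[i]]
    if (!rec$source_id %in% names(dataset$images))
      stop("manifest source id not found in dataset: ", rec$source_id)
    entry <- reg[[rec$op]]
    if (is.null(entry)) stop("unknown operator in manifest: ", rec$op)
    mask <- if (dataset$type == "segmentation") dataset$masks[[rec$source_id]]
            else NULL
    draw <- deserialize_draw(rec$op, rec$params, rec$seed)
    res <- entry$apply(dataset$images[[rec$source_id]], mask, draw)
    new_images[[i]] <- res$image
    if (!is.null(new_masks)) new_masks[[i]] <- res$mask
    out_ids[i] <- rec$output_id
    src_ids[i] <- rec$source_id
  }
  names(new_images) <- out_ids
  if (!is.null(new_masks)) names(new_masks) <- out_ids
  if (way == "replace") {
    images <- dataset$images
    images[out_ids] <- new_images
    masks <- dataset$masks
    if (!is.null(masks)) masks[out_ids] <- new_masks
    labels <- dataset$labels
  } else {
    images <- c(dataset$images, new_images)
    masks <- if (!is.null(dataset$masks)) c(dataset$masks, new_masks) else NULL
    labels <- dataset$labels
    if (!is.null(labels)) {
      extra <- labels[src_ids]
      names(extra) <- out_ids
      labels <- c(labels, extra)
    }
  }
  aug_dataset(images, labels = labels, masks = masks)
}
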