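# Independent brute-force oracles: per-pixel scalar loops that evaluate the
# geometric definitions directly, kept deliberately separate from the
# package's vectorised implementations.

# Enumerate disk membership pixel by pixel.
oracle_disk_mask <- function(shape, cr, cc, r) {
  H <- shape[1]; W <- shape[2]
  m <- matrix(0L, H, W)
  for (i in 0:(H - 1)) for (j in 0:(W - 1))
    if ((i - cr)^2 + (j - cc)^2 <= r^2) m[i + 1, j + 1] <- 1L
  m
}

# Brute-force in-place disk rotation, nearest interpolation.
oracle_rotate_disk <- function(image, cr, cc, r, angle) {
  H <- nrow(image); W <- ncol(image)
  out <- image
  for (i in 0:(H - 1)) for (j in 0:(W - 1)) {
    if ((i - cr)^2 + (j - cc)^2 <= r^2) {
      dr <- i - cr; dc <- j - cc
      sr <- cr + cos(angle) * dr + sin(angle) * dc
      sc <- cc - sin(angle) * dr + cos(angle) * dc
      out[i + 1, j + 1] <- image[round(sr) + 1, round(sc) + 1]
    }
  }
  out
}

# Resolve one 0-based index against an axis of length n per fill policy;
# returns NA for an out-of-grid source under the constant policy.
oracle_resolve <- function(t, n, kind) {
  if (t >= 0 && t <= n - 1) return(t)
  switch(kind,
         constant = NA_real_,
         nearest = min(max(t, 0), n - 1),
         reflect = { m <- t %% (2 * n); if (m >= n) 2 * n - 1 - m else m },
         wrap = t %% n)
}

# Brute-force whole-image rotation, nearest interpolation, one fill policy.
oracle_rotate_full <- function(image, angle, kind, constant_value = 0) {
  H <- nrow(image); W <- ncol(image)
  cr <- (H - 1) / 2; cc <- (W - 1) / 2
  out <- image
  for (i in 0:(H - 1)) for (j in 0:(W - 1)) {
    sr <- cr + cos(angle) * (i - cr) + sin(angle) * (j - cc)
    sc <- cc - sin(angle) * (i - cr) + cos(angle) * (j - cc)
    ri <- oracle_resolve(round(sr), H, kind)
    ci <- oracle_resolve(round(sc), W, kind)
    out[i + 1, j + 1] <- if (is.na(ri) || is.na(ci)) constant_value
                         else image[ri + 1, ci + 1]
  }
  out
}

# Point-reflection relocation of disk pixels (theta = pi about an integer
# centre), used as the closed-form check for half-turn local rotation.
oracle_point_reflect_disk <- function(image, cr, cc, r) {
  H <- nrow(image); W <- ncol(image)
  out <- image
  for (i in 0:(H - 1)) for (j in 0:(W - 1))
    if ((i - cr)^2 + (j - cc)^2 <= r^2)
      out[i + 1, j + 1] <- image[2 * cr - i + 1, 2 * cc - j + 1]
  out
}

# Tiny test datasets -------------------------------------------------------

make_class_dataset <- function(n, classes, shape = c(16, 16), channels = 1) {
  imgs <- lapply(seq_len(n), function(i) {
    if (channels == 1) matrix(stats::runif(prod(shape)), shape[1])
    else array(stats::runif(prod(shape) * channels), c(shape, channels))
  })
  names(imgs) <- sprintf("img%05d", seq_len(n))
  labs <- stats::setNames(rep(classes, length.out = n), names(imgs))
  aug_dataset(imgs, labels = labs)
}

read_tree_bytes <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE))
  stats::setNames(lapply(files, function(f)
    readBin(file.path(dir, f), "raw", file.info(file.path(dir, f))$size)),
    files)
}
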