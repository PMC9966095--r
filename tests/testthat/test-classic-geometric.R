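# Flips, whole-image rotation under the four boundary policies, and random
# crop-resize.

test_that("flip reverses the stated axes and is an involution", {
  g <- matrix(c(1, 3, 2, 4), 2)            # [[1,2],[3,4]]
  expect_identical(flip(g, "horizontal"), matrix(c(2, 4, 1, 3), 2))
  expect_identical(flip(g, "vertical"), matrix(c(3, 1, 4, 2), 2))
  expect_identical(flip(flip(g, "both"), "both"), g)
  expect_identical(flip(g, "both"), flip(flip(g, "horizontal"), "vertical"))
  expect_identical(flip(g, "both"), flip(flip(g, "vertical"), "horizontal"))

  set.seed(1)
  arr <- array(runif(6 * 7 * 3), c(6, 7, 3))
  for (mode in c("horizontal", "vertical", "both")) {
    expect_identical(flip(flip(arr, mode), mode), arr)
    expect_identical(sort(as.vector(flip(arr, mode))), sort(as.vector(arr)))
  }
  expect_error(flip(g, "diagonal"))
})

test_that("half-turn rotation of a 2x2 grid point-reflects for every policy", {
  g <- matrix(c(1, 3, 2, 4), 2)            # [[1,2],[3,4]]
  want <- matrix(c(4, 2, 3, 1), 2)         # [[4,3],[2,1]]
  for (kind in c("constant", "nearest", "reflect", "wrap"))
    expect_identical(rotate_full(g, pi, fill_policy(kind)), want)
})

test_that("rotation at angle 0 is the identity under every policy", {
  set.seed(2)
  img <- matrix(runif(5 * 7), 5)
  for (kind in c("constant", "nearest", "reflect", "wrap"))
    expect_identical(rotate_full(img, 0, fill_policy(kind)), img)
})

test_that("rotate_full agrees with the per-pixel index-rule oracle", {
  set.seed(3)
  angles <- c(pi / 7, pi / 6, pi / 3, 2.5)
  for (H in c(5, 8)) for (W in c(5, 7, 8)) {
    img <- matrix(runif(H * W), H)
    for (kind in c("constant", "nearest", "reflect", "wrap"))
      for (theta in angles)
        expect_identical(rotate_full(img, theta, fill_policy(kind)),
                         oracle_rotate_full(img, theta, kind),
                         label = sprintf("%dx%d %s theta=%.3f", H, W, kind, theta))
  }
})

test_that("constant fill leaves the black-corner artefact for oblique angles", {
  set.seed(4)
  img <- matrix(runif(32 * 32, min = 0.2, max = 1), 32)  # strictly positive
  for (theta in c(pi / 6, 1, 2.5)) {
    out <- rotate_full(img, theta, fill_policy("constant", 0))
    expect_gt(sum(out == 0), 0)
  }
  # the local-rotation alternative introduces no such fill values
  res <- rlr(img)
  expect_true(all(res$image > 0))
})

test_that("half-turn rotation preserves the value multiset exactly", {
  set.seed(5)
  img <- matrix(runif(9 * 12), 9)
  out <- rotate_full(img, pi, fill_policy("constant"))
  expect_identical(sort(as.vector(out)), sort(as.vector(img)))
})

test_that("paired rotation keeps mask labels inside the input label set", {
  set.seed(6)
  pair <- gen_nuclei(nuclei_config(canvas = c(64, 64), n_blobs = 4))
  for (kind in c("constant", "nearest", "reflect", "wrap")) {
    res <- rotate_full_pair(pair$image, pair$mask, 0.7, fill_policy(kind))
    expect_true(all(res$mask %in% c(0L, 1L)))
    expect_identical(dim(res$mask), dim(pair$mask))
  }
})

test_that("crop with full area and unit aspect on a square image is the identity", {
  set.seed(7)
  img <- matrix(runif(24 * 24), 24)
  spec <- crop_spec(area_fraction_range = c(1, 1), aspect_ratio_range = c(1, 1))
  expect_identical(random_crop_resize(img, spec)$image, img)
})

test_that("crop draws are seed-deterministic and respect the configured ranges", {
  set.seed(8); w1 <- random_crop_resize(matrix(runif(64 * 64), 64))$window
  set.seed(8); w2 <- random_crop_resize(matrix(runif(64 * 64), 64))$window
  expect_identical(w1, w2)

  set.seed(9)
  img <- matrix(runif(64 * 64), 64)
  for (i in 1:300) {
    win <- random_crop_resize(img)$window
    expect_gte(win$area_fraction, 0.08)
    expect_lte(win$area_fraction, 1)
    expect_gte(win$aspect_ratio, 3 / 4 - 1e-12)
    expect_lte(win$aspect_ratio, 4 / 3 + 1e-12)
    expect_lte(win$row + win$h, 64)
    expect_lte(win$col + win$w, 64)
  }
})

test_that("resize maps a grid onto itself and masks keep integer labels", {
  m <- matrix(sample(0:3, 30 * 30, replace = TRUE), 30)
  storage.mode(m) <- "integer"
  expect_identical(resize(m, c(30, 30), "nearest"), m)
  small <- resize(m, c(11, 13), "nearest")
  expect_true(all(small %in% unique(as.vector(m))))
  expect_true(is.integer(small))
})
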