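# Random local rotation: the in-place disk rotation operator, its sampler,
# the centred special case and the paired image/mask mode.

test_that("rotate_disk at angle 0 is the identity", {
  set.seed(1)
  img <- matrix(runif(21 * 21), 21)
  expect_identical(rotate_disk(img, disk_region(10, 10, 6), 0), img)
  expect_identical(rotate_disk(img, disk_region(10, 10, 6), 2 * pi), img)
})

test_that("half-turn about an integer centre point-reflects every disk pixel", {
  img <- gen_coordinate_image(c(17, 17))
  out <- rotate_disk(img, disk_region(8, 8, 5), pi)
  expect_identical(out, oracle_point_reflect_disk(img, 8, 8, 5))
  # decode a specific pixel: (8+2, 8+1) must hold the value of (8-2, 8-1)
  dec <- decode_coordinates(out[11, 10], c(17, 17))
  expect_equal(dec$row, 6)
  expect_equal(dec$col, 7)
})

test_that("quarter-turn multiples permute the lattice disk onto itself", {
  set.seed(2)
  img <- matrix(runif(19 * 19), 19)
  region <- disk_region(9, 9, 6)
  m <- rasterize_disk(c(19, 19), region)
  for (theta in c(pi / 2, pi, 3 * pi / 2)) {
    out <- rotate_disk(img, region, theta)
    expect_identical(sort(out[m == 1L]), sort(img[m == 1L]))
    # composing theta with 2*pi - theta recovers the input exactly
    expect_identical(rotate_disk(out, region, 2 * pi - theta), img)
  }
})

test_that("rotate_disk matches the brute-force oracle at arbitrary angles", {
  set.seed(3)
  for (case in 1:6) {
    H <- sample(10:16, 1); W <- sample(10:16, 1)
    img <- matrix(runif(H * W), H)
    r <- runif(1, 1, (min(H, W) - 1) / 2 - 1)
    cr <- runif(1, r + 1, H - 1 - r - 1)
    cc <- runif(1, r + 1, W - 1 - r - 1)
    theta <- runif(1, 0, 2 * pi)
    expect_identical(rotate_disk(img, disk_region(cr, cc, r), theta),
                     oracle_rotate_disk(img, cr, cc, r, theta))
  }
})

test_that("pixels outside the disk are bitwise unchanged and no fill value appears", {
  set.seed(4)
  for (case in 1:20) {
    img <- matrix(runif(48 * 48), 48)
    draw <- sample_rlr_draw(c(48, 48))
    out <- rotate_disk(img, draw$region, draw$angle)
    m <- rasterize_disk(c(48, 48), draw$region)
    expect_identical(out[m == 0L], img[m == 0L])
    expect_true(all(out %in% img))
  }
})

test_that("a constant image is invariant under local rotation", {
  set.seed(5)
  img <- gen_pattern(c(32, 32), "constant")
  res <- rlr(img)
  expect_identical(res$image, img)
})

test_that("rlr equals rotate_disk applied with its returned draw", {
  set.seed(6)
  img <- gen_pattern(c(64, 64), "checkerboard")
  res <- rlr(img)
  expect_identical(res$image,
                   rotate_disk(img, res$draw$region, res$draw$angle,
                               res$draw$interp))
})

test_that("the rlr sampler is seed-deterministic and always in containment", {
  set.seed(7); d1 <- sample_rlr_draw(c(64, 64))
  set.seed(7); d2 <- sample_rlr_draw(c(64, 64))
  expect_identical(d1, d2)

  set.seed(8)
  angles <- numeric(2000)
  for (i in seq_len(2000)) {
    d <- sample_rlr_draw(c(64, 64))
    expect_silent(check_disk_containment(d$region, c(64, 64)))
    s <- 64
    expect_gte(d$region$radius, 0.10 * s)
    expect_lte(d$region$radius, 0.45 * s)
    angles[i] <- d$angle
  }
  # CLT check: mean of uniform [0, 2*pi) within 3 standard errors of pi
  se <- (2 * pi / sqrt(12)) / sqrt(2000)
  expect_lt(abs(mean(angles) - pi), 3 * se)
})

test_that("rcr uses the largest centred disk and leaves corners untouched", {
  set.seed(9)
  img <- matrix(runif(64 * 64), 64)
  res <- rcr(img)
  expect_equal(res$draw$region$center_row, 31.5)
  expect_equal(res$draw$region$center_col, 31.5)
  expect_equal(res$draw$region$radius, 30.5)
  corners <- rbind(c(1, 1), c(1, 64), c(64, 1), c(64, 64))
  expect_identical(res$image[corners], img[corners])
  # rcr is rlr with the fixed centre/radius substitution under a shared seed
  set.seed(10); a1 <- rcr(img)
  set.seed(10)
  theta <- runif(1, 0, 2 * pi)
  expect_identical(a1$image, rotate_disk(img, disk_region(31.5, 31.5, 30.5), theta))

  expect_error(rcr(matrix(0.5, 3, 3)), "too small")
})

test_that("bilinear local rotation stays in range and is identity at angle 0", {
  set.seed(11)
  img <- matrix(runif(32 * 32), 32)
  region <- disk_region(15, 15, 8)
  expect_equal(rotate_disk(img, region, 0, interp = "bilinear"), img)
  out <- rotate_disk(img, region, 1.1, interp = "bilinear")
  expect_true(all(out >= 0 & out <= 1))
  m <- rasterize_disk(c(32, 32), region)
  expect_identical(out[m == 0L], img[m == 0L])
})

test_that("paired local rotation is equivariant and label-safe", {
  set.seed(12)
  pair <- gen_nuclei(nuclei_config(canvas = c(65, 65), n_blobs = 4))
  res <- rlr_pair(pair$image, pair$mask)
  # same draw applied to the mask directly gives the same mask
  direct <- rotate_disk(pair$mask, res$draw$region, res$draw$angle, "nearest")
  storage.mode(direct) <- "integer"
  expect_identical(res$mask, direct)
  expect_true(all(res$mask %in% unique(as.vector(pair$mask))))

  # all-background mask is unchanged by any draw
  blank <- matrix(0L, 65, 65)
  expect_identical(rlr_pair(pair$image, blank)$mask, blank)

  # half-turn about an integer centre preserves the foreground count exactly
  out <- rotate_disk(pair$mask, disk_region(32, 32, 20), pi, "nearest")
  expect_identical(sum(out > 0), sum(pair$mask > 0))

  expect_error(rlr_pair(pair$image, matrix(0L, 64, 65)), "match")
})
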