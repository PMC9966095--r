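# Dataset container, class-balanced subsetting, the two augmentation ways and
# manifest replay.

test_that("balanced_subset returns equal per-class counts", {
  set.seed(1)
  ds <- make_class_dataset(200, classes = letters[1:10], shape = c(4, 4))
  sub <- balanced_subset(ds, fraction = 0.1)
  expect_equal(length(sub), 20L)
  expect_true(all(table(sub$labels) == 2))

  # remainder goes to the lowest class labels, counts differ by at most one
  sub2 <- balanced_subset(ds, count = 23)
  tab <- table(sub2$labels)
  expect_equal(sum(tab), 23)
  expect_lte(max(tab) - min(tab), 1)
  expect_true(all(tab[c("a", "b", "c")] == 3))

  expect_identical(length(balanced_subset(ds, fraction = 1)), 200L)
  expect_error(balanced_subset(ds, count = 300), "out of range")
})

test_that("balanced_subset rejects requests a class cannot fill", {
  imgs <- lapply(1:6, function(i) matrix(0.5, 4, 4))
  names(imgs) <- sprintf("s%d", 1:6)
  labs <- setNames(c("a", "a", "a", "a", "a", "b"), names(imgs))
  ds <- aug_dataset(imgs, labels = labs)
  expect_error(balanced_subset(ds, count = 4), "only")
})

test_that("append and replace honour the Algorithm-1 size contracts", {
  set.seed(2)
  ds <- make_class_dataset(40, classes = c("x", "y"), shape = c(24, 24))
  for (n in c(0L, 1L, 20L, 40L)) {
    app <- augment_dataset(ds, augment_plan("flip", n = n, way = "append", seed = 5))
    expect_equal(length(app$dataset), 40L + n)
    expect_equal(length(app$manifest), n)
    rep <- augment_dataset(ds, augment_plan("flip", n = n, way = "replace", seed = 5))
    expect_equal(length(rep$dataset), 40L)
    # exactly n items differ from the input (flip of a random image is never
    # the identity in practice)
    differ <- sum(!mapply(identical, rep$dataset$images, ds$images))
    expect_equal(differ, n)
  }
  # n = 0 is the identity under both ways
  app0 <- augment_dataset(ds, augment_plan("flip", n = 0L, way = "append", seed = 5))
  expect_identical(app0$dataset$images, ds$images)
  expect_error(augment_dataset(ds, augment_plan("flip", n = 41L, way = "replace")),
               "n <= ")
})

test_that("append with n = |D| doubles the dataset and inherits labels", {
  set.seed(3)
  ds <- make_class_dataset(30, classes = letters[1:3], shape = c(24, 24))
  res <- augment_dataset(ds, augment_plan("rlr", way = "append", seed = 7))
  expect_equal(length(res$dataset), 60L)
  for (rec in res$manifest)
    expect_identical(res$dataset$labels[[rec$output_id]],
                     ds$labels[[rec$source_id]])
})

test_that("augmentation is bit-reproducible end to end under a fixed seed", {
  set.seed(4)
  ds <- make_class_dataset(12, classes = c("a", "b"), shape = c(32, 32))
  r1 <- augment_dataset(ds, augment_plan("rlr", way = "append", seed = 99))
  r2 <- augment_dataset(ds, augment_plan("rlr", way = "append", seed = 99))
  expect_identical(r1$dataset$images, r2$dataset$images)
  expect_identical(r1$manifest, r2$manifest)
  r3 <- augment_dataset(ds, augment_plan("rlr", way = "append", seed = 100))
  expect_false(identical(r1$dataset$images, r3$dataset$images))
})

test_that("replay reproduces every operator bit-exactly through the manifest file", {
  set.seed(5)
  ds <- make_class_dataset(8, classes = c("a", "b"), shape = c(32, 32),
                           channels = 3)
  ops <- c("rlr", "rcr", "tr", "rnr", "rrr", "rwr", "flip", "crop", "jitter",
           "blur", "sobel", "sharpen", "gauss-noise", "salt-pepper", "speckle",
           "erase")
  for (op in ops) {
    res <- augment_dataset(ds, augment_plan(op, n = 3L, way = "replace", seed = 17))
    path <- withr::local_tempfile(fileext = ".jsonl")
    write_manifest(res$manifest, path)
    back <- replay(ds, read_manifest(path), way = "replace")
    expect_identical(back$images, res$dataset$images, label = op)
  }
})

test_that("replay is keyed by identifier, not position", {
  set.seed(6)
  ds <- make_class_dataset(10, classes = c("a", "b"), shape = c(24, 24))
  res <- augment_dataset(ds, augment_plan("rlr", n = 4L, way = "append", seed = 31))
  perm <- aug_dataset(rev(ds$images), labels = ds$labels[rev(names(ds$images))])
  back <- replay(perm, res$manifest, way = "append")
  for (rec in res$manifest)
    expect_identical(back$images[[rec$output_id]],
                     res$dataset$images[[rec$output_id]])
})

test_that("a tampered manifest angle changes the recorded disk only", {
  set.seed(7)
  ds <- make_class_dataset(4, classes = "a", shape = c(48, 48))
  res <- augment_dataset(ds, augment_plan("rlr", n = 1L, way = "replace", seed = 13))
  rec <- res$manifest[[1]]
  tampered <- res$manifest
  tampered[[1]]$params$angle <- rec$params$angle + 0.5
  back <- replay(ds, tampered, way = "replace")
  orig <- ds$images[[rec$source_id]]
  new <- back$images[[rec$output_id]]
  m <- rasterize_disk(dim(orig), disk_region(rec$params$center_row,
                                             rec$params$center_col,
                                             rec$params$radius))
  expect_identical(new[m == 0L], orig[m == 0L])
  expect_false(identical(new, res$dataset$images[[rec$output_id]]))
})

test_that("segmentation datasets keep masks aligned through augmentation", {
  set.seed(8)
  ds <- gen_nuclei_dataset(6, nuclei_config(canvas = c(64, 64), n_blobs = 3))
  res <- augment_dataset(ds, augment_plan("rlr", way = "append", seed = 21))
  expect_equal(length(res$dataset), 12L)
  for (id in names(res$dataset$images)) {
    expect_identical(dim(res$dataset$masks[[id]]),
                     dim(res$dataset$images[[id]])[1:2])
    expect_true(all(res$dataset$masks[[id]] %in% c(0L, 1L)))
  }
  # photometric ops leave the mask untouched
  res2 <- augment_dataset(ds, augment_plan("jitter", n = 6L, way = "replace", seed = 22))
  for (rec in res2$manifest)
    expect_identical(res2$dataset$masks[[rec$output_id]],
                     ds$masks[[rec$source_id]])
})

test_that("manifest replay rejects unknown identifiers", {
  set.seed(9)
  ds <- make_class_dataset(4, classes = "a", shape = c(24, 24))
  res <- augment_dataset(ds, augment_plan("flip", n = 2L, way = "append", seed = 3))
  bad <- res$manifest
  bad[[1]]$source_id <- "missing"
  expect_error(replay(ds, bad, way = "append"), "not found")
})
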