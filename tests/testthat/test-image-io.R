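test_that("write-then-load round trips within 8-bit quantization", {
  ds <- generate_dataset(tiny_spec())
  root <- withr::local_tempdir()
  write_image_dataset(ds, root)
  expect_true(file.exists(file.path(root, "manifest.json")))
  back <- load_image_folder(root)
  expect_equal(dim(back$images), dim(ds$images))
  expect_equal(back$labels, ds$labels)
  expect_equal(back$class_names, ds$class_names)
  expect_lte(max(abs(back$images - ds$images)), 1 / 255)
})

test_that("8-bit intensities scale as value / 255", {
  root <- withr::local_tempdir()
  dir.create(file.path(root, "a"))
  # stored byte 255 must load as exactly 1.0, byte 0 as 0.0
  img <- array(0, c(2, 2, 3)); img[1, 1, ] <- 1
  png::writePNG(img, file.path(root, "a", "img.png"))
  ds <- load_image_folder(root)
  expect_identical(ds$images[1, 1, 1, 1], 1)
  expect_identical(ds$images[2, 2, 1, 1], 0)
})

test_that("class order is lexicographic and empty folders are rejected", {
  root <- withr::local_tempdir()
  for (cl in c("zebra", "apple", "mango")) {
    dir.create(file.path(root, cl))
    png::writePNG(array(0.5, c(4, 4, 3)), file.path(root, cl, "1.png"))
  }
  ds <- load_image_folder(root)
  expect_equal(ds$class_names, c("apple", "mango", "zebra"))
  expect_error(load_image_folder(withr::local_tempdir()), "class subfolder")
})

test_that("images of differing sizes are rejected", {
  root <- withr::local_tempdir()
  dir.create(file.path(root, "a"))
  png::writePNG(array(0.5, c(4, 4, 3)), file.path(root, "a", "1.png"))
  png::writePNG(array(0.5, c(8, 8, 3)), file.path(root, "a", "2.png"))
  expect_error(load_image_folder(root), "differing sizes")
})

test_that("validation split is stratified, sized and reproducible", {
  ds <- image_dataset(array(runif(4 * 4 * 3 * 100), c(4, 4, 3, 100)),
                      rep(1:2, each = 50), c("a", "b"))
  sp <- split_train_validation(ds, 0.1, seed = 3)
  expect_equal(dim(sp$validation$images)[4], 10)
  expect_equal(tabulate(sp$validation$labels), c(5, 5))
  expect_equal(dim(sp$train$images)[4], 90)
  sp2 <- split_train_validation(ds, 0.1, seed = 3)
  expect_identical(sp$validation$images, sp2$validation$images)
  # half split of 4 per class -> 2 + 2
  ds4 <- image_dataset(array(0.5, c(4, 4, 3, 8)), rep(1:2, each = 4),
                       c("a", "b"))
  sp4 <- split_train_validation(ds4, 0.5, seed = 1)
  expect_equal(tabulate(sp4$validation$labels), c(2, 2))
  expect_equal(tabulate(sp4$train$labels), c(2, 2))
  # singleton class cannot be split
  ds1 <- image_dataset(array(0.5, c(4, 4, 3, 3)), c(1L, 1L, 2L), c("a", "b"))
  expect_error(split_train_validation(ds1, 0.1), "at least 2 samples")
})

test_that("train and validation never share a sample", {
  ds <- generate_dataset(tiny_spec())
  sp <- split_train_validation(ds, 0.25, seed = 7)
  expect_equal(dim(sp$train$images)[4] + dim(sp$validation$images)[4],
               dim(ds$images)[4])
  # fingerprints: noisy continuous images are unique with probability 1
  fp <- function(d) apply(d$images, 4, function(x) paste(head(x, 6), collapse = ","))
  expect_length(intersect(fp(sp$train), fp(sp$validation)), 0)
})

test_that("metric tables round trip losslessly through CSV", {
  tb <- random_metric_table(5, 3, seed = 11)
  path <- withr::local_tempfile(fileext = ".csv")
  write_metric_table(tb, path)
  back <- read_metric_table(path)
  expect_equal(unname(back$values), unname(tb$values))
  expect_equal(back$treatment_labels, tb$treatment_labels)
  expect_equal(back$block_labels, tb$block_labels)
})

test_that("ragged rows and non-numeric cells fail with the cell named", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("block,A,B", "r1,1.0,2.0", "r2,3.0"), path)
  expect_error(read_metric_table(path), "row 3")
  writeLines(c("block,A,B", "r1,1.0,2.0", "r2,3.0,oops"), path)
  expect_error(read_metric_table(path), "row 3.*'B'")
  writeLines(c("block,A,B", "r1,1.0,", "r2,3.0,1"), path)
  expect_error(read_metric_table(path), "row 2")
})

test_that("the shipped benchmark fixtures load with the published shape", {
  tb <- read_metric_table(system.file("extdata", "plant_accuracy.csv",
                                      package = "caecnn"))
  expect_equal(dim(tb$values), c(4L, 3L))
  expect_equal(tb$treatment_labels, c("Traditional", "MD", "CAE"))
  combined <- benchmark_table("accuracy")
  expect_equal(nrow(combined$values), 12L)
  expect_equal(combined$values["plant/VGG", "CAE"], 87.6)
})
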