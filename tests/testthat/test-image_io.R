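test_that("BMP and PNG round-trips are bit-identical", {
  px <- random_rgb_array(8, 8, seed = 42)
  img <- rgb_image(px, source_id = "rt", label = "C")
  for (ext in c("bmp", "png")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    save_image(img, path)
    back <- load_image(path)
    expect_identical(back$pixels, img$pixels, label = ext)
  }
  # odd width exercises BMP row padding
  px2 <- random_rgb_array(5, 7, seed = 43)
  path <- withr::local_tempfile(fileext = ".bmp")
  save_image(px2, path)
  expect_identical(load_image(path)$pixels, px2)
})

test_that("load_image rejects malformed input with a named property", {
  grey_png <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(runif(16), 4, 4), grey_png)
  expect_error(load_image(grey_png), "3-channel")
  rgba_png <- withr::local_tempfile(fileext = ".png")
  png::writePNG(array(runif(64), c(4, 4, 4)), rgba_png)
  expect_error(load_image(rgba_png), "3-channel")
  expect_error(load_image("no/such/file.png"), "exist")
  txt <- withr::local_tempfile(fileext = ".bmp")
  writeLines("not a bitmap", txt)
  expect_error(load_image(txt), "not a BMP")
})

test_that("an all-zero PNG loads as zeros", {
  path <- withr::local_tempfile(fileext = ".png")
  png::writePNG(array(0, c(4, 4, 3)), path)
  expect_true(all(load_image(path)$pixels == 0L))
})

test_that("reduce_resolution matches the stated dimensions and block means", {
  px <- random_rgb_array(512, 680, seed = 7)
  img <- rgb_image(px, label = "C")
  half <- reduce_resolution(img, 2L)
  expect_identical(dim(half$pixels), c(256L, 340L, 3L))
  expect_identical(half$resolution, "half")
  quarter <- reduce_resolution(img, 4L)
  expect_identical(dim(quarter$pixels), c(128L, 170L, 3L))
  expect_identical(quarter$resolution, "quarter")
  # identity at factor 1
  expect_identical(reduce_resolution(img, 1L)$pixels, img$pixels)
  # hand-derived 2x2 block mean
  one <- array(0, c(2, 2, 3)); one[, , 1] <- matrix(c(10, 30, 20, 40), 2, 2)
  expect_equal(as.vector(reduce_resolution(rgb_image(one), 2L)$pixels[1, 1, ]),
               c(25, 0, 0))
  expect_error(reduce_resolution(rgb_image(random_rgb_array(6, 6)), 4L),
               "dimension error")
})

test_that("two half reductions agree with one quarter reduction within rounding", {
  px <- random_rgb_array(64, 96, seed = 11)
  img <- rgb_image(px)
  twice <- reduce_resolution(reduce_resolution(img, 2L), 2L)
  once <- reduce_resolution(img, 4L)
  expect_lte(max(abs(twice$pixels - once$pixels)), 1L)
})

test_that("extract_rois tiles a centered region into 4 disjoint ROIs", {
  px <- random_rgb_array(100, 100, seed = 3)
  rois <- extract_rois(rgb_image(px, source_id = "p", label = "F"), margin = 0)
  expect_length(rois, 4L)
  for (r in rois) expect_identical(dim(r$pixels), c(50L, 50L, 3L))
  expect_identical(vapply(rois, function(r) r$position, integer(1)), 0:3)
  # exact partition: every pixel of the source appears exactly once
  total <- sum(vapply(rois, function(r) sum(r$pixels[, , 1]), numeric(1)))
  expect_equal(total, sum(px[, , 1]))
  # odd dimensions: far row/column dropped
  rois101 <- extract_rois(rgb_image(random_rgb_array(101, 101)), margin = 0)
  for (r in rois101) expect_identical(dim(r$pixels)[1:2], c(50L, 50L))
  expect_error(extract_rois(rgb_image(random_rgb_array(40, 40)), margin = 0.2),
               "size error")
  expect_error(extract_rois(rgb_image(random_rgb_array(64, 64)), margin = 0.5),
               "margin")
})

test_that("7 F + 5 C images yield 28 and 20 labeled ROIs", {
  imgs <- c(lapply(1:5, function(i) rgb_image(random_rgb_array(64, 64, i), label = "C")),
            lapply(1:7, function(i) rgb_image(random_rgb_array(64, 64, 10 + i), label = "F")))
  rois <- unlist(lapply(imgs, extract_rois, margin = 0), recursive = FALSE)
  expect_identical(label_counts(rois), c(20L, 28L))
})
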