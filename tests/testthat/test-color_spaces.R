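px1 <- function(r, g, b) array(c(r, g, b), c(1, 1, 3))

test_that("luminance projection uses the BT.601 weights", {
  expect_equal(as.numeric(rgb_to_grey(px1(255, 255, 255))), 255)
  expect_equal(as.numeric(rgb_to_grey(px1(0, 0, 0))), 0)
  expect_equal(as.numeric(rgb_to_grey(px1(100, 150, 50))), 124)
  expect_error(rgb_to_grey(px1(1, 1, 1), weights = c(0.5, 0.5, 0.5)), "sum to 1")
})

test_that("split_rgb is a lossless projection", {
  px <- random_rgb_array(6, 9, seed = 5)
  ch <- split_rgb(px)
  expect_equal(unclass(ch$G), px[, , 2], ignore_attr = TRUE)
  pure <- split_rgb(px1(0, 255, 0))
  expect_true(all(pure$G == 255) && all(pure$R == 0) && all(pure$B == 0))
  recombined <- array(0, dim(px))
  recombined[, , 1] <- ch$R; recombined[, , 2] <- ch$G; recombined[, , 3] <- ch$B
  expect_equal(recombined, px, ignore_attr = TRUE)
})

test_that("HSI conversion matches the closed forms", {
  grey <- rgb_to_hsi(px1(200, 200, 200))
  expect_equal(as.numeric(grey$S), 0)
  expect_equal(as.numeric(grey$H), 0)
  expect_equal(as.numeric(grey$I), 200 / 255, tolerance = 1e-12)
  red <- rgb_to_hsi(px1(255, 0, 0))
  expect_equal(as.numeric(red$H), 0)
  expect_equal(as.numeric(red$S), 1)
  expect_equal(as.numeric(red$I), 1 / 3, tolerance = 1e-12)
  green <- rgb_to_hsi(px1(0, 255, 0))
  expect_equal(as.numeric(green$H), 120, tolerance = 1e-9)
  expect_equal(as.numeric(green$S), 1)
  blueish <- rgb_to_hsi(px1(0, 0, 255))      # b > g branch
  expect_equal(as.numeric(blueish$H), 240, tolerance = 1e-9)
  black <- rgb_to_hsi(px1(0, 0, 0))
  expect_equal(as.numeric(black$S), 0)
})

test_that("HSI invariants hold on random pixels", {
  withr::local_seed(99)
  px <- array(sample(0:255, 300, replace = TRUE), c(10, 10, 3))
  hsi <- rgb_to_hsi(px)
  r <- px[, , 1] / 255; g <- px[, , 2] / 255; b <- px[, , 3] / 255
  expect_true(all(hsi$S >= 0 & hsi$S <= 1))
  expect_true(all(hsi$H >= 0 & hsi$H < 360))
  expect_true(all(hsi$I >= pmin(r, g, b) - 1e-12 & hsi$I <= pmax(r, g, b) + 1e-12))
  # common intensity scaling: H, S unchanged, I scales by k
  for (k in c(0.25, 0.6)) {
    scaled <- rgb_to_hsi(px * k)
    expect_equal(unclass(scaled$H), unclass(hsi$H), tolerance = 1e-9)
    expect_equal(unclass(scaled$S), unclass(hsi$S), tolerance = 1e-9)
    expect_equal(unclass(scaled$I), unclass(hsi$I) * k, tolerance = 1e-12)
  }
})

test_that("achromatic pixels have grey equal to every channel", {
  v <- matrix(sample(0:255, 25, replace = TRUE), 5, 5)
  px <- array(0, c(5, 5, 3)); for (ch in 1:3) px[, , ch] <- v
  expect_equal(unclass(rgb_to_grey(px)), v, ignore_attr = TRUE)
})

test_that("quantize_channel maps H, S, I onto [0, 255] and passes RGB through", {
  h <- channel_image(matrix(c(0, 180, 359.999), 1), "H", c(0, 360))
  qh <- quantize_channel(h)
  expect_equal(as.numeric(qh), c(0, round(180 / 360 * 255), 255))
  s <- channel_image(matrix(c(0, 0.5, 1), 1), "S", c(0, 1))
  expect_equal(as.numeric(quantize_channel(s)), c(0, 128, 255))
  r <- channel_image(matrix(c(0, 17, 255), 1), "R", c(0, 255))
  expect_equal(as.numeric(quantize_channel(r)), c(0, 17, 255))
})

test_that("analysis_channels returns the requested tagged views", {
  px <- random_rgb_array(8, 8, seed = 2)
  chs <- analysis_channels(px)
  expect_identical(names(chs), c("grey", "R", "G", "B", "H", "S", "I"))
  for (nm in names(chs)) {
    expect_identical(attr(chs[[nm]], "channel"), nm)
    expect_true(all(chs[[nm]] >= 0 & chs[[nm]] <= 255))
  }
  expect_identical(names(analysis_channels(px, c("R", "G", "B"))), c("R", "G", "B"))
})
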