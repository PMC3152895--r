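make_table <- function(n_c = 4, n_f = 6, feats) {
  feature_table(sprintf("s%02d", seq_len(n_c + n_f)),
                c(rep("C", n_c), rep("F", n_f)), feats)
}

test_that("pooling concatenates channel tables with prefixed names", {
  withr::local_seed(67)
  feats <- function() as.data.frame(matrix(rnorm(10 * 11), 10,
                                           dimnames = list(NULL, com_feature_names)))
  tabs <- list(R = make_table(feats = feats()), G = make_table(feats = feats()),
               B = make_table(feats = feats()))
  pooled <- pool_scheme(tabs, "RGB")
  fc <- setdiff(names(pooled), c("sample_id", "label"))
  expect_length(fc, 33L)
  expect_true("G_Sum Variance" %in% fc)
  expect_identical(sum(startsWith(fc, "R_")), 11L)
  # greylevel passes through unprefixed
  grey <- pool_scheme(list(grey = make_table(feats = feats())), "greylevel")
  expect_true("Sum of Squares" %in% names(grey))
  # self-pooling duplicates values under two prefixes
  dup <- pool_scheme(list(H = tabs$R, S = tabs$R), "HSI")
  expect_equal(dup[["H_Contrast"]], dup[["S_Contrast"]])
  expect_length(setdiff(names(dup), c("sample_id", "label")), 22L)
  # misaligned samples refuse to pool
  bad <- tabs$G; bad$sample_id[1] <- "zz"
  expect_error(pool_scheme(list(R = tabs$R, G = bad), "RGB"), "alignment")
})

test_that("Fisher coefficient closed forms and degenerate rules", {
  expect_equal(fisher_coefficient(c(1, 2, 3, 7, 8, 9),
                                  c("C", "C", "C", "F", "F", "F")), 18)
  expect_equal(fisher_coefficient(c(1, 2, 1, 2), c("C", "C", "F", "F")), 0)
  expect_identical(fisher_coefficient(c(0, 0, 1, 1), c("C", "C", "F", "F")), Inf)
  expect_equal(fisher_coefficient(rep(5, 6), rep(c("C", "F"), 3)), 0)
  expect_error(fisher_coefficient(1:3, c("C", "F", "F")), "at least 2 samples")
  expect_error(fisher_coefficient(1:4, rep("C", 4)), "two classes")
})

test_that("Fisher coefficient is affine-invariant", {
  withr::local_seed(71)
  v <- rnorm(12); lab <- rep(c("C", "F"), each = 6)
  f0 <- fisher_coefficient(v, lab)
  for (i in 1:5) {
    a <- runif(1, -4, 4); if (a == 0) a <- 1
    expect_equal(fisher_coefficient(a * v + runif(1, -9, 9), lab), f0,
                 tolerance = 1e-9)
  }
})

test_that("select_top returns the k most discriminating features", {
  withr::local_seed(73)
  n <- 12; lab01 <- rep(c(0, 1), each = 6)
  feats <- data.frame(noise1 = rnorm(n), perfect = lab01, noise2 = rnorm(n),
                      weak = lab01 + rnorm(n, sd = 2))
  tab <- feature_table(sprintf("s%d", 1:n), ifelse(lab01 == 0, "C", "F"), feats)
  top <- select_top(tab, k = 3)
  expect_identical(nrow(top), 3L)
  expect_identical(top$feature[1], "perfect")
  expect_identical(top$F[1], Inf)
  expect_true(all(diff(top$F) <= 0))
  expect_error(select_top(tab, k = 5), "fewer than k")
  small <- feature_table(sprintf("t%d", 1:6), rep(c("C", "F"), each = 3),
                         feats[1:6, ])
  expect_error(select_top(small, k = 4), "exceeds the smaller class")
})

test_that("ties break by column order, independent of sample order", {
  n <- 8; lab <- rep(c("C", "F"), each = 4)
  v <- c(1, 2, 3, 4, 11, 12, 13, 14)
  tab <- feature_table(sprintf("s%d", 1:n), lab,
                       data.frame(b_copy = v, a_copy = v, c_other = rev(v)))
  top <- select_top(tab, k = 2)
  expect_identical(top$feature, c("b_copy", "a_copy"))
  perm <- sample(n)
  tab2 <- feature_table(tab$sample_id[perm], tab$label[perm],
                        data.frame(b_copy = v[perm], a_copy = v[perm],
                                   c_other = rev(v)[perm]))
  expect_identical(select_top(tab2, k = 2)$feature, top$feature)
})

test_that("signal confined to the G channel yields G-prefixed selections", {
  withr::local_seed(79)
  n <- 16; lab01 <- rep(c(0, 1), each = 8)
  mk <- function(signal) as.data.frame(matrix(rnorm(n * 5), n,
            dimnames = list(NULL, paste0("f", 1:5)))) +
        if (signal) lab01 * 6 else 0
  tabs <- list(R = make_table(8, 8, mk(FALSE)), G = make_table(8, 8, mk(TRUE)),
               B = make_table(8, 8, mk(FALSE)))
  top <- select_top(pool_scheme(tabs, "RGB"), k = 3)
  expect_true(all(startsWith(top$feature, "G_")))
})
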