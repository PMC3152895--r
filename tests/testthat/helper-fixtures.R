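# Small-scale fixtures built in code at test time.

# A fast synthetic world: same generative process at 160 x 200 pixels, so
# that quarter-resolution ROIs (40 x 50, margin 0.05) stay above the 16 x 16
# floor. Used by module tests; acceptance tests use the full-size defaults.
tiny_config <- function(seed = 0L, collagen_lambda = 8L, ...) {
  synthetic_config(rows = 160L, columns = 200L, n_nuclei = 30L,
                   collagen_lambda = collagen_lambda, seed = seed, ...)
}

label_counts <- function(rois) {
  labels <- vapply(rois, function(r) r$label, character(1))
  as.integer(table(labels)[c("C", "F")])
}

random_rgb_array <- function(nr, nc, seed = 1L) {
  withr::with_seed(seed, array(sample(0:255, nr * nc * 3, replace = TRUE),
                               c(nr, nc, 3L)))
}

# Two-class image set with an obvious class difference in every channel:
# class F gets a bright block. Deterministic, no RNG.
blocky_images <- function(n_c = 2L, n_f = 2L, nr = 80L, nc = 96L, achromatic = FALSE) {
  mk <- function(label, i) {
    base <- matrix(60 + ((seq_len(nr) + i) %% 7) * 10, nr, nc)
    if (label == "F") base[20:60, 20:60] <- 220
    px <- array(0, c(nr, nc, 3L))
    if (achromatic) for (ch in 1:3) px[, , ch] <- base
    else { px[, , 1] <- base; px[, , 2] <- pmin(base * 1.2, 255); px[, , 3] <- base / 2 }
    rgb_image(round(px), source_id = sprintf("%s%d", label, i), label = label)
  }
  c(lapply(seq_len(n_c), function(i) mk("C", i)),
    lapply(seq_len(n_f), function(i) mk("F", i)))
}
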