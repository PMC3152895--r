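#' Channel image container
#'
#' A single-channel view of an image region: a numeric matrix tagged with the
#' channel it came from and its native value range. R, G, B and grey live in
#' \[0, 255\]; S and I in \[0, 1\]; H in \[0, 360) degrees.
#'
#' @param pixels numeric matrix.
#' @param channel one of `"grey"`, `"R"`, `"G"`, `"B"`, `"H"`, `"S"`, `"I"`.
#' @param range length-2 numeric, the nominal (min, max) of the channel.
#' @return An object of class `channel_image`.
#' @export
channel_image <- function(pixels, channel, range) {
  if (!is.matrix(pixels)) stop("pixels must be a matrix")
  if (!channel %in% c("grey", "R", "G", "B", "H", "S", "I"))
    stop("unknown channel tag: ", channel)
  structure(pixels, channel = channel, range = range, class = "channel_image")
}

channel_tag <- function(x) attr(x, "channel")

# Channel slice that never drops the matrix shape (1 x 1 images included).
chan <- function(px, k) matrix(px[, , k], dim(px)[1], dim(px)[2])

#' Project an RGB image onto grey-scale luminance
#'
#' Per-pixel luminance Y = 0.299 R + 0.587 G + 0.114 B (the ITU-R BT.601
#' weighting, the most common grey-scale projection), rounded to the nearest
#' integer in \[0, 255\].
#'
#' @param image an [rgb_image] or rows x cols x 3 array in \[0, 255\].
#' @param weights luminance weights for (R, G, B); must sum to 1.
#' @return A [channel_image] tagged `"grey"`.
#' @export
rgb_to_grey <- function(image, weights = c(0.299, 0.587, 0.114)) {
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  px <- as_pixel_array(image)
  y <- weights[1] * chan(px, 1) + weights[2] * chan(px, 2) + weights[3] * chan(px, 3)
  channel_image(round_half_up(y), "grey", c(0, 255))
}

#' Separate an RGB image into its three channels
#'
#' Each channel is viewed individually as a grey-scale layer with intensity
#' range 0-255; values are copied unmodified.
#'
#' @inheritParams rgb_to_grey
#' @return Named list of three [channel_image]s: `R`, `G`, `B`.
#' @export
split_rgb <- function(image) {
  px <- as_pixel_array(image)
  list(R = channel_image(chan(px, 1), "R", c(0, 255)),
       G = channel_image(chan(px, 2), "G", c(0, 255)),
       B = channel_image(chan(px, 3), "B", c(0, 255)))
}

#' Convert an RGB image to HSI
#'
#' The HSI space separates chromaticity (hue, saturation) from intensity.
#' With r, g, b the channels scaled to \[0, 1\]:
#' I = (r + g + b) / 3; S = 1 - 3 min(r, g, b) / (r + g + b) (0 for a black
#' pixel); H = theta if b <= g else 360 - theta, with
#' theta = arccos\{ ((r - g) + (r - b)) / 2 / sqrt((r - g)^2 + (r - b)(g - b)) \}
#' in degrees. Achromatic pixels (S = 0) take H = 0; the arccos argument is
#' clamped to \[-1, 1\] against floating-point overshoot.
#'
#' @inheritParams rgb_to_grey
#' @return Named list of three [channel_image]s: `H` (degrees, \[0, 360)),
#'   `S` and `I` (both \[0, 1\]).
#' @export
rgb_to_hsi <- function(image) {
  px <- as_pixel_array(image)
  r <- chan(px, 1) / 255; g <- chan(px, 2) / 255; b <- chan(px, 3) / 255
  s3 <- r + g + b
  i <- s3 / 3
  s <- matrix(0, nrow(i), ncol(i))
  nz <- s3 > 0
  s[nz] <- 1 - 3 * pmin(r, g, b)[nz] / s3[nz]
  num <- ((r - g) + (r - b)) / 2
  den <- sqrt((r - g)^2 + (r - b) * (g - b))
  theta <- matrix(0, nrow(i), ncol(i))
  ok <- den > 0
  theta[ok] <- acos(pmin(pmax(num[ok] / den[ok], -1), 1)) * 180 / pi
  h <- ifelse(b <= g, theta, 360 - theta)
  h[s == 0] <- 0
  list(H = channel_image(h, "H", c(0, 360)),
       S = channel_image(s, "S", c(0, 1)),
       I = channel_image(i, "I", c(0, 1)))
}

#' Re-quantize a channel onto the 8-bit range
#'
#' Texture engines need integer grey levels, so H is mapped linearly from
#' \[0, 360) and S, I from \[0, 1\] onto \[0, 255\] and rounded; R, G, B and
#' grey pass through unchanged. This makes all channels commensurate before
#' the standard normalization.
#'
#' @param ch a [channel_image].
#' @return A [channel_image] with integer values in \[0, 255\].
#' @export
quantize_channel <- function(ch) {
  tag <- channel_tag(ch)
  px <- unclass(ch); attributes(px) <- list(dim = dim(ch))
  out <- switch(tag,
    H = round_half_up(px / 360 * 255),
    S = , I = round_half_up(px * 255),
    px)
  channel_image(out, tag, c(0, 255))
}

#' All analysis channels of an RGB image or ROI
#'
#' Convenience wrapper producing the seven single-channel views used by the
#' three schemes (grey | R, G, B | H, S, I), each re-quantized to \[0, 255\].
#'
#' @inheritParams rgb_to_grey
#' @param channels subset of channel tags to compute.
#' @return Named list of [channel_image]s.
#' @export
analysis_channels <- function(image,
                              channels = c("grey", "R", "G", "B", "H", "S", "I")) {
  out <- list()
  if ("grey" %in% channels) out$grey <- rgb_to_grey(image)
  if (any(c("R", "G", "B") %in% channels))
    out <- c(out, split_rgb(image)[intersect(c("R", "G", "B"), channels)])
  if (any(c("H", "S", "I") %in% channels)) {
    hsi <- rgb_to_hsi(image)[intersect(c("H", "S", "I"), channels)]
    out <- c(out, lapply(hsi, quantize_channel))
  }
  out[intersect(channels, names(out))]
}
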