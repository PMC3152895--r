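#' Normalize an ROI to the 1-128 grey-level range
#'
#' Removes the dependency on pixel intensity mean: values are clipped to
#' mu +/- 3 sigma (mu, sigma computed over the ROI, sigma the population
#' standard deviation), the interval \[mu - 3 sigma, mu + 3 sigma\] is mapped
#' linearly onto \[1, 128\] and rounded half-up, i.e. a 7-bit quantization.
#' A constant ROI (sigma = 0) maps every pixel to the mid level 64. The
#' result is invariant under any affine intensity change v -> a v + b, a > 0,
#' that does not engage the clip.
#'
#' @param roi a numeric matrix, [channel_image], or single-channel `roi`.
#' @return Integer matrix of class `normalized_roi` with values in \[1, 128\]
#'   and attribute `Ng = 128`.
#' @export
normalize_roi <- function(roi) {
  px <- if (inherits(roi, "roi")) roi$pixels else unclass(roi)
  if (!is.null(dim(px)) && length(dim(px)) == 3L) {
    if (dim(px)[3] != 1L) stop("normalize_roi needs a single channel")
    px <- px[, , 1]
  }
  attributes(px) <- list(dim = dim(px))
  if (length(px) < 2L) stop("input error: ROI must have at least 2 pixels")
  mu <- mean(px)
  sigma <- sqrt(mean((px - mu)^2))
  if (sigma == 0) {
    out <- matrix(64L, nrow(px), ncol(px))
  } else {
    lo <- mu - 3 * sigma
    v <- pmin(pmax(px, lo), mu + 3 * sigma)
    out <- round_half_up(1 + (v - lo) / (6 * sigma) * 127)
    out[out < 1] <- 1
    out[out > 128] <- 128
    storage.mode(out) <- "integer"
  }
  structure(out, Ng = 128L, class = "normalized_roi")
}

roi_levels <- function(roi) {
  ng <- attr(roi, "Ng")
  if (is.null(ng)) max(roi) else ng
}
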