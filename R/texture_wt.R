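# One orthonormal Haar analysis step along rows (combining adjacent rows).
# An odd trailing row is dropped before filtering; padding would inject
# artificial edges into the texture energy.
haar_rows <- function(m) {
  if (nrow(m) %% 2L) m <- m[-nrow(m), , drop = FALSE]
  o <- m[seq(1L, nrow(m), 2L), , drop = FALSE]
  e <- m[seq(2L, nrow(m), 2L), , drop = FALSE]
  list(lo = (o + e) / sqrt(2), hi = (o - e) / sqrt(2))
}

# Full separable step: returns LL and the three detail subbands.
haar_step <- function(m) {
  if (nrow(m) %% 2L) m <- m[-nrow(m), , drop = FALSE]
  if (ncol(m) %% 2L) m <- m[, -ncol(m), drop = FALSE]
  r <- haar_rows(m)
  cl <- lapply(r, function(x) haar_rows(t(x)))
  list(LL = t(cl$lo$lo), LH = t(cl$lo$hi),
       HL = t(cl$hi$lo), HH = t(cl$hi$hi))
}

#' Maximum wavelet decomposition depth for an ROI
#'
#' floor(log2(min(rows, columns))) - 1, capped at 5: a 128-row ROI supports
#' the scale-5 energy reported at full resolution, a 64-row ROI at least
#' scale 3.
#'
#' @param roi matrix (or anything with a `dim`).
#' @return Integer depth.
#' @export
wavelet_max_level <- function(roi) {
  as.integer(min(floor(log2(min(dim(roi)))) - 1, 5))
}

#' Wavelet subband energies per scale
#'
#' Performs an n_max-level separable orthonormal Haar decomposition of the
#' ROI (odd dimensions at any level are truncated before filtering) and
#' returns, per scale n, the energy E_n: the sum of squared coefficients over
#' the three detail subbands (LH, HL, HH) at that scale divided by the number
#' of coefficients summed. E_n is zero for a constant ROI and invariant to
#' adding a constant to all pixels.
#'
#' @param roi numeric matrix, at least 8 x 8.
#' @param n_max decomposition depth (default [wavelet_max_level]).
#' @return Named numeric vector `E_1` .. `E_<n_max>` of class
#'   `wavelet_energies`, with attribute `wavelet = "haar"`.
#' @export
wavelet_energies <- function(roi, n_max = NULL) {
  m <- unclass(roi); attributes(m) <- list(dim = dim(roi))
  if (nrow(m) < 8L || ncol(m) < 8L)
    stop("size error: ROI must be at least 8 x 8")
  if (is.null(n_max)) n_max <- wavelet_max_level(m)
  if (n_max < 1L) stop("n_max must be at least 1")
  e <- numeric(n_max)
  storage.mode(m) <- "double"
  for (n in seq_len(n_max)) {
    if (nrow(m) < 2L || ncol(m) < 2L)
      stop("size error: ROI exhausted before level ", n)
    s <- haar_step(m)
    det2 <- c(s$LH^2, s$HL^2, s$HH^2)
    e[n] <- sum(det2) / length(det2)
    m <- s$LL
  }
  structure(stats::setNames(e, paste0("E_", seq_len(n_max))),
            wavelet = "haar", class = "wavelet_energies")
}
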