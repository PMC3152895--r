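#' Grey-level co-occurrence matrix at d = 1, theta = 0 degrees
#'
#' Counts every horizontally adjacent ordered pair (Im(x, y), Im(x, y+1)),
#' adds the transpose (symmetrization, the standard Haralick convention, so
#' that the marginal means coincide and Correlation is well defined), and
#' normalizes to joint probabilities summing to 1.
#'
#' @param roi integer matrix of grey levels in 1..Ng (a [normalize_roi]
#'   output, or any positive-integer matrix for testing).
#' @param Ng number of grey levels; defaults to the ROI's `Ng` attribute
#'   (128 for normalized ROIs) or the maximum value present.
#' @return An Ng x Ng probability matrix of class `co_matrix` with attributes
#'   `d = 1`, `theta = 0`.
#' @export
compute_com <- function(roi, Ng = NULL) {
  m <- unclass(roi); attributes(m) <- list(dim = dim(roi))
  if (ncol(m) < 2L) stop("geometry error: ROI must have at least 2 columns")
  if (is.null(Ng)) Ng <- roi_levels(roi)
  a <- m[, -ncol(m), drop = FALSE]
  b <- m[, -1L, drop = FALSE]
  counts <- tabulate((a - 1L) * Ng + b, nbins = Ng * Ng)
  cm <- matrix(counts, Ng, Ng, byrow = TRUE)   # cm[i, j] = #{(i, j) pairs}
  cm <- cm + t(cm)
  structure(cm / sum(cm), d = 1L, theta = 0, class = "co_matrix")
}

com_feature_names <- c(
  "Angular Second Moment", "Contrast", "Correlation", "Entropy",
  "Sum of Squares", "Inverse Difference Moment", "Sum Average",
  "Sum Variance", "Sum Entropy", "Difference Variance", "Difference Entropy")

xlogx <- function(p) ifelse(p > 0, p * log(p), 0)  # 0 log 0 = 0, natural log

#' The 11 co-occurrence (Haralick) features
#'
#' Classical definitions on the joint probability matrix p(i, j) with
#' marginals p_x, p_y and the sum/difference distributions p_{x+y}, p_{x-y}:
#' angular second moment, contrast, correlation, entropy, sum of squares
#' (variance), inverse difference moment, sum average, sum variance, sum
#' entropy, difference variance and difference entropy. Natural logarithms;
#' Correlation is defined as 0 when a single grey level is present
#' (sigma_x = 0).
#'
#' @param m a `co_matrix` from [compute_com].
#' @return Named numeric vector of length 11.
#' @export
com_features <- function(m) {
  p <- unclass(m); attributes(p) <- list(dim = dim(m))
  ng <- nrow(p)
  i <- row(p); j <- col(p)
  px <- rowSums(p); py <- colSums(p)
  lev <- seq_len(ng)
  mx <- sum(lev * px); my <- sum(lev * py)
  sx <- sqrt(sum((lev - mx)^2 * px)); sy <- sqrt(sum((lev - my)^2 * py))
  # p_{x+y}(k), k = 2..2Ng ; p_{x-y}(n), n = 0..Ng-1
  psum  <- as.vector(rowsum(as.vector(p), as.vector(i + j)))
  ksum  <- sort(unique(as.vector(i + j)))
  pdiff <- as.vector(rowsum(as.vector(p), as.vector(abs(i - j))))
  ndiff <- sort(unique(as.vector(abs(i - j))))

  asm      <- sum(p^2)
  contrast <- sum(ndiff^2 * pdiff)
  corr     <- if (sx == 0 || sy == 0) 0 else (sum(i * j * p) - mx * my) / (sx * sy)
  entropy  <- -sum(xlogx(p))
  sos      <- sum((i - mx)^2 * p)
  idm      <- sum(p / (1 + (i - j)^2))
  savg     <- sum(ksum * psum)
  svar     <- sum((ksum - savg)^2 * psum)
  sent     <- -sum(xlogx(psum))
  dmean    <- sum(ndiff * pdiff)
  dvar     <- sum((ndiff - dmean)^2 * pdiff)
  dent     <- -sum(xlogx(pdiff))

  stats::setNames(c(asm, contrast, corr, entropy, sos, idm, savg, svar, sent,
                    dvar, dent), com_feature_names)
}
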