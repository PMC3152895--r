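rlm_directions <- c("0" = 0, "45" = 45, "90" = 90, "135" = 135)

# Decompose the matrix into the scan lines of one direction. Diagonal
# directions traverse every (anti-)diagonal line, including single-pixel
# corners. 45 deg runs along lines of constant row+col (up-right), 135 deg
# along constant row-col (down-right).
direction_lines <- function(m, theta) {
  switch(as.character(theta),
    "0"   = split(m, row(m)),
    "90"  = split(m, col(m)),
    "45"  = split(m, row(m) + col(m)),
    "135" = split(m, row(m) - col(m)),
    stop("theta must be one of 0, 45, 90, 135"))
}

#' Run-length matrix in one direction
#'
#' Scans every maximal run of consecutive equal grey levels along direction
#' theta and counts it in P_theta(i, l) — grey level i by run length l.
#'
#' @param roi integer matrix of grey levels in 1..Ng.
#' @param theta direction in degrees: 0 (horizontal), 90 (vertical), 45
#'   or 135.
#' @param Ng number of grey levels (default: `Ng` attribute or max level).
#' @return Integer Ng x L_max count matrix of class `rl_matrix` with
#'   attributes `theta`, `n_runs` and `n_pixels`.
#' @export
compute_rlm <- function(roi, theta, Ng = NULL) {
  m <- unclass(roi); attributes(m) <- list(dim = dim(roi))
  if (is.null(Ng)) Ng <- roi_levels(roi)
  lines <- direction_lines(m, theta)
  # single rle over all lines, NA-separated so runs never cross lines
  flat <- unlist(lapply(lines, function(v) c(v, NA_integer_)), use.names = FALSE)
  r <- rle(flat)
  keep <- !is.na(r$values)
  val <- r$values[keep]; len <- r$lengths[keep]
  lmax <- max(len)
  counts <- matrix(0L, Ng, lmax)
  idx <- (len - 1L) * Ng + val              # column-major (val, len) cell
  tab <- tabulate(idx, nbins = Ng * lmax)
  counts[] <- tab
  structure(counts, theta = theta, n_runs = length(val),
            n_pixels = length(m), class = "rl_matrix")
}

rlm_feature_names <- c("Short Run Emphasis", "Long Run Emphasis",
                       "Greylevel Non-uniformity", "Run Length Non-uniformity",
                       "Fraction")

#' The five run-length features
#'
#' Short run emphasis, long run emphasis, grey-level non-uniformity, run
#' length non-uniformity and run fraction (fraction of image pixels that
#' start a run). Predominantly long runs indicate coarse texture; short runs
#' fine texture.
#'
#' @param m an `rl_matrix` from [compute_rlm].
#' @return Named numeric vector of length 5.
#' @export
rlm_features <- function(m) {
  r <- unclass(m); attributes(r) <- list(dim = dim(m))
  n_runs <- attr(m, "n_runs"); n_pix <- attr(m, "n_pixels")
  if (is.null(n_runs) || n_runs < 1L) stop("input error: empty run-length matrix")
  l <- col(r)
  sre <- sum(r / l^2) / n_runs
  lre <- sum(r * l^2) / n_runs
  gln <- sum(rowSums(r)^2) / n_runs
  rln <- sum(colSums(r)^2) / n_runs
  frac <- n_runs / n_pix
  stats::setNames(c(sre, lre, gln, rln, frac), rlm_feature_names)
}

rlm_direction_labels <- c("0" = "Horizontal", "45" = "45\u00b0",
                          "90" = "Vertical", "135" = "135\u00b0")

#' All run-length features over the four directions
#'
#' Computes the five features in each of the directions 0, 45, 90, 135
#' degrees and names them with the direction prefix used in reported feature
#' tables (e.g. `"Horizontal Greylevel Non-uniformity"`,
#' `"45\u00b0 Long Run Emphasis"`).
#'
#' @inheritParams compute_rlm
#' @return Named numeric vector of length 20.
#' @export
rlm_all_directions <- function(roi, Ng = NULL) {
  out <- lapply(rlm_directions, function(th) {
    f <- rlm_features(compute_rlm(roi, th, Ng = Ng))
    names(f) <- paste(rlm_direction_labels[[as.character(th)]], names(f))
    f
  })
  unlist(unname(out))
}
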