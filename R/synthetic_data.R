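#' Configuration of the synthetic trichrome generator
#'
#' Describes the generative model for Masson's-trichrome-like liver fields:
#' a pinkish hepatocyte-cytoplasm background of stationary correlated noise,
#' dark blue-purple nuclei, and — for the fibrosis class only — green-dominant
#' curvilinear collagen strands blended over the background. Both classes
#' share the identical process apart from the collagen component.
#'
#' @param rows,columns image size in pixels (native acquisition 512 x 680).
#' @param n_control,n_fibrosis images per group (study sizes 5 and 7).
#' @param background_rgb mean cytoplasm color, length-3 in \[0, 255\].
#' @param blur_sigma background correlation length: Gaussian blur sd, pixels.
#' @param noise_sd per-channel Gaussian noise sd before blurring.
#' @param n_nuclei nuclei per image.
#' @param nucleus_radius inclusive radius range of nuclei, pixels.
#' @param nucleus_rgb nucleus color.
#' @param collagen_lambda number of collagen strands (0 for controls; the
#'   fibrosis severity dial).
#' @param collagen_width strand width, pixels.
#' @param collagen_waviness sd of the per-step direction jitter, radians.
#' @param collagen_rgb collagen color; green-dominant (G >> R, B), as the
#'   trichrome stain renders collagen.
#' @param seed master seed; image i is generated from `seed + i` so any
#'   single image is regenerable in isolation.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(rows = 512L, columns = 680L,
                             n_control = 5L, n_fibrosis = 7L,
                             background_rgb = c(190, 150, 170),
                             blur_sigma = 2.5, noise_sd = 18,
                             n_nuclei = 160L, nucleus_radius = c(2L, 5L),
                             nucleus_rgb = c(70, 55, 110),
                             collagen_lambda = 20L, collagen_width = 4L,
                             collagen_waviness = 0.22,
                             collagen_rgb = c(175, 215, 170),
                             seed = 0L) {
  stopifnot(all(background_rgb >= 0 & background_rgb <= 255),
            all(nucleus_rgb >= 0 & nucleus_rgb <= 255),
            all(collagen_rgb >= 0 & collagen_rgb <= 255),
            collagen_lambda >= 0)
  structure(as.list(environment()), class = "synthetic_config")
}

# Separable Gaussian blur with edge replication; kernel truncated at 3 sigma.
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  rad <- ceiling(3 * sigma)
  w <- stats::dnorm(-rad:rad, sd = sigma); w <- w / sum(w)
  blur_dim <- function(m, along_rows) {
    n <- if (along_rows) nrow(m) else ncol(m)
    out <- 0
    for (k in seq_along(w)) {
      idx <- pmin(pmax(seq_len(n) + (k - rad - 1L), 1L), n)
      out <- out + w[k] * (if (along_rows) m[idx, , drop = FALSE]
                           else m[, idx, drop = FALSE])
    }
    out
  }
  blur_dim(blur_dim(m, TRUE), FALSE)
}

# Offsets of a filled disk of the given radius, as (dr, dc) pairs.
disk_offsets <- function(radius) {
  g <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  g[g$dr^2 + g$dc^2 <= radius^2 + 0.25, , drop = FALSE]
}

# Stamp TRUE into mask at center (r, c) for every in-bounds disk offset.
stamp <- function(mask, r, c, offs) {
  rr <- r + offs$dr; cc <- c + offs$dc
  ok <- rr >= 1L & rr <= nrow(mask) & cc >= 1L & cc <= ncol(mask)
  mask[cbind(rr[ok], cc[ok])] <- TRUE
  mask
}

# One collagen strand: a random-walk polyline of disks of width w, clipped
# at the first step that leaves the field. Step length 2 px; the direction
# accumulates Gaussian jitter, giving smooth curvilinear strands.
strand_mask <- function(mask, config) {
  nr <- nrow(mask); nc <- ncol(mask)
  r0 <- stats::runif(1, 1, nr); c0 <- stats::runif(1, 1, nc)
  ang0 <- stats::runif(1, 0, 2 * pi)
  steps <- sample(150:450, 1L)
  ang <- ang0 + cumsum(stats::rnorm(steps, 0, config$collagen_waviness))
  r <- r0 + cumsum(2 * sin(ang))
  c <- c0 + cumsum(2 * cos(ang))
  out <- which(r < 1 | r > nr | c < 1 | c > nc)
  if (length(out)) {
    keep <- seq_len(out[1L] - 1L)
    r <- r[keep]; c <- c[keep]
  }
  if (!length(r)) return(mask)
  offs <- disk_offsets(max(1L, round(config$collagen_width / 2)))
  rr <- rep(round(r), each = nrow(offs)) + offs$dr
  cc <- rep(round(c), each = nrow(offs)) + offs$dc
  ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
  mask[cbind(rr[ok], cc[ok])] <- TRUE
  mask
}

#' Generate one synthetic liver image
#'
#' Background: per-channel Gaussian noise around the cytoplasm palette,
#' blurred to the configured correlation length. Nuclei: randomly placed
#' filled disks in the nuclear palette. Fibrosis images additionally receive
#' `collagen_lambda` smooth curvilinear strands of the collagen palette
#' blended over the background. Deterministic given (label, config, seed).
#'
#' @param label `"C"` (control, no collagen) or `"F"` (fibrosis).
#' @param config a [synthetic_config].
#' @param seed integer seed for this image.
#' @param source_id identifier stored in the result.
#' @return An [rgb_image].
#' @export
generate_image <- function(label, config = synthetic_config(), seed = 0L,
                           source_id = sprintf("synthetic_%s_seed%d", label, seed)) {
  stopifnot(label %in% c("C", "F"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  nr <- config$rows; nc <- config$columns
  px <- array(0, c(nr, nc, 3L))
  for (ch in 1:3) {
    noise <- matrix(stats::rnorm(nr * nc, 0, config$noise_sd), nr, nc)
    # blur shrinks the noise sd; rescale so the final texture contrast is
    # what noise_sd states
    sm <- gaussian_blur(noise, config$blur_sigma)
    sm <- sm * (config$noise_sd / stats::sd(as.vector(sm)))
    px[, , ch] <- config$background_rgb[ch] + sm
  }
  # nuclei
  offs_by_r <- lapply(seq(config$nucleus_radius[1], config$nucleus_radius[2]),
                      disk_offsets)
  nmask <- matrix(FALSE, nr, nc)
  for (i in seq_len(config$n_nuclei)) {
    rad_i <- sample.int(length(offs_by_r), 1L)
    nmask <- stamp(nmask, sample.int(nr, 1L), sample.int(nc, 1L),
                   offs_by_r[[rad_i]])
  }
  for (ch in 1:3)
    px[, , ch][nmask] <- 0.1 * px[, , ch][nmask] + 0.9 * config$nucleus_rgb[ch]
  # collagen strands (fibrosis only)
  if (label == "F" && config$collagen_lambda > 0) {
    cmask <- matrix(FALSE, nr, nc)
    for (i in seq_len(config$collagen_lambda)) cmask <- strand_mask(cmask, config)
    for (ch in 1:3)
      px[, , ch][cmask] <- 0.2 * px[, , ch][cmask] + 0.8 * config$collagen_rgb[ch]
  }
  px <- round_half_up(pmin(pmax(px, 0), 255))
  rgb_image(px, source_id = source_id, label = label, resolution = "full")
}

#' Generate the full labeled synthetic dataset
#'
#' `n_control` control and `n_fibrosis` fibrosis images (study sizes 5 and 7)
#' from per-image seeds `seed + 1 .. seed + n`, plus a manifest. With the 4
#' ROIs per image this yields 20 C and 28 F ROIs at every resolution.
#'
#' @param config a [synthetic_config] (its `seed` field is the master seed).
#' @return A list: `images` (list of [rgb_image]) and `manifest` (data frame
#'   with source_id, label, seed).
#' @export
generate_dataset <- function(config = synthetic_config()) {
  labels <- c(rep("C", config$n_control), rep("F", config$n_fibrosis))
  ids <- sprintf("img%02d_%s", seq_along(labels), labels)
  images <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    images[[i]] <- generate_image(labels[i], config, seed = config$seed + i,
                                  source_id = ids[i])
  }
  list(images = images,
       manifest = data.frame(source_id = ids, label = labels,
                             seed = as.integer(config$seed) + seq_along(labels),
                             stringsAsFactors = FALSE))
}

#' Write a generated dataset to disk
#'
#' Saves each image (PNG by default, BMP on request) and a manifest CSV
#' (filename, label, seed) into `dir`.
#'
#' @param dataset result of [generate_dataset].
#' @param dir output directory (created if needed).
#' @param format `"png"` or `"bmp"`.
#' @return The manifest data frame with a `filename` column, invisibly.
#' @export
write_dataset <- function(dataset, dir, format = c("png", "bmp")) {
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  man <- dataset$manifest
  man$filename <- sprintf("%s.%s", man$source_id, format)
  for (i in seq_along(dataset$images))
    save_image(dataset$images[[i]], file.path(dir, man$filename[i]))
  write_table_csv(man, file.path(dir, "manifest.csv"))
  invisible(man)
}

#' Load a dataset written by [write_dataset]
#'
#' @param dir directory containing `manifest.csv` and the image files.
#' @return A list with `images` and `manifest`, as [generate_dataset].
#' @export
load_dataset <- function(dir) {
  man <- read_table_csv(file.path(dir, "manifest.csv"))
  images <- lapply(seq_len(nrow(man)), function(i) {
    load_image(file.path(dir, man$filename[i]), label = man$label[i],
               source_id = man$source_id[i])
  })
  list(images = images, manifest = man)
}
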