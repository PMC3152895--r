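#' RGB image container
#'
#' Wraps an integer array of dimension rows x columns x 3 with acquisition
#' metadata. All channel values must lie in \[0, 255\]. The native acquisition
#' size is 512 rows x 680 columns; half and quarter resolution are 256 x 340
#' and 128 x 170.
#'
#' @param pixels numeric or integer array, rows x columns x 3, values in
#'   \[0, 255\].
#' @param source_id character scalar identifying the source image.
#' @param label class label, `"C"` (control) or `"F"` (fibrosis), or `NA`.
#' @param resolution resolution tag: `"full"`, `"half"` or `"quarter"`.
#' @return An object of class `rgb_image`.
#' @export
rgb_image <- function(pixels, source_id = NA_character_, label = NA_character_,
                      resolution = "full") {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("pixels must be a rows x columns x 3 array")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("channel values must lie in [0, 255]")
  if (!is.na(label) && !label %in% c("C", "F"))
    stop("label must be 'C', 'F' or NA")
  storage.mode(pixels) <- "integer"
  structure(list(pixels = pixels, source_id = source_id, label = label,
                 resolution = resolution),
            class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<rgb_image> %d rows x %d cols, label=%s, resolution=%s, id=%s\n",
              d[1], d[2], x$label, x$resolution, x$source_id))
  invisible(x)
}

#' @export
dim.rgb_image <- function(x) dim(x$pixels)

# Pull the pixel array out of an rgb_image, roi, or accept a bare array.
as_pixel_array <- function(x) {
  if (inherits(x, "rgb_image") || inherits(x, "roi")) x$pixels else x
}

round_half_up <- function(x) floor(x + 0.5)

#' Read a BMP or PNG raster image
#'
#' Decodes an 8-bit-per-channel 3-channel raster. BMP support covers the
#' uncompressed 24-bit BI_RGB variant used for the micrographs; PNG is decoded
#' through the png package. Any other layout (palette BMP, RGBA or 16-bit
#' PNG, grayscale) is a format error naming the offending property.
#'
#' @param path path to a `.bmp` or `.png` file.
#' @param label,source_id optional metadata attached to the result;
#'   `source_id` defaults to the file name.
#' @return An [rgb_image].
#' @export
load_image <- function(path, label = NA_character_, source_id = NULL) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    bmp = read_bmp(path),
    png = {
      a <- png::readPNG(path)
      if (length(dim(a)) != 3L || dim(a)[3] != 3L)
        stop("format error: PNG is not 3-channel (found ",
             if (length(dim(a)) == 2L) 1L else dim(a)[3], " channels)")
      v <- a * 255
      if (max(abs(v - round(v))) > 1e-6)
        stop("format error: PNG bit depth is not 8 per channel")
      round(v)
    },
    stop("format error: unsupported extension '", ext, "' (need bmp or png)")
  )
  rgb_image(px, source_id = if (is.null(source_id)) basename(path) else source_id,
            label = label)
}

#' Write an image as BMP or PNG
#'
#' @param image an [rgb_image] or rows x columns x 3 array in \[0, 255\].
#' @param path output path; format chosen by extension (`.bmp` or `.png`).
#' @return `path`, invisibly.
#' @export
save_image <- function(image, path) {
  px <- as_pixel_array(image)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    bmp = write_bmp(px, path),
    png = png::writePNG(px / 255, path),
    stop("unsupported extension '", ext, "'")
  )
  invisible(path)
}

# Minimal uncompressed 24-bit BMP codec (BITMAPINFOHEADER, bottom-up, BGR,
# rows padded to 4 bytes). No pre-installed R package reads BMP.
read_bmp <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  u16 <- function(off) sum(as.integer(raw[off + 1:2]) * c(1, 256))
  u32 <- function(off) sum(as.integer(raw[off + 1:4]) * 256^(0:3))
  if (rawToChar(raw[1:2]) != "BM") stop("format error: not a BMP file")
  data_off <- u32(10)
  hdr_size <- u32(14)
  if (hdr_size < 40L) stop("format error: unsupported BMP header size ", hdr_size)
  width  <- u32(18)
  height <- u32(22)
  bpp    <- u16(28)
  compr  <- u32(30)
  if (bpp != 24L) stop("format error: BMP bit depth is ", bpp, ", need 24")
  if (compr != 0L) stop("format error: compressed BMP not supported")
  top_down <- FALSE
  if (height > 2^31 / 2) { # negative int32: top-down row order
    height <- 2^32 - height
    top_down <- TRUE
  }
  stride <- ((width * 3 + 3) %/% 4) * 4
  px <- array(0L, c(height, width, 3L))
  body <- as.integer(raw[data_off + seq_len(stride * height)])
  rows <- matrix(body, nrow = stride)[seq_len(width * 3), , drop = FALSE]
  # each column of `rows` is one stored row, B,G,R interleaved
  b <- rows[seq(1, width * 3, 3), , drop = FALSE]
  g <- rows[seq(2, width * 3, 3), , drop = FALSE]
  r <- rows[seq(3, width * 3, 3), , drop = FALSE]
  ord <- if (top_down) seq_len(height) else rev(seq_len(height))
  px[, , 1] <- t(r)[ord, , drop = FALSE]
  px[, , 2] <- t(g)[ord, , drop = FALSE]
  px[, , 3] <- t(b)[ord, , drop = FALSE]
  px
}

write_bmp <- function(px, path) {
  px <- round_half_up(px)
  h <- dim(px)[1]; w <- dim(px)[2]
  stride <- ((w * 3 + 3) %/% 4) * 4
  img_size <- stride * h
  u16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(charToRaw("BM"), con)
  u32(54 + img_size); u32(0); u32(54)            # file size, reserved, offset
  u32(40); u32(w); u32(h); u16(1); u16(24)       # BITMAPINFOHEADER
  u32(0); u32(img_size); u32(2835); u32(2835); u32(0); u32(0)
  body <- matrix(as.raw(0), nrow = stride, ncol = h)
  ord <- rev(seq_len(h))                          # bottom-up
  body[seq(1, w * 3, 3), ] <- as.raw(t(px[ord, , 3]))
  body[seq(2, w * 3, 3), ] <- as.raw(t(px[ord, , 2]))
  body[seq(3, w * 3, 3), ] <- as.raw(t(px[ord, , 1]))
  writeBin(as.vector(body), con)
  invisible(path)
}

block_mean <- function(m, f) {
  r <- nrow(m); cl <- ncol(m)
  a <- matrix(colMeans(matrix(m, nrow = f)), nrow = r %/% f, ncol = cl)
  t(matrix(colMeans(matrix(t(a), nrow = f)), nrow = cl %/% f, ncol = r %/% f))
}

#' Reduce image resolution by block averaging
#'
#' Emulates optical resolution loss: each output pixel is the rounded mean of
#' its `factor` x `factor` source block, per channel. Factor 2 maps the native
#' 680 x 512 image to 340 columns x 256 rows; factor 4 to 170 x 128.
#'
#' @param image an [rgb_image] (or rows x cols x 3 array).
#' @param factor integer reduction factor, one of 1, 2, 4.
#' @return An [rgb_image] at the reduced size with the matching resolution tag.
#' @export
reduce_resolution <- function(image, factor) {
  if (!factor %in% c(1L, 2L, 4L)) stop("factor must be 1, 2 or 4")
  px <- as_pixel_array(image)
  d <- dim(px)
  if (d[1] %% factor != 0 || d[2] %% factor != 0)
    stop("dimension error: ", d[1], " x ", d[2], " not divisible by ", factor)
  tag <- unname(c("1" = "full", "2" = "half", "4" = "quarter")[as.character(factor)])
  if (factor == 1L) {
    out <- px
  } else {
    out <- array(0L, c(d[1] %/% factor, d[2] %/% factor, 3L))
    for (ch in 1:3) out[, , ch] <- round_half_up(block_mean(px[, , ch], factor))
  }
  meta <- if (inherits(image, "rgb_image")) image else
    list(source_id = NA_character_, label = NA_character_)
  rgb_image(out, source_id = meta$source_id, label = meta$label, resolution = tag)
}

#' Extract the four regions of interest of an image
#'
#' Trims a border margin ("avoiding boundaries") then splits the remaining
#' centered region on a 2 x 2 grid into four equal non-overlapping ROIs.
#' Odd leftover rows/columns are dropped from the far edge. Coordinates are
#' row-major with origin at the top-left.
#'
#' @param image an [rgb_image] or a 2-D/3-D pixel array.
#' @param margin fraction in \[0, 0.2\] trimmed from each border (default 0.05).
#' @return A list of 4 `roi` objects, position indices 0..3 scanning the grid
#'   row-wise.
#' @export
extract_rois <- function(image, margin = 0.05) {
  if (margin < 0 || margin > 0.2) stop("margin must be in [0, 0.2]")
  px <- as_pixel_array(image)
  d <- dim(px)
  mr <- floor(d[1] * margin); mc <- floor(d[2] * margin)
  h <- (d[1] - 2L * mr) %/% 2L
  w <- (d[2] - 2L * mc) %/% 2L
  if (h < 16L || w < 16L)
    stop("size error: image too small for four ROIs of at least 16 x 16")
  meta <- if (inherits(image, "rgb_image")) image else
    list(source_id = NA_character_, label = NA_character_)
  out <- vector("list", 4L)
  for (k in 0:3) {
    r0 <- mr + (k %/% 2L) * h
    c0 <- mc + (k %%  2L) * w
    sub <- if (length(d) == 3L) px[r0 + seq_len(h), c0 + seq_len(w), , drop = FALSE]
           else px[r0 + seq_len(h), c0 + seq_len(w), drop = FALSE]
    out[[k + 1L]] <- structure(
      list(pixels = sub, parent_id = meta$source_id, position = k,
           label = meta$label),
      class = "roi")
  }
  out
}

#' Write / read a feature or error table as CSV
#'
#' Plain CSV with a header row; feature column names are written exactly as
#' composed by the pooling step (e.g. `"G_Sum Variance"`).
#'
#' @param x data frame.
#' @param path CSV path.
#' @return `path` (write) or the data frame (read).
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}
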