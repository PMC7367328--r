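#' Read an RGB histology image
#'
#' Reads TIFF or PNG into the package's working representation: an
#' `H x W x 3` numeric array with 8-bit intensities in `[0, 255]`, origin at
#' the top-left, row-major.
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @return An RGB array.
#' @export
read_rgb_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    tif = ,
    tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    abort(sprintf("unsupported image format '.%s' (use TIFF or PNG)", ext))
  )
  if (length(dim(raw)) == 2) raw <- array(rep(raw, 3), dim = c(dim(raw), 3))
  if (dim(raw)[3] > 3) raw <- raw[, , 1:3, drop = FALSE]
  round(raw * 255)
}

#' Write an RGB image
#'
#' @param image RGB array (0..255).
#' @param path Output path ending in `.png`, `.tif`, or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_rgb_image <- function(image, path) {
  stopifnot_image(image)
  x <- clip(image) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = ,
    tiff = tiff::writeTIFF(x, path, bits.per.sample = 8),
    png = png::writePNG(x, path),
    abort(sprintf("unsupported image format '.%s' (use TIFF or PNG)", ext))
  )
  invisible(path)
}

#' Crop the centered 700-px tile grid from a capture
#'
#' Cuts a centered grid of up to `max_tiles` square tiles (at most 2 x 2) from
#' a larger capture, then drops tiles whose tissue fraction falls below
#' `min_tissue_fraction`; the single most tissue-rich tile is always retained.
#' A capture exactly `tile_size` on a side returns itself as the only tile.
#'
#' @param image RGB array at least `tile_size` in both dimensions.
#' @param tile_size Tile side length in pixels.
#' @param max_tiles Maximum number of tiles (capped at 4, i.e. a 2 x 2 grid).
#' @param min_tissue_fraction Minimum fraction of tissue pixels (per
#'   [tissue_mask()]) for a tile to be kept.
#' @param white_threshold Luminance threshold passed to [tissue_mask()].
#' @return A tibble with columns `tile` (list of RGB arrays), `offset_row`,
#'   `offset_col` (0-based offsets of each tile in the parent), and
#'   `tissue_fraction`.
#' @export
crop_center_tiles <- function(image, tile_size = 700, max_tiles = 4,
                              min_tissue_fraction = 0.05,
                              white_threshold = 220) {
  stopifnot_image(image)
  h <- dim(image)[1]; w <- dim(image)[2]
  if (h < tile_size || w < tile_size) {
    abort(sprintf("image (%d x %d) is smaller than tile_size (%d)", h, w, tile_size))
  }
  g_max <- if (max_tiles >= 4) 2L else 1L
  gr <- min(g_max, h %/% tile_size)
  gc <- min(g_max, w %/% tile_size)
  start_r <- (h - gr * tile_size) %/% 2
  start_c <- (w - gc * tile_size) %/% 2

  rows <- list()
  for (i in seq_len(gr)) {
    for (j in seq_len(gc)) {
      or <- start_r + (i - 1L) * tile_size
      oc <- start_c + (j - 1L) * tile_size
      tile <- image[(or + 1):(or + tile_size), (oc + 1):(oc + tile_size), , drop = FALSE]
      tf <- mean(tissue_mask(tile, white_threshold = white_threshold))
      rows[[length(rows) + 1]] <- tibble(
        tile = list(tile), offset_row = or, offset_col = oc, tissue_fraction = tf
      )
    }
  }
  out <- bind_rows(rows)
  keep <- out$tissue_fraction >= min_tissue_fraction
  if (!any(keep)) keep[which.max(out$tissue_fraction)] <- TRUE
  out[keep, ]
}

# Gaussian low-pass of a matrix via FFT with mirror padding (exact Gaussian
# transfer function, no boundary wrap artifacts).
fft_gaussian_smooth <- function(m, sigma) {
  h <- nrow(m); w <- ncol(m)
  mp <- rbind(cbind(m, m[, w:1]), cbind(m[h:1, ], m[h:1, w:1]))
  H <- nrow(mp); W <- ncol(mp)
  fu <- c(0:(H %/% 2), -((H - H %/% 2 - 1):1)) / H
  fv <- c(0:(W %/% 2), -((W - W %/% 2 - 1):1)) / W
  G <- exp(-2 * pi^2 * sigma^2 * outer(fu^2, fv^2, "+"))
  Re(fft(fft(mp) * G, inverse = TRUE))[1:h, 1:w] / (H * W)
}

# Low-frequency illumination field of one channel: estimated on a downsampled
# copy (the field is smooth by definition) and resampled back to full size.
estimate_illumination_field <- function(channel, sigma, factor = 10) {
  h <- nrow(channel); w <- ncol(channel)
  hs <- max(8L, h %/% factor); ws <- max(8L, w %/% factor)
  small <- EBImage::resize(channel, hs, ws)
  f <- max(1, h / hs)
  field <- fft_gaussian_smooth(small, sigma / f)
  as.matrix(EBImage::resize(field, h, w))
}

#' Flat-field illumination correction
#'
#' Evens out smooth illumination (gradients and the dark lower-right vignette
#' typical of the capture system) by estimating a per-channel low-frequency
#' field with an FFT-domain Gaussian low-pass and dividing the channel by it.
#' The result is rescaled to preserve each channel's global mean and clipped
#' to `[0, 255]`. A constant image is a fixed point.
#'
#' @param image RGB array.
#' @param sigma_frac Gaussian scale of the field estimate as a fraction of the
#'   image side.
#' @return Corrected RGB array (same dimensions, rounded 0..255).
#' @export
flatfield_correct <- function(image, sigma_frac = 1 / 16) {
  stopifnot_image(image)
  if (all(image == 0)) abort("cannot flat-field an all-zero image")
  n <- min(dim(image)[1:2])
  sigma <- sigma_frac * n
  out <- image
  for (ch in 1:3) {
    plane <- image[, , ch]
    field <- estimate_illumination_field(plane, sigma)
    field[field < 1e-6] <- 1e-6
    corrected <- plane / field
    m <- mean(corrected)
    if (m > 0) corrected <- corrected * mean(plane) / m
    out[, , ch] <- corrected
  }
  round(clip(out))
}

#' Tissue mask by white thresholding
#'
#' A pixel is non-tissue iff its rounded grayscale luminance
#' (`0.299 R + 0.587 G + 0.114 B`) is at least `white_threshold`; H&E
#' non-tissue (cracks, gaps, empty slide) is near-white. A morphological
#' closing (disk radius `closing_radius`) removes salt noise from the tissue
#' mask.
#'
#' @param image RGB array.
#' @param white_threshold Luminance threshold (default 220).
#' @param closing_radius Disk radius of the closing; `0` disables it.
#' @return Logical matrix, `TRUE` = tissue.
#' @export
tissue_mask <- function(image, white_threshold = 220, closing_radius = 2) {
  stopifnot_image(image)
  mask <- luminance(image) < white_threshold
  if (closing_radius > 0 && any(mask) && !all(mask)) {
    brush <- EBImage::makeBrush(2 * closing_radius + 1, "disc")
    mask <- EBImage::closing(mask, brush) > 0
  }
  mask
}
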