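#' Cytoplasm mask
#'
#' Cytoplasm (and stroma) is tissue that is not nucleus: the eosin-stained
#' compartment whose pinkness carries the third invasion pattern.
#'
#' @param tissue_mask,nucleus_mask Aligned logical masks.
#' @return Logical matrix, `TRUE` = cytoplasm.
#' @export
cytoplasm_mask <- function(tissue_mask, nucleus_mask) {
  stopifnot(identical(dim(tissue_mask), dim(nucleus_mask)))
  tissue_mask & !nucleus_mask
}

# per-pixel pinkness index in [-1, 1]: red excess over blue, normalized
pinkness_index <- function(image, mask) {
  (image[, , 1][mask] - image[, , 3][mask]) / 255
}

#' The 13 pinker-cytoplasm (eosin intensity) features
#'
#' Quantifies how pink the eosin-stained cytoplasm is through a per-pixel
#' pinkness index `p = (R - B) / 255` in `[-1, 1]`: an 8-bin histogram of
#' fractions over `[-1, 1]`, the mean and standard deviation of the index,
#' the red/blue mean intensity ratio, and the two background features
#' `cytoplasm_area_fraction` (of the tile) and `tissue_mean_gray`. Invasive
#' tumor cytoplasm takes up more eosin and shifts the index upward. An empty
#' cytoplasm mask yields zeros.
#'
#' @param image RGB tile.
#' @param cyto_mask Cytoplasm mask from [cytoplasm_mask()].
#' @param tissue_mask Tissue mask (for `tissue_mean_gray`); defaults to
#'   `cyto_mask` if missing.
#' @param bins Number of uniform histogram bins on `[-1, 1]`.
#' @return Named numeric vector of length `bins + 5` (13 at the default).
#' @export
eosin_features <- function(image, cyto_mask, tissue_mask = NULL, bins = 8) {
  stopifnot_image(image)
  if (is.null(tissue_mask)) tissue_mask <- cyto_mask
  p <- pinkness_index(image, cyto_mask)
  hist_frac <- fraction_hist(p, -1, 1, bins)
  names(hist_frac) <- paste0("pink_hist_bin_", pad2(seq_len(bins)))
  mean_b <- if (any(cyto_mask)) mean(image[, , 3][cyto_mask]) else 0
  mean_r <- if (any(cyto_mask)) mean(image[, , 1][cyto_mask]) else 0
  c(
    hist_frac,
    cytoplasm_mean_pinkness = if (length(p) > 0) mean(p) else 0,
    cytoplasm_sd_pinkness = if (length(p) > 1) sd(p) else 0,
    cytoplasm_red_blue_ratio = safe_div(mean_r, mean_b),
    cytoplasm_area_fraction = mean(cyto_mask),
    tissue_mean_gray = if (any(tissue_mask)) mean(luminance(image)[tissue_mask]) else 0
  )
}
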