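#' Segment hematoxylin-stained nuclei
#'
#' Selects hematoxylin-dominant pixels (`B > R + blue_margin` and luminance
#' below `lum_max`), applies a morphological opening (disk radius 1) to remove
#' speckle, labels 8-connected components, and discards debris below
#' `min_area` pixels. Touching-nucleus splitting by watershed is available but
#' off by default.
#'
#' @param image Preprocessed RGB tile.
#' @param blue_margin Required blue excess over red (default 15).
#' @param lum_max Maximum luminance of a nucleus pixel (default 180).
#' @param min_area Minimum component area in pixels (default 20).
#' @param watershed Logical; split touching nuclei by distance-map watershed.
#' @return List with `labels` (integer matrix, 0 = background) and
#'   `nucleus_mask` (logical matrix).
#' @export
segment_nuclei <- function(image, blue_margin = 15, lum_max = 180,
                           min_area = 20, watershed = FALSE) {
  stopifnot_image(image)
  mask <- (image[, , 3] > image[, , 1] + blue_margin) & (luminance(image) < lum_max)
  if (any(mask)) {
    cross <- matrix(c(0, 1, 0, 1, 1, 1, 0, 1, 0), 3, 3) # true radius-1 disk
    mask <- EBImage::opening(mask, cross) > 0
  }
  if (watershed && any(mask)) {
    labels <- EBImage::watershed(EBImage::distmap(mask))
    labels <- matrix(as.integer(labels), nrow(mask), ncol(mask))
  } else {
    labels <- label8(mask)
  }
  if (max(labels) > 0 && min_area > 0) {
    areas <- tabulate(labels[labels > 0], max(labels))
    drop <- which(areas < min_area)
    if (length(drop) > 0) {
      labels[labels %in% drop] <- 0L
      if (max(labels) > 0) {
        keep_ids <- sort(unique(labels[labels > 0]))
        remap <- integer(max(keep_ids))
        remap[keep_ids] <- seq_along(keep_ids)
        labels[labels > 0] <- remap[labels[labels > 0]]
      }
    }
  }
  list(labels = labels, nucleus_mask = labels > 0)
}

#' Per-nucleus morphometry
#'
#' One record per labeled nucleus: shape measured on the pixel set (area,
#' exposed-edge perimeter, equivalent diameter, ellipse axes from second
#' moments, eccentricity, orientation, convex-hull solidity, extent, form
#' factor, compactness), per-channel intensity statistics on the original
#' image, and neighborhood measures (nearest-neighbor centroid distance and
#' neighbor count within `neighbor_radius` pixels).
#'
#' @param labels Label matrix from [segment_nuclei()].
#' @param image RGB tile the labels were segmented from.
#' @param neighbor_radius Radius in pixels for the neighbor count.
#' @return A tibble with one row per nucleus.
#' @export
measure_nuclei <- function(labels, image, neighbor_radius = 50) {
  props <- region_props(labels, image)
  if (nrow(props) == 0) return(props)
  if (nrow(props) == 1) {
    props$nn_dist <- 0
    props$neighbor_count <- 0
    return(props)
  }
  d <- as.matrix(dist(cbind(props$centroid_row, props$centroid_col)))
  diag(d) <- Inf
  props$nn_dist <- unname(apply(d, 1, min))
  props$neighbor_count <- unname(rowSums(d <= neighbor_radius))
  props
}

# shared background features used by more than one pattern block; computed
# once per tile from the same masks so every block reports identical values
shared_background_values <- function(image, tissue, nucleus_mask) {
  cyto <- cytoplasm_mask(tissue, nucleus_mask)
  eosin_features(image, cyto, tissue)[c(
    "cytoplasm_mean_pinkness", "cytoplasm_sd_pinkness",
    "cytoplasm_red_blue_ratio", "cytoplasm_area_fraction", "tissue_mean_gray"
  )]
}

#' The 675 desmoplastic-reaction features
#'
#' The largest pattern block: aggregated nucleus morphometry (each shape,
#' intensity and neighborhood measure summarized by mean, median, sd, MAD,
#' min, max and the two quartiles), image-level nucleus counts, densities and
#' a 16-bin nucleus-area histogram, stromal gray-level co-occurrence texture
#' at 3 offsets x 4 angles, stromal per-channel intensity histograms,
#' connective-tissue (stroma) object shape aggregates, a 16-radius granularity
#' spectrum of the nucleus mask, and global background/intensity summaries.
#' The block always has exactly 675 values in manifest order; images with no
#' nuclei emit zeros for all aggregates.
#'
#' @param records Tibble from [measure_nuclei()] (possibly empty).
#' @param image RGB tile.
#' @param tissue_mask Tissue mask.
#' @param nucleus_mask Nucleus mask.
#' @return Named numeric vector of length 675.
#' @export
desmo_features <- function(records, image, tissue_mask, nucleus_mask) {
  stopifnot_image(image)
  gray <- luminance(image)
  tissue_px <- sum(tissue_mask)
  stroma <- cytoplasm_mask(tissue_mask, nucleus_mask)

  # (a) nucleus shape aggregates: 14 x 8
  shape_block <- unlist(lapply(shape_measures, function(m) {
    agg8(if (nrow(records) > 0) records[[m]] else numeric(0), paste0("nuc_", m))
  }))
  # (b) nucleus intensity aggregates: 15 x 8
  int_block <- unlist(lapply(intensity_measures, function(m) {
    agg8(if (nrow(records) > 0) records[[m]] else numeric(0), paste0("nuc_int_", m))
  }))
  # (c) neighborhood aggregates: 2 x 8
  nb_block <- unlist(lapply(c("nn_dist", "neighbor_count"), function(m) {
    agg8(if (nrow(records) > 0) records[[m]] else numeric(0), paste0("nuc_", m))
  }))
  # (d) image-level counts, densities, 16-bin area histogram
  n_nuc <- nrow(records)
  area_hist <- fraction_hist(if (n_nuc > 0) records$area else numeric(0), 0, 1600, 16)
  names(area_hist) <- paste0("nuc_area_hist_bin_", pad2(1:16))
  count_block <- c(
    nucleus_count = n_nuc,
    nucleus_density = safe_div(n_nuc, tissue_px),
    nucleus_area_fraction = safe_div(sum(nucleus_mask), tissue_px),
    area_hist
  )
  # (e) stromal co-occurrence texture: 13 stats x 4 angles x 3 offsets
  q <- pmin(floor(gray / 32) + 1, 8)
  storage.mode(q) <- "integer"
  angle_shift <- list(`0` = c(0L, 1L), `45` = c(-1L, 1L),
                      `90` = c(1L, 0L), `135` = c(1L, 1L))
  glcm_block <- unlist(lapply(glcm_offsets, function(d) {
    unlist(lapply(glcm_angles, function(a) {
      sh <- angle_shift[[as.character(a)]] * d
      st <- glcm_stats(q, stroma, sh[1], sh[2])
      setNames(st, paste0("stroma_glcm_d", d, "_a", a, "_", names(st)))
    }))
  }))
  # (f) stromal intensity histograms: 3 channels x 32 bins
  hist_block <- unlist(lapply(seq_len(3), function(ch) {
    v <- image[, , ch][stroma]
    hb <- fraction_hist(v, 0, 256, 32)
    setNames(hb, paste0("stroma_hist_", c("red", "green", "blue")[ch],
                        "_bin_", pad2(1:32)))
  }))
  # (g) connective-tissue object shape aggregates: 14 x 8
  stroma_labels <- label8(stroma)
  stroma_props <- region_props(stroma_labels)
  stroma_block <- unlist(lapply(shape_measures, function(m) {
    agg8(if (nrow(stroma_props) > 0) stroma_props[[m]] else numeric(0),
         paste0("stroma_obj_", m))
  }))
  # (h) granularity spectrum: fraction of nucleus pixels deeper than radius r
  fg <- sum(nucleus_mask)
  if (fg > 0) {
    dm <- EBImage::distmap(nucleus_mask)
    gran <- vapply(1:16, function(r) sum(dm > r) / fg, numeric(1))
  } else {
    gran <- rep(0, 16)
  }
  names(gran) <- paste0("nuc_granularity_", pad2(1:16))
  # (i) auxiliary background / intensity summaries (incl. the 7 shared)
  ch_stats <- function(mask, prefix) {
    if (sum(mask) == 0) {
      return(setNames(rep(0, 6), paste0(prefix, c("mean_red", "mean_green",
        "mean_blue", "sd_red", "sd_green", "sd_blue"))))
    }
    v <- lapply(1:3, function(ch) image[, , ch][mask])
    setNames(
      c(vapply(v, mean, numeric(1)),
        vapply(v, function(x) if (length(x) > 1) sd(x) else 0, numeric(1))),
      paste0(prefix, c("mean_red", "mean_green", "mean_blue",
                       "sd_red", "sd_green", "sd_blue"))
    )
  }
  all_mask <- matrix(TRUE, nrow(gray), ncol(gray))
  tg <- gray[tissue_mask]
  sg <- gray[stroma]
  shared <- shared_background_values(image, tissue_mask, nucleus_mask)
  aux <- c(
    ch_stats(tissue_mask, "tissue_"),
    ch_stats(all_mask, "image_"),
    tissue_sd_gray = if (length(tg) > 1) sd(tg) else 0,
    tissue_gray_q1 = if (length(tg) > 0) quantile(tg, 0.25, names = FALSE) else 0,
    tissue_gray_median = if (length(tg) > 0) median(tg) else 0,
    tissue_gray_q3 = if (length(tg) > 0) quantile(tg, 0.75, names = FALSE) else 0,
    stroma_mean_gray = if (length(sg) > 0) mean(sg) else 0,
    stroma_sd_gray = if (length(sg) > 1) sd(sg) else 0,
    stroma_area_fraction = mean(stroma),
    image_gray_mean = mean(gray),
    image_gray_sd = sd(as.vector(gray)),
    sample_ratio = tissue_px / length(gray),
    nontissue_fraction = 1 - tissue_px / length(gray),
    shared
  )

  out <- c(shape_block, int_block, nb_block, count_block, glcm_block,
           hist_block, stroma_block, gran, aux)
  expected <- feature_names("desmoplastic")
  out[expected]
}
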