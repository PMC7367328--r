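# classify 8-connected non-tissue components by region "diameter": regions
# with diameter strictly greater than the threshold are inter-tissue space,
# the rest are peri-cellular cracks. Diameter is the equivalent circular
# diameter 2*sqrt(area/pi) by default, or the maximum Feret diameter of the
# pixel corners.
classify_nontissue <- function(nontissue_mask, diameter_threshold = 40,
                               diameter_method = c("equivalent", "feret")) {
  diameter_method <- match.arg(diameter_method)
  labels <- label8(nontissue_mask)
  k <- max(labels)
  crack <- matrix(FALSE, nrow(nontissue_mask), ncol(nontissue_mask))
  inter <- crack
  if (k == 0) {
    return(list(crack_mask = crack, intertissue_mask = inter, labels = labels,
                diameters = numeric(0)))
  }
  idx <- which(labels > 0)
  lab_vec <- labels[idx]
  areas <- tabulate(lab_vec, k)
  if (diameter_method == "equivalent") {
    diameters <- 2 * sqrt(areas / pi)
  } else {
    h <- nrow(labels)
    rows <- ((idx - 1) %% h) + 1
    cols <- ((idx - 1) %/% h) + 1
    by_label <- split(seq_along(idx), lab_vec)
    diameters <- vapply(by_label, function(sel) {
      feret_diameter(rows[sel], cols[sel])
    }, numeric(1))
  }
  is_inter <- diameters > diameter_threshold # strict "more than"
  inter[idx] <- is_inter[lab_vec]
  crack[idx] <- !is_inter[lab_vec]
  list(crack_mask = crack, intertissue_mask = inter, labels = labels,
       diameters = diameters)
}

# maximum Feret diameter: largest pairwise distance between convex-hull
# vertices of the pixel corners
feret_diameter <- function(rows, cols) {
  pts_r <- c(rows - 0.5, rows - 0.5, rows + 0.5, rows + 0.5)
  pts_c <- c(cols - 0.5, cols + 0.5, cols - 0.5, cols + 0.5)
  hull <- grDevices::chull(pts_c, pts_r)
  hr <- pts_r[hull]; hc <- pts_c[hull]
  max(dist(cbind(hr, hc)))
}

#' Segment retraction cracks from inter-tissue space
#'
#' Implements the crack-extraction flow: the tile is binarized to a monochrome
#' image with all non-tissue near-white pixels set on, non-tissue connected
#' components (8-connectivity) are sized, components with diameter strictly
#' greater than `diameter_threshold` pixels are masked out as inter-tissue
#' space, and the remainder — the thin clefts around tumor-cell nests — are
#' returned as the crack mask. No morphological closing is applied before
#' labeling: the closing used by [tissue_mask()] would fill exactly the
#' 1–5 px cracks being measured.
#'
#' @param image Preprocessed RGB tile.
#' @param diameter_threshold Diameter cutoff in pixels (strict `>`).
#' @param diameter_method `"equivalent"` (equivalent circular diameter,
#'   default) or `"feret"` (maximum Feret diameter).
#' @param white_threshold Luminance threshold separating non-tissue white.
#' @return List with disjoint logical masks `crack_mask` and
#'   `intertissue_mask` whose union is the non-tissue mask, plus the component
#'   `labels` and per-component `diameters`.
#' @export
segment_cracks <- function(image, diameter_threshold = 40,
                           diameter_method = c("equivalent", "feret"),
                           white_threshold = 220) {
  stopifnot_image(image)
  nontissue <- !tissue_mask(image, white_threshold = white_threshold,
                            closing_radius = 0)
  classify_nontissue(nontissue, diameter_threshold, diameter_method)
}

#' The 15 retraction-artifact features
#'
#' Summarizes the crack segmentation into the fixed 15-feature block of the
#' retraction pattern group, including the two background features
#' `sample_ratio` (tissue pixels / total pixels) and `nontissue_fraction`.
#' An empty crack mask yields zeros for all crack statistics; an empty tissue
#' mask defines the per-tissue-area densities as 0 (with a warning).
#'
#' @param crack_mask,intertissue_mask Disjoint masks from [segment_cracks()].
#' @param tissue_mask Logical tissue mask (from [tissue_mask()]).
#' @return Named numeric vector of length 15 in manifest order.
#' @export
crack_features <- function(crack_mask, intertissue_mask, tissue_mask) {
  npx <- length(crack_mask)
  tissue_px <- sum(tissue_mask)
  nontissue_px <- sum(crack_mask) + sum(intertissue_mask)
  crack_px <- sum(crack_mask)
  if (tissue_px == 0) {
    warn("empty tissue mask: per-tissue-area crack densities are defined as 0")
  }

  if (crack_px > 0) {
    labels <- label8(crack_mask)
    props <- region_props(labels)
    areas <- props$area
    total_perim <- sum(props$perimeter)
    mean_elong <- mean(props$aspect_ratio)
    n_comp <- nrow(props)
  } else {
    areas <- numeric(0); total_perim <- 0; mean_elong <- 0; n_comp <- 0
  }

  c(
    crack_pixel_count = crack_px,
    crack_fraction_of_image = crack_px / npx,
    crack_fraction_of_nontissue = safe_div(crack_px, nontissue_px),
    crack_component_count = n_comp,
    crack_area_mean = if (n_comp > 0) mean(areas) else 0,
    crack_area_median = if (n_comp > 0) median(areas) else 0,
    crack_area_sd = if (n_comp > 1) sd(areas) else 0,
    crack_area_max = if (n_comp > 0) max(areas) else 0,
    crack_total_perimeter = total_perim,
    crack_edge_density = safe_div(total_perim, tissue_px),
    crack_mean_elongation = mean_elong,
    crack_count_per_tissue_area = safe_div(n_comp, tissue_px),
    crack_mean_width = safe_div(crack_px, total_perim / 2),
    sample_ratio = tissue_px / npx,
    nontissue_fraction = 1 - tissue_px / npx
  )
}
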