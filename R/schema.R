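#' The fixed raw feature schema
#'
#' The extraction pipeline always produces the same 740 raw columns per image:
#' 696 numeric pattern features plus 44 metadata/invalid columns (timestamps,
#' indices, descriptive strings, and measurements that are undefined on empty
#' masks). Each numeric feature is tagged with the histological pattern
#' group(s) it describes: `desmoplastic` (675 features), `cytoplasm` (13), and
#' `retraction` (15). Seven global "background" features belong to two groups
#' at once, so group memberships sum to 703 over 696 unique features.
#'
#' @return A tibble with one row per raw column: `name`, `kind` (one of
#'   `numeric_feature`, `time_metadata`, `index_metadata`, `descriptive_string`,
#'   `na_prone`), logical group flags `desmoplastic`, `cytoplasm`,
#'   `retraction`, and `block` (which extractor emits the column).
#' @examples
#' sch <- feature_schema()
#' sum(sch$kind == "numeric_feature") # 696
#' colSums(sch[, c("desmoplastic", "cytoplasm", "retraction")])
#' @export
feature_schema <- function() {
  if (is.null(schema_env$schema)) schema_env$schema <- build_schema()
  schema_env$schema
}

schema_env <- new.env(parent = emptyenv())

shape_measures <- c(
  "area", "perimeter", "equiv_diameter", "major_axis", "minor_axis",
  "aspect_ratio", "eccentricity", "orientation", "solidity", "extent",
  "form_factor", "compactness", "convex_area", "bbox_area"
)

intensity_measures <- as.vector(outer(
  c("red", "green", "blue"), c("mean", "sd", "min", "max", "median"),
  function(ch, m) paste0(ch, "_", m)
))

glcm_stat_names <- c(
  "contrast", "dissimilarity", "homogeneity", "asm", "energy", "entropy",
  "correlation", "variance", "sum_average", "sum_variance", "sum_entropy",
  "diff_variance", "diff_entropy"
)
glcm_offsets <- c(1L, 2L, 4L)
glcm_angles <- c(0L, 45L, 90L, 135L)

pad2 <- function(i) sprintf("%02d", i)

retraction_feature_names <- function() {
  c(
    "crack_pixel_count", "crack_fraction_of_image", "crack_fraction_of_nontissue",
    "crack_component_count", "crack_area_mean", "crack_area_median",
    "crack_area_sd", "crack_area_max", "crack_total_perimeter",
    "crack_edge_density", "crack_mean_elongation", "crack_count_per_tissue_area",
    "crack_mean_width", "sample_ratio", "nontissue_fraction"
  )
}

cytoplasm_feature_names <- function() {
  c(
    paste0("pink_hist_bin_", pad2(1:8)),
    "cytoplasm_mean_pinkness", "cytoplasm_sd_pinkness",
    "cytoplasm_red_blue_ratio", "cytoplasm_area_fraction", "tissue_mean_gray"
  )
}

# the 7 background features that belong to two pattern groups each
shared_background_names <- function() {
  c(
    "sample_ratio", "nontissue_fraction",                      # retraction + desmoplastic
    "cytoplasm_mean_pinkness", "cytoplasm_sd_pinkness",        # cytoplasm + desmoplastic
    "cytoplasm_red_blue_ratio", "cytoplasm_area_fraction",
    "tissue_mean_gray"
  )
}

desmo_exclusive_names <- function() {
  cross <- function(measures, prefix) {
    as.vector(t(outer(measures, agg8_suffixes, function(m, s) paste0(prefix, m, "_", s))))
  }
  c(
    cross(shape_measures, "nuc_"),                              # 14 x 8 = 112
    cross(intensity_measures, "nuc_int_"),                      # 15 x 8 = 120
    cross(c("nn_dist", "neighbor_count"), "nuc_"),              #  2 x 8 =  16
    "nucleus_count", "nucleus_density", "nucleus_area_fraction",
    paste0("nuc_area_hist_bin_", pad2(1:16)),                   # 3 + 16 =  19
    as.vector(sapply(glcm_offsets, function(d) {
      as.vector(sapply(glcm_angles, function(a) {
        paste0("stroma_glcm_d", d, "_a", a, "_", glcm_stat_names)
      }))
    })),                                                        # 13 x 4 x 3 = 156
    as.vector(sapply(c("red", "green", "blue"), function(ch) {
      paste0("stroma_hist_", ch, "_bin_", pad2(1:32))
    })),                                                        # 3 x 32 = 96
    cross(shape_measures, "stroma_obj_"),                       # 14 x 8 = 112
    paste0("nuc_granularity_", pad2(1:16)),                     # 16
    paste0("tissue_mean_", c("red", "green", "blue")),
    paste0("tissue_sd_", c("red", "green", "blue")),
    paste0("image_mean_", c("red", "green", "blue")),
    paste0("image_sd_", c("red", "green", "blue")),
    "tissue_sd_gray", "tissue_gray_q1", "tissue_gray_median", "tissue_gray_q3",
    "stroma_mean_gray", "stroma_sd_gray", "stroma_area_fraction",
    "image_gray_mean", "image_gray_sd"                          # 21 auxiliary
  )
}

metadata_schema <- function() {
  tibble(
    name = c(
      paste0("meta_", c("acquisition_time", "processing_time", "export_time",
                        "elapsed_seconds")),
      paste0("meta_", c("image_index", "tile_row", "tile_col", "tile_index",
                        "parent_index", "batch_index")),
      paste0("meta_", c(
        "pipeline_name", "stain_label", "scanner_label", "magnification_label",
        "file_format", "operator_initials", "software_version", "channel_names",
        "tissue_site", "fixation_label", "section_label", "block_label",
        "protocol_label", "objective_label", "camera_label", "export_format",
        "colorspace_label", "compression_label", "lot_label", "notes"
      )),
      paste0("naprone_", c(
        "gap_mean_gray", "gap_sd_gray", "gap_mean_red", "gap_mean_blue",
        "crack_mean_gray", "crack_sd_gray", "crack_mean_red", "crack_mean_blue",
        "largest_gap_solidity", "largest_gap_extent", "largest_crack_orientation",
        "nucleus_gray_skew", "stroma_gray_skew", "second_nucleus_area"
      ))
    ),
    kind = c(
      rep("time_metadata", 4), rep("index_metadata", 6),
      rep("descriptive_string", 20), rep("na_prone", 14)
    )
  )
}

build_schema <- function() {
  retr <- retraction_feature_names()
  cyto <- cytoplasm_feature_names()
  desmo_only <- desmo_exclusive_names()
  shared <- shared_background_names()
  meta <- metadata_schema()

  stopifnot(
    length(retr) == 15, length(cyto) == 13, length(desmo_only) == 668,
    nrow(meta) == 44, !anyDuplicated(c(retr, cyto, desmo_only, meta$name))
  )

  numeric <- tibble(
    name = c(retr, cyto, desmo_only),
    kind = "numeric_feature",
    block = c(rep("retraction", 15), rep("cytoplasm", 13), rep("desmoplastic", 668))
  )
  numeric$retraction <- numeric$name %in% retr
  numeric$cytoplasm <- numeric$name %in% cyto
  numeric$desmoplastic <- numeric$block == "desmoplastic" | numeric$name %in% shared

  meta$block <- "metadata"
  meta$retraction <- FALSE
  meta$cytoplasm <- FALSE
  meta$desmoplastic <- FALSE

  out <- bind_rows(meta, numeric)
  out$index <- seq_len(nrow(out))
  out[, c("index", "name", "kind", "block", "desmoplastic", "cytoplasm", "retraction")]
}

#' Names of the numeric analysis features
#'
#' @param group Optional pattern group, one of `"desmoplastic"`, `"cytoplasm"`,
#'   `"retraction"`; `NULL` returns all 696 numeric feature names in manifest
#'   order.
#' @return Character vector of feature names.
#' @export
feature_names <- function(group = NULL) {
  sch <- feature_schema()
  sch <- sch[sch$kind == "numeric_feature", ]
  if (!is.null(group)) {
    group <- match.arg(group, c("desmoplastic", "cytoplasm", "retraction"))
    sch <- sch[sch[[group]], ]
  }
  sch$name
}

#' Write the feature manifest to CSV
#'
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_manifest <- function(path) {
  readr::write_csv(feature_schema(), path)
  invisible(path)
}
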