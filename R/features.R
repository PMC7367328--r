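#' Merge pattern blocks and metadata into one raw feature row
#'
#' Assembles the three pattern blocks (retraction 15, cytoplasm 13,
#' desmoplastic 675) and the 44 metadata columns into a single 740-column row
#' in manifest order. Background features shared between groups are written
#' once, taken from the block that owns their computation; block arrival order
#' never affects the result. Any missing or surplus value in a block raises a
#' schema error naming the block.
#'
#' @param retraction Named numeric vector of the 15 retraction features.
#' @param cytoplasm Named numeric vector of the 13 cytoplasm features.
#' @param desmoplastic Named numeric vector of the 675 desmoplastic features.
#' @param metadata Named list of the 44 metadata values (see
#'   [default_metadata()]).
#' @return A one-row tibble with 740 columns.
#' @export
merge_blocks <- function(retraction, cytoplasm, desmoplastic,
                         metadata = default_metadata()) {
  sch <- feature_schema()
  check_block <- function(values, block_name, expected) {
    missing <- setdiff(expected, names(values))
    extra <- setdiff(names(values), expected)
    if (length(missing) > 0 || length(extra) > 0) {
      abort(sprintf(
        "block '%s' does not conform to the schema (missing: %s; unexpected: %s)",
        block_name,
        if (length(missing)) paste(head(missing, 3), collapse = ", ") else "none",
        if (length(extra)) paste(head(extra, 3), collapse = ", ") else "none"
      ))
    }
  }
  check_block(retraction, "retraction", retraction_feature_names())
  check_block(cytoplasm, "cytoplasm", cytoplasm_feature_names())
  check_block(desmoplastic, "desmoplastic", feature_names("desmoplastic"))
  check_block(metadata, "metadata", metadata_schema()$name)

  owner <- list(retraction = retraction, cytoplasm = cytoplasm,
                desmoplastic = desmoplastic)
  row <- vector("list", nrow(sch))
  names(row) <- sch$name
  for (i in seq_len(nrow(sch))) {
    nm <- sch$name[i]
    if (sch$kind[i] != "numeric_feature") {
      row[[i]] <- metadata[[nm]]
    } else {
      row[[i]] <- unname(owner[[sch$block[i]]][[nm]])
    }
  }
  as_tibble(row)
}

#' Default metadata column values
#'
#' The 44 raw columns that the cleaning step removes: acquisition/processing
#' timestamps, image and tile indices, descriptive-string columns recording
#' the processing pipeline, and numeric measurements that are undefined (`NA`)
#' on empty masks.
#'
#' @param image_index,tile_row,tile_col Indices recorded for the tile.
#' @param na_prone Named numeric vector overriding any of the 14 `naprone_*`
#'   measurements (others stay `NA`).
#' @return Named list of 44 values.
#' @export
default_metadata <- function(image_index = 1, tile_row = 0, tile_col = 0,
                             na_prone = NULL) {
  meta <- metadata_schema()
  out <- vector("list", nrow(meta))
  names(out) <- meta$name
  now <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  for (i in seq_len(nrow(meta))) {
    out[[i]] <- switch(meta$kind[i],
      time_metadata = if (meta$name[i] == "meta_elapsed_seconds") 0 else now,
      index_metadata = 0,
      descriptive_string = "hestage",
      na_prone = NA_real_
    )
  }
  out$meta_image_index <- image_index
  out$meta_tile_row <- tile_row
  out$meta_tile_col <- tile_col
  if (!is.null(na_prone)) {
    for (nm in names(na_prone)) {
      if (nm %in% names(out)) out[[nm]] <- na_prone[[nm]]
    }
  }
  out
}

#' Extract the full 740-column raw feature row from one tile
#'
#' Runs all three pattern extractors on a preprocessed tile and merges their
#' blocks with metadata. This is the per-image unit of the pipeline: tissue
#' masking, crack segmentation and the 15 retraction features, nucleus
#' segmentation/morphometry and the 675 desmoplastic features, and the 13
#' eosin/pinkness features.
#'
#' @param image RGB tile (ideally flat-field corrected; see
#'   [flatfield_correct()]).
#' @param config A [stage_config()] list of extraction tunables.
#' @param image_index Index recorded in the metadata columns.
#' @return A one-row tibble with 740 columns.
#' @export
extract_features <- function(image, config = stage_config(), image_index = 1) {
  stopifnot_image(image)
  tissue <- tissue_mask(image, white_threshold = config$white_threshold,
                        closing_radius = config$closing_radius)
  seg <- segment_cracks(image, diameter_threshold = config$diameter_threshold,
                        diameter_method = config$diameter_method,
                        white_threshold = config$white_threshold)
  retr <- crack_features(seg$crack_mask, seg$intertissue_mask, tissue)

  nuc <- segment_nuclei(image, blue_margin = config$blue_margin,
                        lum_max = config$nucleus_lum_max,
                        min_area = config$min_nucleus_area,
                        watershed = config$watershed)
  records <- measure_nuclei(nuc$labels, image,
                            neighbor_radius = config$neighbor_radius)
  desmo <- desmo_features(records, image, tissue, nuc$nucleus_mask)

  cyto_mask <- cytoplasm_mask(tissue, nuc$nucleus_mask)
  cyto <- eosin_features(image, cyto_mask, tissue, bins = config$pink_bins)

  gray <- luminance(image)
  na_stat <- function(mask, values) if (sum(mask) == 0) NA_real_ else mean(values[mask])
  na_prone <- c(
    naprone_gap_mean_gray = na_stat(seg$intertissue_mask, gray),
    naprone_gap_sd_gray = if (sum(seg$intertissue_mask) > 1) sd(gray[seg$intertissue_mask]) else NA_real_,
    naprone_gap_mean_red = na_stat(seg$intertissue_mask, image[, , 1]),
    naprone_gap_mean_blue = na_stat(seg$intertissue_mask, image[, , 3]),
    naprone_crack_mean_gray = na_stat(seg$crack_mask, gray),
    naprone_crack_sd_gray = if (sum(seg$crack_mask) > 1) sd(gray[seg$crack_mask]) else NA_real_,
    naprone_crack_mean_red = na_stat(seg$crack_mask, image[, , 1]),
    naprone_crack_mean_blue = na_stat(seg$crack_mask, image[, , 3]),
    naprone_second_nucleus_area = if (nrow(records) >= 2) sort(records$area, decreasing = TRUE)[2] else NA_real_
  )
  merge_blocks(retr, cyto, desmo,
               default_metadata(image_index = image_index, na_prone = na_prone))
}

#' Extract the labeled feature table from a phantom dataset
#'
#' Streams a [generate_dataset()] manifest image by image: each phantom is
#' rasterized, flat-field corrected, run through all three extractors, and
#' reduced to its 740-column raw row; images are discarded immediately so
#' memory stays flat.
#'
#' @param dataset A [generate_dataset()] manifest (or a list of RGB arrays
#'   plus a `labels` vector).
#' @param config A [stage_config()].
#' @param flatfield Logical; apply [flatfield_correct()] before extraction.
#' @param progress Logical; report progress via `message()`.
#' @return A tibble: `image_id`, `stage`, then the 740 raw columns.
#' @export
extract_feature_table <- function(dataset, config = stage_config(),
                                  flatfield = TRUE, progress = FALSE) {
  n <- nrow(dataset)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ph <- phantom_for_row(dataset, i)
    img <- ph$image
    if (flatfield) img <- flatfield_correct(img, config$flatfield_sigma_frac)
    rows[[i]] <- bind_cols(
      tibble(image_id = dataset$image_id[i], stage = dataset$stage[i]),
      extract_features(img, config, image_index = i)
    )
    if (progress && i %% 10 == 0) message(sprintf("extracted %d / %d images", i, n))
  }
  bind_rows(rows)
}

#' Clean a raw feature table to the 696 analysis features
#'
#' Drops the 44 metadata/invalid columns (timestamps, indices, descriptive
#' strings, and NA-prone measurements) plus any numeric feature column that
#' contains a missing value in any row. On tables whose numeric features are
#' complete this leaves exactly 696 feature columns. Idempotent. Identifier
#' and label columns (`image_id`, `stage`) are kept if present.
#'
#' @param raw_table A tibble from [extract_feature_table()] (or already
#'   cleaned).
#' @return The cleaned tibble.
#' @export
clean_features <- function(raw_table) {
  sch <- feature_schema()
  drop_meta <- intersect(sch$name[sch$kind != "numeric_feature"], names(raw_table))
  out <- raw_table[, setdiff(names(raw_table), drop_meta)]
  feat_cols <- intersect(feature_names(), names(out))
  has_na <- vapply(out[feat_cols], anyNA, logical(1))
  out[, setdiff(names(out), feat_cols[has_na])]
}

#' Subset a feature table to one pattern group
#'
#' @param table A cleaned feature table.
#' @param group `"desmoplastic"`, `"cytoplasm"`, or `"retraction"`.
#' @return The table restricted to that group's features (manifest order),
#'   keeping `image_id`/`stage` if present.
#' @export
subset_by_group <- function(table, group) {
  group <- match.arg(group, c("desmoplastic", "cytoplasm", "retraction"))
  keep <- intersect(feature_names(group), names(table))
  id_cols <- intersect(c("image_id", "stage"), names(table))
  table[, c(id_cols, keep)]
}

#' Read/write feature tables as CSV
#'
#' Values are serialized at full precision; missing values are written as the
#' literal token `NA`. A write-then-read round trip reproduces the table.
#'
#' @param table Feature table.
#' @param path CSV path.
#' @return `write_feature_table()`: `path` invisibly;
#'   `read_feature_table()`: the tibble.
#' @export
write_feature_table <- function(table, path) {
  readr::write_csv(table, path, na = "NA")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, na = "NA")
}
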