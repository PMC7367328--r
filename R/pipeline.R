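#' Pipeline configuration
#'
#' One flat list of every tunable in the pipeline, with validation; unknown
#' keys are rejected. Defaults follow the staging protocol: 700-px tiles (at
#' most 4 per capture), 40-px inter-tissue diameter threshold, 20 forests of
#' 40 trees for ranking, top-100 feature selection, 70/30 splits repeated 20
#' times at decision threshold 0.5 with class balancing, and k-means over
#' k = 2..9.
#'
#' @param ... Overrides of the defaults listed below.
#' @return A validated `stage_config` list.
#' @export
stage_config <- function(...) {
  defaults <- list(
    tile_size = 700L,
    max_tiles = 4L,
    min_tissue_fraction = 0.05,
    white_threshold = 220,
    closing_radius = 2L,
    flatfield_sigma_frac = 1 / 16,
    diameter_threshold = 40,
    diameter_method = "equivalent",
    blue_margin = 15,
    nucleus_lum_max = 180,
    min_nucleus_area = 20L,
    watershed = FALSE,
    neighbor_radius = 50,
    pink_bins = 8L,
    n_forests = 20L,
    n_trees = 40L,
    top_k = 100L,
    train_fraction = 0.7,
    repeats = 20L,
    threshold = 0.5,
    balance = TRUE,
    k_min = 2L,
    k_max = 9L,
    kmeans_restarts = 10L,
    models = c("PNN", "RF"),
    n_ta = 40L,
    n_t1 = 40L,
    seed = 1L
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, overrides)
  if (cfg$train_fraction <= 0 || cfg$train_fraction >= 1) {
    abort("train_fraction must lie strictly in (0, 1)")
  }
  if (cfg$k_min < 2 || cfg$k_max < cfg$k_min) abort("need 2 <= k_min <= k_max")
  if (!all(cfg$models %in% classifier_names())) {
    abort("models must be a subset of classifier_names()")
  }
  if (cfg$diameter_threshold <= 0) abort("diameter_threshold must be positive")
  structure(cfg, class = "stage_config")
}

#' Read/write a pipeline configuration as YAML
#'
#' The configuration round-trips losslessly through its file form.
#'
#' @param config A [stage_config()].
#' @param path YAML file path.
#' @return `write_config()`: `path` invisibly; `read_config()`: the config.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(stage_config, vals)
}

#' Run the full staging pipeline on synthetic data
#'
#' simulate -> preprocess -> extract -> merge/clean -> rank -> train +
#' cluster, writing every stage's CSV plus a run manifest (config, seeds,
#' session info) into `out_dir`. Rerunning with the same config reproduces
#' all outputs.
#'
#' @param config A [stage_config()].
#' @param out_dir Output directory (created if needed).
#' @param ta_spec,t1_spec Phantom specs for the two stages.
#' @param progress Logical; log stage timings to stderr.
#' @return A list with the cleaned `table`, `ranking`, `evals` (one
#'   `stage_eval` per model), `pca`, `clusters` (with information gain per
#'   k), and `out_dir`, invisibly.
#' @export
run_pipeline <- function(config = stage_config(), out_dir = tempfile("hestage_run_"),
                         ta_spec = hestage::ta_spec(), t1_spec = hestage::t1_spec(),
                         progress = TRUE) {
  stopifnot(inherits(config, "stage_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  say <- function(fmt, ...) {
    line <- sprintf(paste0("[%s] ", fmt), format(Sys.time(), "%H:%M:%S"), ...)
    if (progress) message(line)
    cat(line, "\n", file = log_path, append = TRUE)
  }

  say("simulate: %d Ta + %d T1 phantoms (seed %d)", config$n_ta, config$n_t1,
      config$seed)
  dataset <- generate_dataset(config$n_ta, config$n_t1, ta_spec, t1_spec,
                              seed = config$seed)
  readr::write_csv(dataset[, c("image_id", "stage", "seed")],
                   file.path(out_dir, "dataset_manifest.csv"))

  say("extract: preprocessing + 3 pattern extractors per image")
  raw <- extract_feature_table(dataset, config, flatfield = TRUE,
                               progress = progress)
  write_feature_table(raw, file.path(out_dir, "features_raw.csv"))

  say("clean: enforcing the 696-feature schema")
  table <- clean_features(raw)
  write_feature_table(table, file.path(out_dir, "features_clean.csv"))

  say("rank: %d forests x %d trees", config$n_forests, config$n_trees)
  ranking <- rank_features(table, n_forests = config$n_forests,
                           n_trees = config$n_trees,
                           seed = derive_seed(config$seed, 101))
  readr::write_csv(as_tibble(ranking), file.path(out_dir, "ranking.csv"))

  top <- select_top_k(ranking, min(config$top_k, nrow(ranking)))
  protocol <- eval_protocol(train_fraction = config$train_fraction,
                            repeats = config$repeats,
                            threshold = config$threshold,
                            balance = config$balance,
                            seed = derive_seed(config$seed, 202))

  say("train: %s on top-%d features, %d repeats",
      paste(config$models, collapse = "/"), length(top), config$repeats)
  evals <- evaluate_models(table, models = config$models, protocol = protocol,
                           features = top)
  results <- bind_rows(lapply(evals, tidy))
  readr::write_csv(results, file.path(out_dir, "results.csv"))
  readr::write_csv(
    bind_rows(lapply(names(evals), function(m) {
      mutate(evals[[m]]$mean_roc, model = m)
    })),
    file.path(out_dir, "roc_mean.csv"))

  say("cluster: PCA + k-means k = %d..%d", config$k_min, config$k_max)
  pca <- pca_features(table)
  clusters <- kmeans_sweep(pca, k_range = config$k_min:config$k_max,
                           seed = derive_seed(config$seed, 303),
                           restarts = config$kmeans_restarts)
  clusters$information_gain <- vapply(clusters$assignment, function(a) {
    information_gain(table$stage, a)
  }, numeric(1))
  readr::write_csv(clusters[, c("k", "wcss", "information_gain")],
                   file.path(out_dir, "clusters.csv"))

  manifest <- list(
    config = unclass(config),
    seed = config$seed,
    n_images = nrow(dataset),
    r_version = as.character(getRversion()),
    packages = list(hestage = as.character(utils::packageVersion("hestage")))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done: outputs in %s", out_dir)

  invisible(list(table = table, ranking = ranking, evals = evals, pca = pca,
                 clusters = clusters, out_dir = out_dir))
}
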