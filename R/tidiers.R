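#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy per-repeat metrics of an evaluation
#'
#' @param x A `stage_eval` from [train_eval()].
#' @param ... Unused.
#' @return Tibble with one row per repeat: `model`, `repeat_id`, `accuracy`,
#'   `auc`, `n_balanced`.
#' @method tidy stage_eval
#' @export
tidy.stage_eval <- function(x, ...) {
  mutate(x$metrics, model = x$model, .before = 1)
}

#' One-row summary of an evaluation
#'
#' @param x A `stage_eval`.
#' @param ... Unused.
#' @return Tibble: `model`, `repeats`, `mean_accuracy`, `sd_accuracy`,
#'   `mean_auc`, `sd_auc`.
#' @method glance stage_eval
#' @export
glance.stage_eval <- function(x, ...) {
  tibble(
    model = x$model,
    repeats = nrow(x$metrics),
    mean_accuracy = mean(x$metrics$accuracy),
    sd_accuracy = sd(x$metrics$accuracy),
    mean_auc = mean(x$metrics$auc),
    sd_auc = sd(x$metrics$auc)
  )
}

#' Tidy a feature ranking
#'
#' @param x A `stage_ranking` from [rank_features()].
#' @param ... Unused.
#' @return Tibble sorted by rank.
#' @method tidy stage_ranking
#' @export
tidy.stage_ranking <- function(x, ...) {
  arrange(as_tibble(x), .data$rank)
}

#' One-row summary of a ranking
#'
#' @param x A `stage_ranking`.
#' @param ... Unused.
#' @return Tibble: `n_features`, `n_forests`, `n_trees`, `seed`.
#' @method glance stage_ranking
#' @export
glance.stage_ranking <- function(x, ...) {
  tibble(
    n_features = nrow(x),
    n_forests = attr(x, "n_forests"),
    n_trees = attr(x, "n_trees"),
    seed = attr(x, "seed")
  )
}

#' Tidy PCA eigenvalues
#'
#' @param x A `stage_pca` from [pca_features()].
#' @param ... Unused.
#' @return Tibble with `component`, `eigenvalue`, `variance_fraction`,
#'   `cumulative_fraction`.
#' @method tidy stage_pca
#' @export
tidy.stage_pca <- function(x, ...) {
  ev <- x$eigenvalues
  tibble(
    component = seq_along(ev),
    eigenvalue = ev,
    variance_fraction = ev / sum(ev),
    cumulative_fraction = cumsum(ev) / sum(ev)
  )
}

#' One-row summary of a PCA
#'
#' @param x A `stage_pca`.
#' @param ... Unused.
#' @return Tibble: `n_components`, `n_dropped`, `frac_first_component`,
#'   `n_components_90`.
#' @method glance stage_pca
#' @export
glance.stage_pca <- function(x, ...) {
  ev <- x$eigenvalues
  tibble(
    n_components = length(ev),
    n_dropped = length(x$dropped),
    frac_first_component = ev[1] / sum(ev),
    n_components_90 = min(which(cumsum(ev) / sum(ev) >= 0.9))
  )
}
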