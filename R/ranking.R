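#' Rank features by decision-tree-forest importance
#'
#' Builds `n_forests` independent forests of `n_trees` classification trees.
#' Each tree is grown on a bootstrap sample of the rows with *all* features
#' available at every split (no column subsampling), and per-feature
#' importance is the total Gini impurity decrease attributable to splits on
#' the feature. Each forest's importance vector is normalized to sum 1, the
#' normalized vectors are averaged across forests, and features are ranked by
#' the average (ties broken by manifest column order).
#'
#' @param table Data frame containing the feature columns and a label column.
#' @param label Name of the two-class label column (default `"stage"`).
#' @param features Optional character vector of feature columns; defaults to
#'   all numeric columns except the label.
#' @param n_forests,n_trees Forest count and trees per forest.
#' @param seed Integer seed; the ranking is deterministic given the seed.
#' @return A `stage_ranking` object: tibble with `feature`, `importance`,
#'   `rank`, plus parameters as attributes.
#' @export
rank_features <- function(table, label = "stage", features = NULL,
                          n_forests = 20, n_trees = 40, seed = 1L) {
  y <- factor(table[[label]])
  if (nlevels(y) < 2) abort("labels must contain two classes")
  if (min(table(y)) < 2) abort("need at least 2 rows per class")
  if (is.null(features)) {
    features <- setdiff(names(table)[vapply(table, is.numeric, logical(1))], label)
  }
  x <- as.data.frame(table[, features])
  p <- ncol(x)

  # constant columns can never split; they keep importance 0
  varying <- vapply(x, function(col) length(unique(col)) > 1, logical(1))
  acc <- numeric(p)
  if (any(varying)) {
    xv <- x[, varying, drop = FALSE]
    for (f in seq_len(n_forests)) {
      set.seed(derive_seed(seed, f))
      fit <- randomForest::randomForest(
        x = xv, y = y, ntree = n_trees, mtry = ncol(xv), nodesize = 1,
        replace = TRUE
      )
      imp <- fit$importance[, "MeanDecreaseGini"]
      s <- sum(imp)
      if (s > 0) imp <- imp / s
      acc[varying] <- acc[varying] + imp
    }
  }
  importance <- acc / n_forests
  ord <- order(-importance, seq_len(p))
  ranking <- tibble(
    feature = features,
    importance = as.numeric(importance),
    rank = match(seq_len(p), ord)
  )
  structure(ranking,
            class = c("stage_ranking", class(ranking)),
            n_forests = n_forests, n_trees = n_trees, seed = seed)
}

#' Top-k features of a ranking
#'
#' @param ranking A [rank_features()] result.
#' @param k Number of features (default 100).
#' @return Character vector of the first `k` feature names by rank.
#' @export
select_top_k <- function(ranking, k = 100) {
  n <- nrow(ranking)
  if (k < 1 || k > n) abort(sprintf("k must lie in 1..%d", n))
  ranking$feature[order(ranking$rank)][seq_len(k)]
}

#' Incremental feature-addition accuracy curve
#'
#' Evaluates each classifier on the top-k ranked features for every `k`,
#' under the balanced repeated-split protocol, reproducing the
#' features-added-in-rank-order performance curve.
#'
#' @param table Feature table with a label column.
#' @param ranking A [rank_features()] result.
#' @param models Character vector of classifier names (see [train_eval()]).
#' @param ks Increasing vector of feature counts.
#' @param protocol An [eval_protocol()].
#' @param label Label column name.
#' @return A tibble with one row per (model, k): `mean_accuracy`, `sd_accuracy`,
#'   `mean_auc`.
#' @export
incremental_curve <- function(table, ranking, models = c("RF", "LR"),
                              ks = c(1, 2, 5, 10, 20, 50, 100),
                              protocol = eval_protocol(), label = "stage") {
  ks <- sort(unique(ks))
  rows <- list()
  for (k in ks) {
    feats <- select_top_k(ranking, k)
    sub <- table[, c(label, intersect(c("image_id"), names(table)), feats)]
    for (m in models) {
      ev <- train_eval(sub, model = m, protocol = protocol, label = label,
                       features = feats)
      g <- glance(ev)
      rows[[length(rows) + 1]] <- tibble(
        model = m, k = k,
        mean_accuracy = g$mean_accuracy, sd_accuracy = g$sd_accuracy,
        mean_auc = g$mean_auc
      )
    }
  }
  bind_rows(rows)
}
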