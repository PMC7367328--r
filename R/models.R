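#' Balanced repeated-split evaluation protocol
#'
#' Each repeat balances the classes by subsampling the majority class to the
#' minority count (without replacement), splits the balanced rows 70/30 into
#' disjoint train and test sets, fits the classifier, and scores the test
#' rows; class is called at the decision threshold and ROC/AUC are computed
#' from the scores.
#'
#' @param train_fraction Training fraction in (0, 1) (default 0.7).
#' @param repeats Number of random repeats (default 20).
#' @param threshold Decision threshold on the invasive-class probability
#'   (default 0.5).
#' @param balance Logical; subsample the majority class to the minority size.
#' @param seed Integer seed controlling all repeats.
#' @return An `eval_protocol` list.
#' @export
eval_protocol <- function(train_fraction = 0.7, repeats = 20, threshold = 0.5,
                          balance = TRUE, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("train_fraction must lie strictly between 0 and 1")
  }
  if (repeats < 1) abort("repeats must be >= 1")
  structure(list(train_fraction = train_fraction, repeats = repeats,
                 threshold = threshold, balance = isTRUE(balance),
                 seed = as.integer(seed)),
            class = "eval_protocol")
}

# ---------------------------------------------------------------------------
# Probabilistic neural network (Specht-type Parzen/Bayes classifier)
# ---------------------------------------------------------------------------

#' Fit a probabilistic neural network
#'
#' A kernel-density Bayes classifier: each class score is the average
#' Gaussian kernel `exp(-||x - x_i||^2 / (2 sigma^2))` over that class's
#' stored training vectors, and posteriors are priors times scores,
#' normalized. Features are standardized with training mean/sd (zero-variance
#' features are dropped). The default bandwidth is `sigma_factor` times the
#' median pairwise distance between standardized training vectors.
#'
#' @param x Numeric matrix or data frame of training vectors.
#' @param y Two-class label vector.
#' @param sigma Kernel bandwidth; `NULL` applies the median-distance rule.
#' @param sigma_factor Multiplier of the median pairwise distance.
#' @param priors Class priors; default proportional to class counts.
#' @return A `stage_pnn` model.
#' @export
pnn_fit <- function(x, y, sigma = NULL, sigma_factor = 0.1, priors = NULL) {
  x <- as.matrix(x)
  y <- factor(y)
  if (nlevels(y) < 2 || any(table(y) < 1)) {
    abort("pnn_fit needs at least one training vector in each of two classes")
  }
  center <- colMeans(x)
  scale_ <- apply(x, 2, sd)
  keep <- scale_ > 0
  if (!any(keep)) abort("all features have zero variance")
  xs <- sweep(sweep(x[, keep, drop = FALSE], 2, center[keep]), 2,
              scale_[keep], "/")
  if (is.null(sigma)) {
    n <- nrow(xs)
    sub <- if (n > 600) xs[seq(1, n, length.out = 600), , drop = FALSE] else xs
    med <- median(dist(sub))
    sigma <- sigma_factor * max(med, 1e-8)
  }
  if (sigma <= 0) abort("sigma must be positive")
  if (is.null(priors)) priors <- as.numeric(table(y)) / length(y)
  structure(list(
    x = xs, y = y, levels = levels(y), sigma = sigma, priors = priors,
    center = center[keep], scale = scale_[keep], keep = keep
  ), class = "stage_pnn")
}

#' Posterior class probabilities from a PNN
#'
#' @param object A [pnn_fit()] model.
#' @param newdata Matrix or data frame of query vectors.
#' @param ... Unused.
#' @return Matrix of posteriors (rows sum to 1), columns named by class.
#' @export
predict.stage_pnn <- function(object, newdata, ...) {
  q <- as.matrix(newdata)[, object$keep, drop = FALSE]
  q <- sweep(sweep(q, 2, object$center), 2, object$scale, "/")
  # squared distances query x train
  d2 <- outer(rowSums(q^2), rowSums(object$x^2), "+") - 2 * q %*% t(object$x)
  d2[d2 < 0] <- 0
  logk <- -d2 / (2 * object$sigma^2)
  logpost <- vapply(seq_along(object$levels), function(ci) {
    sel <- object$y == object$levels[ci]
    m <- logk[, sel, drop = FALSE]
    # log of the class-average kernel, stabilized
    mx <- apply(m, 1, max)
    log(object$priors[ci]) + mx + log(rowMeans(exp(m - mx)))
  }, numeric(nrow(q)))
  logpost <- matrix(logpost, nrow = nrow(q))
  mx <- apply(logpost, 1, max)
  post <- exp(logpost - mx)
  post <- post / rowSums(post)
  colnames(post) <- object$levels
  post
}

# ---------------------------------------------------------------------------
# AdaBoost over depth-1 trees, and plain bagging (from scratch; no boosting
# package in the dependency set)
# ---------------------------------------------------------------------------

adaboost_fit <- function(x, y01, n_rounds = 50) {
  n <- length(y01)
  w <- rep(1 / n, n)
  ysign <- ifelse(y01 == 1, 1, -1)
  df <- data.frame(.y = factor(y01), x, check.names = FALSE)
  stumps <- list(); alphas <- numeric(0)
  for (m in seq_len(n_rounds)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w,
                        control = rpart::rpart.control(
                          maxdepth = 1, cp = -1, minsplit = 2, xval = 0))
    pred <- as.integer(as.character(predict(fit, df, type = "class")))
    err <- sum(w * (pred != y01))
    err <- min(max(err, 1e-10), 1 - 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    stumps[[m]] <- fit; alphas[m] <- alpha
    w <- w * exp(-alpha * ysign * ifelse(pred == 1, 1, -1))
    w <- w / sum(w)
    if (err >= 0.5) break
  }
  structure(list(stumps = stumps, alphas = alphas), class = "stage_adaboost")
}

adaboost_score <- function(model, xnew) {
  df <- as.data.frame(xnew)
  f <- rep(0, nrow(df))
  for (m in seq_along(model$stumps)) {
    pred <- as.integer(as.character(predict(model$stumps[[m]], df, type = "class")))
    f <- f + model$alphas[m] * ifelse(pred == 1, 1, -1)
  }
  1 / (1 + exp(-2 * f))
}

bagged_trees_fit <- function(x, y01, n_trees = 50) {
  df <- data.frame(.y = factor(y01), x, check.names = FALSE)
  n <- nrow(df)
  trees <- lapply(seq_len(n_trees), function(m) {
    idx <- sample.int(n, n, replace = TRUE)
    rpart::rpart(.y ~ ., data = df[idx, ],
                 control = rpart::rpart.control(cp = -1, minsplit = 2, xval = 0))
  })
  structure(list(trees = trees), class = "stage_bagging")
}

bagged_trees_score <- function(model, xnew) {
  df <- as.data.frame(xnew)
  probs <- vapply(model$trees, function(tr) predict(tr, df, type = "prob")[, "1"],
                  numeric(nrow(df)))
  rowMeans(matrix(probs, nrow = nrow(df)))
}

# ---------------------------------------------------------------------------
# classifier registry: fit(x, y01) -> model; score(model, x) -> P(class 1)
# ---------------------------------------------------------------------------

standardize_train <- function(x) {
  center <- colMeans(x); scale_ <- apply(x, 2, sd)
  scale_[scale_ == 0] <- 1
  list(center = center, scale = scale_,
       x = sweep(sweep(x, 2, center), 2, scale_, "/"))
}

classifier_registry <- function(config = list()) {
  mlp_size <- config$mlp_size %||% 100
  list(
    PNN = list(
      fit = function(x, y01) pnn_fit(x, factor(y01)),
      score = function(model, xnew) predict(model, xnew)[, "1"]
    ),
    SVM = list(
      fit = function(x, y01) e1071::svm(x, factor(y01), kernel = "radial",
                                        probability = TRUE),
      score = function(model, xnew) {
        p <- attr(predict(model, xnew, probability = TRUE), "probabilities")
        p[, "1"]
      }
    ),
    LR = list(
      fit = function(x, y01) {
        if (ncol(x) >= 2) {
          glmnet::glmnet(x, factor(y01), family = "binomial", alpha = 0,
                         lambda = config$lr_lambda %||% 0.01)
        } else {
          st <- standardize_train(x)
          fit <- suppressWarnings(
            glm(y ~ ., data = data.frame(y = y01, st$x), family = binomial()))
          structure(list(fit = fit, st = st), class = "stage_glm1")
        }
      },
      score = function(model, xnew) {
        if (inherits(model, "stage_glm1")) {
          xs <- sweep(sweep(as.matrix(xnew), 2, model$st$center), 2,
                      model$st$scale, "/")
          as.numeric(predict(model$fit, data.frame(xs), type = "response"))
        } else {
          as.numeric(predict(model, as.matrix(xnew), type = "response"))
        }
      }
    ),
    Bagging = list(
      fit = function(x, y01) adaboost_fit(x, y01,
                                          n_rounds = config$adaboost_rounds %||% 50),
      score = adaboost_score
    ),
    BaggedTrees = list(
      fit = function(x, y01) bagged_trees_fit(x, y01,
                                              n_trees = config$bagging_trees %||% 50),
      score = bagged_trees_score
    ),
    RF = list(
      fit = function(x, y01) randomForest::randomForest(
        x = as.data.frame(x), y = factor(y01),
        ntree = config$rf_trees %||% 100),
      score = function(model, xnew) {
        predict(model, as.data.frame(xnew), type = "prob")[, "1"]
      }
    ),
    MLP = list(
      fit = function(x, y01) {
        st <- standardize_train(x)
        nw <- (ncol(x) + 1) * mlp_size + mlp_size + 1
        fit <- nnet::nnet(st$x, y01, size = mlp_size, entropy = TRUE,
                          decay = 1e-3, maxit = config$mlp_maxit %||% 100,
                          MaxNWts = nw + 10, trace = FALSE)
        structure(list(fit = fit, st = st), class = "stage_mlp")
      },
      score = function(model, xnew) {
        xs <- sweep(sweep(as.matrix(xnew), 2, model$st$center), 2,
                    model$st$scale, "/")
        as.numeric(predict(model$fit, xs))
      }
    )
  )
}

#' Available classifier names
#' @return Character vector.
#' @export
classifier_names <- function() {
  c("PNN", "SVM", "LR", "Bagging", "RF", "MLP", "BaggedTrees")
}

# ---------------------------------------------------------------------------
# ROC / AUC
# ---------------------------------------------------------------------------

#' Area under the ROC curve (Mann-Whitney form)
#'
#' The probability that a random positive scores above a random negative,
#' with ties counted 1/2 — identical to the trapezoidal integral of the
#' empirical ROC curve.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary labels (1/TRUE = positive).
#' @return AUC in `[0, 1]`.
#' @export
auc_mann_whitney <- function(scores, labels) {
  y <- as.integer(as.logical(labels))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) abort("AUC needs both classes present")
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Empirical ROC curve
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (1/TRUE = positive).
#' @return Tibble with `fpr`, `tpr`, monotone from (0,0) to (1,1).
#' @export
roc_curve <- function(scores, labels) {
  y <- as.integer(as.logical(labels))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) abort("ROC needs both classes present")
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]; ss <- scores[ord]
  tp <- cumsum(ys); fp <- cumsum(1 - ys)
  last <- c(ss[-1] != ss[-length(ss)], TRUE) # one point per distinct score
  tibble(fpr = c(0, fp[last] / n0), tpr = c(0, tp[last] / n1))
}

#' Trapezoidal AUC from an ROC curve
#'
#' @param roc A [roc_curve()] tibble.
#' @return AUC in `[0, 1]`.
#' @export
auc_trapezoid <- function(roc) {
  sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
}

# step-function TPR at fixed FPR grid points (vertical averaging support)
roc_at_grid <- function(roc, grid) {
  vapply(grid, function(f) max(roc$tpr[roc$fpr <= f]), numeric(1))
}

# ---------------------------------------------------------------------------
# the evaluation harness
# ---------------------------------------------------------------------------

#' Train and evaluate one classifier under the repeated-split protocol
#'
#' For each repeat: balance classes by subsampling the majority to the
#' minority count, split 70/30 without leakage, fit the classifier, score the
#' held-out rows with the invasive-class probability, and record accuracy at
#' the decision threshold plus the ROC curve and AUC. The mean ROC is formed
#' by vertical averaging on a fixed 101-point FPR grid. A degenerate repeat
#' whose test split lacks a class is redrawn from the next seed substream.
#'
#' @param table Data frame with feature columns and a label column.
#' @param model Classifier name, one of [classifier_names()].
#' @param protocol An [eval_protocol()].
#' @param label Label column name (default `"stage"`); the *second* factor
#'   level (e.g. `"T1"` for Ta/Ta ordering `c("Ta","T1")`) is the positive
#'   class, or pass `positive`.
#' @param features Optional feature column names; default all numeric except
#'   the label.
#' @param positive Positive-class label; default `"T1"` when present.
#' @param config Optional list of classifier hyperparameter overrides.
#' @return A `stage_eval` object: per-repeat metrics, per-repeat ROC curves,
#'   and the vertically averaged mean ROC.
#' @export
train_eval <- function(table, model = "PNN", protocol = eval_protocol(),
                       label = "stage", features = NULL, positive = NULL,
                       config = list()) {
  registry <- classifier_registry(config)
  if (!model %in% names(registry)) {
    abort(sprintf("unknown classifier '%s' (choose from %s)", model,
                  paste(names(registry), collapse = ", ")))
  }
  if (is.null(features)) {
    features <- setdiff(names(table)[vapply(table, is.numeric, logical(1))], label)
  }
  y_raw <- table[[label]]
  if (is.null(positive)) {
    positive <- if ("T1" %in% y_raw) "T1" else sort(unique(as.character(y_raw)))[2]
  }
  y <- as.integer(as.character(y_raw) == as.character(positive))
  if (length(unique(y)) < 2) abort("labels must contain two classes")
  x <- as.matrix(as.data.frame(table[, features]))
  storage.mode(x) <- "double"

  cls <- registry[[model]]
  grid <- seq(0, 1, length.out = 101)
  accs <- numeric(protocol$repeats)
  aucs <- numeric(protocol$repeats)
  tprs <- matrix(NA_real_, protocol$repeats, length(grid))
  rocs <- vector("list", protocol$repeats)
  balanced_n <- integer(protocol$repeats)
  n_train_v <- integer(protocol$repeats)
  n_test_v <- integer(protocol$repeats)

  substream <- 0
  for (r in seq_len(protocol$repeats)) {
    repeat {
      substream <- substream + 1
      set.seed(derive_seed(protocol$seed, substream))
      idx1 <- which(y == 1); idx0 <- which(y == 0)
      if (protocol$balance) {
        n_min <- min(length(idx1), length(idx0))
        idx1 <- sample(idx1, n_min)
        idx0 <- sample(idx0, n_min)
      }
      pool <- c(idx1, idx0)
      n_train <- floor(protocol$train_fraction * length(pool))
      train_idx <- sample(pool, n_train)
      test_idx <- setdiff(pool, train_idx)
      if (length(unique(y[test_idx])) == 2 &&
          length(unique(y[train_idx])) == 2) break
      message(sprintf("repeat %d: degenerate split, redrawing", r))
    }
    fit <- cls$fit(x[train_idx, , drop = FALSE], y[train_idx])
    score <- cls$score(fit, x[test_idx, , drop = FALSE])
    truth <- y[test_idx]
    accs[r] <- mean((score >= protocol$threshold) == (truth == 1))
    roc <- roc_curve(score, truth)
    rocs[[r]] <- roc
    aucs[r] <- auc_trapezoid(roc)
    tprs[r, ] <- roc_at_grid(roc, grid)
    balanced_n[r] <- length(pool)
    n_train_v[r] <- length(train_idx)
    n_test_v[r] <- length(test_idx)
  }

  structure(list(
    model = model,
    protocol = protocol,
    metrics = tibble(repeat_id = seq_len(protocol$repeats),
                     accuracy = accs, auc = aucs, n_balanced = balanced_n,
                     n_train = n_train_v, n_test = n_test_v),
    rocs = rocs,
    mean_roc = tibble(fpr = grid,
                      tpr_mean = colMeans(tprs),
                      tpr_sd = apply(tprs, 2, sd))
  ), class = "stage_eval")
}

#' Evaluate several classifiers on one table
#'
#' @param table Feature table with label column.
#' @param models Character vector of classifier names.
#' @inheritParams train_eval
#' @return Named list of `stage_eval` objects.
#' @export
evaluate_models <- function(table, models = c("PNN", "SVM", "LR", "Bagging",
                                              "RF", "MLP"),
                            protocol = eval_protocol(), label = "stage",
                            features = NULL, positive = NULL, config = list()) {
  out <- lapply(models, function(m) {
    train_eval(table, model = m, protocol = protocol, label = label,
               features = features, positive = positive, config = config)
  })
  names(out) <- models
  out
}

#' @export
print.stage_eval <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<stage_eval> %s: %d repeats, mean accuracy %.3f (sd %.3f), mean AUC %.3f\n",
    x$model, nrow(x$metrics), g$mean_accuracy, g$sd_accuracy, g$mean_auc))
  invisible(x)
}
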