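test_that("PNN behaves as a nearest-neighbor classifier in the small-sigma limit", {
  x <- rbind(c(0, 0), c(1, 1))
  fit <- pnn_fit(x, c("a", "b"), sigma = 0.05)
  post <- predict(fit, rbind(c(0.1, 0)))
  expect_gt(post[, "a"], 0.99)
  expect_equal(rowSums(post), 1, tolerance = 1e-12)
})

test_that("equidistant queries with equal priors give symmetric posteriors", {
  x <- rbind(c(-1, 0), c(1, 0))
  fit <- pnn_fit(x, c("a", "b"), sigma = 0.7)
  post <- predict(fit, rbind(c(0, 5), c(0, 0)))
  expect_equal(unname(post[, "a"]), c(0.5, 0.5), tolerance = 1e-9)
})

test_that("PNN separates well-separated gaussian classes perfectly", {
  for (s in 1:5) {
    set.seed(s)
    train <- rbind(matrix(rnorm(200), 100, 2),
                   matrix(rnorm(200, mean = 10), 100, 2))
    y <- rep(c(0, 1), each = 100)
    test <- rbind(matrix(rnorm(100), 50, 2),
                  matrix(rnorm(100, mean = 10), 50, 2))
    ytest <- rep(c(0, 1), each = 50)
    fit <- pnn_fit(train, y)
    pred <- as.integer(predict(fit, test)[, "1"] >= 0.5)
    expect_equal(mean(pred == ytest), 1.0)
  }
})

test_that("PNN rejects degenerate training input", {
  expect_error(pnn_fit(rbind(c(0, 0), c(1, 1)), c("a", "a")), "two classes")
  expect_error(pnn_fit(rbind(c(0, 0), c(1, 1)), c("a", "b"), sigma = -1),
               "positive")
})

test_that("AUC matches hand-counted positive-negative pair comparisons", {
  expect_equal(auc_mann_whitney(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0)), 0.75)
  expect_equal(auc_mann_whitney(c(1, 2, 3, 10), c(0, 0, 1, 1)), 1.0)
  expect_equal(auc_mann_whitney(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(auc_mann_whitney(1:3, c(1, 1, 1)), "both classes")
})

test_that("trapezoidal ROC integral equals the pairwise count to 1e-12", {
  set.seed(99)
  for (trial in 1:200) {
    n <- sample(10:60, 1)
    scores <- if (trial %% 3 == 0) sample(1:5, n, replace = TRUE) else rnorm(n)
    labels <- sample(c(0, 1), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    roc <- roc_curve(scores, labels)
    expect_equal(auc_trapezoid(roc), oracle_auc_pairs(scores, labels),
                 tolerance = 1e-12)
    expect_equal(auc_trapezoid(roc), auc_mann_whitney(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("ROC curves are monotone from (0,0) to (1,1) and AUC is symmetric", {
  set.seed(5)
  scores <- rnorm(80); labels <- sample(c(0, 1), 80, replace = TRUE)
  roc <- roc_curve(scores, labels)
  expect_equal(roc$fpr[1], 0); expect_equal(roc$tpr[1], 0)
  expect_equal(roc$fpr[nrow(roc)], 1); expect_equal(roc$tpr[nrow(roc)], 1)
  expect_true(all(diff(roc$fpr) >= 0))
  expect_true(all(diff(roc$tpr) >= 0))
  expect_equal(auc_mann_whitney(scores, labels) +
                 auc_mann_whitney(-scores, labels), 1, tolerance = 1e-12)
  # invariant under strictly monotone transforms
  expect_equal(auc_mann_whitney(exp(scores), labels),
               auc_mann_whitney(scores, labels), tolerance = 1e-12)
})

test_that("AUC agrees with an independent ROC implementation", {
  set.seed(11)
  scores <- rnorm(120); labels <- sample(c(0, 1), 120, replace = TRUE)
  ours <- auc_mann_whitney(scores, labels)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("balancing reproduces the 460+460 design and the 644/276 split", {
  set.seed(8)
  n1 <- 717; n0 <- 460
  tbl <- tibble::tibble(
    f1 = c(rnorm(n0), rnorm(n1, 1)),
    f2 = rnorm(n0 + n1),
    stage = c(rep("Ta", n0), rep("T1", n1))
  )
  ev <- train_eval(tbl, model = "LR",
                   protocol = eval_protocol(repeats = 3, seed = 4))
  expect_true(all(ev$metrics$n_balanced == 920))
  expect_true(all(ev$metrics$n_train == 644)) # floor(0.7 * 920)
  expect_true(all(ev$metrics$n_test == 276))
  expect_equal(nrow(ev$metrics), 3)
})

test_that("protocol produces one accuracy per repeat and honors the seed", {
  tbl <- blob_table(40, sep = 1, seed = 2)
  ev1 <- train_eval(tbl, model = "PNN", protocol = eval_protocol(repeats = 5, seed = 9))
  ev2 <- train_eval(tbl, model = "PNN", protocol = eval_protocol(repeats = 5, seed = 9))
  expect_equal(nrow(ev1$metrics), 5)
  expect_identical(ev1$metrics, ev2$metrics)
  ev3 <- train_eval(tbl, model = "PNN", protocol = eval_protocol(repeats = 5, seed = 10))
  expect_false(identical(ev1$metrics$accuracy, ev3$metrics$accuracy))
})

test_that("every classifier learns an easy two-blob problem", {
  tbl <- blob_table(40, sep = 4, seed = 3)
  proto <- eval_protocol(repeats = 3, seed = 1)
  for (m in c("PNN", "SVM", "LR", "Bagging", "RF", "MLP", "BaggedTrees")) {
    ev <- train_eval(tbl, model = m, protocol = proto,
                     config = list(mlp_size = 10))
    expect_gt(mean(ev$metrics$accuracy), 0.9)
    expect_gt(mean(ev$metrics$auc), 0.95)
  }
  expect_error(train_eval(tbl, model = "nope"), "unknown classifier")
})

test_that("mean ROC is a valid vertically averaged band", {
  tbl <- blob_table(30, sep = 2, seed = 6)
  ev <- train_eval(tbl, model = "RF", protocol = eval_protocol(repeats = 4, seed = 2))
  mr <- ev$mean_roc
  expect_equal(nrow(mr), 101)
  expect_true(all(diff(mr$tpr_mean) >= -1e-12))
  expect_true(all(mr$tpr_mean >= 0 & mr$tpr_mean <= 1))
  expect_equal(mr$tpr_mean[101], 1)
  g <- glance(ev)
  expect_true(all(c("mean_accuracy", "mean_auc") %in% names(g)))
  td <- tidy(ev)
  expect_equal(nrow(td), 4)
})
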