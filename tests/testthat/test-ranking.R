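planted_table <- function(n = 200, p_noise = 99, seed = 1) {
  set.seed(seed)
  stage <- rep(c("Ta", "T1"), each = n / 2)
  x <- as.data.frame(matrix(rnorm(n * p_noise), n, p_noise))
  names(x) <- sprintf("noise_%03d", seq_len(p_noise))
  x$signal <- as.numeric(stage == "T1") # perfectly separating
  x$stage <- stage
  tibble::as_tibble(x[, c(p_noise + 1, seq_len(p_noise), p_noise + 2)])
}

test_that("defaults match the 20-forest, 40-tree design", {
  tbl <- planted_table(60, 10, seed = 2)
  rk <- rank_features(tbl, seed = 3)
  g <- glance(rk)
  expect_equal(g$n_forests, 20)
  expect_equal(g$n_trees, 40)
  expect_equal(g$n_features, 11)
  expect_true(all(sort(rk$rank) == seq_len(11)))
  expect_true(all(rk$importance >= 0))
  # mean importance is non-increasing in rank
  imp_by_rank <- rk$importance[order(rk$rank)]
  expect_true(all(diff(imp_by_rank) <= 1e-12))
})

test_that("all-constant features tie at zero and fall back to manifest order", {
  tbl <- tibble::tibble(a = rep(1, 40), b = rep(2, 40), c = rep(3, 40),
                        stage = rep(c("Ta", "T1"), 20))
  rk <- rank_features(tbl, n_forests = 2, n_trees = 5, seed = 1)
  expect_true(all(rk$importance == 0))
  expect_equal(select_top_k(rk, 3), c("a", "b", "c"))
})

test_that("a planted separating feature ranks first under reseeding", {
  tbl <- planted_table(200, 99, seed = 5)
  wins <- 0
  for (s in 1:5) {
    rk <- rank_features(tbl, n_forests = 5, n_trees = 40, seed = 100 + s)
    wins <- wins + (select_top_k(rk, 1) == "signal")
  }
  expect_equal(wins, 5)
})

test_that("rankings are deterministic given the seed and reject bad input", {
  tbl <- planted_table(60, 10, seed = 4)
  a <- rank_features(tbl, n_forests = 3, n_trees = 10, seed = 7)
  b <- rank_features(tbl, n_forests = 3, n_trees = 10, seed = 7)
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
  one_class <- dplyr::mutate(tbl, stage = "Ta")
  expect_error(rank_features(one_class), "two classes")
  expect_error(select_top_k(a, 0), "1\\.\\.")
  expect_error(select_top_k(a, 999), "1\\.\\.")
})

test_that("informative features dominate the incremental curve", {
  set.seed(12)
  n <- 120
  stage <- rep(c("Ta", "T1"), each = n / 2)
  inf <- matrix(rnorm(n * 10, mean = rep(ifelse(stage == "T1", 1.2, 0), 10)), n, 10)
  noise <- matrix(rnorm(n * 90), n, 90)
  tbl <- tibble::as_tibble(as.data.frame(cbind(inf, noise)), .name_repair = "unique")
  names(tbl) <- c(sprintf("inf_%02d", 1:10), sprintf("noise_%02d", 1:90))
  tbl$stage <- stage
  rk <- rank_features(tbl, n_forests = 5, n_trees = 20, seed = 3)
  proto <- eval_protocol(repeats = 5, seed = 11)
  curve <- incremental_curve(tbl, rk, models = "RF", ks = c(10, 100),
                             protocol = proto)
  acc10 <- curve$mean_accuracy[curve$k == 10]
  acc100 <- curve$mean_accuracy[curve$k == 100]
  expect_gte(acc10, acc100 - 0.02)

  # the true ranking reaches its plateau earlier than a randomized order
  shuffled <- rk
  set.seed(99)
  shuffled$rank <- sample(shuffled$rank)
  curve_rand <- incremental_curve(tbl, shuffled, models = "RF", ks = c(10, 100),
                                  protocol = proto)
  expect_gte(acc10, 0.95 * acc100)
  expect_gt(acc10, curve_rand$mean_accuracy[curve_rand$k == 10])
})

test_that("evaluating all ranked features equals evaluating the full table", {
  tbl <- planted_table(60, 9, seed = 8)
  rk <- rank_features(tbl, n_forests = 2, n_trees = 10, seed = 2)
  proto <- eval_protocol(repeats = 3, seed = 5)
  curve <- incremental_curve(tbl, rk, models = "PNN", ks = 10, protocol = proto)
  full <- train_eval(tbl, model = "PNN", protocol = proto)
  expect_equal(curve$mean_accuracy, mean(full$metrics$accuracy), tolerance = 1e-12)
})
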