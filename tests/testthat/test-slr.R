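test_that("periodic folds cycle samples and balance every group", {
  # acquisition-ordered labels, 70 each
  y <- rep(c(8, 10, 13, 16, 32), 70)
  f <- periodic_folds(y, k = 7)
  for (lab in unique(y)) {
    expect_equal(as.integer(table(f[y == lab])), rep(10L, 7))
  }
  # 60 train / 10 test per label per fold; 300 five-choice training rows
  expect_equal(sum(f != 1), 300)
  expect_equal(sum(f == 1), 50)
  # two-choice subset: 120 training rows per fold
  sub <- y %in% c(8, 32)
  expect_equal(sum(f[sub] != 1), 120)
  # 7 per label with k = 7: singleton groups
  f7 <- periodic_folds(rep(c(1, 2), each = 7), k = 7)
  expect_equal(as.integer(table(f7)), rep(2L, 7))
  expect_error(periodic_folds(rep(1:5, 3), k = 7), "fewer than k")
})

test_that("rolling folds are strictly chronological", {
  y <- rep(c(8, 10, 13, 16, 32), 70)
  sp <- rolling_folds(y, n_folds = 3)
  expect_length(sp, 3)
  for (s in sp) {
    for (lab in unique(y)) {
      tr <- intersect(s$train, which(y == lab))
      te <- intersect(s$test, which(y == lab))
      expect_equal(length(te), 17)          # b = floor(70 / 4)
      expect_lt(max(tr), min(te))
    }
  }
  # expanding training: fold i trains on i blocks
  expect_equal(length(sp[[1]]$train), 5 * 17)
  expect_equal(length(sp[[3]]$train), 5 * 3 * 17)
  # two rows, one fold: train on the first, test on the second
  sp1 <- rolling_folds(c(1, 1, 2, 2)[c(1, 3, 2, 4)], n_folds = 1)
  expect_equal(length(sp1[[1]]$train), 2)
  expect_equal(length(sp1[[1]]$test), 2)
  expect_error(rolling_folds(rep(1:2, each = 3), n_folds = 3), "insufficient")
})

test_that("ARD keeps informative features and prunes noise", {
  toy <- separable_toy(n = 120, p = 100, seed = 1)
  m <- fit_slr(toy$x, toy$y)
  expect_true(all(m$active[1:2]))
  expect_gte(sum(!m$active[3:100]), 0.9 * 98)
  expect_true(all(m$weights[which(!m$active) + 1, ] == 0))
  # held-out accuracy of the sparse model
  toy2 <- separable_toy(n = 120, p = 100, seed = 2)
  expect_gte(mean(predict(m, toy2$x) == toy2$y), 0.95)
  # near-perfect self-classification on the training points
  expect_gte(mean(predict(m, toy$x) == toy$y), 0.95)
})

test_that("the fit is deterministic and sparsity only shrinks", {
  toy <- separable_toy(n = 60, p = 30, seed = 3)
  m1 <- fit_slr(toy$x, toy$y)
  m2 <- fit_slr(toy$x, toy$y)
  expect_identical(m1$weights, m2$weights)
  # the deterministic trajectory never re-activates a pruned feature
  actives <- vapply(c(1, 2, 3, 5, 10, 20), function(k) {
    sum(suppressMessages(fit_slr(toy$x, toy$y, max_outer = k))$active)
  }, numeric(1))
  expect_true(all(diff(actives) <= 0))
})

test_that("label-free inputs fall back to the majority class at chance", {
  # all-constant features: everything pruned, prediction = majority class
  x <- matrix(1, 30, 4)
  y <- rep(c(100, 200), c(20, 10))
  m <- suppressMessages(fit_slr(x, y))
  expect_false(any(m$active))
  expect_true(all(predict(m, x) == 100))

  # permuted labels, five classes: accuracy within binomial 99% bounds of 20%
  set.seed(9)
  yp <- sample(rep(c(8, 10, 13, 16, 32), each = 28))
  xp <- matrix(rnorm(140 * 40), 140, 40)
  res <- suppressMessages(
    run_task(as_feature_table(xp, yp), decoding_task(c(8, 10, 13, 16, 32))))
  n_dec <- 140
  half <- 2.576 * sqrt(0.2 * 0.8 / n_dec) * 100
  expect_gte(res$mean_acc, 20 - half - 1e-9)
  expect_lte(res$mean_acc, 20 + half + 1e-9)
})

test_that("degenerate decoder inputs are rejected", {
  expect_error(fit_slr(matrix(rnorm(10), 5, 2), rep(1, 5)), "two classes")
  expect_error(fit_slr(matrix(rnorm(6), 3, 2), c(1, 1, 2)), "two samples")
  m <- fit_slr(separable_toy(40, 10, seed = 4)$x, separable_toy(40, 10)$y)
  expect_error(predict(m, matrix(0, 1, 3)), "features")
})

test_that("probabilities are proper and ties resolve to the lowest frequency", {
  # balanced constant features: uniform probabilities, argmax tie -> lowest Hz
  x <- matrix(1, 20, 3)
  y <- rep(c(8000, 10000, 13000, 16000, 32000), each = 4)
  m <- suppressMessages(fit_slr(x, y))
  pr <- predict(m, x[1:3, ], type = "prob")
  expect_equal(rowSums(pr), rep(1, 3), tolerance = 1e-12)
  expect_equal(unname(pr[1, ]), rep(0.2, 5), tolerance = 1e-3)
  expect_true(all(predict(m, x[1:2, ]) == 8000))
  # single test row
  pr1 <- predict(m, x[1, , drop = FALSE], type = "prob")
  expect_equal(sum(pr1), 1, tolerance = 1e-12)
})

test_that("run_task validates labels and reports bounded accuracies", {
  toy <- separable_toy(n = 140, p = 20, seed = 5)
  tab <- as_feature_table(toy$x, toy$y)
  res <- run_task(tab, decoding_task(c(1000, 2000)))
  expect_true(all(res$fold_label_acc >= 0 & res$fold_label_acc <= 100))
  expect_equal(dim(res$fold_label_acc), c(7, 2))
  expect_gte(res$mean_acc, 90)
  expect_error(run_task(tab, decoding_task(c(1000, 3000))), "lacks label")
  # rolling scheme on the same table
  res_r <- run_task(tab, decoding_task(c(1000, 2000)), scheme = "rolling")
  expect_equal(dim(res_r$fold_label_acc), c(3, 2))
})

test_that("frequency pairs bin into the six canonical ratio classes", {
  tasks <- two_choice_tasks(c(8000, 10000, 13000, 16000, 32000))
  pairs <- attr(tasks, "pairs")
  expect_equal(nrow(pairs), 10)
  expect_equal(length(unique(pairs$ratio_class)), 6)
  key <- function(f1, f2) pairs$ratio_class[pairs$f1 == f1 & pairs$f2 == f2]
  # adjacent pairs (~1/3 octave) share the hardest class
  expect_equal(key(8000, 10000), key(10000, 13000))
  expect_equal(key(10000, 13000), key(13000, 16000))
  # ~0.7 octave
  expect_equal(key(8000, 13000), key(10000, 16000))
  # exactly one octave
  expect_equal(key(8000, 16000), key(16000, 32000))
  # the remaining distances are singleton classes, ordered by difficulty
  expect_equal(length(unique(c(key(13000, 32000), key(10000, 32000),
                               key(8000, 32000)))), 3)
  expect_true(key(8000, 10000) < key(8000, 13000))
  expect_true(key(8000, 16000) < key(13000, 32000))

  expect_equal(nrow(attr(two_choice_tasks(c(8000, 16000, 32000)), "pairs")), 3)
  expect_equal(length(unique(attr(two_choice_tasks(c(8000, 16000, 32000)),
                                  "pairs")$ratio_class)), 2)
  expect_length(two_choice_tasks(c(8000, 16000)), 1)
  expect_error(two_choice_tasks(c(8000, 8000)), "distinct")
})
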