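test_that("masked classification loss covers observed cells only", {
  scores <- matrix(c(2, -1, 0.5, -0.5), 2, 2)
  labels <- matrix(c(1, 0, 1, 0), 2, 2)
  mask <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)
  # hand-computed cross-entropy over the 3 observed cells
  p <- stats::plogis(scores)
  hand <- -mean(c(log(p[1, 1]), log(1 - p[2, 1]), log(p[1, 2])))
  expect_equal(masked_classification_loss(scores, labels, mask), hand,
               tolerance = 1e-12)
  expect_warning(l0 <- masked_classification_loss(scores, labels, mask & FALSE),
                 "no observed")
  expect_equal(l0, 0)
})

test_that("masked regression loss is the mean squared error over observed cells", {
  expect_equal(masked_regression_loss(matrix(1), matrix(1), matrix(TRUE)), 0)
  expect_equal(masked_regression_loss(matrix(3), matrix(1), matrix(TRUE)), 4)
  set.seed(41)
  p <- matrix(rnorm(12), 4, 3)
  y <- matrix(rnorm(12), 4, 3)
  m <- matrix(runif(12) > 0.4, 4, 3)
  hand <- 0; n <- 0
  for (i in 1:4) for (j in 1:3) if (m[i, j]) { hand <- hand + (p[i, j] - y[i, j])^2; n <- n + 1 }
  expect_equal(masked_regression_loss(p, y, m), hand / n, tolerance = 1e-12)
})

test_that("losses and metrics ignore appended all-missing rows", {
  set.seed(42)
  scores <- matrix(rnorm(10), 5, 2)
  labels <- matrix(rbinom(10, 1, 0.5), 5, 2)
  mask <- matrix(TRUE, 5, 2)
  pad <- function(x, fill) rbind(x, matrix(fill, 3, 2))
  expect_identical(masked_classification_loss(pad(scores, 0), pad(labels, 1),
                                              pad(mask, FALSE)),
                   masked_classification_loss(scores, labels, mask))
  expect_identical(masked_regression_loss(pad(scores, 9), pad(labels, 9),
                                          pad(mask, FALSE)),
                   masked_regression_loss(scores, labels, mask))
  for (metric in c("roc-auc", "prc-auc", "rmse", "mae")) {
    expect_identical(evaluate(pad(scores, 0), pad(labels, 1), pad(mask, FALSE),
                              metric)$per_task,
                     evaluate(scores, labels, mask, metric)$per_task)
  }
})

test_that("evaluation metrics behave at their reference points", {
  y <- matrix(c(0, 0, 1, 1), 4, 1)
  perfect <- matrix(c(-2, -1, 1, 2), 4, 1)
  m <- matrix(TRUE, 4, 1)
  expect_equal(evaluate(perfect, y, m, "roc-auc")$aggregate, 1.0)
  expect_equal(evaluate(perfect, y, m, "prc-auc")$aggregate, 1.0)
  expect_equal(evaluate(-perfect, y, m, "roc-auc")$aggregate, 0.0)

  # random scores on balanced labels drift to 0.5
  set.seed(43)
  n <- 4000
  yb <- matrix(rep(c(0, 1), n / 2), n, 1)
  rnd <- matrix(rnorm(n), n, 1)
  expect_equal(evaluate(rnd, yb, matrix(TRUE, n, 1), "roc-auc")$aggregate, 0.5,
               tolerance = 0.05)

  # six-point toy list: step-integral average precision by hand
  ys <- c(1, 0, 1, 1, 0, 0)
  sc <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.2)
  # ranked: y = 1,0,1,1,0,0 -> precision at the positives: 1/1, 2/3, 3/4
  hand_ap <- (1 / 1 + 2 / 3 + 3 / 4) / 3
  expect_equal(evaluate(matrix(sc), matrix(ys), matrix(TRUE, 6, 1),
                        "prc-auc")$aggregate, hand_ap, tolerance = 1e-12)

  expect_equal(evaluate(matrix(c(1, 2)), matrix(c(3, 4)), matrix(TRUE, 2, 1),
                        "rmse")$aggregate, 2)
  expect_equal(evaluate(matrix(c(1, 2)), matrix(c(3, 0)), matrix(TRUE, 2, 1),
                        "mae")$aggregate, 2)
  expect_error(evaluate(matrix(1), matrix(1), matrix(TRUE), "f1"))
})

test_that("single-class tasks are excluded from the metric aggregate", {
  preds <- matrix(rnorm(8), 4, 2)
  labels <- cbind(c(0, 1, 0, 1), c(1, 1, 1, 1))
  ev <- evaluate(preds, labels, matrix(TRUE, 4, 2), "roc-auc")
  expect_true(is.na(ev$per_task[[2]]))
  expect_equal(ev$aggregate, ev$per_task[[1]])
})

test_that("training is deterministic and selects the best validation epoch", {
  smiles <- gen_molecules(40, seed = 51)
  tbl <- gen_labels(smiles, list(list(rule = "has_aromatic")), seed = 52)
  split <- random_split(40, seed = 0)
  cfg <- tiny_config("selu-mpnn", K = 1)
  cfg$learn_rate <- 5e-3
  f1 <- train_model(cfg, tbl, split, seed = 7, epochs = 6, batch_size = 16)
  f2 <- train_model(cfg, tbl, split, seed = 7, epochs = 6, batch_size = 16)
  expect_identical(f1$history, f2$history)   # epoch-by-epoch identical
  expect_identical(f1$report, f2$report)
  best <- f1$history$valid_metric[f1$best_epoch]
  expect_true(all(f1$history$valid_metric <= best))
})

test_that("training loss trends down in early epochs on a separable task", {
  smiles <- gen_molecules(40, seed = 51)
  tbl <- gen_labels(smiles, list(list(rule = "has_aromatic")), seed = 52)
  split <- random_split(40, seed = 0)
  cfg <- tiny_config("selu-mpnn", K = 1)
  cfg$learn_rate <- 5e-3
  fit <- train_model(cfg, tbl, split, seed = 7, epochs = 10, batch_size = 16)
  first <- mean(fit$history$train_loss[1:3])
  last <- mean(fit$history$train_loss[8:10])
  expect_lt(last, first)
})

test_that("regression metrics are reported in original units", {
  smiles <- gen_molecules(40, seed = 53)
  tbl <- gen_labels(smiles, list(list(rule = "n_atoms")),
                    task_kind = "regression", seed = 54)
  split <- random_split(40, seed = 1)
  cfg <- tiny_config("selu-mpnn", K = 1)
  cfg$learn_rate <- 5e-3
  fit <- train_model(cfg, tbl, split, seed = 3, epochs = 4, batch_size = 16,
                     metric = "rmse")
  # recompute the test RMSE directly in original units from predictions
  preds <- predict(fit, tbl$smiles[split$test])
  direct <- sqrt(mean((preds - tbl$labels[split$test, , drop = FALSE])^2))
  expect_equal(fit$report$test$aggregate, direct, tolerance = 1e-8)
})

test_that("the three-repeat protocol handles both split modes", {
  smiles <- gen_molecules(30, seed = 55, scaffold_diversity = 8)
  tbl <- gen_labels(smiles, list(list(rule = "n_atoms")),
                    task_kind = "regression", seed = 56)
  cfg <- tiny_config("selu-mpnn", K = 1)
  cfg$learn_rate <- 5e-3

  rep_r <- repeat_protocol(cfg, tbl, "random", epochs = 2, batch_size = 16,
                           metric = "rmse")
  tests <- lapply(rep_r$splits, `[[`, "test")
  expect_false(identical(tests[[1]], tests[[2]]))  # distinct memberships
  expect_length(rep_r$repeats, 3)
  expect_true(is.finite(rep_r$summary$sd))

  rep_s <- repeat_protocol(cfg, tbl, "scaffold", epochs = 2, batch_size = 16,
                           metric = "rmse")
  expect_identical(rep_s$splits[[1]], rep_s$splits[[2]])  # one membership
  expect_identical(rep_s$splits[[2]], rep_s$splits[[3]])

  # identical repeats forced by a shared weight seed: zero spread
  rep_0 <- repeat_protocol(cfg, tbl, "scaffold", seeds = c(4L, 4L, 4L),
                           epochs = 2, batch_size = 16, metric = "rmse")
  expect_equal(rep_0$summary$sd, 0)
})
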