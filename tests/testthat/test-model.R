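make_table <- function(n = 120, p = 4, seed = 1) {
  set.seed(seed)
  X <- as.data.frame(matrix(rnorm(n * p), n, p))
  names(X) <- paste0("v", seq_len(p))
  X
}

test_that("m defaults to floor(sqrt(p)) and importance is scaled to 1", {
  X <- make_table(p = 18)
  y <- ifelse(X$v1 > 0, "A", "B")
  fit <- train_rf(X, y, rf_config(ntree = 25, seed = 1))
  expect_equal(fit$m, 4L) # floor(sqrt(18))
  expect_equal(max(fit$importance$scaled), 1)
  X2 <- make_table(p = 2)
  fit2 <- train_rf(X2, ifelse(X2$v1 > 0, "A", "B"), rf_config(ntree = 10))
  expect_equal(fit2$m, 1L)
})

test_that("a single decisive variable dominates the importance ranking", {
  for (seed in 1:10) {
    X <- make_table(n = 150, p = 5, seed = seed)
    y <- ifelse(X$v3 > 0, "A", "B") # label depends on v3 only
    fit <- train_rf(X, y, rf_config(ntree = 50, seed = seed))
    expect_equal(fit$importance$variable[1], "v3")
    expect_equal(fit$importance$scaled[1], 1)
    expect_true(all(fit$importance$scaled[-1] < 0.2))
  }
})

test_that("permutation importance also singles out the decisive variable", {
  X <- make_table(n = 150, p = 5, seed = 2)
  y <- ifelse(X$v3 > 0, "A", "B")
  fit <- train_rf(X, y, rf_config(ntree = 40, seed = 2),
                  importance = "permutation")
  expect_equal(fit$importance$variable[1], "v3")
  expect_equal(fit$importance$scaled[1], 1)
  expect_true(all(fit$importance$scaled[-1] < 0.2))
})

test_that("training is deterministic under (seed, cfg) and refuses one class", {
  X <- make_table()
  y <- ifelse(X$v1 + X$v2 > 0, "A", "B")
  f1 <- train_rf(X, y, rf_config(ntree = 20, seed = 42))
  f2 <- train_rf(X, y, rf_config(ntree = 20, seed = 42))
  expect_identical(f1$importance, f2$importance)
  expect_identical(predict(f1, X), predict(f2, X))
  expect_error(train_rf(X, rep("A", nrow(X))), "2 classes")
  Xna <- X; Xna$v1[3] <- NA
  expect_error(train_rf(Xna, y), "missing")
})

test_that("select_features walks the two addition rules", {
  mk <- function(s) data.frame(variable = paste0("v", seq_along(s)), scaled = s)
  # spec trace: two leaders, then a triple within a 0.2 spread; 0.05 is at
  # the negligibility floor and never added
  out <- select_features(mk(c(1.0, 1.0, 0.55, 0.50, 0.45, 0.05)))
  expect_equal(out, list(c("v1", "v2"), c("v1", "v2", "v3", "v4", "v5")))
  # simple pair
  out2 <- select_features(mk(c(1.0, 0.7)))
  expect_equal(out2, list("v1", c("v1", "v2")))
  # rule 2: gap of 0.3 >= 0.2 splits the addition
  out3 <- select_features(mk(c(1.0, 0.6, 0.3)))
  expect_equal(out3, list("v1", c("v1", "v2"), c("v1", "v2", "v3")))
  # subsets strictly nested, union = all considered variables
  out4 <- select_features(mk(c(1.0, 0.9, 0.85, 0.8, 0.75, 0.7, 0.2)))
  for (i in seq_along(out4)[-1])
    expect_true(all(out4[[i - 1]] %in% out4[[i]]))
  expect_setequal(out4[[length(out4)]], paste0("v", 1:7))
})

test_that("run_model separates a separable problem and guards its inputs", {
  X <- make_table(n = 200, p = 3, seed = 2)
  y <- ifelse(X$v1 > 0, "MB", "NVB")
  split <- rep(c("train", "test"), each = 100)
  run <- run_model(X, y, split, c("v1", "v2"), rf_config(ntree = 30, seed = 1))
  expect_equal(run$stats$overall_accuracy, 100)
  expect_equal(run$stats$kappa, 1)
  expect_length(run$predictions, 100L)
  expect_error(run_model(X, y, split, character(0)), "empty")
  expect_warning(run2 <- run_model(X, y, split, c("v1", "v1"), rf_config(ntree = 5)),
                 "dedup")
  expect_equal(run2$subset, "v1")
  expect_error(run_model(X, y, split, "nope", rf_config(ntree = 5)), "nope")
})

test_that("predict_map votes per pixel and propagates nodata", {
  # two-layer stack, label decided by layer a
  set.seed(8)
  a <- grid_of(matrix(rnorm(64), 8, 8))
  b <- grid_of(matrix(rnorm(64), 8, 8))
  st <- stack_layers(a = a, b = b)
  df <- data.frame(a = as.numeric(a$values), b = as.numeric(b$values))
  y <- ifelse(df$a > 0, "INV", "MB")
  fit <- train_rf(df, y, rf_config(ntree = 30, seed = 3))
  map <- predict_map(fit, st)
  pred <- fit$classes[map$values]
  expect_equal(pred[!is.na(pred)], y[!is.na(pred)])
  # nodata in one layer -> nodata prediction
  a2 <- a; a2$values[2, 2] <- NA
  map2 <- predict_map(fit, stack_layers(a = a2, b = b))
  expect_true(is.na(map2$values[2, 2]))
  expect_error(predict_map(fit, stack_layers(a = a)), "missing layer")
})

test_that("training-point predictions are consistent on separable data", {
  X <- make_table(n = 150, p = 2, seed = 4)
  y <- ifelse(X$v1 > 0.2, "A", ifelse(X$v1 < -0.2, "B", "C"))
  fit <- train_rf(X, y, rf_config(ntree = 40, seed = 9))
  expect_equal(predict(fit, X), y)
})
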