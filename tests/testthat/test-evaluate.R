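test_that("error_matrix counts predicted x reference and validates labels", {
  em <- error_matrix(rep(c("A", "B"), each = 10), rep(c("A", "B"), each = 10))
  expect_equal(em$counts, matrix(c(10L, 0L, 0L, 10L), 2, 2,
                                 dimnames = list(predicted = c("A", "B"),
                                                 reference = c("A", "B"))))
  # degenerate predictor
  em2 <- error_matrix(rep("A", 10), rep(c("A", "B"), 5), classes = c("A", "B"))
  expect_equal(em2$counts["A", ], c(A = 5L, B = 5L))
  expect_equal(em2$counts["B", ], c(A = 0L, B = 0L))
  # column sums = reference class counts
  set.seed(1)
  pred <- sample(c("A", "B", "C"), 60, TRUE)
  ref <- sample(c("A", "B", "C"), 60, TRUE)
  em3 <- error_matrix(pred, ref)
  expect_equal(colSums(em3$counts), c(table(ref)[em3$classes]))
  expect_error(error_matrix("Z", "A", classes = c("A", "B")), "vocabulary")
  expect_error(error_matrix(c("A", "B"), "A"), "equal length")
})

test_that("accuracy_stats matches definitions and the kappa oracle", {
  em <- error_matrix(rep(c("A", "B"), each = 10), rep(c("A", "B"), each = 10))
  st <- accuracy_stats(em)
  expect_equal(st$overall_accuracy, 100)
  expect_equal(st$kappa, 1)
  # observed agreement equal to chance agreement -> kappa 0
  chance <- structure(list(counts = matrix(c(4L, 1L, 4L, 1L), 2, 2),
                           classes = c("A", "B"), N = 10L),
                      class = "ErrorMatrix")
  expect_equal(accuracy_stats(chance)$kappa, 0)
  # toy matrix with hand-computed sums
  toy <- structure(list(counts = matrix(c(65L, 3L, 4L, 28L), 2, 2),
                        classes = c("A", "B"), N = 100L),
                   class = "ErrorMatrix")
  st_toy <- accuracy_stats(toy)
  expect_equal(st_toy$overall_accuracy, 93)
  o <- kappa_oracle(toy$counts)
  expect_equal(st_toy$kappa, o$kappa, tolerance = 1e-12)
  expect_equal(st_toy$kappa_variance, o$variance, tolerance = 1e-12)
  # per-class user's/producer's and their mean
  expect_equal(st_toy$per_class$users, 100 * c(65 / 69, 28 / 31))
  expect_equal(st_toy$per_class$producers, 100 * c(65 / 68, 28 / 32))
  expect_equal(st_toy$per_class$mean,
               (st_toy$per_class$users + st_toy$per_class$producers) / 2)
  # empty column -> producer's accuracy undefined
  em4 <- error_matrix(c("A", "A"), c("A", "A"), classes = c("A", "B"))
  expect_true(is.na(accuracy_stats(em4)$per_class$producers[2]))
})

test_that("OA and kappa are invariant under class permutation", {
  set.seed(3)
  pred <- sample(c("A", "B", "C"), 90, TRUE)
  ref <- sample(c("A", "B", "C"), 90, TRUE)
  st1 <- accuracy_stats(error_matrix(pred, ref, classes = c("A", "B", "C")))
  st2 <- accuracy_stats(error_matrix(pred, ref, classes = c("C", "A", "B")))
  expect_equal(st1$overall_accuracy, st2$overall_accuracy)
  expect_equal(st1$kappa, st2$kappa, tolerance = 1e-12)
})

test_that("z_test is symmetric, zero for identical matrices, huge for extremes", {
  set.seed(4)
  em_a <- random_error_matrix(3)
  em_b <- random_error_matrix(4)
  expect_equal(z_test(em_a, em_a)$z, 0)
  expect_false(z_test(em_a, em_a)$significant)
  expect_equal(z_test(em_a, em_b)$z, z_test(em_b, em_a)$z)
  # kappa 1 vs kappa 0 at large N
  perfect <- error_matrix(rep(c("A", "B"), each = 500),
                          rep(c("A", "B"), each = 500))
  chance <- error_matrix(rep(c("A", "B"), 500),
                         rep(c("A", "A", "B", "B"), 250))
  zt <- z_test(perfect, chance)
  expect_true(zt$significant)
  expect_gt(zt$z, 1.96)
  # zero variance in both -> undefined with a warning
  degen <- structure(list(counts = matrix(c(5L, 0L, 0L, 0L), 2, 2),
                          classes = c("A", "B"), N = 5L), class = "ErrorMatrix")
  expect_warning(zu <- z_test(degen, degen), "undefined|variance")
  expect_true(is.na(zu$z))
})

test_that("layer_correlation computes pairwise R^2 with nodata exclusion", {
  set.seed(11)
  n <- 100
  a <- grid_of(matrix(rnorm(n * n), n, n))
  b <- with_values(a, -a$values)
  noise <- with_values(a, matrix(rnorm(n * n), n, n))
  st <- stack_layers(a = a, neg = b, noise = noise)
  lc <- layer_correlation(st)
  expect_equal(diag(lc$r2), c(a = 1, neg = 1, noise = 1))
  expect_equal(lc$r2["a", "neg"], 1, tolerance = 1e-12) # R^2 kills sign
  expect_lt(lc$r2["a", "noise"], 0.01)                  # 1e4 independent px
  expect_true(lc$flagged["a", "neg"])
  expect_false(lc$flagged["a", "noise"])
  # nodata excluded pairwise
  a$values[1, 1] <- NA
  lc2 <- layer_correlation(stack_layers(a = a, neg = b))
  expect_equal(lc2$r2["a", "neg"], 1, tolerance = 1e-12)
  # constant layer undefined and warned about
  flat <- with_values(b, matrix(3, n, n))
  expect_warning(lc3 <- layer_correlation(stack_layers(a = a, flat = flat)),
                 "constant")
  expect_true(is.na(lc3$r2["a", "flat"]))
  expect_error(layer_correlation(stack_layers(a = a)), "2 layers")
})

test_that("write_evaluation_reports emits the full CSV report set", {
  X <- data.frame(v1 = rnorm(80), v2 = rnorm(80))
  y <- ifelse(X$v1 > 0, "MB", "NVB")
  split <- rep(c("train", "test"), 40)
  runs <- list(
    m1 = run_model(X, y, split, "v1", rf_config(ntree = 10, seed = 1)),
    m2 = run_model(X, y, split, c("v1", "v2"), rf_config(ntree = 10, seed = 1)))
  dir <- withr::local_tempdir()
  files <- write_evaluation_reports(runs, dir)
  expect_true(file.exists(file.path(dir, "accuracy_summary.csv")))
  expect_true(file.exists(file.path(dir, "error_matrix_m1.csv")))
  expect_true(file.exists(file.path(dir, "pairwise_z.csv")))
  summ <- read.csv(file.path(dir, "accuracy_summary.csv"))
  expect_equal(summ$model, c("m1", "m2"))
  expect_true(all(summ$overall_accuracy >= 0 & summ$overall_accuracy <= 100))
})
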