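test_that("euclidean distance: examples, symmetry, triangle inequality", {
  expect_equal(euclidean_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(euclidean_distance(c(0, 0), c(3, 4)), 5)
  expect_error(euclidean_distance(1:3, 1:4), class = "dermoknn_shape_error")
  set.seed(401)
  for (rep in 1:50) {
    a <- rnorm(6); b <- rnorm(6); cc <- rnorm(6)
    expect_identical(euclidean_distance(a, b), euclidean_distance(b, a))
    expect_lte(euclidean_distance(a, cc),
               euclidean_distance(a, b) + euclidean_distance(b, cc) + 1e-12)
  }
})

test_that("standardization is fitted on training rows; refit is a no-op", {
  set.seed(402)
  X <- matrix(rnorm(40 * 5, mean = 10, sd = 4), 40, 5)
  colnames(X) <- paste0("f", 1:5)
  m <- knn_fit(X, rep(c(0L, 1L), 20), k = 3)
  m2 <- knn_fit(m$train, m$labels, k = 3)
  expect_true(all(abs(m2$center) < 1e-9))
  expect_true(all(abs(m2$scale - 1) < 1e-9))

  Xc <- cbind(X, constant = 7)
  expect_warning(mc <- knn_fit(Xc, rep(c(0L, 1L), 20), k = 3), "constant")
  expect_identical(unname(mc$scale["constant"]), 1)
})

test_that("single-point and memorization behaviors of 1-NN", {
  X <- matrix(c(0, 0, 5, 5, 9, 1), 3, 2, byrow = TRUE)
  colnames(X) <- c("a", "b")
  m <- knn_fit(X, c(0L, 1L, 0L), k = 1)
  expect_identical(predict(m, X)$.pred_label, c(0L, 1L, 0L))

  expect_warning(
    lone <- knn_fit(matrix(c(1, 2), 1, 2, dimnames = list(NULL, c("a", "b"))),
                    1L, k = 1),
    "constant")
  expect_identical(predict(lone, c(a = 50, b = -3))$.pred_label, 1L)
  expect_identical(predict(lone, c(a = 50, b = -3))$.pred_class, "melanoma")
})

test_that("predictions agree with the exhaustive-sort oracle on random instances", {
  set.seed(403)
  for (rep in 1:50) {
    n <- sample(5:50, 1); d <- sample(2:8, 1)
    k <- sample(c(1, 3, 5, 7, 9)[c(1, 3, 5, 7, 9) <= n], 1)
    X <- matrix(rnorm(n * d), n, d, dimnames = list(NULL, paste0("f", 1:d)))
    y <- sample(0:1, n, TRUE)
    if (length(unique(y)) == 1) y[1] <- 1 - y[1]
    m <- knn_fit(X, y, k = k, standardize = FALSE)
    x <- rnorm(d); names(x) <- paste0("f", 1:d)
    expect_identical(predict(m, x)$.pred_label,
                     bf_knn_predict(X, y, x, k))
  }
})

test_that("prediction is invariant to training-row permutation (no ties)", {
  set.seed(404)
  X <- matrix(rnorm(30 * 4), 30, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- sample(0:1, 30, TRUE)
  m1 <- knn_fit(X, y, k = 5)
  perm <- sample(30)
  m2 <- knn_fit(X[perm, ], y[perm], k = 5)
  Xt <- matrix(rnorm(10 * 4), 10, 4, dimnames = list(NULL, paste0("f", 1:4)))
  expect_identical(predict(m1, Xt)$.pred_label, predict(m2, Xt)$.pred_label)
})

test_that("accuracy-plot K selection: separable case and independent LOO oracle", {
  set.seed(405)
  X <- rbind(matrix(rnorm(40, 0, 1), 20, 2), matrix(rnorm(40, 20, 1), 20, 2))
  colnames(X) <- c("a", "b")
  y <- rep(c(0L, 1L), each = 20)
  sel <- select_k(X, y)
  expect_identical(sel$k, 1L)                       # smallest k on all-equal tie
  expect_true(all(sel$curve$accuracy == 1))

  for (rep in 1:5) {
    Xr <- matrix(rnorm(26 * 3), 26, 3, dimnames = list(NULL, c("a", "b", "c")))
    yr <- sample(0:1, 26, TRUE); yr[1:2] <- 0:1
    grid <- c(1L, 3L, 5L, 7L)
    sel <- select_k(Xr, yr, k_grid = grid)
    oracle <- bf_loo_select(Xr, yr, grid)
    expect_identical(sel$k, oracle$k)
    expect_equal(sel$curve$accuracy, oracle$accuracy)
    expect_true(all(sel$curve$accuracy >= 0 & sel$curve$accuracy <= 1))
  }
  expect_error(select_k(X, y, k_grid = integer()), class = "dermoknn_validation_error")
  expect_error(select_k(X, y, k_grid = 40L), class = "dermoknn_validation_error")
})

test_that("LOO at k = n - 1 equals the majority-class rate under class imbalance", {
  set.seed(406)
  X <- matrix(rnorm(80 * 3), 80, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- sample(rep(c(0L, 1L), c(50, 30)))            # labels independent of X
  sel <- select_k(X, y, k_grid = 79L)
  # every left-out point is outvoted unless it belongs to the majority class
  expect_equal(sel$curve$accuracy, 50 / 80)
})

test_that("evaluation metrics follow the confusion-matrix arithmetic", {
  # k = 1 on a memorized grid: truth flips create exactly TP 9, FN 1, TN 10
  X <- matrix(seq_len(20) * 10, 20, 1, dimnames = list(NULL, "f"))
  train_y <- rep(c(1L, 0L), c(9, 11))
  m <- knn_fit(X, train_y, k = 1)
  truth <- rep(c(1L, 0L), c(10, 10))                # row 10 is a false negative
  ev <- knn_evaluate(m, X, truth)
  expect_equal(ev$sensitivity, 0.9)
  expect_equal(ev$specificity, 1.0)
  expect_equal(ev$accuracy, 0.95)
  expect_identical(as.vector(ev$confusion), c(10L, 1L, 0L, 9L))

  set.seed(407)
  Xr <- matrix(rnorm(40 * 2), 40, 2, dimnames = list(NULL, c("a", "b")))
  yr <- sample(0:1, 40, TRUE); yr[1:2] <- 0:1
  mr <- knn_fit(Xr[1:30, ], yr[1:30], k = 3)
  evr <- knn_evaluate(mr, Xr[31:40, ], yr[31:40])
  P <- sum(yr[31:40] == 1); N <- 10 - P
  expect_equal(evr$accuracy, (evr$sensitivity * P + evr$specificity * N) / 10)
  expect_error(knn_evaluate(mr, Xr[31:40, ], rep(2L, 10)),
               class = "dermoknn_validation_error")
})

test_that("model JSON round trip predicts bit-identically", {
  set.seed(408)
  X <- matrix(rnorm(30 * 17), 30, 17, dimnames = list(NULL, feature_names()))
  y <- sample(0:1, 30, TRUE); y[1:2] <- 0:1
  m <- knn_fit(X, y, k = 5)
  path <- withr::local_tempfile(fileext = ".json")
  write_knn_model(m, path)
  m2 <- read_knn_model(path)
  Xt <- matrix(rnorm(8 * 17), 8, 17, dimnames = list(NULL, feature_names()))
  expect_identical(predict(m, Xt), predict(m2, Xt))
  expect_identical(m2$k, m$k)
  expect_identical(m2$feature_order, m$feature_order)
})

test_that("tidy and glance summaries expose the model and evaluation state", {
  set.seed(409)
  X <- matrix(rnorm(20 * 3), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rep(c(0L, 1L), 10)
  m <- knn_fit(X, y, k = 3)
  td <- tidy(m)
  expect_identical(td$feature, c("a", "b", "c"))
  expect_identical(names(td), c("feature", "center", "scale"))
  gl <- glance(m)
  expect_identical(gl$k, 3L); expect_identical(gl$n_train, 20L)
  ev <- knn_evaluate(m, X, y)
  expect_identical(tidy(ev)$metric, c("accuracy", "sensitivity", "specificity"))
})
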