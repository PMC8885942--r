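# K-nearest-neighbor classification of lesion feature vectors.
#
# Features are z-scored with center/scale fitted on the training rows only
# (raw features span pixels ~1e3 down to indices ~1, so unstandardized
# Euclidean distance would be dominated by area). K is chosen by the
# "accuracy plot": leave-one-out accuracy over a grid of odd k.

as_feature_matrix <- function(x, feature_order = NULL) {
  if (is.data.frame(x)) {
    if (!is.null(feature_order)) {
      missing_cols <- setdiff(feature_order, names(x))
      if (length(missing_cols)) {
        abort(paste0("feature columns missing: ", paste(missing_cols, collapse = ", ")))
      }
      x <- x[, feature_order, drop = FALSE]
    } else {
      x <- x[, vapply(x, is.numeric, logical(1)), drop = FALSE]
    }
    x <- as.matrix(x)
  } else if (is.numeric(x) && is.null(dim(x))) {
    x <- matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
  }
  storage.mode(x) <- "double"
  x
}

check_labels <- function(labels, n) {
  labels <- as.integer(labels)
  if (length(labels) != n) abort("`labels` must have one entry per feature row")
  if (!all(labels %in% c(0L, 1L))) {
    abort("labels must be 0 (normal) or 1 (melanoma)",
          class = "dermoknn_validation_error")
  }
  labels
}

#' Euclidean distance between two feature points
#'
#' @param a,b Numeric vectors of equal length.
#' @return `sqrt(sum((a - b)^2))`.
#' @export
euclidean_distance <- function(a, b) {
  if (length(a) != length(b)) {
    abort("`a` and `b` must have the same dimension", class = "dermoknn_shape_error")
  }
  sqrt(sum((a - b)^2))
}

#' Fit a KNN lesion classifier
#'
#' Stores the training rows standardized by per-feature center (mean) and
#' scale (population standard deviation) fitted on the training data only.
#' Constant features get scale 1 with a warning. If `k` is not given it is
#' chosen by [select_k()].
#'
#' @param features Numeric matrix or data frame, one row per training case.
#' @param labels Class labels in `{0, 1}` (1 = melanoma).
#' @param k Number of neighbors; odd values avoid vote ties. `NULL` selects
#'   it by leave-one-out accuracy.
#' @param k_grid Candidate k values for selection (see [select_k()]).
#' @param standardize Set `FALSE` to use raw feature distances.
#' @return An object of class `knn_model`.
#' @export
knn_fit <- function(features, labels, k = NULL, k_grid = NULL, standardize = TRUE) {
  X <- as_feature_matrix(features)
  n <- nrow(X)
  if (n < 1L) abort("need at least one training row")
  labels <- check_labels(labels, n)
  if (standardize) {
    center <- colMeans(X)
    scale <- apply(X, 2, pop_sd)
    if (any(scale == 0)) {
      warn(paste0("constant training features (scale set to 1): ",
                  paste(colnames(X)[scale == 0], collapse = ", ")))
      scale[scale == 0] <- 1
    }
  } else {
    center <- rep(0, ncol(X)); scale <- rep(1, ncol(X))
    names(center) <- names(scale) <- colnames(X)
  }
  Xs <- sweep(sweep(X, 2, center), 2, scale, "/")
  selection <- NULL
  if (is.null(k)) {
    if (n >= 2L) {
      selection <- select_k(features, labels, k_grid = k_grid,
                            standardize = standardize)
      k <- selection$k
    } else {
      k <- 1L
    }
  }
  k <- as.integer(k)
  if (k < 1L || k > n) abort("`k` must lie in [1, n]",
                             class = "dermoknn_validation_error")
  structure(
    list(train = Xs, labels = labels, center = center, scale = scale,
         k = k, feature_order = colnames(X), standardize = standardize,
         selection = selection, version = 1L),
    class = "knn_model")
}

# Majority vote among the k nearest rows; distance ties at the k-th neighbor
# are admitted by ascending training-row index (stable order), and a 50/50
# vote (possible only for even k) falls back to the single nearest neighbor.
knn_vote <- function(d, labels, k) {
  ord <- order(d, seq_along(d))
  nb <- ord[seq_len(k)]
  votes1 <- sum(labels[nb] == 1L)
  pred <- if (2L * votes1 > k) 1L
  else if (2L * votes1 < k) 0L
  else labels[nb[1L]]
  list(pred = pred,
       vote_fraction = max(votes1, k - votes1) / k,
       neighbors = nb)
}

#' Predict lesion class for new feature rows
#'
#' @param object A [knn_fit()] model.
#' @param new_data Numeric vector (one case) or matrix/data frame of raw
#'   (unstandardized) feature rows with the model's feature columns.
#' @param ... Unused.
#' @return A tibble with one row per case: `.pred_label`, `.pred_class`
#'   (`"normal"`/`"melanoma"`), `.vote_fraction` and list-column
#'   `.neighbors` (training-row indices of the voting neighbors).
#' @export
predict.knn_model <- function(object, new_data, ...) {
  X <- as_feature_matrix(new_data, feature_order = object$feature_order)
  if (ncol(X) != ncol(object$train)) {
    abort("new data dimension does not match the model",
          class = "dermoknn_shape_error")
  }
  Xs <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  res <- purrr::map(seq_len(nrow(Xs)), function(i) {
    d <- sqrt(rowSums(sweep(object$train, 2, Xs[i, ])^2))
    knn_vote(d, object$labels, object$k)
  })
  tibble(
    .pred_label = vapply(res, function(r) r$pred, integer(1)),
    .pred_class = ifelse(vapply(res, function(r) r$pred, integer(1)) == 1L,
                         "melanoma", "normal"),
    .vote_fraction = vapply(res, function(r) r$vote_fraction, numeric(1)),
    .neighbors = purrr::map(res, "neighbors")
  )
}

#' Choose K by the accuracy plot (leave-one-out)
#'
#' Computes leave-one-out accuracy for every k in the grid and returns the
#' maximizer (smallest k on ties) together with the full accuracy curve for
#' plotting. The feature scaler is fitted once on the full training set and
#' the LOO loop runs over the standardized rows.
#'
#' @param features,labels Training data as in [knn_fit()].
#' @param k_grid Candidate k values; default odd values `1, 3, ..,
#'   min(15, n - 1)`.
#' @param standardize As in [knn_fit()].
#' @return Object of class `knn_k_selection`: list with `k`, `curve`
#'   (tibble of `k`, `accuracy`) and `n`.
#' @export
select_k <- function(features, labels, k_grid = NULL, standardize = TRUE) {
  X <- as_feature_matrix(features)
  n <- nrow(X)
  if (n < 2L) abort("K selection needs at least 2 training rows")
  labels <- check_labels(labels, n)
  if (is.null(k_grid)) k_grid <- seq(1L, min(15L, n - 1L), by = 2L)
  k_grid <- as.integer(k_grid)
  if (length(k_grid) == 0L) abort("`k_grid` must not be empty",
                                  class = "dermoknn_validation_error")
  if (any(k_grid < 1L) || any(k_grid > n - 1L)) {
    abort("`k_grid` values must lie in [1, n - 1]",
          class = "dermoknn_validation_error")
  }
  if (standardize) {
    center <- colMeans(X)
    scale <- apply(X, 2, pop_sd); scale[scale == 0] <- 1
    X <- sweep(sweep(X, 2, center), 2, scale, "/")
  }
  D <- as.matrix(stats::dist(X))
  acc <- vapply(k_grid, function(k) {
    correct <- vapply(seq_len(n), function(i) {
      d <- D[i, ]; d[i] <- Inf
      knn_vote(d, labels, k)$pred == labels[i]
    }, logical(1))
    mean(correct)
  }, numeric(1))
  best <- k_grid[which.max(acc)]   # which.max takes the first (smallest k) tie
  structure(list(k = best, curve = tibble(k = k_grid, accuracy = acc), n = n),
            class = "knn_k_selection")
}

#' Evaluate a fitted model on labeled test cases
#'
#' Melanoma (label 1) is the positive class: sensitivity = TP / (TP + FN),
#' specificity = TN / (TN + FP). The confusion matrix has truth in rows
#' (0 then 1) and prediction in columns.
#'
#' @param model A `knn_model`.
#' @param test_features,test_labels Test data, raw feature scale.
#' @return Object of class `knn_evaluation`: accuracy, sensitivity,
#'   specificity, confusion matrix and n.
#' @export
knn_evaluate <- function(model, test_features, test_labels) {
  X <- as_feature_matrix(test_features, feature_order = model$feature_order)
  n <- nrow(X)
  if (n < 1L) abort("test set must be non-empty")
  test_labels <- check_labels(test_labels, n)
  pred <- predict(model, X)$.pred_label
  cm <- table(factor(test_labels, levels = c(0, 1)),
              factor(pred, levels = c(0, 1)))
  dimnames(cm) <- list(truth = c("0", "1"), prediction = c("0", "1"))
  tn <- cm[1, 1]; fp <- cm[1, 2]; fn <- cm[2, 1]; tp <- cm[2, 2]
  structure(
    list(accuracy = (tp + tn) / n,
         sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
         specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
         confusion = cm, n = n),
    class = "knn_evaluation")
}

#' @export
tidy.knn_model <- function(x, ...) {
  tibble(feature = x$feature_order, center = unname(x$center),
         scale = unname(x$scale))
}

#' @export
glance.knn_model <- function(x, ...) {
  tibble(k = x$k, n_train = nrow(x$train), n_features = ncol(x$train),
         standardize = x$standardize,
         n_melanoma = sum(x$labels == 1L), n_normal = sum(x$labels == 0L))
}

#' @export
tidy.knn_evaluation <- function(x, ...) {
  tibble(metric = c("accuracy", "sensitivity", "specificity"),
         value = c(x$accuracy, x$sensitivity, x$specificity))
}

#' @export
glance.knn_evaluation <- function(x, ...) {
  tibble(accuracy = x$accuracy, sensitivity = x$sensitivity,
         specificity = x$specificity, n_test = x$n)
}

#' @export
tidy.knn_k_selection <- function(x, ...) x$curve

#' @export
print.knn_model <- function(x, ...) {
  cat(sprintf("KNN lesion classifier: n = %d, d = %d, k = %d%s\n",
              nrow(x$train), ncol(x$train), x$k,
              if (x$standardize) " (z-scored features)" else ""))
  invisible(x)
}

#' Serialize a KNN model to versioned JSON
#'
#' The file stores `format`, `version`, `feature_order`, `standardize`,
#' `center`, `scale`, `labels`, `k` and the standardized training matrix as a
#' row-major list, all at full double precision, so a reloaded model predicts
#' bit-identically.
#'
#' @param model A `knn_model`.
#' @param path Output path (conventionally `.json`).
#' @return `path`, invisibly.
#' @export
write_knn_model <- function(model, path) {
  payload <- list(
    format = "dermoknn_knn_model",
    version = model$version,
    feature_order = model$feature_order,
    standardize = model$standardize,
    k = model$k,
    center = as.list(model$center),
    scale = as.list(model$scale),
    labels = model$labels,
    train = lapply(seq_len(nrow(model$train)),
                   function(i) unname(model$train[i, ]))
  )
  # digits = I(17): enough decimal digits to reproduce every double exactly
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Load a KNN model written by [write_knn_model()]
#'
#' @param path Path to the JSON model file.
#' @return A `knn_model`.
#' @export
read_knn_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "dermoknn_knn_model")) {
    abort(sprintf("'%s' is not a dermoknn model file", path),
          class = "dermoknn_io_error")
  }
  train <- if (is.matrix(p$train)) p$train else do.call(rbind, p$train)
  dimnames(train) <- list(NULL, p$feature_order)
  structure(
    list(train = train, labels = as.integer(p$labels),
         center = unlist(p$center), scale = unlist(p$scale),
         k = as.integer(p$k), feature_order = p$feature_order,
         standardize = isTRUE(p$standardize), selection = NULL,
         version = as.integer(p$version)),
    class = "knn_model")
}
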