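#' Classifier configuration
#'
#' Collects the hyperparameters of the cotton-pixel SVM and the feature
#' selection / split procedure that surround it.
#'
#' @param C SVM soft-margin cost (default 1.0).
#' @param gamma RBF bandwidth: `"scale"` (default) for
#'   `1 / (n_features * Var(X))` where `Var(X)` is the variance of all
#'   entries of the training feature matrix, or a positive number.
#' @param selected_k Number of color features kept by recursive feature
#'   elimination (default 4).
#' @param split_ratio Train:test ratio as a length-2 numeric (default
#'   `c(4, 1)`).
#' @param seed Integer seed governing the split, the random-forest
#'   estimator and the probability calibration.
#' @param rf_trees Trees in the random-forest importance estimator
#'   (default 100).
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(C = 1.0, gamma = "scale", selected_k = 4L,
                              split_ratio = c(4, 1), seed = 1L,
                              rf_trees = 100L) {
  if (!is_scalar_number(C) || C <= 0) stop_validation("C must be positive")
  if (!(identical(gamma, "scale") || (is_scalar_number(gamma) && gamma > 0)))
    stop_validation("gamma must be \"scale\" or a positive number")
  if (length(split_ratio) != 2L || any(split_ratio <= 0))
    stop_validation("split_ratio parts must be positive")
  structure(list(C = C, gamma = gamma, selected_k = as.integer(selected_k),
                 split_ratio = as.numeric(split_ratio), seed = as.integer(seed),
                 rf_trees = as.integer(rf_trees)),
            class = "classifier_config")
}

#' Split a labeled feature table into training and test subsets
#'
#' A uniform (unstratified) shuffle governed by `seed`; the training set
#' takes `floor(N * train_fraction)` rows and the test set the remainder,
#' so the two are disjoint and exhaustive.
#'
#' @param table A labeled pixel feature table (see [extract_features()]).
#' @param ratio Train:test ratio, length-2 numeric (default `c(4, 1)`).
#' @param seed Integer seed.
#' @return A list with tibbles `train` and `test`.
#' @export
split_dataset <- function(table, ratio = c(4, 1), seed = 1L) {
  n <- nrow(table)
  if (n == 0L) stop_validation("cannot split an empty table")
  if (length(ratio) != 2L || any(ratio <= 0))
    stop_validation("ratio parts must be positive")
  n_train <- floor(n * ratio[1] / sum(ratio))
  perm <- withr::with_seed(seed, sample.int(n))
  list(train = table[sort(perm[seq_len(n_train)]), , drop = FALSE],
       test = table[sort(perm[setdiff(seq_len(n), seq_len(n_train))]), , drop = FALSE])
}

#' Recursive feature elimination over the nine color channels
#'
#' Starting from the candidate set R, G, B, H, S, V, L*, a*, b*, fits a
#' random-forest classifier at each round, drops the feature with the
#' lowest impurity-based importance, and repeats until `k` features
#' remain. Pixel coordinates are never candidates.
#'
#' @param train Labeled feature table.
#' @param k Number of features to keep (default 4).
#' @param seed Integer seed for the forest.
#' @param n_trees Trees per forest fit (default 100).
#' @return A `feature_selection` object: `selected` (feature names ordered
#'   by final importance, descending), `importance` (tibble over all
#'   candidates with the round each was eliminated; `NA` = survived) and
#'   `n_rounds`.
#' @export
select_features <- function(train, k = 4L, seed = 1L, n_trees = 100L) {
  candidates <- intersect(feature_columns, names(train))
  if (is.null(train$label)) stop_validation("training table must carry a 'label' column")
  if (k > length(candidates))
    stop_validation(sprintf("k = %d exceeds the %d candidate features", k, length(candidates)))
  y <- factor(train$label, levels = c(0, 1))
  current <- candidates
  eliminated <- character(); rounds <- 0L
  final_imp <- NULL
  withr::with_seed(seed, {
    repeat {
      fit <- randomForest::randomForest(
        x = as.data.frame(train[current]), y = y, ntree = n_trees)
      imp <- stats::setNames(fit$importance[, "MeanDecreaseGini"],
                             rownames(fit$importance))
      if (length(current) == k) { final_imp <- imp; break }
      drop <- names(which.min(imp))
      eliminated <- c(eliminated, drop)
      current <- setdiff(current, drop)
      rounds <- rounds + 1L
    }
  })
  selected <- names(sort(final_imp, decreasing = TRUE))
  imp_tbl <- tibble(
    feature = c(selected, rev(eliminated)),
    importance = c(final_imp[selected], rep(NA_real_, length(eliminated))),
    eliminated_round = c(rep(NA_integer_, length(selected)),
                         rev(seq_along(eliminated))))
  structure(list(selected = selected, importance = imp_tbl, n_rounds = rounds),
            class = "feature_selection")
}

#' @export
print.feature_selection <- function(x, ...) {
  cat("Selected features:", paste(x$selected, collapse = ", "),
      sprintf(" (%d elimination rounds)\n", x$n_rounds))
  invisible(x)
}

#' @export
tidy.feature_selection <- function(x, ...) x$importance

svm_gamma <- function(X, gamma) {
  if (identical(gamma, "scale")) {
    v <- mean((X - mean(X))^2)  # population variance of all entries
    1 / (ncol(X) * v)
  } else gamma
}

#' Train the RBF-kernel cotton-pixel SVM
#'
#' Fits a binary support vector machine on the selected color features of
#' a labeled pixel table. No feature standardization is applied; the
#' `"scale"` bandwidth convention absorbs feature scale. Class
#' probabilities are fitted so predictions can carry a cotton probability.
#'
#' @param train Labeled feature table.
#' @param config A [classifier_config()].
#' @param features Character vector of feature columns to use; `NULL`
#'   (default) runs [select_features()] with `config$selected_k`.
#' @return A `pixel_svm` object.
#' @export
train_svm <- function(train, config = classifier_config(), features = NULL) {
  if (is.null(train$label)) stop_validation("training table must carry a 'label' column")
  if (length(unique(train$label)) < 2L)
    stop_validation("training data must contain both classes")
  selection <- NULL
  if (is.null(features)) {
    selection <- select_features(train, k = config$selected_k,
                                 seed = config$seed, n_trees = config$rf_trees)
    features <- selection$selected
  }
  missing <- setdiff(features, names(train))
  if (length(missing))
    stop_validation(sprintf("missing feature column(s): %s", paste(missing, collapse = ", ")))
  X <- as.matrix(train[features])
  g <- svm_gamma(X, config$gamma)
  fit <- withr::with_seed(config$seed,
    e1071::svm(X, factor(train$label, levels = c(0, 1)),
               kernel = "radial", cost = config$C, gamma = g,
               scale = FALSE, probability = TRUE))
  structure(list(model = fit, selected_features = features,
                 selection = selection, gamma_value = g,
                 config = config, n_train = nrow(train)),
            class = "pixel_svm")
}

#' @export
print.pixel_svm <- function(x, ...) {
  cat(sprintf("<pixel_svm> RBF SVM on %s | C = %g, gamma = %.4g | %d training pixels, %d SV\n",
              paste(x$selected_features, collapse = ", "),
              x$config$C, x$gamma_value, x$n_train, nrow(x$model$SV)))
  invisible(x)
}

#' Predict cotton / non-cotton labels for pixel rows
#'
#' @param classifier A [train_svm()] fit.
#' @param table Feature table containing the classifier's selected feature
#'   columns (background-removed pixels only).
#' @param prob If `TRUE`, return a tibble with the label and the
#'   probability of the cotton class; otherwise an integer vector of
#'   labels in `{0, 1}`.
#' @return Integer labels, or a tibble `label`/`p_cotton`.
#' @export
predict_pixels <- function(classifier, table, prob = FALSE) {
  stopifnot(inherits(classifier, "pixel_svm"))
  missing <- setdiff(classifier$selected_features, names(table))
  if (length(missing))
    stop_validation(sprintf("missing feature column(s): %s", paste(missing, collapse = ", ")))
  if (nrow(table) == 0L) {
    return(if (prob) tibble(label = integer(), p_cotton = numeric()) else integer())
  }
  X <- as.matrix(table[classifier$selected_features])
  pred <- predict(classifier$model, X, probability = prob)
  labels <- as.integer(as.character(pred))
  if (!prob) return(labels)
  p <- attr(pred, "probabilities")[, "1"]
  tibble(label = labels, p_cotton = as.numeric(p))
}

#' Persist / restore a trained classifier
#'
#' The fitted state is serialized with `saveRDS()`; a JSON sidecar
#' (`<path>.json`) records the selected features, configuration, training
#' size and a hash of the fit for provenance.
#'
#' @param classifier A `pixel_svm`.
#' @param path Destination path for the binary artifact.
#' @return `path` (`save_classifier`) or a `pixel_svm`
#'   (`load_classifier`), invisibly for the former.
#' @export
save_classifier <- function(classifier, path) {
  stopifnot(inherits(classifier, "pixel_svm"))
  saveRDS(classifier, path)
  jsonlite::write_json(
    list(format_version = 1L,
         selected_features = classifier$selected_features,
         C = classifier$config$C, gamma = classifier$gamma_value,
         seed = classifier$config$seed, n_train = classifier$n_train,
         fit_hash = rlang::hash(classifier$model)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "pixel_svm")) stop_format("not a pixel_svm artifact")
  obj
}

#' Classification metrics from predictions or raw counts
#'
#' `compute_metrics()` counts the confusion matrix of predicted versus
#' true binary labels (1 = cotton is the positive class);
#' `metrics_from_counts()` computes the same report from the four counts
#' directly. Percentages: accuracy, precision, recall, F1, and the Type I
#' (false discovery among predicted cotton) and Type II (missed cotton)
#' error rates. A metric whose denominator is zero is reported as `NA`
#' rather than raising, so batch evaluation never crashes on an empty
#' class.
#'
#' @param predicted,truth Equal-length binary label vectors.
#' @return A `classification_metrics` object.
#' @export
compute_metrics <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stop_validation("predicted and truth must have equal length")
  if (!length(predicted)) stop_validation("cannot compute metrics on zero pixels")
  p <- as.integer(predicted); y <- as.integer(truth)
  metrics_from_counts(tp = sum(p == 1 & y == 1), tn = sum(p == 0 & y == 0),
                      fp = sum(p == 1 & y == 0), fn = sum(p == 0 & y == 1))
}

#' @rdname compute_metrics
#' @param tp,tn,fp,fn Confusion-matrix counts.
#' @export
metrics_from_counts <- function(tp, tn, fp, fn) {
  total <- tp + tn + fp + fn
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  precision <- pct(tp, tp + fp)
  recall <- pct(tp, tp + fn)
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  structure(
    list(tp = tp, tn = tn, fp = fp, fn = fn,
         accuracy = pct(tp + tn, total),
         precision = precision,
         recall = recall,
         f1 = f1,
         type1_rate = pct(fp, tp + fp),
         type2_rate = pct(fn, tp + fn)),
    class = "classification_metrics")
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf("Pixels: %d (TP %d, TN %d, FP %d, FN %d)\n",
              x$tp + x$tn + x$fp + x$fn, x$tp, x$tn, x$fp, x$fn))
  cat(sprintf("accuracy %.1f%% | precision %.1f%% | recall %.1f%% | F1 %.1f%%\n",
              x$accuracy, x$precision, x$recall, x$f1))
  cat(sprintf("Type I %.1f%% | Type II %.1f%%\n", x$type1_rate, x$type2_rate))
  invisible(x)
}

#' @export
tidy.classification_metrics <- function(x, ...) {
  tibble(metric = c("accuracy", "precision", "recall", "f1",
                    "type1_rate", "type2_rate"),
         value = c(x$accuracy, x$precision, x$recall, x$f1,
                   x$type1_rate, x$type2_rate))
}

#' @export
glance.classification_metrics <- function(x, ...) {
  tibble(tp = x$tp, tn = x$tn, fp = x$fp, fn = x$fn,
         accuracy = x$accuracy, precision = x$precision, recall = x$recall,
         f1 = x$f1, type1_rate = x$type1_rate, type2_rate = x$type2_rate)
}
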