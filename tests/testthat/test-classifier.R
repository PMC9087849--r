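make_blob_table <- function(n_per_class = 60, sep = 6, seed = 1) {
  # two linearly separable blobs in (S, b); other features uninformative noise
  set.seed(seed)
  tibble::tibble(
    row = seq_len(2 * n_per_class) - 1L, col = 0L,
    R = runif(2 * n_per_class, 0, 255), G = runif(2 * n_per_class, 0, 255),
    B = runif(2 * n_per_class, 0, 255),
    H = runif(2 * n_per_class), S = c(rnorm(n_per_class, 0), rnorm(n_per_class, sep)),
    V = runif(2 * n_per_class), L = runif(2 * n_per_class, 0, 100),
    a = runif(2 * n_per_class, -20, 20),
    b = c(rnorm(n_per_class, 0), rnorm(n_per_class, sep)),
    label = rep(c(0L, 1L), each = n_per_class))
}

test_that("splitting is disjoint, exhaustive, floor-sized and seeded", {
  tbl <- make_blob_table(5)   # N = 10
  parts <- split_dataset(tbl, c(4, 1), seed = 3)
  expect_equal(nrow(parts$train), 8L)
  expect_equal(nrow(parts$test), 2L)
  expect_equal(sort(c(parts$train$row, parts$test$row)), tbl$row)

  # same seed -> identical partition; different seed -> different one
  again <- split_dataset(tbl, c(4, 1), seed = 3)
  expect_identical(parts$train$row, again$train$row)
  other <- split_dataset(tbl, c(4, 1), seed = 4)
  expect_false(identical(parts$test$row, other$test$row))

  # floor rule across a range of sizes
  for (n in c(7, 11, 34, 101)) {
    p <- split_dataset(make_blob_table(1)[rep(1, n), ], c(4, 1), seed = 1)
    expect_equal(nrow(p$train), floor(0.8 * n))
    expect_equal(nrow(p$test), n - floor(0.8 * n))
  }

  expect_error(split_dataset(tbl[0, ], c(4, 1), 1),
               class = "bollcount_validation_error")
  expect_error(split_dataset(tbl, c(4, 0), 1),
               class = "bollcount_validation_error")
})

test_that("recursive feature elimination keeps the informative features", {
  # identity case: k = 9 returns all candidates without elimination
  tbl <- make_blob_table(30)
  sel9 <- select_features(tbl, k = 9, seed = 1)
  expect_setequal(sel9$selected, c("R", "G", "B", "H", "S", "V", "L", "a", "b"))
  expect_equal(sel9$n_rounds, 0L)

  # k = 4 -> exactly 4 names after 5 elimination rounds
  sel4 <- select_features(tbl, k = 4, seed = 1)
  expect_length(sel4$selected, 4L)
  expect_equal(sel4$n_rounds, 5L)
  expect_equal(sum(!is.na(sel4$importance$eliminated_round)), 5L)

  # a single informative column is found at k = 1; verified independently
  # by exhaustive single-feature threshold classification
  set.seed(8)
  n <- 80
  tbl1 <- tibble::tibble(
    R = runif(n, 0, 255), G = runif(n, 0, 255), B = runif(n, 0, 255),
    H = runif(n), S = runif(n), V = c(runif(n / 2, 0, 0.4), runif(n / 2, 0.6, 1)),
    L = runif(n, 0, 100), a = runif(n, -10, 10), b = runif(n, -10, 10),
    label = rep(c(0L, 1L), each = n / 2))
  single_feature_acc <- vapply(c("R", "G", "B", "H", "S", "V", "L", "a", "b"),
    function(f) {
      x <- tbl1[[f]]
      max(vapply(sort(x), function(th) {
        max(mean((x > th) == tbl1$label), mean((x <= th) == tbl1$label))
      }, numeric(1)))
    }, numeric(1))
  expect_equal(names(which.max(single_feature_acc)), "V")  # oracle agrees
  expect_equal(select_features(tbl1, k = 1, seed = 2)$selected, "V")

  # determinism under a fixed seed
  expect_identical(select_features(tbl, k = 4, seed = 7)$selected,
                   select_features(tbl, k = 4, seed = 7)$selected)

  expect_error(select_features(tbl, k = 10, seed = 1),
               class = "bollcount_validation_error")
})

test_that("the RBF SVM separates separable blobs and is deterministic", {
  tbl <- make_blob_table(60, sep = 8)
  # separability oracle: a threshold on S alone classifies perfectly
  expect_true(max(tbl$S[tbl$label == 0]) < min(tbl$S[tbl$label == 1]))

  cfg <- classifier_config(seed = 5)
  fit <- train_svm(tbl, cfg, features = c("S", "b"))
  expect_equal(predict_pixels(fit, tbl), tbl$label)

  # probability output is available and sides with the label
  pr <- predict_pixels(fit, tbl, prob = TRUE)
  expect_true(all((pr$p_cotton > 0.5) == (tbl$label == 1)))

  # same data and seed -> identical predictions on a probe set
  probe <- make_blob_table(20, sep = 8, seed = 99)
  fit2 <- train_svm(tbl, cfg, features = c("S", "b"))
  expect_identical(predict_pixels(fit, probe), predict_pixels(fit2, probe))

  # irreducible conflict: identical points, opposite labels
  conf <- tbl[c(1, 1), ]; conf$label <- c(0L, 1L)
  cfit <- train_svm(dplyr::bind_rows(tbl, conf), cfg, features = c("S", "b"))
  pred_conf <- predict_pixels(cfit, conf)
  expect_lte(mean(pred_conf == conf$label), 0.5)

  # all-identical rows get all-identical labels
  same <- tbl[rep(3, 5), ]
  expect_length(unique(predict_pixels(fit, same)), 1L)

  # validation errors
  one_class <- tbl[tbl$label == 1, ]
  expect_error(train_svm(one_class, cfg), class = "bollcount_validation_error")
  expect_error(predict_pixels(fit, tbl[c("R", "G")]),
               class = "bollcount_validation_error")
  # empty prediction input
  expect_identical(predict_pixels(fit, tbl[0, ]), integer())
})

test_that("the scale-convention bandwidth matches 1/(d * Var(X))", {
  tbl <- make_blob_table(40)
  fit <- train_svm(tbl, classifier_config(seed = 1), features = c("S", "b", "H"))
  X <- as.matrix(tbl[c("S", "b", "H")])
  expect_equal(fit$gamma_value, 1 / (3 * mean((X - mean(X))^2)), tolerance = 1e-12)
})

test_that("classifier persistence round trips through the artifact + sidecar", {
  d <- withr::local_tempdir()
  tbl <- make_blob_table(40)
  fit <- train_svm(tbl, classifier_config(seed = 2), features = c("S", "b"))
  p <- file.path(d, "clf.rds")
  save_classifier(fit, p)
  expect_true(file.exists(paste0(p, ".json")))
  side <- jsonlite::read_json(paste0(p, ".json"), simplifyVector = TRUE)
  expect_equal(side$selected_features, c("S", "b"))
  back <- load_classifier(p)
  expect_identical(predict_pixels(back, tbl), predict_pixels(fit, tbl))
})

test_that("classification metrics agree with brute-force counting and stay consistent", {
  # perfect prediction
  perfect <- compute_metrics(c(1, 0, 1, 1, 0), c(1, 0, 1, 1, 0))
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$f1, 100)
  expect_equal(perfect$type1_rate, 0)
  expect_equal(perfect$type2_rate, 0)

  set.seed(21)
  for (i in 1:25) {
    n <- sample(5:60, 1)
    pred <- rbinom(n, 1, 0.5); truth <- rbinom(n, 1, 0.5)
    m <- compute_metrics(pred, truth)
    o <- brute_force_metrics(pred, truth)
    expect_equal(m$tp, o$tp); expect_equal(m$tn, o$tn)
    expect_equal(m$fp, o$fp); expect_equal(m$fn, o$fn)
    expect_equal(m$accuracy, o$accuracy)
    # accuracy invariant under swapping both labelings
    sw <- compute_metrics(1 - pred, 1 - truth)
    expect_equal(sw$accuracy, m$accuracy)
  }

  # zero-denominator cases return NA, never raise
  none_pred <- compute_metrics(c(0, 0, 0), c(0, 1, 0))
  expect_true(is.na(none_pred$precision))
  expect_true(is.na(none_pred$type1_rate))
  no_pos <- compute_metrics(c(0, 1, 0), c(0, 0, 0))
  expect_true(is.na(no_pos$recall))

  expect_error(compute_metrics(c(1, 0), c(1)),
               class = "bollcount_validation_error")
})
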